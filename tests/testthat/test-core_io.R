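test_that("packaged compound table has 32 rows with the printed ADME values", {
  comp <- pr_compounds()
  expect_equal(nrow(comp), 32L)
  expect_false(anyDuplicated(comp$compound_id) > 0)
  c30 <- comp[comp$compound_id == "C30", ]
  expect_equal(c30$name, "Ursolic acid")
  expect_equal(c30$ob_percent, 16.77)
  expect_equal(c30$caco2, 0.67)
  expect_equal(c30$dl, 0.75)
  c12 <- comp[comp$compound_id == "C12", ]
  expect_equal(unlist(c12[c("ob_percent", "caco2", "dl")], use.names = FALSE),
               c(2.69, -1.51, -2.18))
})

test_that("packaged target table has 182 unique accessions, symbols uppercased", {
  targ <- pr_targets()
  expect_equal(nrow(targ), 182L)
  expect_equal(length(unique(targ$uniprot_id)), 182L)
  expect_equal(targ$gene_symbol[targ$uniprot_id == "P35354"], "PTGS2")
  expect_true(all(targ$gene_symbol == toupper(targ$gene_symbol)))
  # calmodulin kept under its printed (obsolete) accession
  expect_equal(targ$gene_symbol[targ$uniprot_id == "P62158"], "CALM1")
})

test_that("packaged overlap table resolves entirely against the target table", {
  ovl <- pr_de_overlap()
  # the printed table carries 24 rows (its source text summarizes 23)
  expect_equal(nrow(ovl), 24L)
  expect_true(all(ovl$uniprot_id %in% pr_targets()$uniprot_id))
  expect_equal(ovl$gene_symbol[1], "ABCC2")
  expect_equal(ovl$gene_symbol[nrow(ovl)], "TPH1")
})

test_that("compound reader enforces header, numeric values and unique ids", {
  path <- write_tsv_tmp(data.frame(compound_id = "C1", name = "x",
                                   ob_percent = "abc", caco2 = 1, dl = 1))
  expect_error(read_compound_table(path), "row 1, column ob_percent")

  path2 <- write_tsv_tmp(data.frame(compound_id = c("C1", "C1"),
                                    name = c("x", "y"),
                                    ob_percent = c(1, 2), caco2 = c(0, 0),
                                    dl = c(0, 0)))
  expect_error(read_compound_table(path2), "duplicate compound_id")

  path3 <- write_tsv_tmp(data.frame(compound_id = character(0),
                                    name = character(0),
                                    ob_percent = numeric(0),
                                    caco2 = numeric(0), dl = numeric(0)))
  expect_equal(nrow(read_compound_table(path3)), 0L)

  path4 <- write_tsv_tmp(data.frame(compound_id = "C1", name = "x"))
  expect_error(read_compound_table(path4), "missing required column")

  path5 <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound_id,name,ob_percent,caco2,dl", path5)
  expect_error(read_compound_table(path5), "TSV only")
})

test_that("target reader normalizes case and rejects malformed accessions", {
  path <- write_tsv_tmp(data.frame(uniprot_id = "P35354",
                                   protein_name = "synthase",
                                   gene_symbol = "ptgs2"))
  expect_equal(read_target_table(path)$gene_symbol, "PTGS2")

  path2 <- write_tsv_tmp(data.frame(uniprot_id = "NOTANID",
                                    protein_name = "x", gene_symbol = "Y"))
  expect_error(read_target_table(path2), "malformed UniProt accession")

  path3 <- write_tsv_tmp(data.frame(uniprot_id = c("P35354", "P35354"),
                                    protein_name = c("a", "b"),
                                    gene_symbol = c("X", "Y")))
  expect_error(read_target_table(path3), "duplicate uniprot_id")
})

test_that("GMT reader parses, deduplicates and validates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("IBD\tKEGG IBD\tIL6\tTNF\tRELA", path)
  coll <- read_gmt(path)
  expect_length(coll, 1L)
  expect_setequal(coll$IBD$members, c("IL6", "TNF", "RELA"))

  writeLines("S1\tdesc\tA\ta\tB", path)  # duplicate member after uppercasing
  expect_equal(sort(read_gmt(path)$S1$members), c("A", "B"))

  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), path)
  expect_error(read_gmt(path), "duplicate set_id")

  writeLines("S1\tdesc-only", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("expression matrix reader validates shape and nonnegativity", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("t1", "t2", "t3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(mat, path)
  back <- read_expression_matrix(path)
  expect_equal(back, mat)

  writeLines(c("row_id\tt1\tt2", "g1\t1\t-1.0"), path)
  expect_error(read_expression_matrix(path), "negative expression")

  writeLines(c("row_id\tt1\tt2", "g1\t1"), path)
  expect_error(read_expression_matrix(path), "ragged|malformed")

  writeLines(c("row_id\tt1\tt1", "g1\t1\t2"), path)
  expect_error(read_expression_matrix(path), "duplicate column label")
})

test_that("network writers round-trip and emit attribute rows for every node", {
  net <- build_bipartite(data.frame(from = c("c1", "c2"), to = c("t1", "t1")),
                         c("c1", "c2"), c("t1", "t2"))
  path <- withr::local_tempfile(fileext = ".sif")
  write_network(net, path, "sif")
  lines <- readLines(path)
  expect_length(lines, 3L)  # 2 edges + isolated t2
  expect_true("t2" %in% lines)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path2, "edge_tsv", centrality = centrality_table(net))
  back <- read_network_edges(path2)
  expect_equal(back, net$edges)
  nodes <- utils::read.delim(herbnet:::node_attr_path(path2),
                             colClasses = "character")
  expect_setequal(nodes$node_id, c("c1", "c2", "t1", "t2"))
  expect_true(all(nzchar(nodes$degree)))  # attributes present, not omitted

  # attribute-less nodes: empty fields, rows still present
  write_network(net, path2, "edge_tsv")
  nodes <- utils::read.delim(herbnet:::node_attr_path(path2),
                             colClasses = "character")
  expect_equal(nrow(nodes), 4L)
  expect_true(all(nodes$degree == ""))

  path3 <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path3, "graphml")
  g <- igraph::read_graph(path3, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_equal(igraph::gsize(g), 2)

  expect_error(write_network(net, path, "gexf"), "unknown network dialect")
})
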