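toy_calls <- function() {
  mat <- matrix(c(1, 1, 4,
                  5, 5, 5,
                  9, 1, 2), nrow = 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("A", "B", "C")))
  above_average_calls(mat)
}

test_that("above-average calls use the strict mean rule over all tissues", {
  calls <- toy_calls()
  expect_equal(unname(calls$gene_means), c(2, 5, 4))
  expect_equal(unname(calls$calls["g1", ]), c(FALSE, FALSE, TRUE))
  expect_equal(unname(calls$calls["g2", ]), c(FALSE, FALSE, FALSE))  # constant
  expect_equal(unname(calls$calls["g3", ]), c(TRUE, FALSE, FALSE))
})

test_that("single-tissue matrices and unknown panel tissues are rejected", {
  m <- matrix(1:3, ncol = 1, dimnames = list(c("a", "b", "c"), "t1"))
  expect_error(above_average_calls(m), "at least two tissues")
  m2 <- matrix(1:6, ncol = 2, dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  expect_error(above_average_calls(m2, panel = "t9"), "absent from the matrix")
})

test_that("organ frequency counts, orders and sums correctly", {
  calls <- toy_calls()
  freq <- organ_frequency(calls)
  expect_equal(freq$tissue, c("A", "C", "B"))  # ties broken lexicographically
  expect_equal(freq$count, c(1L, 1L, 0L))
  expect_equal(sum(freq$count), sum(calls$calls))

  none <- above_average_calls(matrix(c(5, 5, 5, 5), 2, 2,
                                     dimnames = list(c("x", "y"), c("A", "B"))))
  expect_equal(organ_frequency(none)$count, c(0L, 0L))
})

test_that("k-organ and all-organ gene selections match brute-force recounts", {
  calls <- toy_calls()
  expect_setequal(genes_in_at_least_k_organs(calls, 1), c("g1", "g3"))
  expect_length(genes_in_at_least_k_organs(calls, 4), 0L)  # k > panel size

  # gene true everywhere in the panel is included, missing one is excluded
  mat <- matrix(c(9, 9, 0, 1,
                  9, 0, 9, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("hit", "miss"), c("A", "B", "C", "D")))
  calls2 <- above_average_calls(mat, panel = c("A", "B"))
  expect_equal(genes_in_all_panel_organs(calls2), "hit")

  set.seed(31)
  gen <- gen_expression_matrix(50, paste0("T", 1:10),
                               planted = data.frame(
                                 gene = rep(sprintf("G%d", 1:10), each = 3),
                                 tissue = rep(c("T1", "T2", "T3"), 10)),
                               boost = 8, sigma = 0.5, seed = 17)
  calls3 <- above_average_calls(gen$matrix, panel = paste0("T", 1:5))
  pc <- calls3$calls[, paste0("T", 1:5), drop = FALSE]
  for (k in 1:5) {
    manual <- sort(rownames(pc)[rowSums(pc) >= k])
    expect_equal(genes_in_at_least_k_organs(calls3, k), manual)
  }
})

test_that("panel-call counts respect the structural bounds", {
  set.seed(7)
  gen <- gen_expression_matrix(100, paste0("T", 1:20), boost = 8,
                               sigma = 0.5, seed = 7)
  calls <- above_average_calls(gen$matrix, panel = paste0("T", 1:8))
  total <- rowSums(calls$calls)
  panel <- rowSums(calls$calls[, calls$panel, drop = FALSE])
  expect_true(all(panel <= total))
  # the strict mean rule forbids a gene being above average everywhere
  expect_true(all(total <= ncol(gen$matrix) - 1))
})

test_that("planted overexpression is recovered exactly at boost 8", {
  planted <- data.frame(gene = rep(sprintf("G%d", 1:30), each = 3),
                        tissue = rep(c("T2", "T5", "T9"), 30),
                        stringsAsFactors = FALSE)
  gen <- gen_expression_matrix(200, paste0("T", 1:20), planted = planted,
                               boost = 8, sigma = 0.5, seed = 101)
  calls <- above_average_calls(gen$matrix)
  expect_true(all(calls$calls[cbind(planted$gene, planted$tissue)]))
})

test_that("probe collapsing aggregates per cell by max or mean", {
  mat <- matrix(c(1, 2,
                  3, 0,
                  7, 7), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), c("A", "B")))
  map <- c(p1 = "g", p2 = "g", p3 = "h")
  mx <- collapse_probes(mat, map, "max")
  expect_equal(unname(mx["G", ]), c(3, 2))
  expect_equal(unname(mx["H", ]), c(7, 7))
  mn <- collapse_probes(mat, map, "mean")
  expect_equal(unname(mn["G", ]), c(2, 1))
  expect_equal(attr(mx, "n_dropped"), 0L)

  # one probe per gene is the identity; unmapped probes dropped with count
  map2 <- c(p1 = "g1", p3 = "g3")
  out <- collapse_probes(mat, map2, "max")
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_error(collapse_probes(mat, character(0)), "empty probe-to-gene")

  # seeded synthetic probes equal brute-force per-cell aggregation
  set.seed(12)
  big <- matrix(rlnorm(60), nrow = 20,
                dimnames = list(sprintf("pr%d", 1:20), c("A", "B", "C")))
  map3 <- setNames(sprintf("GENE%d", rep(1:5, each = 4)), sprintf("pr%d", 1:20))
  got <- collapse_probes(big, map3, "max")
  for (g in paste0("GENE", 1:5)) {
    probes <- names(map3)[map3 == g]
    expect_equal(unname(got[toupper(g), ]),
                 unname(apply(big[probes, ], 2, max)))
  }
})

test_that("organ network edges equal the true panel calls", {
  calls <- toy_calls()
  net <- build_organ_network(calls)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("C g1", "A g3"))
  expect_false("g2" %in% net$right)  # zero-call gene excluded
  expect_setequal(net$left, c("A", "B", "C"))

  none <- above_average_calls(matrix(c(5, 5, 5, 5), 2, 2,
                                     dimnames = list(c("x", "y"), c("A", "B"))))
  expect_equal(nrow(build_organ_network(none)$edges), 0L)

  planted <- data.frame(gene = sprintf("G%d", 1:10), tissue = rep("T3", 10),
                        stringsAsFactors = FALSE)
  gen <- gen_expression_matrix(100, paste0("T", 1:12), planted = planted,
                               boost = 8, sigma = 0.5, seed = 5)
  net2 <- build_organ_network(above_average_calls(gen$matrix))
  got <- net2$edges[net2$edges$from == "T3", ]
  expect_true(all(planted$gene %in% got$to))
})
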