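# Readers and writers for the tabular and graph formats the pipeline
# consumes: TSV compound/target/edge/expression tables, GMT gene-set
# collections, and SIF / GraphML / edge-TSV network exports.
#
# Dialect is strict TSV with a mandatory header; comma-separated input is
# rejected rather than sniffed, so parsing is deterministic.

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) == 1L && grepl(",", names(df)[1], fixed = TRUE)) {
    stop_parse("'%s' looks comma-separated; this reader accepts TSV only", path)
  }
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop_parse("'%s': missing required column(s): %s",
               path, paste(missing, collapse = ", "))
  }
  df
}

parse_numeric_col <- function(df, col, path) {
  raw <- trimws(df[[col]])
  raw <- gsub("−", "-", raw)  # tolerate typographic minus
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw) & nzchar(raw))
  if (any(is.na(val))) {
    row <- if (length(bad)) bad[1] else which(is.na(val))[1]
    stop_parse("'%s': non-numeric value '%s' in row %d, column %s",
               path, raw[row], row, col)
  }
  val
}

#' Read a compound ADME table
#'
#' Parses a TSV of candidate compounds with predicted ADME values: oral
#' bioavailability (percent), Caco-2 permeability and drug-likeness.
#' Drug-likeness values are consumed as given and may be negative (the
#' packaged table contains -2.18), so no unit-interval bound is enforced.
#'
#' @param path TSV file with header columns `compound_id`, `name`,
#'   `ob_percent`, `caco2`, `dl`.
#' @return A `data.frame` with one row per compound, numeric ADME columns,
#'   input row order preserved.
#' @seealso [pr_compounds()] for the packaged 32-compound table.
#' @export
#' @examples
#' tab <- pr_compounds()
#' tab[tab$compound_id == "C30", ]
read_compound_table <- function(path) {
  df <- read_tsv_strict(path, c("compound_id", "name", "ob_percent", "caco2", "dl"))
  for (col in c("ob_percent", "caco2", "dl")) {
    df[[col]] <- parse_numeric_col(df, col, path)
  }
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup)) {
    stop_parse("'%s': duplicate compound_id: %s", path,
               paste(unique(dup), collapse = ", "))
  }
  if (any(df$ob_percent < 0)) {
    stop_parse("'%s': negative ob_percent in row %d", path,
               which(df$ob_percent < 0)[1])
  }
  rownames(df) <- NULL
  df
}

#' Read a protein target table
#'
#' Parses a TSV of protein targets keyed by UniProt accession. Gene symbols
#' are uppercased at ingest; all downstream gene matching is exact string
#' equality after that normalization.
#'
#' @param path TSV file with header columns `uniprot_id`, `protein_name`,
#'   `gene_symbol`.
#' @return A `data.frame` of targets; `uniprot_id` unique, `gene_symbol`
#'   uppercased.
#' @seealso [pr_targets()] for the packaged 182-target table.
#' @export
read_target_table <- function(path) {
  df <- read_tsv_strict(path, c("uniprot_id", "protein_name", "gene_symbol"))
  df$uniprot_id <- trimws(df$uniprot_id)
  bad <- which(!is_uniprot_accession(df$uniprot_id))
  if (length(bad)) {
    stop_parse("'%s': malformed UniProt accession '%s' in row %d",
               path, df$uniprot_id[bad[1]], bad[1])
  }
  dup <- df$uniprot_id[duplicated(df$uniprot_id)]
  if (length(dup)) {
    stop_parse("'%s': duplicate uniprot_id: %s", path,
               paste(unique(dup), collapse = ", "))
  }
  df$gene_symbol <- normalize_symbols(df$gene_symbol)
  if (any(!nzchar(df$gene_symbol))) {
    stop_parse("'%s': empty gene_symbol in row %d", path,
               which(!nzchar(df$gene_symbol))[1])
  }
  rownames(df) <- NULL
  df
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member...`.
#' Members are uppercased and deduplicated within each set.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: a named list of sets, each a list with
#'   `set_id`, `description` and `members` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_parse("'%s': line %d has %d field(s); GMT requires set_id, description and at least one member",
                 path, i, length(fields))
    }
    members <- unique(normalize_symbols(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop_parse("'%s': line %d defines an empty set", path, i)
    }
    ids[i] <- fields[1]
    sets[[i]] <- list(set_id = fields[1], description = fields[2],
                      members = members)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_parse("'%s': duplicate set_id: %s", path, paste(unique(dup), collapse = ", "))
  }
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' Construct a gene-set collection in code
#'
#' @param sets Named list mapping set_id to a character vector of member
#'   gene symbols (uppercased and deduplicated here).
#' @param descriptions Optional named character vector of descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  out <- lapply(names(sets), function(id) {
    members <- unique(normalize_symbols(sets[[id]]))
    members <- members[nzchar(members)]
    if (!length(members)) stop_parse("set '%s' is empty", id)
    list(set_id = id,
         description = unname(descriptions[id] %||% ""),
         members = members)
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_collection")
}

#' Read a gene-by-tissue (or gene-by-sample) expression matrix
#'
#' TSV with the identifier in the first column and one column per tissue or
#' sample. Intensities must be nonnegative; ragged rows and duplicate
#' column labels are rejected.
#'
#' @param path TSV file.
#' @return A numeric matrix with row and column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      quote = "", fill = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_parse("'%s': ragged or malformed table (%s)",
                                   path, conditionMessage(e)))
  if (ncol(df) < 2L) stop_parse("'%s': expected an id column plus at least one data column", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop_parse("'%s': duplicate row id '%s'", path, ids[duplicated(ids)][1])
  }
  labels <- names(df)[-1]
  if (anyDuplicated(labels)) {
    stop_parse("'%s': duplicate column label '%s'", path,
               labels[duplicated(labels)][1])
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(labels),
                dimnames = list(ids, labels))
  for (j in seq_along(labels)) {
    mat[, j] <- parse_numeric_col(df, labels[j], path)
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop_parse("'%s': negative expression value at row '%s', column '%s'",
               path, ids[idx[1]], labels[idx[2]])
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips exactly at the
#' printed precision.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output TSV path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_col = "row_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compound-target edge table
#'
#' TSV with columns `compound_id`, `uniprot_id` and optionally `source`
#' (database of origin; defaults to `"FIXTURE"`).
#'
#' @param path TSV file.
#' @param default_source Source label used when the file has no `source`
#'   column.
#' @return A `data.frame` with columns `compound_id`, `uniprot_id`, `source`.
#' @export
read_edge_table <- function(path, default_source = "FIXTURE") {
  df <- read_tsv_strict(path, c("compound_id", "uniprot_id"))
  if (!"source" %in% names(df)) df$source <- default_source
  df[c("compound_id", "uniprot_id", "source")]
}

# ---- network export -------------------------------------------------------

node_attr_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_nodes.tsv")
}

#' Write a bipartite network to disk
#'
#' Supported dialects: `"sif"` (Cytoscape simple interaction format,
#' interaction type `pp`; isolated nodes written as single-field lines),
#' `"graphml"`, and `"edge_tsv"` (two-column TSV that round-trips exactly
#' through [read_network_edges()]). A node attribute table
#' (`<path sans ext>_nodes.tsv` with partition, degree, betweenness) is
#' written alongside; nodes missing from `centrality` get empty attribute
#' fields rather than being dropped.
#'
#' @param network A [build_bipartite()] network.
#' @param path Output file path.
#' @param dialect One of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @param centrality Optional centrality table from [centrality_table()].
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("edge_tsv", "sif", "graphml"),
                          centrality = NULL) {
  stopifnot(inherits(network, "bipartite_network"))
  if (!is.character(dialect) || !all(dialect %in% c("edge_tsv", "sif", "graphml"))) {
    stop_parse("unknown network dialect: %s",
               paste(setdiff(dialect, c("edge_tsv", "sif", "graphml")), collapse = ", "))
  }
  dialect <- match.arg(dialect)
  edges <- network$edges
  if (dialect == "sif") {
    lines <- character(0)
    if (nrow(edges)) lines <- paste(edges$from, "pp", edges$to, sep = "\t")
    isolated <- setdiff(c(network$left, network$right), c(edges$from, edges$to))
    writeLines(c(lines, isolated), path)
  } else if (dialect == "edge_tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  nodes <- data.frame(node_id = c(network$left, network$right),
                      partition = c(rep("left", length(network$left)),
                                    rep("right", length(network$right))),
                      stringsAsFactors = FALSE)
  nodes$degree <- ""
  nodes$betweenness <- ""
  if (!is.null(centrality)) {
    m <- match(nodes$node_id, centrality$node_id)
    hit <- !is.na(m)
    nodes$degree[hit] <- centrality$degree[m[hit]]
    nodes$betweenness[hit] <- centrality$betweenness[m[hit]]
  }
  utils::write.table(nodes, node_attr_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge-TSV network file back as an edge data frame
#'
#' @param path File written by [write_network()] with `dialect = "edge_tsv"`.
#' @return A `data.frame` with columns `from`, `to`.
#' @export
read_network_edges <- function(path) {
  read_tsv_strict(path, c("from", "to"))[c("from", "to")]
}

# ---- packaged fixtures ----------------------------------------------------

herbnet_extdata <- function(file) {
  path <- system.file("extdata", file, package = "herbnet")
  if (!nzchar(path)) stop_parse("packaged file not found: %s", file)
  path
}

#' Packaged compound, target and overlap tables
#'
#' The published tables for *Pulsatillae Radix* versus Crohn's disease,
#' stored verbatim as printed: 32 screened compounds with ADME values
#' (`pr_compounds()`), 182 protein targets (`pr_targets()`), and the
#' printed table of targets also highly expressed in Crohn's disease
#' (`pr_de_overlap()`; 24 rows as printed, although the source text
#' summarizes them as 23). `pr_rescue_ids()` returns the 14 compounds that
#' fail the default ADME thresholds and are retained on literature
#' evidence; `pr_organ_panel()` the 17 immunity-related tissues used for
#' organ localization. Calmodulin is kept under its printed (obsolete)
#' accession P62158: provenance over currency.
#'
#' @return `pr_compounds()`, `pr_targets()`, `pr_de_overlap()`: data frames.
#'   `pr_rescue_ids()`, `pr_organ_panel()`: character vectors.
#' @export
pr_compounds <- function() {
  read_compound_table(herbnet_extdata("pr_table1_compounds.tsv"))
}

#' @rdname pr_compounds
#' @export
pr_targets <- function() {
  read_target_table(herbnet_extdata("pr_table2_targets.tsv"))
}

#' @rdname pr_compounds
#' @export
pr_de_overlap <- function() {
  read_target_table(herbnet_extdata("pr_table3_de_overlap.tsv"))
}

#' @rdname pr_compounds
#' @export
pr_rescue_ids <- function() {
  readLines(herbnet_extdata("pr_rescue_compounds.txt"), warn = FALSE)
}

#' @rdname pr_compounds
#' @export
pr_organ_panel <- function() {
  readLines(herbnet_extdata("organ_panel_17.txt"), warn = FALSE)
}
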