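# Target fishing: merge compound-target edges exported from several
# interaction databases, deduplicate with source provenance, and derive
# the unique target catalog.

#' Merge compound-target edge tables into a target catalog
#'
#' Edges from multiple database exports are merged as a set union:
#' duplicate (compound, target) pairs collapse to one edge retaining the
#' union of their source labels. The catalog records the distinct targets
#' and per-compound distinct-target counts. Interactions are treated as
#' presence/absence; affinity values are out of scope.
#'
#' @param edge_tables A list of edge data frames (columns `compound_id`,
#'   `uniprot_id`, `source`), e.g. from [read_edge_table()].
#' @param compound_ids Character vector of admissible compound ids
#'   (typically `passed` plus `rescued` from [apply_adme_filter()]); an
#'   edge referencing any other compound is an error.
#' @param target_table Target table from [read_target_table()] used to
#'   resolve accessions to gene symbols. Accessions absent from the table
#'   are retained but collected in `unresolved` with a warning.
#' @return A `target_catalog`: list with `edges` (one row per unique pair,
#'   `sources` comma-joined, `gene_symbol` joined from the target table),
#'   `targets` (unique resolved target rows), `per_compound_counts` (named
#'   integer vector) and `unresolved` (character vector of accessions).
#' @export
merge_interactions <- function(edge_tables, compound_ids, target_table) {
  if (inherits(edge_tables, "data.frame")) edge_tables <- list(edge_tables)
  stopifnot(is.list(edge_tables))
  edges <- do.call(rbind, lapply(edge_tables, function(df) {
    stopifnot(all(c("compound_id", "uniprot_id") %in% names(df)))
    if (!"source" %in% names(df)) df$source <- "FIXTURE"
    df[c("compound_id", "uniprot_id", "source")]
  }))
  if (is.null(edges) || !nrow(edges)) {
    return(structure(list(edges = data.frame(compound_id = character(0),
                                             uniprot_id = character(0),
                                             sources = character(0),
                                             gene_symbol = character(0),
                                             stringsAsFactors = FALSE),
                          targets = target_table[0, , drop = FALSE],
                          per_compound_counts = integer(0),
                          unresolved = character(0)),
                     class = "target_catalog"))
  }
  unknown <- setdiff(edges$compound_id, compound_ids)
  if (length(unknown)) {
    stop("edge(s) reference compound id(s) outside the admitted set: ",
         paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)
  }
  key <- paste(edges$compound_id, edges$uniprot_id, sep = "\r")
  split_sources <- split(edges$source, key)
  uniq <- !duplicated(key)
  merged <- edges[uniq, c("compound_id", "uniprot_id"), drop = FALSE]
  merged$sources <- vapply(
    paste(merged$compound_id, merged$uniprot_id, sep = "\r"),
    function(k) paste(sort(unique(split_sources[[k]])), collapse = ","),
    character(1), USE.NAMES = FALSE)
  ord <- order(merged$compound_id, merged$uniprot_id)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL

  m <- match(merged$uniprot_id, target_table$uniprot_id)
  unresolved <- sort(unique(merged$uniprot_id[is.na(m)]))
  if (length(unresolved)) {
    warning("accession(s) not resolved by the target table (edges retained): ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  merged$gene_symbol <- ifelse(is.na(m), NA_character_, target_table$gene_symbol[m])

  target_ids <- sort(unique(merged$uniprot_id))
  targets <- target_table[match(setdiff(target_ids, unresolved),
                                target_table$uniprot_id), , drop = FALSE]
  rownames(targets) <- NULL

  counts <- vapply(split(merged$uniprot_id, merged$compound_id),
                   function(x) length(unique(x)), integer(1))
  structure(list(edges = merged, targets = targets,
                 per_compound_counts = counts, unresolved = unresolved),
            class = "target_catalog")
}

#' @export
print.target_catalog <- function(x, ...) {
  cat(sprintf("target catalog: %d edges, %d unique targets, %d compounds\n",
              nrow(x$edges), length(unique(x$edges$uniprot_id)),
              length(x$per_compound_counts)))
  invisible(x)
}

#' Average number of unique targets per compound
#'
#' The summary statistic quoted for multi-target herbs: number of distinct
#' targets divided by number of compounds, reported to one decimal
#' (182 targets over 32 compounds gives 5.7).
#'
#' @param catalog A `target_catalog`, or a number of unique targets.
#' @param n_compounds Number of compounds; required when `catalog` is a
#'   number, otherwise taken from the catalog.
#' @return Numeric, rounded to one decimal place.
#' @export
#' @examples
#' average_targets_per_compound(182, 32)  # 5.7
average_targets_per_compound <- function(catalog, n_compounds = NULL) {
  if (inherits(catalog, "target_catalog")) {
    n_targets <- length(unique(catalog$edges$uniprot_id))
    if (is.null(n_compounds)) n_compounds <- length(catalog$per_compound_counts)
  } else {
    stopifnot(is.numeric(catalog), length(catalog) == 1L)
    n_targets <- catalog
    if (is.null(n_compounds)) {
      stop("n_compounds is required when passing a target count", call. = FALSE)
    }
  }
  if (!is.numeric(n_compounds) || n_compounds <= 0) {
    stop("cannot average over zero compounds", call. = FALSE)
  }
  round(n_targets / n_compounds, 1)
}
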