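# Over-representation analysis: upper-tail hypergeometric p-values
# (optionally the EASE one-removed variant), Benjamini-Hochberg
# correction, cutoff filtering, and pathway membership mapping.

check_hyper_args <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0)) {
    stop("hypergeometric arguments must be nonnegative integers", call. = FALSE)
  }
  if (K > N || n > N || k > min(K, n)) {
    stop(sprintf("invalid hypergeometric bounds: k=%d, K=%d, n=%d, N=%d",
                 k, K, n, N), call. = FALSE)
  }
  invisible(TRUE)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing
#' at least `k` annotated genes in a size-`n` query drawn from a universe
#' of `N` genes of which `K` carry the annotation. Computed via the
#' numerically stable distribution function (log-space internally), not by
#' naive summation.
#'
#' @param k Observed overlap count.
#' @param K Annotated genes in the universe (set size).
#' @param n Query size.
#' @param N Universe size.
#' @return A probability in (0, 1].
#' @export
#' @examples
#' hypergeometric_upper(2, 5, 2, 10)  # 10/45
hypergeometric_upper <- function(k, K, n, N) {
  check_hyper_args(k, K, n, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (one-removed hypergeometric)
#'
#' The conservative variant used by the DAVID annotation tool: the
#' upper-tail hypergeometric probability with one overlapping gene
#' removed, i.e. `hypergeometric_upper(max(k - 1, 0), K, n, N)`.
#'
#' @inheritParams hypergeometric_upper
#' @return A probability in (0, 1].
#' @export
ease_score <- function(k, K, n, N) {
  check_hyper_args(k, K, n, N)
  hypergeometric_upper(max(k - 1, 0), K, n, N)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: sort ascending, take
#' `q_i = min_{j >= i} p_j * m / j` capped at 1, return in input order.
#' Delegates to `stats::p.adjust(method = "BH")` after validating that all
#' inputs are probabilities in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each set in the collection for over-representation of the query
#' genes by the upper-tail hypergeometric test (or the EASE variant),
#' adjusts all raw p-values by Benjamini-Hochberg, then filters to sets
#' with raw p-value below `p_cutoff` (both columns are reported, since
#' published workflows are often ambiguous about which was thresholded).
#' The universe defaults to the union of all collection members; query
#' genes outside the universe are dropped with a warning count.
#' Results are invariant to gene order and to duplicated query genes.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param collection A `gene_set_collection` from [read_gmt()] or
#'   [gene_set_collection()].
#' @param universe_genes Optional character vector of background genes;
#'   defaults to the union of collection members.
#' @param p_cutoff Raw p-value threshold for reporting (default 0.01).
#' @param use_ease Use [ease_score()] instead of the standard test.
#' @return Data frame with columns `set_id`, `description`, `k`, `K`, `n`,
#'   `N`, `p_value`, `p_adjusted`, `genes` (comma-joined overlap), sorted
#'   by ascending `p_value` (ties by `set_id`).
#' @export
run_enrichment <- function(query_genes, collection, universe_genes = NULL,
                           p_cutoff = 0.01, use_ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(universe_genes)) {
    universe <- sort(unique(unlist(lapply(collection, `[[`, "members"))))
  } else {
    universe <- sort(unique(normalize_symbols(universe_genes)))
  }
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  query <- unique(normalize_symbols(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(collection, function(set) {
    members <- intersect(set$members, universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- if (use_ease) ease_score(k, K, n, N) else hypergeometric_upper(k, K, n, N)
    data.frame(set_id = set$set_id, description = set$description,
               k = k, K = K, n = n, N = N, p_value = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  res <- res[res$p_value < p_cutoff, , drop = FALSE]
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res[c("set_id", "description", "k", "K", "n", "N", "p_value",
        "p_adjusted", "genes")]
}

#' Partition target genes by pathway membership
#'
#' Splits a target gene list into the genes found on a pathway and those
#' not, after symbol normalization. Used to map filtered targets onto a
#' curated disease pathway.
#'
#' @param target_genes Character vector of gene symbols.
#' @param pathway_set Either a character vector of pathway member symbols
#'   or a single set from a `gene_set_collection`.
#' @return List with sorted character vectors `mapped` and `unmapped`.
#' @export
#' @examples
#' map_to_pathway(c("RELA", "IL6", "ACE"), c("RELA", "IL6", "TNF"))
map_to_pathway <- function(target_genes, pathway_set) {
  members <- if (is.list(pathway_set)) pathway_set$members else pathway_set
  members <- unique(normalize_symbols(members))
  targets <- unique(normalize_symbols(target_genes))
  list(mapped = sort(intersect(targets, members)),
       unmapped = sort(setdiff(targets, members)))
}
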