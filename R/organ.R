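# Organ localization of target expression: per-gene mean over all
# tissues, strict above-average calls, organ-panel frequency ranking, and
# the organ-gene bipartite network.

#' Collapse probe-level rows to gene-level rows
#'
#' Microarray atlases are probe-keyed; this aggregates probe rows mapping
#' to the same gene. Default method is `max` (conservative for presence
#' calls); `mean` is available. Probes without a mapping are dropped, with
#' the count attached as attribute `n_dropped`.
#'
#' @param matrix Numeric probe-by-tissue matrix (rownames = probe ids).
#' @param probe_to_gene Named character vector: names are probe ids,
#'   values gene symbols.
#' @param method `"max"` (default) or `"mean"`.
#' @return A gene-by-tissue numeric matrix (rownames = uppercased gene
#'   symbols).
#' @export
collapse_probes <- function(matrix, probe_to_gene, method = c("max", "mean")) {
  method <- match.arg(method)
  if (!length(probe_to_gene)) stop("empty probe-to-gene mapping", call. = FALSE)
  genes <- normalize_symbols(probe_to_gene[rownames(matrix)])
  mapped <- !is.na(genes) & nzchar(genes)
  n_dropped <- sum(!mapped)
  sub <- matrix[mapped, , drop = FALSE]
  genes <- genes[mapped]
  if (!nrow(sub)) stop("no probes map to a gene", call. = FALSE)
  agg <- if (method == "max") {
    rowsum_max(sub, genes)
  } else {
    rowsum(sub, genes) / as.vector(table(genes)[sort(unique(genes))])
  }
  structure(agg, n_dropped = n_dropped)
}

# per-group columnwise max with sorted group rownames (rowsum() analogue)
rowsum_max <- function(mat, groups) {
  ug <- sort(unique(groups))
  out <- matrix(NA_real_, nrow = length(ug), ncol = ncol(mat),
                dimnames = list(ug, colnames(mat)))
  for (g in ug) {
    out[g, ] <- apply(mat[groups == g, , drop = FALSE], 2, max)
  }
  out
}

#' Above-average expression calls per gene and tissue
#'
#' For each gene, the mean expression over ALL tissues in the matrix is
#' computed; a (gene, tissue) pair is called iff its expression strictly
#' exceeds that mean. The mean is deliberately taken over the full tissue
#' complement (e.g. 84 tissues) even when calls are later summarized over
#' a smaller organ panel. A constant-expression gene is called nowhere,
#' and no gene can be called in every tissue of the full matrix.
#'
#' @param matrix Gene-by-tissue numeric matrix with at least two tissues
#'   (with a single tissue the mean equals the value and the call is
#'   undefined).
#' @param panel Character vector of panel tissues over which downstream
#'   summaries operate; must be a subset of the matrix columns. Defaults
#'   to all columns.
#' @return An `organ_calls` object: list with `calls` (logical
#'   gene-by-tissue matrix over all tissues), `gene_means`, `panel`.
#' @seealso [pr_organ_panel()] for the packaged 17-tissue immune panel.
#' @export
above_average_calls <- function(matrix, panel = colnames(matrix)) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!nrow(matrix)) stop("empty expression matrix", call. = FALSE)
  if (ncol(matrix) < 2L) {
    stop("above-average calls need at least two tissues per gene", call. = FALSE)
  }
  missing <- setdiff(panel, colnames(matrix))
  if (length(missing)) {
    stop("panel tissue(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  means <- rowMeans(matrix)
  calls <- sweep(matrix, 1, means, `>`)
  structure(list(calls = calls, gene_means = means, panel = panel),
            class = "organ_calls")
}

panel_calls <- function(calls) {
  stopifnot(inherits(calls, "organ_calls"))
  calls$calls[, calls$panel, drop = FALSE]
}

#' Per-organ frequency of above-average calls
#'
#' Counts, for each panel tissue, the genes called above average there;
#' ordered by descending count with lexicographic tie-breaking.
#'
#' @param calls An `organ_calls` object.
#' @return Data frame with columns `tissue`, `count`.
#' @export
organ_frequency <- function(calls) {
  pc <- panel_calls(calls)
  if (!ncol(pc)) stop("empty organ panel", call. = FALSE)
  counts <- colSums(pc)
  ord <- order(-counts, colnames(pc))
  data.frame(tissue = colnames(pc)[ord], count = as.integer(counts[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes called above average in at least k panel organs
#'
#' @param calls An `organ_calls` object.
#' @param k Minimum number of panel tissues (>= 1).
#' @return Sorted character vector of gene ids.
#' @export
genes_in_at_least_k_organs <- function(calls, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  pc <- panel_calls(calls)
  sort(rownames(pc)[rowSums(pc) >= k])
}

#' Genes called above average in every panel organ
#'
#' @param calls An `organ_calls` object.
#' @return Sorted character vector of gene ids.
#' @export
genes_in_all_panel_organs <- function(calls) {
  pc <- panel_calls(calls)
  if (!ncol(pc)) stop("empty organ panel", call. = FALSE)
  sort(rownames(pc)[rowSums(pc) == ncol(pc)])
}

#' Build the organ-gene network from above-average calls
#'
#' One edge per true (gene, tissue) call within the panel. Panel organs
#' are always nodes; genes with no panel call are excluded.
#'
#' @param calls An `organ_calls` object.
#' @return A `bipartite_network` with organs on the left and genes on the
#'   right.
#' @export
build_organ_network <- function(calls) {
  pc <- panel_calls(calls)
  idx <- which(pc, arr.ind = TRUE)
  edges <- data.frame(from = colnames(pc)[idx[, "col"]],
                      to = rownames(pc)[idx[, "row"]],
                      stringsAsFactors = FALSE)
  active_genes <- sort(unique(edges$to))
  build_bipartite(edges, left_ids = colnames(pc), right_ids = active_genes)
}
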