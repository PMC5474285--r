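# GEO2R-style two-group differential expression: a moderated t statistic
# with an empirical-Bayes variance prior, top-N upregulated extraction,
# union across datasets, and intersection with a target gene set.

#' Two-group design
#'
#' @param labels Character (or factor) vector of per-sample labels, values
#'   `"control"` or `"disease"`, named by sample or aligned with the
#'   matrix columns. At least two samples per group.
#' @return A `group_design` object with `labels` and per-group counts.
#' @export
group_design <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("control", "disease"))
  if (length(bad)) {
    stop("design labels must be 'control' or 'disease'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n1 <- sum(labels == "control")
  n2 <- sum(labels == "disease")
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least two samples (control=", n1,
         ", disease=", n2, ")", call. = FALSE)
  }
  structure(list(labels = labels, n_control = n1, n_disease = n2),
            class = "group_design")
}

#' Empirical-Bayes prior for gene-wise variances
#'
#' Method-of-moments fit of the scaled-F model for gene-wise sample
#' variances (s^2 distributed as s0^2 * F(d, d0)) by matching the mean and
#' variance of log s^2, using digamma/trigamma moments of the
#' log-chi-square. The prior degrees of freedom d0 are capped at 100
#' (beyond which moderation is effectively complete); when the observed
#' spread of log-variances does not exceed the sampling floor
#' trigamma(d/2), the cap is returned. If the moments are inconsistent
#' (non-finite), the fit falls back to `d0 = 4`, `s0_sq = mean(variances)`
#' with a message.
#'
#' @param variances Gene-wise pooled sample variances (>= 10 genes; zero
#'   variances are excluded from the fit, all-zero is an error).
#' @param d Residual degrees of freedom per gene (n1 + n2 - 2).
#' @return List with elements `d0` and `s0_sq`.
#' @export
estimate_prior <- function(variances, d) {
  stopifnot(is.numeric(variances), is.numeric(d), length(d) == 1L, d >= 1)
  if (length(variances) < 10L) {
    stop("prior estimation needs at least 10 genes", call. = FALSE)
  }
  if (all(variances <= 0)) stop("all gene variances are zero", call. = FALSE)
  v <- variances[variances > 0]
  z <- log(v)
  # E[log s^2] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
  # Var[log s^2] = trigamma(d/2) + trigamma(d0/2)
  evar <- stats::var(z) - trigamma(d / 2)
  cap <- 100
  if (!is.finite(evar) || !is.finite(mean(z))) {
    message("variance moments inconsistent; falling back to d0 = 4, s0_sq = mean variance")
    return(list(d0 = 4, s0_sq = mean(variances)))
  }
  if (stats::var(z) < 1e-10) {
    # literally constant variances carry no sampling noise to correct for:
    # maximal moderation, prior equal to the common value
    return(list(d0 = cap, s0_sq = exp(mean(z))))
  }
  if (evar <= trigamma(cap / 2)) {
    d0 <- cap
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > cap) d0 <- cap
  }
  s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  if (!is.finite(s0_sq) || s0_sq <= 0) {
    message("variance moments inconsistent; falling back to d0 = 4, s0_sq = mean variance")
    return(list(d0 = 4, s0_sq = mean(variances)))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x by Newton iteration on the monotone decreasing
# trigamma (x > 0).
trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  y <- 0.5 + 1 / x  # asymptotic start: trigamma(y) ~ 1/y for large y
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Moderated two-sample t test per gene
#'
#' For each gene, the pooled two-sample variance s_g^2 (d = n1 + n2 - 2
#' degrees of freedom) is shrunk toward the prior value s0_sq:
#' \deqn{\tilde{s}_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}}
#' and the statistic is the group-mean difference (disease minus control)
#' divided by \eqn{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}}, with two-sided
#' p-values from a t distribution on d0 + d degrees of freedom. With
#' `d0 = 0` this is exactly the ordinary pooled t test. When `d0` and
#' `s0_sq` are omitted they are estimated from the data with
#' [estimate_prior()].
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @param design A [group_design()] aligned with the matrix columns.
#' @param d0 Prior degrees of freedom (>= 0, `Inf` allowed: the variance
#'   collapses to the prior); `NULL` to estimate.
#' @param s0_sq Prior variance (> 0); `NULL` to estimate.
#' @return Data frame with columns `gene`, `mean_diff`, `t_stat`,
#'   `p_value`, `rank` (1-based, by ascending p-value, ties by descending
#'   |t| then gene id), in input gene order.
#' @export
moderated_t <- function(matrix, design, d0 = NULL, s0_sq = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            inherits(design, "group_design"))
  if (ncol(matrix) != length(design$labels)) {
    stop("design has ", length(design$labels), " samples but matrix has ",
         ncol(matrix), " columns", call. = FALSE)
  }
  ctrl <- matrix[, design$labels == "control", drop = FALSE]
  dis <- matrix[, design$labels == "disease", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(dis)
  d <- n1 + n2 - 2
  m1 <- rowMeans(ctrl)
  m2 <- rowMeans(dis)
  v1 <- apply(ctrl, 1, stats::var)
  v2 <- apply(dis, 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (is.null(d0) || is.null(s0_sq)) {
    prior <- estimate_prior(s2, d)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }
  stopifnot(is.numeric(d0), d0 >= 0, is.numeric(s0_sq), s0_sq > 0)
  if (d0 == 0 && any(s2 == 0)) {
    stop("zero pooled variance with d0 = 0 for gene(s): ",
         paste(utils::head(rownames(matrix)[s2 == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  diff <- m2 - m1
  t_stat <- diff / se
  p <- 2 * stats::pt(abs(t_stat), df = d0 + d, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- data.frame(gene = rownames(matrix) %||% as.character(seq_len(nrow(matrix))),
                    mean_diff = unname(diff), t_stat = unname(t_stat),
                    p_value = unname(p), stringsAsFactors = FALSE)
  ord <- order(res$p_value, -abs(res$t_stat), res$gene)
  res$rank <- integer(nrow(res))
  res$rank[ord] <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Top upregulated genes
#'
#' Restricts to genes more highly expressed in the disease group
#' (`mean_diff > 0`), orders by ascending p-value (ties by descending |t|,
#' then gene id), and truncates to `n`. `direction = "both"` skips the
#' positive-direction filter. Fewer than `n` qualifying genes yield a
#' shorter list. The result is invariant to the input row order.
#'
#' @param results Data frame from [moderated_t()].
#' @param n Maximum list length (>= 1); conventionally 250.
#' @param direction `"up"` (default) or `"both"`.
#' @return Character vector of gene ids in rank order.
#' @export
top_upregulated <- function(results, n = 250, direction = c("up", "both")) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  direction <- match.arg(direction)
  res <- results
  if (direction == "up") res <- res[res$mean_diff > 0, , drop = FALSE]
  res <- res[order(res$p_value, -abs(res$t_stat), res$gene), , drop = FALSE]
  utils::head(res$gene, n)
}

#' Union of gene lists with deduplication
#'
#' Set union after symbol normalization: the deduplicated pool of
#' per-dataset top gene lists.
#'
#' @param lists A list of character vectors.
#' @return Sorted character vector of unique symbols.
#' @export
union_dedupe <- function(lists) {
  if (!length(lists)) return(character(0))
  sort(unique(normalize_symbols(unlist(lists, use.names = FALSE))))
}

#' Intersect a differential-expression union with the target gene set
#'
#' The genes both differentially expressed and targeted by the compound
#' set. When a target table is supplied, the matching annotation rows
#' (UniProt accession, protein name) are joined onto the result.
#'
#' @param de_union Character vector of differentially expressed gene
#'   symbols (e.g. from [union_dedupe()]).
#' @param target_genes Character vector of target gene symbols.
#' @param target_table Optional table from [read_target_table()] for
#'   annotation.
#' @return Sorted character vector of common symbols, or an annotated
#'   data frame when `target_table` is given.
#' @export
intersect_targets <- function(de_union, target_genes, target_table = NULL) {
  common <- sort(intersect(normalize_symbols(de_union),
                           normalize_symbols(target_genes)))
  if (is.null(target_table)) return(common)
  ann <- target_table[match(common, target_table$gene_symbol), , drop = FALSE]
  out <- data.frame(gene_symbol = common,
                    uniprot_id = ann$uniprot_id,
                    protein_name = ann$protein_name,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
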