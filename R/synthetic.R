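# Seeded synthetic-data generators with recorded ground truth. Every
# generator is a pure function of its arguments including the seed, and
# forces threshold sidedness by construction rather than sampling and
# hoping, so planted counts are exact and tests never flake.

truth <- function(seed, ...) {
  structure(list(..., seed = seed), class = "ground_truth")
}

#' Generate a synthetic compound ADME table with known pass fraction
#'
#' Exactly `round(n * frac_pass)` compounds satisfy the default ADME
#' thresholds by construction. Values are drawn from realistic marginals
#' (log-normal oral bioavailability, normal Caco-2 with mean 0.5 and sd
#' 0.8, uniform drug-likeness on \[-0.5, 0.95\]) and then forced to the
#' intended side of each threshold; non-passing compounds violate a
#' random nonempty subset of the three criteria.
#'
#' @param n Number of compounds (0 gives an empty table and truth).
#' @param frac_pass Fraction in \[0, 1\] passing the default thresholds.
#' @param seed Integer RNG seed.
#' @param thresholds [filter_thresholds()] the pass fraction refers to.
#' @return List with `compounds` (a compound table) and `truth` (a
#'   `ground_truth` with `pass_ids`).
#' @export
gen_compound_table <- function(n, frac_pass, seed,
                               thresholds = filter_thresholds()) {
  stopifnot(n >= 0, frac_pass >= 0, frac_pass <= 1)
  ids <- if (n > 0) sprintf("S%03d", seq_len(n)) else character(0)
  if (n == 0) {
    tab <- data.frame(compound_id = character(0), name = character(0),
                      ob_percent = numeric(0), caco2 = numeric(0),
                      dl = numeric(0), stringsAsFactors = FALSE)
    return(list(compounds = tab, truth = truth(seed, pass_ids = character(0))))
  }
  n_pass <- round(n * frac_pass)
  with_seed(seed, {
    pass_ids <- sort(sample(ids, n_pass))
    ob <- stats::rlnorm(n, meanlog = log(20), sdlog = 0.7)
    caco2 <- stats::rnorm(n, mean = 0.5, sd = 0.8)
    dl <- stats::runif(n, -0.5, 0.95)
    force_above <- function(v, thr) ifelse(v >= thr, v, thr + (thr - v) + 0.01)
    force_below <- function(v, thr) ifelse(v < thr, v, thr - (v - thr) - 0.01)
    is_pass <- ids %in% pass_ids
    ob[is_pass] <- force_above(ob[is_pass], thresholds$ob_min)
    caco2[is_pass] <- force_above(caco2[is_pass], thresholds$caco2_min)
    dl[is_pass] <- force_above(dl[is_pass], thresholds$dl_min)
    for (i in which(!is_pass)) {
      viol <- sample(c("ob", "caco2", "dl"), sample(3, 1))
      ob[i] <- if ("ob" %in% viol) force_below(ob[i], thresholds$ob_min) else
        force_above(ob[i], thresholds$ob_min)
      caco2[i] <- if ("caco2" %in% viol) force_below(caco2[i], thresholds$caco2_min) else
        force_above(caco2[i], thresholds$caco2_min)
      dl[i] <- if ("dl" %in% viol) force_below(dl[i], thresholds$dl_min) else
        force_above(dl[i], thresholds$dl_min)
    }
    ob <- pmax(ob, 0)  # OB is a percentage, nonnegative
    tab <- data.frame(compound_id = ids,
                      name = paste0("synthetic compound ", seq_len(n)),
                      ob_percent = ob, caco2 = caco2, dl = dl,
                      stringsAsFactors = FALSE)
    list(compounds = tab, truth = truth(seed, pass_ids = pass_ids))
  })
}

#' Generate synthetic compound-target edge tables across three sources
#'
#' Per-compound target counts are drawn from a shifted geometric
#' distribution with the given mean (heterogeneous degrees, as in
#' multi-database target fishing). Each unique edge is assigned a primary
#' source among `TCMSP`, `SEA`, `BINDINGDB`; a fraction `dup_frac` is
#' additionally copied into a second source, so merging must deduplicate.
#' The truth records the deduplicated pair set.
#'
#' @param compound_ids Character vector of compound ids.
#' @param n_targets Number of synthetic targets (accessions are generated
#'   in the UniProt style along with a resolving target table).
#' @param mean_degree Mean targets per compound (>= 1, <= n_targets).
#' @param seed Integer RNG seed.
#' @param dup_frac Fraction of edges duplicated into a second source
#'   (default 0.3).
#' @return List with `edge_tables` (list of three data frames),
#'   `target_table`, and `truth` (with `planted_edges`, a data frame of
#'   unique compound/uniprot pairs).
#' @export
gen_interaction_edges <- function(compound_ids, n_targets, mean_degree, seed,
                                  dup_frac = 0.3) {
  stopifnot(length(compound_ids) >= 1, mean_degree >= 1,
            dup_frac >= 0, dup_frac <= 1)
  if (n_targets < mean_degree) {
    stop("n_targets must be at least mean_degree", call. = FALSE)
  }
  accessions <- sprintf("P%05d", seq_len(n_targets))
  target_table <- data.frame(
    uniprot_id = accessions,
    protein_name = paste0("synthetic protein ", seq_len(n_targets)),
    gene_symbol = sprintf("SYNG%d", seq_len(n_targets)),
    stringsAsFactors = FALSE)
  sources <- c("TCMSP", "SEA", "BINDINGDB")
  with_seed(seed, {
    degs <- pmin(1L + stats::rgeom(length(compound_ids),
                                   prob = 1 / mean_degree), n_targets)
    pairs <- do.call(rbind, lapply(seq_along(compound_ids), function(i) {
      data.frame(compound_id = compound_ids[i],
                 uniprot_id = sample(accessions, degs[i]),
                 stringsAsFactors = FALSE)
    }))
    pairs <- pairs[order(pairs$compound_id, pairs$uniprot_id), , drop = FALSE]
    rownames(pairs) <- NULL
    primary <- sample(sources, nrow(pairs), replace = TRUE)
    dup <- stats::runif(nrow(pairs)) < dup_frac
    second <- vapply(primary, function(s) sample(setdiff(sources, s), 1),
                     character(1), USE.NAMES = FALSE)
    tables <- lapply(sources, function(s) {
      take <- primary == s | (dup & second == s)
      cbind(pairs[take, , drop = FALSE],
            source = rep(s, sum(take)), stringsAsFactors = FALSE)
    })
    names(tables) <- sources
    list(edge_tables = tables, target_table = target_table,
         truth = truth(seed, planted_edges = pairs))
  })
}

#' Generate a tissue expression matrix with planted overexpression
#'
#' Baseline intensities are log-normal (meanlog 5, sdlog `sigma`) per
#' cell; each planted (gene, tissue) cell is multiplied by `boost`. At the
#' default boost of 8 on a sigma = 0.5 baseline, planted calls are
#' recovered exactly by [above_average_calls()].
#'
#' @param n_genes Number of genes (ids `G1...`).
#' @param tissues Character vector of tissue labels.
#' @param planted Data frame with columns `gene`, `tissue` of cells to
#'   boost (may be empty).
#' @param boost Multiplicative boost (> 1).
#' @param sigma Log-scale baseline sd.
#' @param seed Integer RNG seed.
#' @return List with `matrix` and `truth` (with `planted_calls`).
#' @export
gen_expression_matrix <- function(n_genes, tissues, planted = NULL,
                                  boost = 8, sigma = 0.5, seed = 1) {
  stopifnot(n_genes >= 1, length(tissues) >= 2, boost > 1, sigma > 0)
  genes <- sprintf("G%d", seq_len(n_genes))
  if (is.null(planted)) {
    planted <- data.frame(gene = character(0), tissue = character(0),
                          stringsAsFactors = FALSE)
  }
  bad_g <- setdiff(planted$gene, genes)
  bad_t <- setdiff(planted$tissue, tissues)
  if (length(bad_g) || length(bad_t)) {
    stop("planted cells reference unknown gene/tissue: ",
         paste(c(bad_g, bad_t), collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    mat <- matrix(stats::rlnorm(n_genes * length(tissues), meanlog = 5,
                                sdlog = sigma),
                  nrow = n_genes, ncol = length(tissues),
                  dimnames = list(genes, tissues))
    if (nrow(planted)) {
      mat[cbind(planted$gene, planted$tissue)] <-
        mat[cbind(planted$gene, planted$tissue)] * boost
    }
    list(matrix = mat, truth = truth(seed, planted_calls = planted))
  })
}

#' Generate a two-group expression matrix with planted effects
#'
#' Control cells are standard normal; disease-group cells of the planted
#' genes are shifted upward by `effect_sd` (in units of the unit noise
#' sd). Sample labels follow the `control`/`disease` convention of
#' [group_design()].
#'
#' @param n_genes Number of genes (ids `G1...`).
#' @param n_per_group Samples per group (>= 2).
#' @param de_genes Character vector of planted upregulated gene ids
#'   (subset of the gene ids).
#' @param effect_sd Mean shift in the disease group (>= 0).
#' @param seed Integer RNG seed.
#' @return List with `matrix`, `design` (a [group_design()]) and `truth`
#'   (with `planted_de_genes`).
#' @export
gen_two_group_matrix <- function(n_genes, n_per_group, de_genes = character(0),
                                 effect_sd = 3, seed = 1) {
  stopifnot(n_genes >= 1, effect_sd >= 0)
  if (n_per_group < 2) stop("n_per_group must be at least 2", call. = FALSE)
  genes <- sprintf("G%d", seq_len(n_genes))
  bad <- setdiff(de_genes, genes)
  if (length(bad)) {
    stop("de_genes outside the gene set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- rep(c("control", "disease"), each = n_per_group)
  with_seed(seed, {
    mat <- matrix(stats::rnorm(n_genes * 2 * n_per_group),
                  nrow = n_genes, ncol = 2 * n_per_group,
                  dimnames = list(genes, paste0("s", seq_len(2 * n_per_group))))
    if (length(de_genes)) {
      mat[de_genes, labels == "disease"] <-
        mat[de_genes, labels == "disease"] + effect_sd
    }
    list(matrix = mat, design = group_design(labels),
         truth = truth(seed, planted_de_genes = sort(de_genes)))
  })
}
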