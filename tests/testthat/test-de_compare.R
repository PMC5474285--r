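test_that("moderated t with d0 = 0 equals the ordinary pooled t", {
  for (seed in c(1, 2, 3)) {
    gen <- gen_two_group_matrix(50, 6, de_genes = sprintf("G%d", 1:5),
                                effect_sd = 2, seed = seed)
    res <- moderated_t(gen$matrix, gen$design, d0 = 0, s0_sq = 1)
    for (g in sample(rownames(gen$matrix), 10)) {
      ctrl <- gen$matrix[g, gen$design$labels == "control"]
      dis <- gen$matrix[g, gen$design$labels == "disease"]
      tt <- stats::t.test(dis, ctrl, var.equal = TRUE)
      row <- res[res$gene == g, ]
      expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
      expect_equal(row$mean_diff, mean(dis) - mean(ctrl), tolerance = 1e-12)
    }
  }
})

test_that("large d0 drives every posterior variance to the prior", {
  gen <- gen_two_group_matrix(100, 8, seed = 4)
  s0 <- 2.5
  res <- moderated_t(gen$matrix, gen$design, d0 = 1e6, s0_sq = s0)
  n <- 8
  se_expected <- sqrt(s0 * (2 / n))
  implied_s2 <- (res$mean_diff / res$t_stat)^2 / (2 / n)
  expect_true(all(abs(implied_s2 - s0) / s0 < 1e-3))
})

test_that("planted genes at 3-sigma effect occupy the top ranks exactly", {
  planted <- sprintf("G%d", 1:20)
  gen <- gen_two_group_matrix(200, 10, de_genes = planted, effect_sd = 3,
                              seed = 42)
  res <- moderated_t(gen$matrix, gen$design)
  top <- top_upregulated(res, 20)
  expect_setequal(top, planted)
  # ranks are a permutation of 1..G
  expect_setequal(res$rank, seq_len(nrow(res)))
})

test_that("top list respects direction, truncation and row-order invariance", {
  gen <- gen_two_group_matrix(50, 5, de_genes = c("G1", "G2", "G3"),
                              effect_sd = 5, seed = 9)
  res <- moderated_t(gen$matrix, gen$design)
  expect_length(top_upregulated(res, 250),
                sum(res$mean_diff > 0))  # shorter list when fewer positives
  shuffled <- res[sample(nrow(res)), ]
  expect_equal(top_upregulated(res, 10), top_upregulated(shuffled, 10))
  allneg <- res
  allneg$mean_diff <- -abs(allneg$mean_diff)
  expect_length(top_upregulated(allneg, 10), 0L)
  expect_gt(length(top_upregulated(allneg, 10, direction = "both")), 0L)
})

test_that("prior estimation recovers known parameters and handles degenerate input", {
  # scaled-F model with known truth: s2 = s0^2 * d0/chi2_d0 * chi2_d/d
  set.seed(77)
  d <- 8; d0_true <- 4; s0_true <- 1
  sigma2 <- s0_true * d0_true / rchisq(5000, d0_true)
  s2 <- sigma2 * rchisq(5000, d) / d
  fit <- estimate_prior(s2, d)
  expect_lt(abs(fit$d0 - d0_true), 1)
  expect_lt(abs(fit$s0_sq - s0_true) / s0_true, 0.10)

  # all-equal variances: maximal moderation, prior near the common value
  fit2 <- estimate_prior(rep(3, 100), d = 8)
  expect_equal(fit2$d0, 100)
  expect_equal(fit2$s0_sq, 3, tolerance = 0.02)

  expect_error(estimate_prior(rep(1, 5), 8), "at least 10 genes")
  expect_error(estimate_prior(rep(0, 20), 8), "all gene variances are zero")
})

test_that("moderated statistics agree with limma on the same prior", {
  skip_if_not_installed("limma")
  gen <- gen_two_group_matrix(300, 8, de_genes = sprintf("G%d", 1:30),
                              effect_sd = 2, seed = 15)
  design <- cbind(Intercept = 1,
                  disease = as.integer(gen$design$labels == "disease"))
  fit <- limma::eBayes(limma::lmFit(gen$matrix, design))
  mine <- moderated_t(gen$matrix, gen$design,
                      d0 = fit$df.prior, s0_sq = fit$s2.prior)
  expect_equal(mine$t_stat, unname(fit$t[, "disease"]), tolerance = 1e-8)
  # limma caps its total df at the aggregate residual df when the prior
  # df is infinite; we use d0 + d, so p-values agree only approximately
  expect_equal(mine$p_value, unname(fit$p.value[, "disease"]),
               tolerance = 0.02)
  # and the in-package prior fit lands near limma's
  s2 <- fit$sigma^2
  prior <- estimate_prior(s2, d = 2 * 8 - 2)
  expect_equal(prior$s0_sq, fit$s2.prior, tolerance = 0.05)
})

test_that("union deduplicates across lists; intersections recover planted overlaps", {
  expect_equal(union_dedupe(list(c("A", "B"), c("B", "C"))), c("A", "B", "C"))
  expect_length(union_dedupe(rep(list(character(0)), 6)), 0L)

  # six seeded top lists with constructed overlaps: union equals the
  # brute-force set union
  set.seed(55)
  pool <- sprintf("GENE%03d", 1:400)
  lists <- lapply(1:6, function(i) sample(pool, 100))
  expect_equal(union_dedupe(lists), sort(unique(unlist(lists))))

  expect_equal(intersect_targets(c("IL6", "FOS"), c("IL6", "TNF")), "IL6")
  expect_length(intersect_targets(c("A"), c("B")), 0L)

  # planted overlap sizes {0, 5, 23} recovered exactly
  targets <- sprintf("TRG%02d", 1:60)
  for (m in c(0, 5, 23)) {
    overlap <- if (m > 0) targets[seq_len(m)] else character(0)
    de <- c(overlap, sprintf("OTH%03d", 1:150))
    expect_length(intersect_targets(de, targets), m)
    expect_setequal(intersect_targets(de, targets), overlap)
  }
})

test_that("target-table annotation joins onto the intersection", {
  targ <- pr_targets()
  out <- intersect_targets(c("PTGS2", "IL6", "NOVEL1"),
                           targ$gene_symbol, targ)
  expect_equal(out$gene_symbol, c("IL6", "PTGS2"))
  expect_equal(out$uniprot_id, c("P05231", "P35354"))
})

test_that("group design enforces labels and minimum sizes", {
  expect_error(group_design(c("control", "case")), "must be 'control' or 'disease'")
  expect_error(group_design(c("control", "disease", "disease")),
               "at least two samples")
  d <- group_design(rep(c("control", "disease"), each = 3))
  expect_equal(d$n_control, 3L)
  expect_equal(d$n_disease, 3L)
})
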