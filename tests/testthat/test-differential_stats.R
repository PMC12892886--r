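test_that("log2_fold_change is the geometric-mean ratio on log2 scale", {
  expect_equal(log2_fold_change(c(2, 8), c(1, 1)), 2)
  expect_equal(log2_fold_change(c(1, 1), c(2, 8)), -2)        # antisymmetry
  expect_equal(log2_fold_change(c(4, 4, 4), c(4, 4, 4)), 0)
  expect_equal(log2_fold_change(c(2, NA, 8), c(1, 1, NA)), 2) # missing skipped
  expect_true(is.na(log2_fold_change(c(NA, NA), c(1, 2))))    # untestable
  # zeros hit the configured floor instead of -Inf
  expect_equal(log2_fold_change(c(0, 4), c(4, 4), floor = 1), -1)
})

test_that("pairwise_ttest matches the closed-form pooled-variance oracle", {
  sheet <- data.frame(
    sample_id = c(paste0("a", 1:3), paste0("b", 1:3), "pool"),
    group = c(rep("WT", 3), rep("mdx_saline", 3), "POOL"),
    replicate = c(1:3, 1:3, NA), plex_id = "plex1",
    channel_label = TMT <- c("126", "127N", "127C", "128N", "128C", "129N", "129C"),
    is_pool = c(rep(FALSE, 6), TRUE)
  )
  # log2 abundances A = [1,2,3], B = [2,3,4] -> t = -1.2247, df = 4
  vals <- matrix(2^c(1, 2, 3, 2, 3, 4, 1), nrow = 1,
                 dimnames = list("p1", sheet$sample_id))
  filler <- matrix(vals + 1e6, nrow = 1, dimnames = list("p2", sheet$sample_id))
  am <- abundance_matrix(rbind(vals, filler), state = "bridge_scaled")
  p <- pairwise_ttest(am, sheet, c("WT", "mdx_saline"))
  tstat <- -1 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(unname(p["p1"]), 2 * pt(tstat, df = 4), tolerance = 1e-12)
  expect_equal(unname(p["p1"]), 0.2879, tolerance = 1e-3)

  # identical groups -> p = 1 by convention
  same <- matrix(2^rep(1, 7), nrow = 2, ncol = 7, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), sheet$sample_id))
  am2 <- abundance_matrix(same, state = "bridge_scaled")
  expect_equal(unname(pairwise_ttest(am2, sheet, c("WT", "mdx_saline"))["p1"]), 1)
  # zero pooled variance with different means -> p = 0
  sep <- matrix(rep(2^c(1, 1, 1, 2, 2, 2, 1), each = 2), nrow = 2,
                dimnames = list(c("p1", "p2"), sheet$sample_id))
  am3 <- abundance_matrix(sep, state = "bridge_scaled")
  expect_equal(unname(pairwise_ttest(am3, sheet, c("WT", "mdx_saline"))["p1"]), 0)
  # a missing value reduces the degrees of freedom, < 2 makes it untestable
  miss <- am
  miss$values["p1", "b3"] <- NA
  pm <- pairwise_ttest(miss, sheet, c("WT", "mdx_saline"))
  expect_false(is.na(pm["p1"]))
  miss$values["p1", c("b2", "b3")] <- NA
  expect_true(is.na(pairwise_ttest(miss, sheet, c("WT", "mdx_saline"))["p1"]))
})

test_that("bh_adjust matches the brute-force step-up definition", {
  expect_equal(unname(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05))), rep(0.05, 5))
  expect_equal(unname(bh_adjust(0.037)), 0.037)             # single p: q = p
  expect_equal(unname(bh_adjust(c(0.001, 0.5))), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "restoromics_validation_error")

  set.seed(21)
  for (rep in 1:200) {
    p <- runif(sample(1:100, 1L))^sample(1:3, 1L)
    q <- bh_adjust(p)
    expect_identical(unname(q), bh_oracle(p))  # same step-up arithmetic, bitwise
    # monotonicity properties (up to one ulp of the p*m/j rounding)
    expect_true(all(q >= p * (1 - 1e-12)))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  # NA entries are excluded from m and passed through
  p <- c(0.01, NA, 0.02)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[-2], bh_oracle(p[-2]))
})

test_that("call_deps applies both gates with significant boundaries", {
  cfg <- run_config()
  expect_equal(unname(call_deps(1.5, 0.01, cfg)), "up")
  expect_equal(unname(call_deps(0.5, 0.001, cfg)), "ns")   # fails fold-change gate
  expect_equal(unname(call_deps(-2, 0.04, cfg)), "down")
  expect_equal(unname(call_deps(1.0, 0.05, cfg)), "up")    # exact boundary significant
  expect_equal(unname(call_deps(2, 0.051, cfg)), "ns")
  expect_equal(unname(call_deps(NA, 0.01, cfg)), "untestable")
})

test_that("dep_table is antisymmetric under contrast reversal", {
  sim <- simulate_study(quiet_cfg(n_proteins = 80, noise_cv = 0.2,
                                  frac_up = 0.2, frac_down = 0.1, seed = 22))
  am <- bridge_scale(normalize_within_plex(sim$matrix, sim$sheet), sim$sheet)
  ab <- dep_table(am, sim$sheet, c("mdx_saline", "WT"))
  ba <- dep_table(am, sim$sheet, c("WT", "mdx_saline"))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_raw, ba$p_raw)
  expect_equal(ab$q, ba$q)
  expect_equal(ab$status == "up", ba$status == "down")
  expect_equal(dep_reverse(ab)$status, ba$status)
  expect_equal(dep_reverse(ab)$log2fc, ba$log2fc)
})

test_that("planted DEPs are recovered with high power", {
  sim <- simulate_study(quiet_cfg(n_proteins = 500, noise_cv = 0.2,
                                  frac_up = 0.1, frac_down = 0.1,
                                  effect_log2 = 2, seed = 23))
  am <- bridge_scale(normalize_within_plex(sim$matrix, sim$sheet), sim$sheet)
  dep <- dep_table(am, sim$sheet, c("mdx_saline", "WT"))
  truth <- sim$truth$direction[dep$protein]
  called_up <- dep$status == "up"
  expect_gte(mean(called_up[truth == "up"]), 0.95)
  expect_gte(mean(dep$status[truth == "down"] == "down"), 0.95)
  expect_lte(mean(dep$status[truth == "null"] != "ns"), 0.02)
})

test_that("anova_tukey reduces to the t-test for two groups and handles degeneracy", {
  sheet <- tiny_sheet()
  am <- tiny_matrix(sheet, n = 10, seed = 24)
  res <- anova_tukey(am, sheet, groups = c("WT", "mdx_saline"))
  p_t <- pairwise_ttest(am, sheet, c("WT", "mdx_saline"))
  # two-group one-way ANOVA: F = t^2, identical p
  expect_equal(res$p_omnibus, unname(p_t), tolerance = 1e-12)

  # identical groups -> F = 0, p = 1
  flat <- abundance_matrix(matrix(5, nrow = 2, ncol = nrow(sheet),
                                  dimnames = list(c("a", "b"), sheet$sample_id)))
  resf <- anova_tukey(flat, sheet)
  expect_equal(resf$F, c(0, 0))
  expect_equal(resf$p_omnibus, c(1, 1))
  expect_true(all(resf[, startsWith(names(resf), "tukey_")] == 1))
})

test_that("anova_tukey flags only truly separated pairs (Monte Carlo)", {
  # 3 groups n = 4, means (0, 0, 2) sd 0.5: Tukey at alpha = .05 should hit
  # only pairs involving group 3 in >= 95% of simulations
  set.seed(25)
  n_sim <- 200
  hits_13 <- hits_23 <- fp_12 <- 0
  sheet <- data.frame(
    sample_id = c(sprintf("g%d_%d", rep(1:3, each = 4), 1:4), "pool"),
    group = c(rep(c("WT", "mdx_saline", "uDys"), each = 4), "POOL"),
    replicate = c(rep(1:4, 3), NA), plex_id = "plex1",
    channel_label = TMTPRO <- c("126", "127N", "127C", "128N", "128C", "129N",
                                "129C", "130N", "130C", "131N", "131C", "132N", "132C"),
    is_pool = c(rep(FALSE, 12), TRUE)
  )
  for (i in seq_len(n_sim)) {
    y <- c(rnorm(4, 0, 0.5), rnorm(4, 0, 0.5), rnorm(4, 2, 0.5), 0)
    am <- abundance_matrix(matrix(2^y, nrow = 1, dimnames = list("p", sheet$sample_id)) + 0,
                           state = "raw")
    am$values <- rbind(p = am$values[1, ], q = am$values[1, ] * 2)
    res <- anova_tukey(am, sheet, groups = c("WT", "mdx_saline", "uDys"))[1, ]
    hits_13 <- hits_13 + (res$tukey_WT_vs_uDys <= 0.05)
    hits_23 <- hits_23 + (res$tukey_mdx_saline_vs_uDys <= 0.05)
    fp_12 <- fp_12 + (res$tukey_WT_vs_mdx_saline <= 0.05)
  }
  expect_gte(hits_13 / n_sim, 0.95)
  expect_gte(hits_23 / n_sim, 0.95)
  expect_lte(fp_12 / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("volcano_table is plot-ready", {
  sim <- simulate_study(quiet_cfg(n_proteins = 30, noise_cv = 0.2, seed = 26))
  am <- bridge_scale(normalize_within_plex(sim$matrix, sim$sheet), sim$sheet)
  dep <- dep_table(am, sim$sheet, c("mdx_saline", "WT"))
  dep$q[1] <- 0.05
  vol <- volcano_table(dep)
  expect_equal(vol$neg_log10_q[1], -log10(0.05))  # ~1.30103
  expect_equal(nrow(vol), sum(dep$status != "untestable"))
  expect_true(all(is.finite(vol$neg_log10_q)))
})
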