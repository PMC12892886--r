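test_that("normalize_within_plex equalizes channel totals and skips missing rows", {
  sheet <- tiny_sheet()
  am <- tiny_matrix(sheet, n = 6, seed = 10)
  am$values[2, 4] <- NA
  norm <- normalize_within_plex(am, sheet)
  expect_equal(norm$state, "within_plex_normalized")
  for (plex in unique(sheet$plex_id)) {
    cols <- sheet$sample_id[sheet$plex_id == plex]
    shared <- rowSums(is.na(norm$values[, cols])) == 0
    # brute-force totals over the shared non-missing row set
    totals <- colSums(norm$values[shared, cols])
    expect_equal(unname(totals), rep(mean(totals), length(cols)))
  }
  # within-channel ratios between proteins are invariant
  r_before <- am$values[1, ] / am$values[3, ]
  r_after <- norm$values[1, ] / norm$values[3, ]
  expect_equal(r_after, r_before)
  # already-equal totals -> identity
  again <- norm
  again$state <- "raw"
  expect_equal(normalize_within_plex(again, sheet)$values, norm$values)
  # forced factors on a 2-channel toy: totals [100, 200] -> [150, 150]
  toy_sheet <- data.frame(
    sample_id = c("s1", "s2", "pool"), group = c("WT", "WT", "POOL"),
    replicate = c(1L, 2L, NA), plex_id = "plex1",
    channel_label = c("126", "127N", "127C"), is_pool = c(FALSE, FALSE, TRUE)
  )
  toy <- abundance_matrix(matrix(c(40, 60, 80, 120, 1, 1), nrow = 2,
                                 dimnames = list(c("a", "b"), toy_sheet$sample_id)))
  toy_n <- normalize_within_plex(toy, toy_sheet)
  expect_equal(unname(colSums(toy_n$values[, c("s1", "s2")])),
               c(100.666, 100.666), tolerance = 1e-3)
  expect_equal(toy_n$values["a", "s1"] / toy$values["a", "s1"],
               mean(c(100, 200, 2)) / 100)
  # zero-total channel is a typed error naming the channel
  z <- toy
  z$values[, "s1"] <- 0
  expect_error(normalize_within_plex(z, toy_sheet), "s1",
               class = "restoromics_validation_error")
})

test_that("bridge_scale equalizes pools via the geometric mean and is idempotent", {
  sheet <- tiny_sheet()
  am <- tiny_matrix(sheet, n = 4, seed = 11, state = "within_plex_normalized")
  am$values["P01", "POOL_plex1"] <- 50
  am$values["P01", "POOL_plex2"] <- 100
  out <- bridge_scale(am, sheet)
  expect_equal(out$state, "bridge_scaled")
  # closed form: plex-1 columns x sqrt(2), plex-2 columns x 1/sqrt(2)
  expect_equal(out$values["P01", "POOL_plex1"], sqrt(50 * 100))
  expect_equal(out$values["P01", "POOL_plex2"], sqrt(50 * 100))
  p1 <- sheet$sample_id[sheet$plex_id == "plex1"]
  expect_equal(out$values["P01", p1], am$values["P01", p1] * sqrt(2))
  # protein with equal pools is untouched
  eq <- am
  eq$values["P02", c("POOL_plex1", "POOL_plex2")] <- 75
  out2 <- bridge_scale(eq, sheet)
  expect_equal(out2$values["P02", ], eq$values["P02", ])
  # idempotence
  twice <- out
  twice$state <- "within_plex_normalized"
  expect_equal(bridge_scale(twice, sheet)$values, out$values)
  # within-channel ratios between proteins in the same plex block scale
  # consistently: pool ratio equality across plexes
  expect_equal(out$values[, "POOL_plex1"], out$values[, "POOL_plex2"])
  # missing pool is an error pointing at filter_pooled_missing
  bad <- am
  bad$values["P03", "POOL_plex2"] <- NA
  expect_error(bridge_scale(bad, sheet), "filter_pooled_missing",
               class = "restoromics_validation_error")
})

test_that("state machine rejects out-of-order stages", {
  sheet <- tiny_sheet()
  am <- tiny_matrix(sheet, n = 3, seed = 12)
  expect_error(bridge_scale(am, sheet), class = "restoromics_state_error")
  expect_error(apply_grubbs(am, sheet), class = "restoromics_state_error")
  norm <- normalize_within_plex(am, sheet)
  expect_error(normalize_within_plex(norm, sheet), class = "restoromics_state_error")
})

test_that("filter_pooled_missing drops rows missing or zero in any pool", {
  sheet <- tiny_sheet()
  am <- tiny_matrix(sheet, n = 4, seed = 13)
  am$values["P01", "POOL_plex2"] <- NA   # missing in one screen only
  am$values["P02", "POOL_plex1"] <- 0    # zero intensity = non-detection
  out <- filter_pooled_missing(am, sheet)
  expect_setequal(out$excluded, c("P01", "P02"))
  expect_setequal(rownames(out$matrix$values), c("P03", "P04"))
  # boundary: everything missing -> empty matrix, full exclusion list
  allbad <- am
  allbad$values[, "POOL_plex1"] <- NA
  out2 <- filter_pooled_missing(allbad, sheet)
  expect_equal(nrow(out2$matrix$values), 0L)
  expect_setequal(out2$excluded, rownames(am$values))
})

test_that("grubbs_test matches the closed-form oracle", {
  res <- grubbs_test(c(1, 1, 1, 1, 10), alpha = 0.05)
  expect_equal(res$G, 7.2 / sqrt(64.8 / 4), tolerance = 1e-12)  # 1.7889
  expect_equal(res$G_crit, 1.7150, tolerance = 1e-4)
  expect_equal(res$outlier_index, 5L)

  res2 <- grubbs_test(c(1, 2, 3, 4, 5), alpha = 0.05)
  expect_equal(res2$G, 2 / sd(1:5), tolerance = 1e-12)  # 1.2649
  expect_true(is.na(res2$outlier_index))

  res3 <- grubbs_test(c(3, 3, 3))
  expect_true(is.na(res3$G) && is.na(res3$outlier_index))

  expect_error(grubbs_test(c(1, 2)), class = "restoromics_validation_error")
  expect_error(grubbs_test(c(1, 2, Inf)), class = "restoromics_validation_error")

  # critical values against an independent inversion of the t relation:
  # recovering t from G_crit must reproduce the alpha/(2n) tail mass
  for (n in 3:30) {
    g <- grubbs_crit(n, 0.05)
    t <- sqrt((n - 2) * g^2 / ((n - 1)^2 / n - g^2))
    expect_equal(pt(t, df = n - 2, lower.tail = FALSE), 0.05 / (2 * n),
                 tolerance = 1e-9)
  }
})

test_that("apply_grubbs removes exactly the planted outlier and skips tiny groups", {
  cfg <- quiet_cfg(n_proteins = 60, noise_cv = 0.05, seed = 14)
  sim <- simulate_study(cfg)
  am <- bridge_scale(normalize_within_plex(sim$matrix, sim$sheet), sim$sheet)
  # plant one x10 outlier by hand
  am$values["P00007", "WT_2"] <- am$values["P00007", "WT_2"] * 10
  out <- apply_grubbs(am, sim$sheet, alpha = 0.05)
  hit <- out$ledger[out$ledger$row_id == "P00007", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$sample_id, "WT_2")
  expect_true(is.na(out$matrix$values["P00007", "WT_2"]))
  # at most one removal per protein-group
  expect_false(any(duplicated(out$ledger[, c("row_id", "group")])))

  # a group shrunk below n = 3 is skipped entirely
  am2 <- am
  wt <- sim$sheet$sample_id[sim$sheet$group == "WT"]
  am2$values["P00010", wt[1:4]] <- NA
  am2$values["P00010", wt[5]] <- am2$values["P00010", wt[5]] * 100
  out2 <- apply_grubbs(am2, sim$sheet)
  expect_equal(nrow(out2$ledger[out2$ledger$row_id == "P00010" &
                                  out2$ledger$group == "WT", ]), 0L)
})

test_that("filter_min_peptides applies the acceptance boundary", {
  sheet <- tiny_sheet()
  am <- tiny_matrix(sheet, n = 3, seed = 15)
  counts <- c(P01 = 1L, P02 = 2L, P03 = 5L)
  out <- filter_min_peptides(am, counts, 2L)
  expect_equal(out$excluded, "P01")    # 1 peptide -> excluded
  expect_true("P02" %in% rownames(out$matrix$values))  # boundary retained
  ident <- filter_min_peptides(am, counts, 0L)
  expect_length(ident$excluded, 0L)
  expect_error(filter_min_peptides(am, counts[1:2], 2L),
               class = "restoromics_validation_error")
})

test_that("rollup_proteins credits unique and razor peptides deterministically", {
  sheet <- tiny_sheet()
  vals <- matrix(rep(c(1, 2, 4, 8), each = nrow(sheet)), nrow = 4, byrow = TRUE,
                 dimnames = list(c("pepA", "pepB", "pepC", "shared"), sheet$sample_id))
  am <- abundance_matrix(vals, level = "peptide")
  mapping <- list(pepA = "prot1", pepB = "prot1", pepC = "prot2",
                  shared = c("prot1", "prot2"))
  out <- rollup_proteins(am, mapping)
  # prot1 has 2 unique peptides vs prot2's 1: razor goes to prot1
  expect_equal(unname(out$matrix$values["prot1", 1L]), 1 + 2 + 8)
  expect_equal(unname(out$matrix$values["prot2", 1L]), 4)
  expect_equal(out$peptide_counts, c(prot1 = 3L, prot2 = 1L))
  # tie on unique counts -> lexicographically smallest id
  mapping2 <- list(pepA = "protB", pepC = "protA", shared = c("protA", "protB"))
  out2 <- rollup_proteins(
    abundance_matrix(vals[c("pepA", "pepC", "shared"), ], level = "peptide"),
    mapping2
  )
  expect_equal(unname(out2$matrix$values["protA", 1L]), 4 + 8)
})
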