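#' Simulation configuration
#'
#' Describes a synthetic two-plex TMT study: 5 groups (WT, saline-treated
#' mdx, and three dystrophin-construct treatments) x `reps_per_group`
#' biological replicates split equally across `n_plex` 16-channel plexes,
#' each carrying one pooled bridge channel.
#'
#' Defaults state the emulated study: 6 replicates per group over 2 plexes;
#' a muscle proteome of 3000 quantified proteins; planted disease effects
#' (mdx vs WT) of |log2FC| = 2 for about 8% up and 1% down regulated
#' proteins (the observed 250 up / 31 down imbalance); treatments restoring
#' most disease changes (90% full, 5% partial, 5% none); a small
#' treatment-induced fraction; 15% CV multiplicative log-normal measurement
#' noise; a modest inter-plex batch effect; and low-level coisolation
#' interference, outliers and missingness.
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_up,frac_down Proportions of proteins planted up/down in mdx
#'   vs WT (`frac_up + frac_down <= 1`).
#' @param effect_log2 Planted absolute log2 fold change of disease effects.
#' @param restoration_profile_probs Named numeric vector over
#'   `c(full, partial, none)`: probability of each restoration profile for
#'   a planted disease protein under each treatment.
#' @param frac_treatment_induced Per-treatment probability that a null
#'   protein is altered by treatment alone.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 disables noise).
#' @param plex_shift_log2 Log2 span of the inter-plex batch effect; plexes
#'   get centred shifts of -/+ half this value so the batch factors have
#'   geometric mean 1.
#' @param coisolation_rho Fraction of each channel's signal replaced by the
#'   within-plex across-channel mean of that protein (coisolation
#'   interference), in `[0, 1)`.
#' @param outlier_rate Probability that one replicate in a (protein, group)
#'   set is multiplied by `outlier_factor` (at most one per set).
#' @param outlier_factor Multiplicative size of planted outliers.
#' @param missing_rate Per-cell missingness probability.
#' @param reps_per_group,n_plex Study layout; `reps_per_group` must divide
#'   evenly across plexes.
#' @param seed Integer RNG seed; all randomness derives from it.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_proteins = 3000L,
                       frac_up = 0.083, frac_down = 0.010,
                       effect_log2 = 2,
                       restoration_profile_probs = c(full = 0.90, partial = 0.05, none = 0.05),
                       frac_treatment_induced = 0.005,
                       noise_cv = 0.15,
                       plex_shift_log2 = 0.2,
                       coisolation_rho = 0.05,
                       outlier_rate = 0.01,
                       outlier_factor = 10,
                       missing_rate = 0.01,
                       reps_per_group = 6L,
                       n_plex = 2L,
                       seed = 1L) {
  probs <- c(frac_up, frac_down, frac_treatment_induced, missing_rate,
             outlier_rate, restoration_profile_probs)
  if (any(probs < 0 | probs > 1)) ro_config_error("all proportions must be in [0, 1]")
  if (frac_up + frac_down > 1) ro_config_error("frac_up + frac_down must be <= 1")
  if (noise_cv < 0) ro_config_error("noise_cv must be >= 0")
  if (coisolation_rho < 0 || coisolation_rho >= 1) {
    ro_config_error("coisolation_rho must be in [0, 1)")
  }
  if (!setequal(names(restoration_profile_probs), c("full", "partial", "none"))) {
    ro_config_error("restoration_profile_probs needs names full, partial, none")
  }
  if (abs(sum(restoration_profile_probs) - 1) > 1e-8) {
    ro_config_error("restoration_profile_probs must sum to 1")
  }
  if (n_proteins < 1L) ro_config_error("n_proteins must be >= 1")
  if (reps_per_group %% n_plex != 0L) {
    ro_config_error(sprintf(
      "layout infeasible: %d replicates per group cannot be split equally over %d plexes",
      reps_per_group, n_plex
    ))
  }
  structure(list(
    n_proteins = as.integer(n_proteins), frac_up = frac_up, frac_down = frac_down,
    effect_log2 = effect_log2,
    restoration_profile_probs = restoration_profile_probs[c("full", "partial", "none")],
    frac_treatment_induced = frac_treatment_induced,
    noise_cv = noise_cv, plex_shift_log2 = plex_shift_log2,
    coisolation_rho = coisolation_rho,
    outlier_rate = outlier_rate, outlier_factor = outlier_factor,
    missing_rate = missing_rate,
    reps_per_group = as.integer(reps_per_group), n_plex = as.integer(n_plex),
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

#' Study design sample sheet
#'
#' Builds the channel-to-sample mapping: each plex carries
#' `reps_per_group / n_plex` replicates of every group plus one pooled
#' bridge channel, on consecutive TMTpro reporter channels.
#'
#' @param reps_per_group Biological replicates per group.
#' @param n_plex Number of plexes.
#' @return A validated sample sheet data frame.
#' @export
study_design <- function(reps_per_group = 6L, n_plex = 2L) {
  if (reps_per_group %% n_plex != 0L) {
    ro_config_error("replicates not divisible across plexes")
  }
  per_plex <- reps_per_group %/% n_plex
  n_study <- length(STUDY_GROUPS) * per_plex
  if (n_study + 1L > length(TMTPRO16_CHANNELS)) {
    ro_config_error("layout exceeds 16 channels per plex")
  }
  rows <- lapply(seq_len(n_plex), function(p) {
    plex <- sprintf("plex%d", p)
    group <- rep(STUDY_GROUPS, each = per_plex)
    replicate <- rep(seq_len(per_plex) + (p - 1L) * per_plex, times = length(STUDY_GROUPS))
    data.frame(
      sample_id = c(sprintf("%s_%d", group, replicate), sprintf("POOL_%s", plex)),
      group = c(group, POOL_GROUP),
      replicate = c(replicate, NA_integer_),
      plex_id = plex,
      channel_label = TMTPRO16_CHANNELS[seq_len(n_study + 1L)],
      is_pool = c(rep(FALSE, n_study), TRUE),
      stringsAsFactors = FALSE
    )
  })
  validate_sample_sheet(do.call(rbind, rows))
}

## Centred per-plex batch shifts (log2): geometric mean of the factors is 1,
## so bridge scaling can recover the unshifted matrix exactly.
plex_shifts <- function(cfg) {
  s <- seq_len(cfg$n_plex)
  shifts <- (s - (cfg$n_plex + 1) / 2) / max(cfg$n_plex - 1, 1) *
    cfg$plex_shift_log2 * ifelse(cfg$n_plex > 1, 2, 0) / 2
  # for n_plex = 2 this is c(-1, +1) * plex_shift_log2 / 2
  names(shifts) <- sprintf("plex%d", s)
  shifts
}

## Measurement chain applied to a matrix of expected (true) intensities:
## plex shift -> coisolation mixing -> log-normal noise, in that order.
apply_measurement_chain <- function(expected, sheet, cfg) {
  x <- expected
  shifts <- plex_shifts(cfg)
  for (plex in unique(sheet$plex_id)) {
    cols <- sheet$sample_id[sheet$plex_id == plex]
    x[, cols] <- x[, cols] * 2^shifts[[plex]]
    if (cfg$coisolation_rho > 0) {
      x[, cols] <- (1 - cfg$coisolation_rho) * x[, cols] +
        cfg$coisolation_rho * rowMeans(x[, cols, drop = FALSE])
    }
  }
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    # mean-preserving log-normal multiplicative noise
    eps <- matrix(rnorm(length(x), mean = -sdlog^2 / 2, sd = sdlog), nrow = nrow(x))
    x <- x * exp(eps)
  }
  list(values = x, shifts = shifts)
}

#' Inject outliers and missing values
#'
#' Plants at most one multiplicative outlier per (protein, group) replicate
#' set (matching the single-outlier test design downstream) and i.i.d.
#' missing cells, returning a complete artifact ledger.
#'
#' @param matrix An [abundance_matrix()].
#' @param sheet Sample sheet for the matrix.
#' @param cfg A [sim_config()]; uses `outlier_rate`, `outlier_factor`,
#'   `missing_rate`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with `matrix` (modified) and `ledger`: data frames
#'   `outliers` (`row_id`, `sample_id`, `group`, `factor`) and `missing`
#'   (`row_id`, `sample_id`).
#' @export
inject_artifacts <- function(matrix, sheet, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix$values
  sheet <- validate_sample_sheet(sheet)
  out_rows <- list()
  if (cfg$outlier_rate > 0) {
    study <- sheet[!sheet$is_pool, , drop = FALSE]
    for (g in unique(study$group)) {
      cols <- study$sample_id[study$group == g]
      hit <- runif(nrow(x)) < cfg$outlier_rate
      pick <- sample.int(length(cols), nrow(x), replace = TRUE)
      for (i in which(hit)) {
        cell <- cols[pick[i]]
        if (!is.na(x[i, cell])) {
          x[i, cell] <- x[i, cell] * cfg$outlier_factor
          out_rows[[length(out_rows) + 1L]] <- data.frame(
            row_id = rownames(x)[i], sample_id = cell, group = g,
            factor = cfg$outlier_factor, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  outliers <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(row_id = character(0L), sample_id = character(0L),
               group = character(0L), factor = numeric(0L))
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(length(x)) < cfg$missing_rate, nrow = nrow(x))
    drop <- drop & !is.na(x)
    x[drop] <- NA_real_
    idx <- which(drop, arr.ind = TRUE)
    missing <- data.frame(row_id = rownames(x)[idx[, 1L]],
                          sample_id = colnames(x)[idx[, 2L]],
                          stringsAsFactors = FALSE)
  } else {
    missing <- data.frame(row_id = character(0L), sample_id = character(0L))
  }
  matrix$values <- x
  list(matrix = matrix, ledger = list(outliers = outliers, missing = missing))
}

#' Simulate a ground-truthed protein-level study
#'
#' Generates the full design: per-protein log-normal baselines; mdx group
#' means shifted by the planted disease effect; treatment means set by the
#' sampled restoration profile (full restoration -> WT mean, none -> mdx
#' mean, partial -> geometric midpoint, treatment-induced -> shifted in
#' that treatment only); pooled bridge channels equal to the across-group
#' mean of true means; then plex shift, coisolation, noise, outliers and
#' missingness, in that order. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (protein-level [abundance_matrix()], state
#'   `"raw"`), `sheet`, and `truth` (a `GroundTruth` list: `direction`,
#'   `profile` matrix (proteins x treatments), `group_means`, `pool_true`,
#'   `plex_shift_log2`, `outliers`, `missing`).
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  sheet <- study_design(cfg$reps_per_group, cfg$n_plex)

  baseline <- rlnorm(n, meanlog = log(1e5), sdlog = 1)
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  direction <- rep("null", n)
  dep_idx <- sample.int(n, n_up + n_down)
  direction[dep_idx[seq_len(n_up)]] <- "up"
  direction[dep_idx[seq_len(n_down) + n_up]] <- "down"
  names(direction) <- ids

  sign_fc <- ifelse(direction == "up", 1, ifelse(direction == "down", -1, 0))
  mdx_mean <- baseline * 2^(sign_fc * cfg$effect_log2)

  profile <- matrix("n/a", nrow = n, ncol = length(TREATMENT_GROUPS),
                    dimnames = list(ids, TREATMENT_GROUPS))
  group_means <- cbind(WT = baseline, mdx_saline = mdx_mean)
  pp <- cfg$restoration_profile_probs
  for (trt in TREATMENT_GROUPS) {
    tm <- mdx_mean  # default; overwritten below
    is_dep <- direction != "null"
    prof <- sample(names(pp), n, replace = TRUE, prob = pp)
    prof[!is_dep] <- "n/a"
    induced <- !is_dep & runif(n) < cfg$frac_treatment_induced
    prof[induced] <- "induced"
    tm[!is_dep] <- baseline[!is_dep]
    tm[prof == "full"] <- baseline[prof == "full"]
    tm[prof == "none"] <- mdx_mean[prof == "none"]
    sel <- prof == "partial"
    tm[sel] <- sqrt(baseline[sel] * mdx_mean[sel])
    ind_sign <- sample(c(-1, 1), n, replace = TRUE)
    tm[induced] <- baseline[induced] * 2^(ind_sign[induced] * cfg$effect_log2)
    profile[, trt] <- prof
    group_means <- cbind(group_means, tm)
  }
  colnames(group_means) <- STUDY_GROUPS
  rownames(group_means) <- ids
  pool_true <- rowMeans(group_means)

  expected <- matrix(NA_real_, nrow = n, ncol = nrow(sheet),
                     dimnames = list(ids, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    expected[, j] <- if (sheet$is_pool[j]) pool_true else group_means[, sheet$group[j]]
  }

  chain <- apply_measurement_chain(expected, sheet, cfg)
  am <- abundance_matrix(chain$values, level = "protein", state = "raw")
  art <- inject_artifacts(am, sheet, cfg, seed = NULL)

  truth <- structure(list(
    direction = direction,
    profile = profile,
    group_means = group_means,
    pool_true = pool_true,
    baseline = setNames(baseline, ids),
    plex_shift_log2 = chain$shifts,
    outliers = art$ledger$outliers,
    missing = art$ledger$missing
  ), class = "GroundTruth")

  list(matrix = art$matrix, sheet = sheet, truth = truth)
}

#' Simulate dystrophin-like construct sequences
#'
#' Builds a synthetic construct family mirroring the study's comparison set:
#' an endogenous full-length protein; a transgenic (human-like) full-length
#' version carrying scattered substitutions; a midi construct deleting one
#' internal block of the transgenic sequence; and a micro construct deleting
#' that block plus two flanking blocks. The block structure guarantees
#' non-empty FULL_ONLY (deleted in both shortened constructs), LARGE_ONLY
#' (deleted in micro only) and TRANSGENIC_SHARED (substitution-bearing,
#' retained everywhere) panels.
#'
#' @param length_full Length of the full-length parent sequence.
#' @param sub_rate Per-residue substitution rate endogenous -> transgenic.
#' @param seed RNG seed.
#' @return Named list of four [construct_sequence()] objects:
#'   `dys_endog`, `fullDys_tg`, `midiDys_tg`, `uDys_tg`.
#' @export
simulate_constructs <- function(length_full = 900L, sub_rate = 0.03, seed = 1L) {
  set.seed(seed)
  if (length_full < 200L) ro_config_error("length_full must be >= 200")
  parent <- sample(AA_LETTERS, length_full, replace = TRUE)
  human <- parent
  sub <- which(runif(length_full) < sub_rate)
  human[sub] <- vapply(human[sub], function(a) sample(setdiff(AA_LETTERS, a), 1L),
                       character(1L))
  # internal deletion blocks (positions within the parent)
  third <- length_full %/% 6L
  block_a <- seq(2L * third, 3L * third)          # deleted in micro only
  block_b <- seq(3L * third + 1L, 4L * third)     # deleted in micro and midi
  block_c <- seq(4L * third + 1L, 5L * third)     # deleted in micro only
  midi <- human[-block_b]
  micro <- human[-c(block_a, block_b, block_c)]
  validate_construct_set(list(
    construct_sequence("dys_endog", paste(parent, collapse = ""), "endogenous", "full"),
    construct_sequence("fullDys_tg", paste(human, collapse = ""), "transgenic", "full"),
    construct_sequence("midiDys_tg", paste(midi, collapse = ""), "transgenic", "midi"),
    construct_sequence("uDys_tg", paste(micro, collapse = ""), "transgenic", "micro")
  ))
}

#' Default construct expression by group
#'
#' WT expresses the endogenous protein only; dystrophic saline-treated mice
#' express nothing; each treated group expresses its own transgene at a
#' lower copy level than endogenous (as observed for AAV-delivered
#' constructs).
#'
#' @param constructs Construct set from [simulate_constructs()] or
#'   [read_constructs()].
#' @param endogenous_level,transgene_level Relative copy levels.
#' @return Named list: group -> named numeric vector of per-construct copy
#'   levels.
#' @export
default_group_expression <- function(constructs, endogenous_level = 1,
                                     transgene_level = 0.4) {
  constructs <- validate_construct_set(constructs)
  origin <- vapply(constructs, `[[`, character(1L), "origin")
  size <- vapply(constructs, `[[`, character(1L), "size_class")
  endog <- names(constructs)[origin == "endogenous"]
  tg <- function(cls) names(constructs)[origin == "transgenic" & size == cls]
  zero <- setNames(rep(0, length(constructs)), names(constructs))
  lev <- function(ids, value) {
    v <- zero
    v[ids] <- value
    v
  }
  list(
    WT = lev(endog, endogenous_level),
    mdx_saline = zero,
    uDys = lev(tg("micro"), transgene_level),
    midiDys = lev(tg("midi"), transgene_level),
    fullDys = lev(tg("full"), transgene_level)
  )
}

#' Simulate a peptide-level dystrophin panel study
#'
#' Each peptide's expected abundance in a sample is
#' `response_factor(peptide) * sum of the group's copy levels over the
#' constructs whose digest contains it` — peptide-specific response factors
#' model the observed variable sensitivity from one peptide to another.
#' Pools, plex shifts, coisolation, noise and artifacts follow
#' [simulate_study()].
#'
#' @param constructs Construct set (must digest to at least one peptide).
#' @param group_expression Named list: study group -> named numeric vector
#'   of copy levels per construct id (see [default_group_expression()]).
#' @param cfg A [sim_config()] (layout, noise and artifact fields used).
#' @param settings A [digest_settings()].
#' @return List with `matrix` (peptide-level, state `"raw"`), `sheet`,
#'   `class_map`, and `truth` (response factors, expected group abundances,
#'   artifact ledgers).
#' @export
simulate_peptide_panel <- function(constructs,
                                   group_expression = default_group_expression(constructs),
                                   cfg = sim_config(),
                                   settings = digest_settings()) {
  set.seed(cfg$seed)
  constructs <- validate_construct_set(constructs)
  class_map <- classify_peptides(constructs, settings)
  peptides <- names(class_map$membership)
  if (!length(peptides)) ro_config_error("empty digest: no peptides to simulate")
  miss <- setdiff(STUDY_GROUPS, names(group_expression))
  if (length(miss)) {
    ro_config_error(sprintf("group_expression missing group(s): %s",
                            paste(miss, collapse = ", ")))
  }
  sheet <- study_design(cfg$reps_per_group, cfg$n_plex)
  rf <- setNames(rlnorm(length(peptides), meanlog = log(1e4), sdlog = 0.5), peptides)
  group_abund <- vapply(STUDY_GROUPS, function(g) {
    lev <- group_expression[[g]]
    vapply(peptides, function(p) {
      sum(lev[class_map$membership[[p]]])
    }, numeric(1L)) * rf
  }, numeric(length(peptides)))
  rownames(group_abund) <- peptides
  pool_true <- rowMeans(group_abund)
  expected <- matrix(NA_real_, nrow = length(peptides), ncol = nrow(sheet),
                     dimnames = list(peptides, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    expected[, j] <- if (sheet$is_pool[j]) pool_true else group_abund[, sheet$group[j]]
  }
  chain <- apply_measurement_chain(expected, sheet, cfg)
  am <- abundance_matrix(chain$values, level = "peptide", state = "raw")
  art <- inject_artifacts(am, sheet, cfg, seed = NULL)
  truth <- structure(list(
    response_factors = rf,
    group_abund = group_abund,
    pool_true = pool_true,
    plex_shift_log2 = chain$shifts,
    outliers = art$ledger$outliers,
    missing = art$ledger$missing
  ), class = "GroundTruth")
  list(matrix = art$matrix, sheet = sheet, class_map = class_map, truth = truth)
}
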