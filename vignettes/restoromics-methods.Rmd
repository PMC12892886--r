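---
title: "Methods: models, parameters and design choices in restoromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in restoromics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

restoromics evaluates protein-level outcomes of AAV dystrophin gene therapy
from multiplexed isobaric-label (TMTpro 16plex) proteomics. The study design
it targets compares five groups of mice — healthy wild type (WT), dystrophic
saline-treated (`mdx_saline`), and dystrophic mice treated with a
micro- (`uDys`), midi- (`midiDys`) or full-length (`fullDys`) dystrophin
construct — with 6 biological replicates per group, split equally over two
16-channel plexes that each carry one pooled bridge channel (an equal-part
mixture of all samples). The package starts from quantified reporter-ion
abundance tables; spectrum matching and reporter-ion extraction are upstream
and out of scope.

# The processing model

## Construct peptide panels

Whether a treated muscle expresses its construct is read out from peptides
that discriminate the constructs. Peptides are generated by in-silico
tryptic digestion (cleavage after K or R unless followed by P; up to 2
missed cleavages; length 6–50, the standard database-search settings).
Membership is *digest-based*: a peptide belongs to a construct if and only
if it appears in that construct's digest at identical settings. This
mirrors how a search engine sees peptides and makes peptides spanning a
deletion junction specific to the shortened construct. Panels are defined
by set predicates over membership, with precedence PAN > FULL_ONLY >
TRANSGENIC_SHARED > LARGE_ONLY > OTHER to force disjointness:

* **FULL_ONLY** — in a full-size construct, absent from micro and midi
  constructs (reports full-length dystrophin only);
* **TRANSGENIC_SHARED** — in every transgenic construct and no endogenous
  one (reports transgene expression regardless of size);
* **LARGE_ONLY** — in a midi or full construct and not in the micro
  construct;
* **PAN** — in everything; **OTHER** — the remainder.

Isoleucine and leucine are treated as distinct letters (the search engine
distinguishes them at the sequence level), and modifications (including
N-terminal methionine loss) are ignored for membership: panels are a
sequence-level concept. Panel abundance per sample is the arithmetic mean
of the panel's peptide abundances, skipping missing values; peptides are
given no detectability weighting because observed response is strongly
peptide-dependent and unknown a priori.

## Normalization

Two stages with an enforced state machine
(`raw -> within_plex_normalized -> bridge_scaled`):

1. **Within-plex**: every channel is scaled so channel totals (over rows
   observed in all channels of the plex) equal the plex mean total —
   standard total-intensity normalization over all quantified peptides. It
   corrects loading and labeling-efficiency differences.
2. **Bridge scaling**: per protein, each plex's values are multiplied by
   (geometric mean of that protein's pooled-channel values across plexes) /
   (its pooled value in that plex). Afterwards the protein's pooled values
   agree across plexes. The geometric mean makes the step symmetric in the
   plexes and idempotent.

Proteins with a missing or zero pooled value in any plex cannot be bridged
and are excluded (zero reporter intensity is treated as non-detection, not
as a quantity). Missing values are never imputed anywhere; they propagate
and reduce per-test replicate counts.

A caveat worth stating precisely: equalizing channel totals multiplies each
channel by `mean_total / total_c`, which shifts every between-group log2
fold change by `-log2(T_A/T_B)`, the log-ratio of the groups' true total
intensities. When disease effects are unbalanced (many more up- than
down-regulated proteins, as in dystrophic muscle) this offset is nonzero.
It is a property of total-intensity normalization itself, not of this
implementation; estimates near a decision boundary can be flipped by it
(see Limitations).

## Outlier exclusion

Grubbs' single-outlier test runs independently on each (protein, group)
replicate set, on log2 abundances, two-sided at `alpha = 0.05`, one pass
(no iteration): `G = max|x - mean|/sd` against
`G_crit = ((n-1)/sqrt(n)) * sqrt(t^2/(n-2+t^2))`, `t` the upper
`alpha/(2n)` t-quantile on `n-2` df. At most one value per set is removed;
sets with fewer than 3 observed values are skipped, and a zero-variance set
has undefined `G` and no outlier. The test is applied after bridge scaling
(the original workflow does not state the order; applying it to the
quantities actually used downstream is the defensible default, and the
stage API lets a user reorder).

## Differential expression

Fold changes are ratios of per-group geometric means of replicate
abundances (equivalently, differences of mean log2 values), the natural
estimator under multiplicative log-normal noise. Zeros are floored once at
half the smallest positive value in the matrix before the log. P-values
come from the two-tailed, unpaired, equal-variance Student's t-test on
log2 abundances (a Welch option exists); untestable proteins (fewer than 2
observed replicates in either group) are excluded from the multiplicity
count. BH step-up adjustment controls the FDR. A protein is a DEP when
`q <= 0.05` **and** `|log2FC| >= 1`; boundary equalities are significant.
The "fold change cutoff of ±1" is read on the log2 scale (a raw ratio
cutoff of ±1 would be vacuous); both cutoffs are configurable. A
zero-pooled-variance test is defined as p = 1 for equal means and p = 0
otherwise, so noise-free fixtures behave sensibly. One-way ANOVA with
Tukey HSD (studentized-range distribution, Tukey–Kramer for unequal n)
is provided for all-group comparisons, as used for the bar-graph panels.

## Restoration taxonomy

For each treatment, three DEP tables (disease vs WT, treated vs WT, treated
vs disease) are combined per protein:

| baseline (mdx vs WT) | treated vs WT | treated vs mdx | category |
|---|---|---|---|
| DEP | ns | — | restored |
| DEP | DEP | DEP | partial |
| DEP | DEP | ns | unrestored |
| ns | DEP | — | treatment_induced |
| ns | ns | — | unchanged |

The `unrestored` row is exactly the published two-criterion filter
(significantly altered vs WT, yet not significantly different from
untreated disease); the remaining rows are the minimal completion that
makes the categories exclusive and exhaustive, which counting requires.
DEP *status* (not raw p) drives the table, so the fold-change gate applies
to all three contrasts symmetrically. The headline "restored X out of N"
counts `restored + partial` by default — proteins whose disease change was
at least partly corrected — with a strict mode (fully restored only)
reported alongside, because the published counting rule is not spelled out.

# The simulator: a stated world

`simulate_study()` emulates the study design so that every stage is
testable without raw data. Defaults state the emulated world and are not
tuned to tests:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 3000 | typical quantified muscle proteome depth |
| `reps_per_group`, `n_plex` | 6, 2 | the study layout, split equally |
| `frac_up`, `frac_down` | 0.083, 0.010 | the observed 250-up / 31-down imbalance at ~3000 proteins |
| `effect_log2` | 2 | planted disease effects comfortably beyond the 2-fold DEP gate |
| `restoration_profile_probs` | full .90 / partial .05 / none .05 | most disease changes restored (262/258/235 of 281) |
| `frac_treatment_induced` | 0.005 | a singular treatment-induced protein was observed |
| `noise_cv` | 0.15 | typical reporter-ion replicate CV |
| `plex_shift_log2` | 0.2 | modest inter-plex batch effect |
| `coisolation_rho` | 0.05 | low-level coisolation interference |
| `outlier_rate`, `outlier_factor` | 0.01, 10 | sporadic single-replicate artifacts |
| `missing_rate` | 0.01 | sporadic missing reporter values |

Per-protein baselines are log-normal (`meanlog = log(1e5)`, `sdlog = 1`).
The disease group mean is the baseline times `2^(±effect_log2)`; treatment
means follow the sampled profile: full → WT mean, none → disease mean,
partial → the geometric midpoint (an intermediate level between healthy
and dystrophin-deficient muscle), treatment-induced → shifted in that
treatment only. The pooled channel is the across-group mean of true means.
The measurement chain is applied in a fixed, documented order: plex shift →
coisolation mixing (convex combination with the within-plex row mean, which
reproduces non-zero dystrophin signal in dystrophin-null samples with one
parameter) → mean-preserving multiplicative log-normal noise → outliers (at
most one per protein-group set, matching the single-outlier test design) →
missingness. Everything derives from one seed, and ledgers record every
planted effect and artifact.

Per-plex batch shifts are *centred*: with two plexes they are
`∓ plex_shift_log2 / 2`, so the batch factors have geometric mean 1. This
is required for internal consistency: geometric-mean pooled-channel
bridging can only recover a matrix up to the geometric mean of the plex
factors, so a stated world in which bridging exactly inverts the batch
effect must have that mean equal to one.

`simulate_peptide_panel()` plants peptide-level data as
`response_factor(peptide) × Σ copy levels of the constructs containing it`,
with log-normal response factors modelling the observed peptide-to-peptide
sensitivity differences. `simulate_constructs()` builds a synthetic
construct family (endogenous full-length; transgenic full with scattered
substitutions; midi and micro deletions of it) whose block structure
guarantees non-empty discrimination panels; it is a synthetic stand-in, not
the real dystrophin sequences.

**What the simulator does not emulate** — and hence what a green test does
not establish: peptide-spectrum matching errors, isotopic impurity,
ratio compression beyond one-parameter coisolation mixing, correlated
(pathway-level) effects, compositional closure of reporter intensities,
intensity-dependent missingness, or any real biological covariance.
Green tests establish that the algorithms do what their definitions say on
data whose generative structure is known, not that the published biological
findings are reproduced.

# Numerical choices

* BH q-values use the literal step-up arithmetic `p·m/j` with a cumulative
  minimum; q ≥ p then holds up to one unit of floating-point rounding.
* Zero floor: half the minimum positive matrix value, applied once
  (avoids per-protein pseudo-counts and `-Inf`).
* `q = 0` is floored at the smallest positive double for volcano axes.
* Degenerate tests: zero pooled variance gives p ∈ {0, 1} by mean equality;
  all-equal ANOVA gives F = 0, p = 1.
* Grubbs on groups shrunk below n = 3 (by missingness or prior exclusion)
  is skipped; the razor roll-up rule breaks ties lexicographically so
  roll-up is deterministic.
* TSV output renders doubles as `%.17g`, so write-then-read round-trips
  are bit-for-bit.

# Limitations

* **The partial category sits on the decision boundary when
  `effect_log2 = 2`.** The geometric midpoint puts a partially restored
  protein's true |log2FC| at exactly 1.0 — the DEP fold-change cutoff —
  against *both* WT and disease. Its estimated fold change is then centred
  on the cutoff, each of the two required DEP calls succeeds with
  probability near one half, and the two estimates are positively coupled
  through the shared treated-group mean (joint success probability 1/6 for
  bivariate-normal estimates with correlation 1/2). Partial restoration at
  a 4-fold disease effect is therefore intrinsically under-called at these
  cutoffs, leaking mostly into `restored`; the package reports it
  faithfully rather than adjusting the midpoint or the cutoffs. The
  restoration-recovery acceptance test documents this as an expected
  failure for the partial fraction.
* Total-intensity normalization introduces a group-total offset on fold
  changes when planted effects are unbalanced (see above); exactness
  invariants are therefore stated on balanced or effect-free worlds.
* The published headline counts (262/258/235 of 281) require the deposited
  raw data and the original search pipeline; nothing here claims to
  reproduce them numerically.
* The within-plex group allocation (3 replicates per group per plex) is
  the equal split of 6 replicates over 2 plexes; the layout is
  configurable.
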