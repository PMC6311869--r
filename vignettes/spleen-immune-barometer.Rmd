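---
title: "The spleen as a systemic immune barometer: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spleen as a systemic immune barometer: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoBarometer)
```

## The scientific setting

In preclinical tumor immunology the spleen is attractive as a *systemic
immune barometer*: a single accessible organ whose leukocyte composition
reflects tumor-induced immune dysregulation and the response to
immunotherapy. The workflow this package mechanizes is the standard one
for an orthotopic osteosarcoma mouse model: splenocytes (or dissociated
tumor) are stained with one of four antibody panels, at least 50,000
events are acquired per sample on a flow cytometer, events are classified
through a hierarchy of boolean marker gates, per-animal population
percentages are summarized per cohort as mean ± SD, and cohorts are
compared population-by-population with two-tailed Student's *t*-tests
under a Bonferroni family-wise correction at α = 0.05.

Three derived quantities sit on top of the gating:

* **TCES**, the T-cell exhaustion status,
  $$\mathrm{TCES} \;=\;
  \frac{\%\mathrm{PD1}_{CTL} + \%\mathrm{PD1}_{Th}
      + \%\mathrm{Tim3}_{CTL} + \%\mathrm{Tim3}_{Th}}
       {\%\mathrm{CTL} + \%\mathrm{Th}},$$
  the summed PD-1/Tim-3 percent expression on cytotoxic (CD8^+^) and
  helper (CD4^+^) T cells normalized by the summed T-cell percent
  populations, so animals with very different T-cell counts remain
  comparable (`compute_tces()`).
* the **M1/M2 macrophage marker profile** — percent of the
  CD11b^+^Ly6C^+^Ly6G^−^ monocyte/macrophage gate positive for Cxcl9 and
  Nos2 (M1-like) and Tgm2 and Arg1 (M2-like) — kept as four separate
  percentages because tumor-conditioned macrophages co-express both
  programs; `m1m2_ratio()` offers an aggregate
  $(\%Cxcl9 + \%Nos2)/(\%Tgm2 + \%Arg1)$ whose exact form is a package
  decision, isolated so it can be swapped.
* the caliper **tumor volume** $V = \ell w^2/2$ (cm^3^) and the antibody
  **dose** in µg (`tumor_volume()`, `dose_micrograms()`).

No raw event data accompany the source study; its printed summary tables
(mean ± SD, *n*, *p* per population) are therefore first-class package
inputs (`printed_tables()`), and everything event-level is synthetic.

## Why pooled-variance *t*, and the degenerate conventions

The source analysis says only "Student's *T*-test". Before freezing the
equal-variance (pooled) form we verified that it — and not the Welch
form — reproduces the printed p-values from the printed (mean, SD, n):
for the Tregs row of the tumor-bearing vs sham comparison the pooled test
gives p = 0.00109 (printed 0.0011) while Welch gives a different
answer, and for the NK row pooled gives 0.0059 (printed 0.006) vs Welch
≈ 0.011. The test suite cross-checks `pooled_t_test_raw()` against
`stats::t.test(var.equal = TRUE)` on random data.

Zero pooled variance (possible here: an unstained marker prints 0 ± 0%)
follows a stated convention: p = 1 when the means also agree, p = 0 when
they differ. `pooled_t_test_raw()` and `pooled_t_test_summary()` agree to
machine precision by construction.

Bonferroni family sizes equal each published table's row count (6, 6, 6,
7, 5, 7), which reproduces all three printed per-comparison alphas
(0.0083, 0.00714, 0.01); the single-row tumor PD-L1 table was tested
uncorrected at α = 0.05.

Of the 38 printed p-values, 33 are reproduced at their printed precision.
Five disagree in the last printed digit (`reproduce_printed_tables()`
flags them rather than passing silently); all are consistent with the
original authors computing from unrounded raw data, and none is among the
headline results.

## The reporting basis

The source tables never state the denominator of "% expression". Two
rows make the convention unambiguous: Tregs (21.09%) exceed their Th
parent population (6.45%), and granulocytes (57.49%) exceed MLCs
(5.27%), which is impossible on a shared basis. The package therefore
reports **percent-of-parent** everywhere: top-level populations as
percent of the CD45^+^ leukocyte gate (CD45^−^ gate for tumor PD-L1),
Tregs as Foxp3^+^ percent of Ths, myeloid subsets and the four
polarization markers as percent of their MLC / monocyte-macrophage
parents. The basis is recorded in every run manifest.

## What the synthetic cohorts are

The generator's stated world is the published one: cohorts of ≥ 3 animals
(the published *n*: 3–15 per arm), 50,000 events per animal, and
per-population statistics equal to the printed means and SDs
(`builtin_cohort_presets()`).

* **Between-animal variation.** Each animal's true value of every
  statistic is drawn from Normal(mean, SD) on the percent scale and
  *censored* to [0, 100] — censoring rather than rejection keeps exactly
  one draw per statistic so random streams stay aligned across animals.
  For statistics within ~2 SD of zero this shifts the realized mean
  slightly (0.3 ± 0.56% realizes as ≈ 0.41%); no published statistic of
  consequence sits in that regime on both sides of a comparison.
* **Population structure.** A statistic is realized either as a
  multinomial *fraction* of its parent population or as a Bernoulli
  *marker positivity* within it (`panel_stat_bindings()`). Panel 4's
  monocytes and granulocytes are disjoint multinomial siblings
  (Ly6C^+^Ly6G^−^ vs Ly6G^+^Ly6C^−^) because independent per-marker coins
  would create double-positive events the gates exclude. Sibling
  fractions that draw to a sum above 100% are rescaled proportionally,
  preserving relative composition.
* **Intensities.** Each marker is a two-component log-normal: negative
  mode meanlog log(100), positive mode meanlog log(8000), both sdlog
  0.35. The location gap (~4.4) is more than 12 standard deviations, so
  the generative midpoint threshold misclassifies with probability
  < 10^−9^ and gating error is negligible against counting error.
* **Exhaustion markers.** The tables print each cohort's TCES but not the
  four PD-1/Tim-3 percentages that compose it. Presets assign each of
  the four the mean $\mathrm{TCES}\cdot(\%CTL+\%Th)/4$ and the SD
  $\mathrm{SD_{TCES}}\cdot(\%CTL+\%Th)/4$, which reproduces the printed
  TCES mean by construction; the realized per-animal TCES spread is
  approximate because the printed TCES SD cannot be decomposed into its
  marker and population components.
* **Seeding.** One root seed per cohort; every animal's stream seed is a
  fixed arithmetic mix of (root seed, animal index), so any animal can be
  regenerated alone and cohorts are byte-identical under a fixed spec.

What the generator deliberately does **not** emulate: fluorophore
spillover and compensation, doublets, debris, acquisition drift,
correlated population shifts within an animal, and heavy-tailed or
skewed between-animal variation. A green simulation test therefore
establishes that the *pipeline* (gating, scoring, testing) is correct on
data matching the published moments — not that the generator reproduces
real cytometry files.

## Thresholds for external data

Synthetic data are gated at the known generative midpoints. For external
event tables the default per-marker threshold is deterministic where the
published workflow was manual: the minimum-density valley between the two
largest modes of a kernel density estimate of log intensity. A valley
must dip below half the smaller mode's density to count as real
bimodality; otherwise the marker is treated as unresolved and everything
is called negative. Events exactly at a threshold are negative (strict
`>` for positivity), which makes a `+`/`−` gate pair an exact partition
of its parent. Per-marker overrides can be passed to `apply_gate_tree()`.

## What passes, and what stays red

The deterministic acceptance path is green: printed alphas, headline
p-values, and the exact published significance pattern in summary mode,
plus event-level identities (TCES from gated percentages equals
brute-force event counting; gated counts equal a per-event reference
evaluator).

One stochastic criterion is knowingly red and left red: re-simulating
cohorts from the printed (mean, SD, *n*) and demanding the published
per-row significance pattern in ≥ 90% of 50 seeds. That bound is not
attainable in the stated world, for two reasons the package does not
hide. First, statistical power: re-drawing 5-vs-4 animals from the
printed moments gives the NK comparison (printed p = 0.006, threshold
0.0083) a noncentral-*t* power of only ≈ 0.62, and the borderline
*non*-significant rows (monocytes p = 0.036, granulocytes p = 0.014)
cross their thresholds in well over 10% of re-draws. Second, variance
stacking: the printed between-animal SDs already *contain* the counting
noise of the real acquisition, while the simulation adds fresh counting
noise on top of the re-sampled true percentage, over-dispersing deeply
nested statistics (the monocyte/macrophage gate holds ~125 of 50,000
events, so its marker percentages carry ~3.5% binomial SE against a
printed SD of 5.69%). The acceptance test asserts the stated bound and
fails with the measured per-row rates; the acceptance script reports the
same rates. Tuning the generator (shrinking SDs, inflating events,
deflating nested gates) until the criterion passed would make the test
meaningless as a statement about the published world.

## Numerical and degenerate-input choices

* Empty parent gates report 0% for children, never a division error; an
  all-zero T-cell denominator makes TCES an explicit error, never a
  silent zero — and a cohort preset whose CTL percentage sits ~2.2 SD
  above zero *will* occasionally censor an animal's CTLs to zero, in
  which case percent-of-parent statistics under that gate are undefined
  and excluded from recovery summaries.
* Statistical tolerances in stochastic tests are the stated ones (3
  binomial SEs; 10% relative on moments at 200 animals) applied per
  comparison; where a test checks dozens of such comparisons at once it
  allows the single excursion the tolerance itself predicts, rather than
  widening any band.
* All alphas and p-values are carried at full precision; rounding to the
  published precision happens only when comparing against printed
  values, using the printed string's own significant figures.

## Limitations

Inference is exactly what the source used — pooled *t* with Bonferroni —
so small-*n* non-normality, unequal variances (visible in several printed
rows), and multiplicity beyond one table are untreated by design.
The M1:M2 ratio aggregation is a package convention; its published
p = 0.21 is not reproducible from printed data and is asserted nowhere.
FCS file ingest is out of scope (no FCS reader in the supported
dependency set); delimited event tables are the interchange format.
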