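#' Group summary statistic (mean, SD, n)
#'
#' The atom of a published comparison table: the sample mean, Bessel-
#' corrected standard deviation, and animal count of one population
#' percentage (or score) across one cohort.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Number of animals (>= 1).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  mean <- as.numeric(mean); sd <- as.numeric(sd); n <- as.integer(n)
  if (length(mean) != 1L || is.na(mean))
    stop("'mean' must be a single number", call. = FALSE)
  if (length(sd) != 1L || is.na(sd) || sd < 0)
    stop("'sd' must be a single number >= 0", call. = FALSE)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a positive integer", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = n), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %.4g +/- %.4g (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Summarize raw per-animal values into a group summary
#'
#' @param x Numeric vector of per-animal values (length >= 1).
#' @return A [group_summary()]; `sd` is 0 for a single value.
#' @export
summarize_values <- function(x) {
  x <- as.numeric(x)
  if (!length(x) || anyNA(x))
    stop("'x' must be non-empty and free of NA", call. = FALSE)
  group_summary(mean(x), if (length(x) > 1L) stats::sd(x) else 0, length(x))
}

#' Two-sample pooled-variance Student's t-test from summary statistics
#'
#' The classical equal-variance form: pooled variance
#' `sp^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)`,
#' `t = (mean_a - mean_b) / (sp * sqrt(1/n_a + 1/n_b))`, with a two-tailed
#' p-value on `n_a + n_b - 2` degrees of freedom.  Degenerate zero pooled
#' variance follows a documented convention: p = 1 when the means agree,
#' p = 0 when they differ (needed for all-zero rows such as an unstained
#' marker).
#'
#' @param a,b [group_summary()] objects.
#' @return List with elements `t`, `df`, `p`.
#' @export
#' @examples
#' pooled_t_test_summary(group_summary(21.09, 5.12, 5),
#'                       group_summary(7.25, 0.23, 4))
pooled_t_test_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n + b$n < 3L)
    stop("inference error: n_a + n_b must be at least 3", call. = FALSE)
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1L) * a$sd^2 + (b$n - 1L) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(a$mean - b$mean) * Inf, df = df, p = 0))
  }
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pooled-variance Student's t-test from raw per-animal values
#'
#' Identical, to machine precision, to [pooled_t_test_summary()] applied to
#' the samples' Bessel-corrected summaries.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df`, `p`.
#' @export
pooled_t_test_raw <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("inference error: each group needs at least 2 values", call. = FALSE)
  pooled_t_test_summary(summarize_values(values_a), summarize_values(values_b))
}

#' Bonferroni per-comparison significance threshold
#'
#' @param family_size Number of comparisons in the family (>= 1).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return Per-comparison alpha `family_alpha / family_size`.
#' @export
#' @examples
#' bonferroni_threshold(6)  # 0.008333...
bonferroni_threshold <- function(family_size, family_alpha = 0.05) {
  family_size <- as.integer(family_size)
  if (is.na(family_size) || family_size < 1L)
    stop("'family_size' must be a positive integer", call. = FALSE)
  if (!is.numeric(family_alpha) || length(family_alpha) != 1L ||
      is.na(family_alpha) || family_alpha <= 0 || family_alpha > 1)
    stop("'family_alpha' must be in (0, 1]", call. = FALSE)
  family_alpha / family_size
}

#' The six percentages entering the T-cell exhaustion status
#'
#' PD-1 and Tim-3 percent expression are percent-of-parent within the CTL
#' and Th gates; `pct_CTL` and `pct_Th` are the percent populations of the
#' subsets themselves (of the CD45+ leukocyte gate).
#'
#' @param pct_PD1_CTL,pct_Tim3_CTL,pct_PD1_Th,pct_Tim3_Th Percent of each
#'   T-cell subset positive for the exhaustion marker, in `[0, 100]`.
#' @param pct_CTL,pct_Th Percent population of each subset, in `[0, 100]`.
#' @return An object of class `tces_inputs`.
#' @export
tces_inputs <- function(pct_PD1_CTL, pct_Tim3_CTL, pct_PD1_Th, pct_Tim3_Th,
                        pct_CTL, pct_Th) {
  v <- c(pct_PD1_CTL = pct_PD1_CTL, pct_Tim3_CTL = pct_Tim3_CTL,
         pct_PD1_Th = pct_PD1_Th, pct_Tim3_Th = pct_Tim3_Th,
         pct_CTL = pct_CTL, pct_Th = pct_Th)
  if (anyNA(v) || any(v < 0) || any(v > 100))
    stop("all TCES inputs must be percentages in [0, 100]", call. = FALSE)
  structure(as.list(v), class = "tces_inputs")
}

#' T-cell exhaustion status (TCES)
#'
#' The summed PD-1 and Tim-3 percent expression on CTLs and Ths, normalized
#' by the summed percent population of the two T-cell subsets:
#' `TCES = (%PD1_CTL + %PD1_Th + %Tim3_CTL + %Tim3_Th) / (%CTL + %Th)`.
#' Dimensionless, non-negative, and zero exactly when no exhaustion-marker
#' expression is present.
#'
#' @param inputs A [tces_inputs()] object.
#' @return TCES score (scalar).
#' @export
#' @examples
#' compute_tces(tces_inputs(50, 50, 50, 50, 10, 10))  # 10
compute_tces <- function(inputs) {
  stopifnot(inherits(inputs, "tces_inputs"))
  denom <- inputs$pct_CTL + inputs$pct_Th
  if (denom <= 0)
    stop("undefined TCES: total T-cell percent population is zero",
         call. = FALSE)
  (inputs$pct_PD1_CTL + inputs$pct_PD1_Th +
     inputs$pct_Tim3_CTL + inputs$pct_Tim3_Th) / denom
}

#' M1/M2 macrophage marker profile
#'
#' Percent of the monocyte/macrophage gate positive for each polarization
#' marker: Cxcl9 and Nos2 (M1-like, pro-inflammatory), Tgm2 and Arg1
#' (M2-like, anti-inflammatory).
#'
#' @param pct_Tgm2,pct_Arg1,pct_Cxcl9,pct_Nos2 Percentages in `[0, 100]`.
#' @return An object of class `macrophage_profile`.
#' @export
macrophage_profile <- function(pct_Tgm2, pct_Arg1, pct_Cxcl9, pct_Nos2) {
  v <- c(pct_Tgm2 = pct_Tgm2, pct_Arg1 = pct_Arg1,
         pct_Cxcl9 = pct_Cxcl9, pct_Nos2 = pct_Nos2)
  if (anyNA(v) || any(v < 0) || any(v > 100))
    stop("all marker percentages must be in [0, 100]", call. = FALSE)
  structure(as.list(v), class = "macrophage_profile")
}

#' M1 : M2 macrophage marker ratio
#'
#' Summed M1 marker expression over summed M2 marker expression:
#' `(%Cxcl9 + %Nos2) / (%Tgm2 + %Arg1)`.  The aggregation into a single
#' ratio is a package design choice (the markers are published
#' individually); the function is isolated so the form can be swapped.
#'
#' @param profile A [macrophage_profile()].
#' @return Ratio (dimensionless).
#' @export
m1m2_ratio <- function(profile) {
  stopifnot(inherits(profile, "macrophage_profile"))
  denom <- profile$pct_Tgm2 + profile$pct_Arg1
  if (denom <= 0)
    stop("undefined M1:M2 ratio: M2 marker expression is zero", call. = FALSE)
  (profile$pct_Cxcl9 + profile$pct_Nos2) / denom
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `V = (length x width^2) / 2`, the standard caliper formula for
#' subcutaneous/orthotopic tumor volume.
#'
#' @param length Greatest tumor length in cm (> 0).
#' @param width Greatest tumor width in cm (> 0).
#' @return Volume in cm^3.
#' @export
#' @examples
#' tumor_volume(1, 1)    # 0.5
#' tumor_volume(2, 1.3)  # 1.69
tumor_volume <- function(length, width) {
  if (!is.numeric(length) || !is.numeric(width) ||
      anyNA(length) || anyNA(width) || any(length <= 0) || any(width <= 0))
    stop("tumor dimensions must be positive", call. = FALSE)
  length * width^2 / 2
}

#' Antibody dose in micrograms
#'
#' Converts a per-mass dose rate to the absolute amount for one animal:
#' `mass_kg x dose_rate x 1000`.  A 20 g mouse at 1 mg/kg receives 20 ug.
#'
#' @param mass_kg Body mass in kg (> 0).
#' @param dose_rate_mg_per_kg Dose rate in mg per kg (>= 0).
#' @return Dose in micrograms.
#' @export
#' @examples
#' dose_micrograms(0.020, 1)   # 20
#' dose_micrograms(0.020, 10)  # 200
dose_micrograms <- function(mass_kg, dose_rate_mg_per_kg) {
  if (!is.numeric(mass_kg) || anyNA(mass_kg) || any(mass_kg <= 0))
    stop("'mass_kg' must be positive", call. = FALSE)
  if (!is.numeric(dose_rate_mg_per_kg) || anyNA(dose_rate_mg_per_kg) ||
      any(dose_rate_mg_per_kg < 0))
    stop("'dose_rate_mg_per_kg' must be >= 0", call. = FALSE)
  mass_kg * dose_rate_mg_per_kg * 1000
}
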