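#' Bonferroni-corrected two-group comparison of panel statistics
#'
#' Runs one pooled-variance Student's t-test per population and flags
#' significance against the Bonferroni per-comparison threshold
#' `family_alpha / family_size`.
#'
#' @param stats_a,stats_b Data frames with columns `population`, `mean`,
#'   `sd`, `n` -- one row per population, the same population set in both
#'   groups.
#' @param family_size Number of comparisons in the family; defaults to the
#'   number of populations compared (one table's row count).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return Data frame with one row per population: the two summaries,
#'   `t`, `df`, `p_value`, `corrected_alpha` and `significant`.
#' @export
compare_panels <- function(stats_a, stats_b, family_size = NULL,
                           family_alpha = 0.05) {
  stats_a <- as.data.frame(stats_a)
  stats_b <- as.data.frame(stats_b)
  need <- c("population", "mean", "sd", "n")
  for (nm in c("stats_a", "stats_b")) {
    df <- get(nm)
    if (!all(need %in% names(df)))
      stop("'", nm, "' needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
  }
  only_a <- setdiff(stats_a$population, stats_b$population)
  only_b <- setdiff(stats_b$population, stats_a$population)
  if (length(only_a) || length(only_b))
    stop("mismatched population sets; only in A: {",
         paste(only_a, collapse = ", "), "}, only in B: {",
         paste(only_b, collapse = ", "), "}", call. = FALSE)
  if (is.null(family_size)) family_size <- nrow(stats_a)
  alpha <- bonferroni_threshold(family_size, family_alpha)

  stats_b <- stats_b[match(stats_a$population, stats_b$population), ]
  rows <- lapply(seq_len(nrow(stats_a)), function(i) {
    a <- group_summary(stats_a$mean[i], stats_a$sd[i], stats_a$n[i])
    b <- group_summary(stats_b$mean[i], stats_b$sd[i], stats_b$n[i])
    tt <- pooled_t_test_summary(a, b)
    data.frame(population = stats_a$population[i],
               mean_a = a$mean, sd_a = a$sd, n_a = a$n,
               mean_b = b$mean, sd_b = b$sd, n_b = b$n,
               t = tt$t, df = tt$df, p_value = tt$p,
               corrected_alpha = alpha,
               significant = tt$p < alpha)
  })
  do.call(rbind, rows)
}

#' Summarize per-animal population percentages cohort-wise
#'
#' @param per_animal Long data frame with columns `animal_id`,
#'   `population`, `pct` (one row per animal per statistic).
#' @return Data frame `population`, `mean`, `sd`, `n` suitable for
#'   [compare_panels()], in first-appearance order of `population`.
#' @export
summarize_cohort <- function(per_animal) {
  per_animal <- as.data.frame(per_animal)
  need <- c("animal_id", "population", "pct")
  if (!all(need %in% names(per_animal)))
    stop("'per_animal' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  pops <- unique(per_animal$population)
  do.call(rbind, lapply(pops, function(p) {
    x <- per_animal$pct[per_animal$population == p]
    s <- summarize_values(x)
    data.frame(population = p, mean = s$mean, sd = s$sd, n = s$n)
  }))
}
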