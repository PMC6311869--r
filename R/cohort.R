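#' Specification of a simulated animal cohort
#'
#' A cohort fixes the panel, the number of animals, and the cohort-level
#' distribution (mean %, SD %) of every statistic the panel reports.
#' Per-animal values are drawn from normal distributions with those moments,
#' censored to `[0, 100]` -- the convention matching how cohort statistics
#' are reported as mean +/- SD.
#'
#' @param cohort_label Cohort name, conventionally one of `"WT"`, `"TF"`,
#'   `"SH"`, `"TF_aPDL1"` (any non-empty string is accepted).
#' @param panel Panel identifier (see [panel_markers()]).
#' @param n_animals Number of animals (at least 3, the minimum group size
#'   for inference).
#' @param population_stats Data frame with columns `population`, `mean`,
#'   `sd`; one row per statistic of the panel (a subset of
#'   `panel_stat_bindings(panel)$stat`).  Means are percentages in
#'   `[0, 100]`, SDs are non-negative.
#' @param events_per_animal Events acquired per animal (default 50000, the
#'   minimum acquisition size of the assay).
#' @param seed Integer root seed; per-animal random streams are derived
#'   from it so that each animal is reproducible independently of
#'   generation order.
#' @param tissue `"spleen"` or `"tumor"`; fixes the top-level compartment
#'   split of simulated events.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_label, panel, n_animals, population_stats,
                        events_per_animal = 50000L, seed = 1L,
                        tissue = c("spleen", "tumor")) {
  if (!is.character(cohort_label) || length(cohort_label) != 1L ||
      !nzchar(cohort_label))
    stop("'cohort_label' must be a single non-empty string", call. = FALSE)
  panel <- normalize_panel(panel)
  tissue <- match.arg(tissue)
  n_animals <- as.integer(n_animals)
  if (is.na(n_animals) || n_animals < 3L)
    stop("'n_animals' must be at least 3", call. = FALSE)
  events_per_animal <- as.integer(events_per_animal)
  if (is.na(events_per_animal) || events_per_animal < 1L)
    stop("'events_per_animal' must be positive", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)

  ps <- as.data.frame(population_stats)
  need <- c("population", "mean", "sd")
  if (!all(need %in% names(ps)))
    stop("'population_stats' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  known <- panel_stat_bindings(panel)$stat
  unknown <- setdiff(ps$population, known)
  if (length(unknown))
    stop("configuration error: unknown population label(s) for panel ",
         panel, ": ", paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ps$population))
    stop("duplicate population labels in 'population_stats'", call. = FALSE)
  if (any(is.na(ps$mean)) || any(ps$mean < 0) || any(ps$mean > 100))
    stop("population means must be percentages in [0, 100]", call. = FALSE)
  if (any(is.na(ps$sd)) || any(ps$sd < 0))
    stop("population SDs must be >= 0", call. = FALSE)

  structure(list(cohort_label = cohort_label, panel = panel,
                 n_animals = n_animals, population_stats = ps,
                 events_per_animal = events_per_animal, seed = seed,
                 tissue = tissue),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s, panel %s (%s), %d animals x %d events, seed %d\n",
              x$cohort_label, x$panel, x$tissue, x$n_animals,
              x$events_per_animal, x$seed))
  print(x$population_stats, row.names = FALSE)
  invisible(x)
}

# Derive the random stream seed of one animal from the cohort root seed.
# A fixed LCG-style mix keeps streams reproducible independently of the
# order in which animals are generated; the result stays inside the
# positive 32-bit integer range R requires of set.seed().
derive_stream_seed <- function(seed, animal_index) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(animal_index) * 30269) %% 2147483629 + 1)
}

#' Sample one animal's true statistic values
#'
#' Each statistic is drawn from a normal with the cohort's (mean, SD),
#' censored to `[0, 100]`, and returned as a fraction in `[0, 1]`.  Sampled
#' sibling *population* fractions that would exceed their parent's capacity
#' (sum > 1) are rescaled proportionally, preserving relative composition.
#' The draw is a pure function of `(cohort$seed, animal_index)`.
#'
#' @param cohort A [cohort_spec()].
#' @param animal_index Positive integer identifying the animal.
#' @return Named numeric vector of fractions, one per statistic.
#' @export
sample_animal_fractions <- function(cohort, animal_index) {
  stopifnot(inherits(cohort, "cohort_spec"))
  animal_index <- as.integer(animal_index)
  if (is.na(animal_index) || animal_index < 1L)
    stop("'animal_index' must be a positive integer", call. = FALSE)
  st <- cohort$population_stats
  vals <- withr::with_seed(
    derive_stream_seed(cohort$seed, animal_index),
    stats::rnorm(nrow(st), mean = st$mean, sd = st$sd))
  vals <- pmin(pmax(vals, 0), 100) / 100
  names(vals) <- st$population

  # proportional renormalization of over-full sibling sets
  bind <- panel_stat_bindings(cohort$panel)
  bind <- bind[bind$kind == "fraction" & bind$stat %in% names(vals), ,
               drop = FALSE]
  for (par in unique(bind$parent)) {
    sibs <- bind$stat[bind$parent == par]
    s <- sum(vals[sibs])
    if (s > 1) vals[sibs] <- vals[sibs] / s
  }
  vals
}
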