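#' Generate one animal's event-level data
#'
#' Events are assigned multinomially to the leaves of the population tree
#' according to the supplied fractions; each event then receives one
#' intensity per marker, drawn from the positive or negative mode of the
#' marker's model according to the population's marker profile.  Ground
#' truth population labels are recorded per event.
#'
#' @param fractions Named vector overriding `target_fraction` per population
#'   label (fractions of the parent population); may be `NULL` to use the
#'   specs as given.
#' @param marker_models Named list of [marker_model()] objects covering
#'   every marker referenced by the population specs.
#' @param population_specs List of [population_spec()] objects.
#' @param n_events Number of events to generate (>= 1).
#' @param seed Integer seed; the result is a pure function of all
#'   arguments.
#' @param animal_id Identifier stored on the returned table.
#' @return An [event_table()] with truth labels.
#' @export
generate_events <- function(fractions, marker_models, population_specs,
                            n_events, seed, animal_id = "animal_1") {
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L)
    stop("'n_events' must be >= 1", call. = FALSE)
  if (!length(marker_models) ||
      !all(vapply(marker_models, inherits, logical(1L), "marker_model")))
    stop("'marker_models' must be a list of marker models", call. = FALSE)
  names(marker_models) <- vapply(marker_models, function(m) m$marker,
                                 character(1L))
  markers <- names(marker_models)

  resolved <- resolve_population_tree(population_specs, fractions)
  used <- unique(unlist(lapply(resolved$nodes,
                               function(n) names(n$profile))))
  missing <- setdiff(used, markers)
  if (length(missing))
    stop("configuration error: marker(s) referenced in a profile but absent ",
         "from marker_models: ", paste(missing, collapse = ", "),
         call. = FALSE)

  leaves <- resolved$leaves
  leaf_labels <- vapply(leaves, function(l) l$label, character(1L))
  leaf_fracs <- vapply(leaves, function(l) l$abs_frac, numeric(1L))

  withr::with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n_events, leaf_fracs))
    truth <- rep(leaf_labels, counts)
    X <- matrix(NA_real_, nrow = n_events, ncol = length(markers),
                dimnames = list(NULL, markers))
    row0 <- 0L
    for (i in seq_along(leaves)) {
      ni <- counts[i]
      if (ni == 0L) next
      rows <- row0 + seq_len(ni)
      prof <- leaves[[i]]$profile
      for (m in markers) {
        p <- if (m %in% names(prof)) prof[[m]] else 0
        pos <- stats::runif(ni) < p
        x <- numeric(ni)
        npos <- sum(pos)
        if (npos) x[pos] <- sample_mode(marker_models[[m]], npos, TRUE)
        if (npos < ni) x[!pos] <- sample_mode(marker_models[[m]], ni - npos, FALSE)
        X[rows, m] <- x
      }
      row0 <- row0 + ni
    }
    event_table(animal_id, X, truth)
  })
}

#' Simulate a full cohort of animals
#'
#' For every animal: draw its true statistic values
#' ([sample_animal_fractions()]), build the panel's population tree with
#' those values ([build_population_specs]), and generate its event table
#' ([generate_events()]).  Identical `cohort_spec`s yield byte-identical
#' cohorts.
#'
#' @param cohort A [cohort_spec()].
#' @param marker_models Optional marker models; defaults to
#'   [default_marker_models()] over the panel's markers.
#' @param out_dir Optional directory: per-animal event CSVs plus a JSON
#'   cohort manifest (label, panel, seeds, file paths) are written there.
#' @return An object of class `cohort_sim`: list with the `cohort` spec,
#'   `animals` (list of [event_table()]s), `truth` (data frame of sampled
#'   per-animal statistic values, percent scale), and `marker_models`.
#' @export
simulate_cohort <- function(cohort, marker_models = NULL, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (is.null(marker_models))
    marker_models <- default_marker_models(panel_markers(cohort$panel))

  animals <- vector("list", cohort$n_animals)
  truth <- vector("list", cohort$n_animals)
  for (i in seq_len(cohort$n_animals)) {
    fr <- sample_animal_fractions(cohort, i)
    specs <- build_population_specs(cohort$panel, fr, cohort$tissue)
    id <- sprintf("%s_%02d", cohort$cohort_label, i)
    animals[[i]] <- generate_events(
      fractions = NULL, marker_models = marker_models,
      population_specs = specs, n_events = cohort$events_per_animal,
      seed = derive_stream_seed(cohort$seed, 100000L + i), animal_id = id)
    truth[[i]] <- data.frame(animal_id = id, population = names(fr),
                             pct = unname(fr) * 100)
  }
  sim <- structure(list(cohort = cohort, animals = animals,
                        truth = do.call(rbind, truth),
                        marker_models = marker_models),
                   class = "cohort_sim")
  if (!is.null(out_dir)) write_cohort(sim, out_dir)
  sim
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %s, panel %s: %d animals x %d events\n",
              x$cohort$cohort_label, x$cohort$panel,
              length(x$animals), x$cohort$events_per_animal))
  invisible(x)
}

# Write per-animal event tables and a JSON manifest for a simulated cohort.
write_cohort <- function(sim, out_dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$animals, function(a) {
    p <- file.path(out_dir, paste0(a$animal_id, ".csv"))
    write_event_table(a, p)
    p
  }, character(1L))
  manifest <- list(
    cohort_label = sim$cohort$cohort_label,
    panel = sim$cohort$panel,
    tissue = sim$cohort$tissue,
    n_animals = sim$cohort$n_animals,
    events_per_animal = sim$cohort$events_per_animal,
    seed = sim$cohort$seed,
    animal_seeds = vapply(seq_along(sim$animals), function(i)
      derive_stream_seed(sim$cohort$seed, 100000L + i), integer(1L)),
    files = basename(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
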