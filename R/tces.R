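#' TCES inputs from gated population results
#'
#' Pulls the six percentages the exhaustion score needs out of an
#' [apply_gate_tree()] result for panel 3 (or 3mod): PD-1/Tim-3 percent
#' expression within the CTL and Th gates (percent-of-parent of the
#' sub-gates) and the CTL/Th percent populations (percent-of-parent of the
#' subset gates under the leukocyte gate).
#'
#' @param results Data frame returned by [apply_gate_tree()] for a panel 3
#'   or 3mod tree.
#' @return A [tces_inputs()] object.
#' @export
tces_from_results <- function(results) {
  pick <- function(pop) {
    i <- match(pop, results$population)
    if (is.na(i))
      stop("population '", pop, "' not found in gated results", call. = FALSE)
    results$pct_of_parent[i]
  }
  tces_inputs(pct_PD1_CTL = pick("PD-1+ CTLs"),
              pct_Tim3_CTL = pick("Tim-3+ CTLs"),
              pct_PD1_Th = pick("PD-1+ Ths"),
              pct_Tim3_Th = pick("Tim-3+ Ths"),
              pct_CTL = pick("CTLs"),
              pct_Th = pick("Ths"))
}

#' Per-animal panel statistics from a simulated (or ingested) cohort
#'
#' Gates every animal's event table through the panel's built-in gate tree
#' and extracts one percent value per panel statistic (the
#' percent-of-parent of the statistic's gate node; see
#' [panel_stat_bindings()]).  For panels 3/3mod a derived `TCES` row is
#' appended per animal.
#'
#' @param animals List of [event_table()]s, or a `cohort_sim` from
#'   [simulate_cohort()] (whose generative thresholds are then used
#'   automatically).
#' @param panel Panel identifier; taken from the cohort when `animals` is a
#'   `cohort_sim`.
#' @param thresholds Named per-marker thresholds; `NULL` estimates them
#'   from each animal's data.
#' @return Long data frame: `animal_id`, `population`, `pct`.
#' @export
per_animal_stats <- function(animals, panel = NULL, thresholds = NULL) {
  if (inherits(animals, "cohort_sim")) {
    if (is.null(panel)) panel <- animals$cohort$panel
    if (is.null(thresholds))
      thresholds <- generative_thresholds(animals$marker_models)
    animals <- animals$animals
  }
  if (is.null(panel))
    stop("'panel' must be given when 'animals' is a plain list", call. = FALSE)
  panel <- normalize_panel(panel)
  tree <- builtin_panels()[[panel]]
  bind <- panel_stat_bindings(panel)

  do.call(rbind, lapply(animals, function(a) {
    res <- apply_gate_tree(a, tree, thresholds)
    pct <- res$pct_of_parent[match(bind$stat, res$population)]
    out <- data.frame(animal_id = a$animal_id, population = bind$stat,
                      pct = pct)
    if (panel %in% c("3", "3mod")) {
      out <- rbind(out, data.frame(
        animal_id = a$animal_id, population = "TCES",
        pct = compute_tces(tces_from_results(res))))
    }
    out
  }))
}
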