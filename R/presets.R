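#' @name cohort-presets
#' @title Built-in cohort presets
#'
#' @description
#' Cohort specifications transcribing the published group summary
#' statistics (mean %, SD %, n) of each experimental arm:
#'
#' * `WT` / `TF`: wild-type and luciferase-transfected K7M2 tumor-bearing
#'   mice (panels 1-2 on dissociated tumors, panels 1, 3, 4 on spleens),
#' * `SH`: vehicle-inoculated sham controls (spleens, panels 3-4),
#' * `TF_aPDL1`: TF tumor-bearing mice treated with 20 ug (1 mg/kg)
#'   anti-PD-L1 twice weekly (spleens, panels 3mod and 4).
#'
#' The published tables report the aggregate TCES per cohort but not the
#' four PD-1/Tim-3 percentages that produce it.  Presets for panel 3 derive
#' hidden per-marker statistics that reproduce the printed TCES mean and
#' spread: each of the four marker percentages gets mean
#' `TCES_mean * (CTL_mean + Th_mean) / 4` and SD
#' `TCES_sd * (CTL_mean + Th_mean) / 4`.
NULL

# (mean, sd) of the four exhaustion-marker percentages implied by a printed
# TCES summary and the printed CTL/Th percent populations.
tces_marker_stats <- function(tces_mean, tces_sd, ctl_mean, th_mean) {
  denom <- ctl_mean + th_mean
  c(mean = tces_mean * denom / 4, sd = tces_sd * denom / 4)
}

pop_stats <- function(...) {
  rows <- list(...)
  data.frame(population = vapply(rows, `[[`, character(1L), 1L),
             mean = vapply(rows, function(r) as.numeric(r[[2L]]), numeric(1L)),
             sd = vapply(rows, function(r) as.numeric(r[[3L]]), numeric(1L)))
}

panel3_stats <- function(nk, ctl, th, treg, ctla4, tces, with_nk = TRUE) {
  mk <- tces_marker_stats(tces[1L], tces[2L], ctl[1L], th[1L])
  base <- if (with_nk) list(list("NK cells", nk[1L], nk[2L])) else list()
  do.call(pop_stats, c(base, list(
    list("CTLs", ctl[1L], ctl[2L]),
    list("Ths", th[1L], th[2L]),
    list("Tregs", treg[1L], treg[2L]),
    list("CTLA-4+ CTLs", ctla4[1L], ctla4[2L]),
    list("PD-1+ CTLs", mk[["mean"]], mk[["sd"]]),
    list("Tim-3+ CTLs", mk[["mean"]], mk[["sd"]]),
    list("PD-1+ Ths", mk[["mean"]], mk[["sd"]]),
    list("Tim-3+ Ths", mk[["mean"]], mk[["sd"]]))))
}

panel4_stats <- function(mlc, mono, gran, tgm2, arg1, cxcl9, nos2) {
  pop_stats(
    list("MLCs", mlc[1L], mlc[2L]),
    list("Monocytes/macrophages", mono[1L], mono[2L]),
    list("Granulocytes", gran[1L], gran[2L]),
    list("Tgm2+ macrophages", tgm2[1L], tgm2[2L]),
    list("Arg1+ macrophages", arg1[1L], arg1[2L]),
    list("Cxcl9+ macrophages", cxcl9[1L], cxcl9[2L]),
    list("Nos2+ macrophages", nos2[1L], nos2[2L]))
}

#' Built-in cohort presets transcribing the published summary tables
#'
#' @param events_per_animal Events per simulated animal (default 50000).
#' @param seed Root seed attached to every preset (default 1).
#' @return Named list of [cohort_spec()] objects.  Keys are
#'   `"<cohort>.panel<id>"` for splenic cohorts and
#'   `"<cohort>.panel<id>.tumor"` for the tumor-tissue cohorts of panels
#'   1-2, e.g. `"TF.panel3"`, `"SH.panel4"`, `"WT.panel1.tumor"`.
#' @seealso [preset()] for keyed access.
#' @export
builtin_cohort_presets <- function(events_per_animal = 50000L, seed = 1L) {
  mk <- function(label, panel, n, stats, tissue = "spleen")
    cohort_spec(label, panel, n, stats,
                events_per_animal = events_per_animal, seed = seed,
                tissue = tissue)
  p1 <- function(nk, ctl, th, treg, mlc, gran) pop_stats(
    list("NK cells", nk[1L], nk[2L]), list("CTLs", ctl[1L], ctl[2L]),
    list("Ths", th[1L], th[2L]), list("Tregs", treg[1L], treg[2L]),
    list("MLCs", mlc[1L], mlc[2L]), list("Granulocytes", gran[1L], gran[2L]))

  list(
    # tumor tissue, lymphoid/myeloid overview (panel 1)
    WT.panel1.tumor = mk("WT", "1", 11, p1(
      c(19.76, 4.76), c(5.45, 3.09), c(6.96, 1.69),
      c(16.95, 10.44), c(36.5, 23.12), c(35.8, 18.32)), "tumor"),
    TF.panel1.tumor = mk("TF", "1", 15, p1(
      c(20.94, 12.67), c(6.07, 7.55), c(5.42, 3.39),
      c(24.02, 15.37), c(34.74, 17.53), c(36.59, 16.38)), "tumor"),
    # tumor tissue, PD-L1 on CD45- cells (panel 2)
    WT.panel2.tumor = mk("WT", "2", 11, pop_stats(
      list("PD-L1+ tumor cells", 1.96, 0.77)), "tumor"),
    TF.panel2.tumor = mk("TF", "2", 15, pop_stats(
      list("PD-L1+ tumor cells", 1.91, 1.28)), "tumor"),
    # spleens, panel 1
    WT.panel1 = mk("WT", "1", 10, p1(
      c(5.35, 4.58), c(7.23, 2.41), c(18, 13.61),
      c(12.68, 6.01), c(5.2, 11.41), c(15.27, 21.82))),
    TF.panel1 = mk("TF", "1", 9, p1(
      c(7.55, 5), c(5.03, 2.64), c(11.71, 12.95),
      c(16.19, 8.43), c(9.76, 10.76), c(52.33, 19.02))),
    # spleens, exhaustion panel
    TF.panel3 = mk("TF", "3", 5, panel3_stats(
      nk = c(10.78, 4.5), ctl = c(2.73, 1.22), th = c(6.45, 3.08),
      treg = c(21.09, 5.12), ctla4 = c(18.35, 10.12),
      tces = c(18.23, 4.58))),
    SH.panel3 = mk("SH", "3", 4, panel3_stats(
      nk = c(1.85, 0.4), ctl = c(3.72, 0.86), th = c(7.72, 1.1),
      treg = c(7.25, 0.23), ctla4 = c(1.72, 0.42),
      tces = c(0.16, 0.054))),
    TF.panel3mod = mk("TF", "3mod", 5, panel3_stats(
      nk = NULL, ctl = c(2.73, 1.22), th = c(6.45, 3.08),
      treg = c(21.09, 5.12), ctla4 = c(18.35, 10.12),
      tces = c(18.23, 4.58), with_nk = FALSE)),
    TF_aPDL1.panel3mod = mk("TF_aPDL1", "3mod", 3, panel3_stats(
      nk = NULL, ctl = c(2.85, 1.13), th = c(5.14, 3.74),
      treg = c(26.63, 7.02), ctla4 = c(44.95, 37.19),
      tces = c(0.79, 0.71), with_nk = FALSE)),
    # spleens, myeloid / M1-M2 panel
    TF.panel4 = mk("TF", "4", 5, panel4_stats(
      mlc = c(5.27, 1.11), mono = c(4.92, 1.29), gran = c(57.49, 9.62),
      tgm2 = c(18.58, 5.69), arg1 = c(0.3, 0.56),
      cxcl9 = c(18.28, 5.38), nos2 = c(97.99, 1.62))),
    SH.panel4 = mk("SH", "4", 4, panel4_stats(
      mlc = c(1.39, 0.4), mono = c(7.49, 1.7), gran = c(74.69, 4.55),
      tgm2 = c(4.22, 2.66), arg1 = c(0, 0),
      cxcl9 = c(1.44, 1.23), nos2 = c(16.56, 10.19))),
    TF_aPDL1.panel4 = mk("TF_aPDL1", "4", 3, panel4_stats(
      mlc = c(5.73, 1.68), mono = c(12.8, 2.92), gran = c(51.37, 9.11),
      tgm2 = c(2.1, 2.17), arg1 = c(0.23, 0.17),
      cxcl9 = c(1.52, 1.24), nos2 = c(50.89, 18.07))))
}

#' Look up one built-in cohort preset
#'
#' @param cohort_label Cohort name (`"WT"`, `"TF"`, `"SH"`, `"TF_aPDL1"`).
#' @param panel Panel identifier.
#' @param tissue `"spleen"` (default) or `"tumor"`.
#' @param ... Passed to [builtin_cohort_presets()] (`events_per_animal`,
#'   `seed`).
#' @return A [cohort_spec()].
#' @export
preset <- function(cohort_label, panel, tissue = "spleen", ...) {
  key <- paste0(cohort_label, ".panel", normalize_panel(panel),
                if (tissue == "tumor") ".tumor" else "")
  presets <- builtin_cohort_presets(...)
  if (!key %in% names(presets))
    stop("no built-in preset '", key, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[key]]
}
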