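#' @name panels
#' @title Built-in antibody panels
#'
#' @description
#' Four staining panels cover the immunophenotyping workflow:
#'
#' * **panel 1** (lymphoid + myeloid overview): CD45, CD4, CD8, NKp46,
#'   CD11b, Ly6G, Foxp3.  Populations: NK cells, CTLs, Ths, Tregs
#'   (Foxp3+ within Ths), MLCs, granulocytes (Ly6G+ within MLCs).
#' * **panel 2** (tumor PD-L1): CD45, PD-L1.  The CD45- gate captures
#'   tumor cells and stroma; PD-L1 positivity is scored within it.
#' * **panel 3** (T-cell exhaustion): CD45, CD4, CD8, NKp46, Foxp3,
#'   PD-1, Tim-3, CTLA-4.  Adds the exhaustion / checkpoint sub-gates on
#'   CTLs and Ths that feed the TCES statistic.  **panel 3mod** is the
#'   same panel without the NKp46 NK-cell identifier.
#' * **panel 4** (myeloid maturation + M1/M2): CD45, CD11b, Ly6C, Ly6G,
#'   Tgm2, Arg1, Cxcl9, Nos2.  MLCs split into Ly6C+Ly6G-
#'   monocytes/macrophages and Ly6G+Ly6C- granulocytes; the four
#'   polarization markers are scored on monocytes/macrophages.
#'
#' All population percentages are reported as percent-of-parent; top-level
#' leukocyte populations therefore read as percent of the CD45+ gate, and
#' tumor PD-L1 as percent of the CD45- gate.
NULL

PANEL_IDS <- c("1", "2", "3", "3mod", "4")

normalize_panel <- function(panel) {
  panel <- as.character(panel)
  if (length(panel) != 1L || !panel %in% PANEL_IDS)
    stop("unknown panel '", paste(panel, collapse = ","),
         "'; available: ", paste(PANEL_IDS, collapse = ", "), call. = FALSE)
  panel
}

#' Marker list of a staining panel
#'
#' @param panel Panel identifier: `"1"`, `"2"`, `"3"`, `"3mod"` or `"4"`.
#' @return Character vector of marker names.
#' @export
panel_markers <- function(panel) {
  switch(normalize_panel(panel),
    "1"    = c("CD45", "CD4", "CD8", "NKp46", "CD11b", "Ly6G", "Foxp3"),
    "2"    = c("CD45", "PDL1"),
    "3"    = c("CD45", "CD4", "CD8", "NKp46", "Foxp3", "PD1", "Tim3", "CTLA4"),
    "3mod" = c("CD45", "CD4", "CD8", "Foxp3", "PD1", "Tim3", "CTLA4"),
    "4"    = c("CD45", "CD11b", "Ly6C", "Ly6G", "Tgm2", "Arg1", "Cxcl9", "Nos2"))
}

#' Built-in gate trees, one per antibody panel
#'
#' Thresholds are left unset (`NA`) in the returned trees; they are supplied
#' at gating time, either as the generative thresholds of the simulation's
#' marker models or estimated from the data (see [apply_gate_tree()]).
#'
#' @return Named list of [gate_tree()] objects keyed by panel id.
#' @seealso [panel_markers()], [panel_stat_bindings()]
#' @export
builtin_panels <- function() {
  g <- function(marker, sign = "+") gate(marker, sign)
  node <- function(parent, ...) list(parent = parent, gates = list(...))

  lymphoid <- list(
    "leukocytes" = node("all", g("CD45")),
    "NK cells"   = node("leukocytes", g("NKp46")),
    "CTLs"       = node("leukocytes", g("CD8")),
    "Ths"        = node("leukocytes", g("CD4")),
    "Tregs"      = node("Ths", g("Foxp3")))

  exhaustion <- list(
    "CTLA-4+ CTLs" = node("CTLs", g("CTLA4")),
    "PD-1+ CTLs"   = node("CTLs", g("PD1")),
    "Tim-3+ CTLs"  = node("CTLs", g("Tim3")),
    "PD-1+ Ths"    = node("Ths", g("PD1")),
    "Tim-3+ Ths"   = node("Ths", g("Tim3")))

  list(
    "1" = gate_tree(c(lymphoid, list(
      "MLCs"         = node("leukocytes", g("CD11b")),
      "Granulocytes" = node("MLCs", g("Ly6G"))))),
    "2" = gate_tree(list(
      "tumor cells"        = node("all", g("CD45", "-")),
      "PD-L1+ tumor cells" = node("tumor cells", g("PDL1")))),
    "3" = gate_tree(c(lymphoid, exhaustion)),
    "3mod" = gate_tree(c(lymphoid[names(lymphoid) != "NK cells"], exhaustion)),
    "4" = gate_tree(list(
      "leukocytes"            = node("all", g("CD45")),
      "MLCs"                  = node("leukocytes", g("CD11b")),
      "Monocytes/macrophages" = node("MLCs", g("Ly6C"), g("Ly6G", "-")),
      "Granulocytes"          = node("MLCs", g("Ly6G"), g("Ly6C", "-")),
      "Tgm2+ macrophages"     = node("Monocytes/macrophages", g("Tgm2")),
      "Arg1+ macrophages"     = node("Monocytes/macrophages", g("Arg1")),
      "Cxcl9+ macrophages"    = node("Monocytes/macrophages", g("Cxcl9")),
      "Nos2+ macrophages"     = node("Monocytes/macrophages", g("Nos2")))))
}

#' How each reported statistic binds to the simulation
#'
#' Every "% expression" statistic of a panel is either the *fraction* a
#' population occupies of its parent gate (realized by multinomial event
#' assignment) or the probability that events of a parent population are
#' positive for one *marker* (realized per event as a Bernoulli draw).  The
#' binding table drives both the cohort simulator and the extraction of
#' per-animal statistics from gated results: in both cases the statistic is
#' the percent-of-parent of the gate-tree node named in `node`.
#'
#' @param panel Panel identifier.
#' @return Data frame with columns `stat` (statistic label = gate-tree node
#'   label), `kind` (`"fraction"` or `"marker"`), `parent` (parent
#'   population), and `marker` (`NA` for fractions).
#' @export
panel_stat_bindings <- function(panel) {
  b <- function(stat, kind, parent, marker = NA_character_)
    data.frame(stat = stat, kind = kind, parent = parent, marker = marker)
  switch(normalize_panel(panel),
    "1" = rbind(
      b("NK cells", "fraction", "leukocytes"),
      b("CTLs", "fraction", "leukocytes"),
      b("Ths", "fraction", "leukocytes"),
      b("Tregs", "marker", "Ths", "Foxp3"),
      b("MLCs", "fraction", "leukocytes"),
      b("Granulocytes", "marker", "MLCs", "Ly6G")),
    "2" = b("PD-L1+ tumor cells", "marker", "tumor cells", "PDL1"),
    "3" = rbind(
      b("NK cells", "fraction", "leukocytes"),
      b("CTLs", "fraction", "leukocytes"),
      b("Ths", "fraction", "leukocytes"),
      b("Tregs", "marker", "Ths", "Foxp3"),
      b("CTLA-4+ CTLs", "marker", "CTLs", "CTLA4"),
      b("PD-1+ CTLs", "marker", "CTLs", "PD1"),
      b("Tim-3+ CTLs", "marker", "CTLs", "Tim3"),
      b("PD-1+ Ths", "marker", "Ths", "PD1"),
      b("Tim-3+ Ths", "marker", "Ths", "Tim3")),
    "3mod" = {
      x <- panel_stat_bindings("3")
      x[x$stat != "NK cells", , drop = FALSE]
    },
    "4" = rbind(
      b("MLCs", "fraction", "leukocytes"),
      b("Monocytes/macrophages", "fraction", "MLCs"),
      b("Granulocytes", "fraction", "MLCs"),
      b("Tgm2+ macrophages", "marker", "Monocytes/macrophages", "Tgm2"),
      b("Arg1+ macrophages", "marker", "Monocytes/macrophages", "Arg1"),
      b("Cxcl9+ macrophages", "marker", "Monocytes/macrophages", "Cxcl9"),
      b("Nos2+ macrophages", "marker", "Monocytes/macrophages", "Nos2")))
}

#' Rows of a panel's comparison report
#'
#' These are the populations a published comparison table of the panel
#' carries, in table order.  Their number is the Bonferroni family size of
#' the panel's comparisons.  The exhaustion sub-gates of panel 3 are not
#' rows themselves: they enter through the derived `TCES` row.
#'
#' @param panel Panel identifier.
#' @return Character vector of row labels.
#' @export
report_rows <- function(panel) {
  switch(normalize_panel(panel),
    "1"    = c("NK cells", "CTLs", "Ths", "Tregs", "MLCs", "Granulocytes"),
    "2"    = "PD-L1+ tumor cells",
    "3"    = c("NK cells", "CTLs", "Ths", "Tregs", "CTLA-4+ CTLs", "TCES"),
    "3mod" = c("CTLs", "Ths", "Tregs", "CTLA-4+ CTLs", "TCES"),
    "4"    = c("MLCs", "Monocytes/macrophages", "Granulocytes",
               "Tgm2+ macrophages", "Arg1+ macrophages",
               "Cxcl9+ macrophages", "Nos2+ macrophages"))
}

# Fraction of acquired events inside the top-level compartment (CD45+ for
# spleens after density-gradient leukocyte enrichment; for dissociated
# tumors most events are CD45- tumor/stroma).  Stated-world constants of
# the simulator, not tunables.
leukocyte_fraction <- function(tissue = c("spleen", "tumor")) {
  switch(match.arg(tissue), spleen = 0.95, tumor = 0.40)
}

# Build the population_spec list realizing one simulated animal of a panel.
# `fractions` is a named vector (binding stat -> fraction in [0, 1]); kind
# "fraction" stats become population target_fractions, kind "marker" stats
# become marker-positivity probabilities on their parent population.
build_population_specs <- function(panel, fractions,
                                   tissue = c("spleen", "tumor")) {
  panel <- normalize_panel(panel)
  tissue <- match.arg(tissue)
  bind <- panel_stat_bindings(panel)
  missing <- setdiff(bind$stat, names(fractions))
  if (length(missing))
    stop("configuration error: no fraction supplied for statistic(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  frac <- function(stat) unname(fractions[[stat]])
  # marker probabilities attached to each population
  prof_extra <- list()
  for (i in which(bind$kind == "marker")) {
    par <- bind$parent[i]
    prof_extra[[par]] <- c(prof_extra[[par]],
                           stats::setNames(frac(bind$stat[i]), bind$marker[i]))
  }
  prof <- function(pop, base) c(as.list(base), as.list(prof_extra[[pop]]))

  lf <- leukocyte_fraction(tissue)
  if (panel == "2") {
    return(list(
      population_spec("leukocytes", "root", lf, c(CD45 = 1)),
      population_spec("tumor cells", "root", 1 - lf,
                      prof("tumor cells", c(CD45 = 0)))))
  }

  specs <- list(population_spec("leukocytes", "root", lf, c(CD45 = 1)))
  add <- function(label, parent, fraction, base)
    population_spec(label, parent, fraction, prof(label, base))
  if (panel %in% c("1", "3")) {
    specs <- c(specs, list(add("NK cells", "leukocytes",
                               frac("NK cells"), c(NKp46 = 1))))
  }
  if (panel %in% c("1", "3", "3mod")) {
    specs <- c(specs, list(
      add("CTLs", "leukocytes", frac("CTLs"), c(CD8 = 1)),
      add("Ths", "leukocytes", frac("Ths"), c(CD4 = 1))))
  }
  if (panel == "1") {
    specs <- c(specs, list(add("MLCs", "leukocytes",
                               frac("MLCs"), c(CD11b = 1))))
  }
  if (panel == "4") {
    specs <- c(specs, list(
      add("MLCs", "leukocytes", frac("MLCs"), c(CD11b = 1)),
      add("Monocytes/macrophages", "MLCs", frac("Monocytes/macrophages"),
          c(Ly6C = 1, Ly6G = 0)),
      add("Granulocytes", "MLCs", frac("Granulocytes"),
          c(Ly6G = 1, Ly6C = 0))))
  }
  specs
}
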