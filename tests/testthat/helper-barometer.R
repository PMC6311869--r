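# Shared fixtures and independent oracles for the suite.

# Hand-written event table: intensities chosen far from any sensible
# threshold (lo = 10, hi = 1e4; generative default threshold ~ 894).
LO <- 10
HI <- 1e4

manual_events <- function(..., animal_id = "fixture") {
  # each argument: named numeric vector of marker intensities for one event
  rows <- list(...)
  markers <- names(rows[[1L]])
  X <- do.call(rbind, lapply(rows, function(r) r[markers]))
  colnames(X) <- markers
  event_table(animal_id, X)
}

# 10 events, CD45 hi for the first five
fixture_cd45 <- function() {
  X <- matrix(c(rep(HI, 5), rep(LO, 5)), ncol = 1,
              dimnames = list(NULL, "CD45"))
  event_table("cd45_fixture", X)
}

# 20 labeled events across a CTL/Th/Treg hierarchy, manual tally:
#   leukocytes 18 (CD45 hi), CTLs 8, Ths 10 of which Tregs 3, debris 2
fixture_tcells <- function() {
  mk <- function(cd45, cd8, cd4, foxp3, n)
    matrix(rep(c(cd45, cd8, cd4, foxp3), each = n), nrow = n,
           dimnames = list(NULL, c("CD45", "CD8", "CD4", "Foxp3")))
  X <- rbind(mk(HI, HI, LO, LO, 8),   # CTLs
             mk(HI, LO, HI, LO, 7),   # Ths, Foxp3-
             mk(HI, LO, HI, HI, 3),   # Tregs
             mk(LO, LO, LO, LO, 2))   # non-leukocyte debris
  event_table("tcell_fixture", X,
              truth = rep(c("CTL", "Th", "Treg", "debris"), c(8, 7, 3, 2)))
}

tcell_tree <- function() {
  gate_tree(list(
    leukocytes = list(parent = "all", gates = list(gate("CD45"))),
    CTLs = list(parent = "leukocytes", gates = list(gate("CD8"))),
    Ths = list(parent = "leukocytes", gates = list(gate("CD4"))),
    Tregs = list(parent = "Ths", gates = list(gate("Foxp3")))))
}

FIX_THRESH <- c(CD45 = 1000, CD8 = 1000, CD4 = 1000, Foxp3 = 1000)

# Independent per-event brute-force evaluator of a gate tree: walks the
# hierarchy separately for every single event, no vectorization, no shared
# code with apply_gate_tree beyond the gate fields themselves.
brute_force_gate_counts <- function(events, tree, thresholds) {
  X <- events$intensities
  labs <- names(tree$nodes)
  event_member <- function(i, label) {
    if (label == tree$root) return(TRUE)
    node <- tree$nodes[[label]]
    if (!event_member(i, node$parent)) return(FALSE)
    for (g in node$gates) {
      thr <- if (!is.na(g$threshold)) g$threshold else thresholds[[g$marker]]
      v <- X[i, g$marker]
      ok <- if (g$sign == "+") v > thr else v <= thr
      if (!ok) return(FALSE)
    }
    TRUE
  }
  counts <- integer(length(labs))
  names(counts) <- labs
  for (i in seq_len(nrow(X)))
    for (lab in labs)
      if (event_member(i, lab)) counts[lab] <- counts[lab] + 1L
  counts
}

# Random population tree + mirrored gate tree for recovery/property tests.
# Every node is defined by its own dedicated marker (positive), so gating
# with the generative thresholds recovers the population structure exactly.
random_tree_case <- function(seed, max_children = 3L) {
  withr::with_seed(seed, {
    n_top <- sample(2:max_children, 1L)
    labels <- paste0("P", seq_len(n_top))
    fr_top <- stats::runif(n_top)
    fr_top <- 0.85 * fr_top / sum(fr_top)
    specs <- list()
    gnodes <- list()
    frac <- stats::setNames(fr_top, labels)
    parent <- stats::setNames(rep("root", n_top), labels)
    for (i in seq_len(n_top)) {
      specs[[labels[i]]] <- population_spec(
        labels[i], "root", fr_top[i],
        stats::setNames(list(1), paste0("M", labels[i])))
      gnodes[[labels[i]]] <- list(parent = "all",
                                  gates = list(gate(paste0("M", labels[i]))))
    }
    # give one random top node a pair of children
    par <- sample(labels, 1L)
    fr_kid <- stats::runif(2L)
    fr_kid <- 0.8 * fr_kid / sum(fr_kid)
    for (j in 1:2) {
      lab <- paste0(par, "c", j)
      specs[[lab]] <- population_spec(
        lab, par, fr_kid[j], stats::setNames(list(1), paste0("M", lab)))
      gnodes[[lab]] <- list(parent = par,
                            gates = list(gate(paste0("M", lab))))
      frac[lab] <- fr_kid[j]
      parent[lab] <- par
    }
    markers <- paste0("M", names(specs))
    list(specs = unname(specs), tree = gate_tree(gnodes),
         models = default_marker_models(markers),
         frac = frac, parent = parent)
  })
}
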