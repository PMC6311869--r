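# Gating engine: boolean classification, tree evaluation, built-in panels.

test_that("an empty gate list is the vacuous conjunction", {
  et <- fixture_cd45()
  expect_true(all(classify_events(et, list())))
})

test_that("a threshold between the modes of a manual fixture splits 5/5", {
  et <- fixture_cd45()
  mask <- classify_events(et, list(gate("CD45", threshold = 1000)))
  expect_equal(sum(mask), 5)
  expect_equal(which(mask), 1:5)
})

test_that("negative gates complement positive gates at the same threshold", {
  case <- random_tree_case(12)
  et <- generate_events(NULL, case$models, case$specs, 3000, seed = 2)
  m <- colnames(et$intensities)[1]
  pos <- classify_events(et, list(gate(m, "+", 500)))
  neg <- classify_events(et, list(gate(m, "-", 500)))
  expect_identical(neg, !pos)
  expect_equal(sum(pos) + sum(neg), 3000)
})

test_that("gating a missing marker names the marker in the error", {
  expect_error(classify_events(fixture_cd45(), list(gate("CD99"))),
               "gating error.*CD99")
})

test_that("hand-tallied T-cell fixture is gated exactly", {
  res <- apply_gate_tree(fixture_tcells(), tcell_tree(), FIX_THRESH)
  cnt <- stats::setNames(res$n_events, res$population)
  expect_equal(cnt[["leukocytes"]], 18)
  expect_equal(cnt[["CTLs"]], 8)
  expect_equal(cnt[["Ths"]], 10)
  expect_equal(cnt[["Tregs"]], 3)
  pct <- stats::setNames(res$pct_of_parent, res$population)
  expect_equal(pct[["Tregs"]], 100 * 3 / 10)
  expect_equal(pct[["leukocytes"]], 100 * 18 / 20)
  root_pct <- stats::setNames(res$pct_of_root, res$population)
  expect_equal(root_pct[["Tregs"]], 100 * 3 / 20)
})

test_that("empty populations report zero percent, not a division error", {
  et <- fixture_cd45()
  tree <- gate_tree(list(
    none = list(parent = "all", gates = list(gate("CD45", threshold = 1e9))),
    sub = list(parent = "none", gates = list(gate("CD45", threshold = 0)))))
  res <- apply_gate_tree(et, tree, c(CD45 = 1000))
  expect_equal(res$n_events, c(0L, 0L))
  expect_equal(res$pct_of_parent, c(0, 0))
})

test_that("adding a gate to a node never increases its count", {
  case <- random_tree_case(21)
  et <- generate_events(NULL, case$models, case$specs, 4000, seed = 3)
  thr <- generative_thresholds(case$models)
  markers <- colnames(et$intensities)
  base <- list(gate(markers[1]))
  n0 <- sum(classify_events(et, base, thr))
  for (m in markers[-1]) {
    n1 <- sum(classify_events(et, c(base, list(gate(m))), thr))
    expect_lte(n1, n0)
  }
})

test_that("apply_gate_tree matches a per-event brute-force walker", {
  for (s in c(2, 5, 9)) {
    case <- random_tree_case(s)
    et <- generate_events(NULL, case$models, case$specs, 800, seed = 30 + s)
    thr <- generative_thresholds(case$models)
    res <- apply_gate_tree(et, case$tree, thr)
    brute <- brute_force_gate_counts(et, case$tree, thr)
    expect_equal(stats::setNames(res$n_events, res$population),
                 brute[res$population])
  }
  # also on the hand fixture
  res <- apply_gate_tree(fixture_tcells(), tcell_tree(), FIX_THRESH)
  brute <- brute_force_gate_counts(fixture_tcells(), tcell_tree(), FIX_THRESH)
  expect_equal(stats::setNames(res$n_events, res$population),
               brute[res$population])
})

test_that("gated counts agree exactly with generator truth labels", {
  case <- random_tree_case(14)
  et <- generate_events(NULL, case$models, case$specs, 8000, seed = 77)
  res <- apply_gate_tree(et, case$tree, generative_thresholds(case$models))
  # a truth label belongs to a node when the node lies on its parent chain
  # ("<lab>/other" remainder leaves sit directly under <lab>)
  in_subtree <- function(truth_lab, node) {
    lab <- sub("/other$", "", truth_lab)
    while (TRUE) {
      if (lab == node) return(TRUE)
      if (!lab %in% names(case$parent)) return(FALSE)
      lab <- case$parent[[lab]]
      if (lab == "root") return(FALSE)
    }
  }
  for (k in seq_len(nrow(res))) {
    lab <- res$population[k]
    expected <- sum(vapply(et$truth, in_subtree, logical(1L), node = lab))
    expect_equal(res$n_events[k], expected, label = lab)
  }
})

test_that("cyclic or orphaned gate trees are rejected", {
  expect_error(gate_tree(list(
    a = list(parent = "b", gates = list()),
    b = list(parent = "a", gates = list()))), "cycle or orphan")
  expect_error(gate_tree(list(
    a = list(parent = "nowhere", gates = list()))), "cycle or orphan")
})

test_that("built-in panels encode the published population definitions", {
  panels <- builtin_panels()
  # effective monocyte/macrophage gate chain: CD45+ CD11b+ Ly6C+ Ly6G-
  p4 <- panels[["4"]]
  chain <- list()
  lab <- "Monocytes/macrophages"
  while (lab != "all") {
    chain <- c(p4$nodes[[lab]]$gates, chain)
    lab <- p4$nodes[[lab]]$parent
  }
  sig <- vapply(chain, function(g) paste0(g$marker, g$sign), character(1L))
  expect_setequal(sig, c("CD45+", "CD11b+", "Ly6C+", "Ly6G-"))

  # tumor panel roots at the CD45- (non-leukocyte) gate
  p2 <- panels[["2"]]
  expect_equal(p2$nodes[["tumor cells"]]$parent, "all")
  g <- p2$nodes[["tumor cells"]]$gates[[1]]
  expect_equal(c(g$marker, g$sign), c("CD45", "-"))

  # the modified exhaustion panel drops the NK identifier
  expect_false("NK cells" %in% names(panels[["3mod"]]$nodes))
  expect_false("NKp46" %in% panel_markers("3mod"))
  expect_true("NKp46" %in% panel_markers("3"))

  # every panel statistic is a node of its panel's tree
  for (p in c("1", "2", "3", "3mod", "4")) {
    bind <- panel_stat_bindings(p)
    expect_true(all(bind$stat %in% names(panels[[p]]$nodes)), label = p)
  }
})

test_that("density-valley threshold estimation separates clear modes", {
  models <- default_marker_models("M")
  specs <- list(population_spec("hi", "root", 0.4, c(M = 1)))
  et <- generate_events(NULL, models, specs, 20000, seed = 13)
  thr <- estimate_threshold(et$intensities[, "M"])
  gen <- generative_threshold(models[["M"]])
  # threshold lands between the modes: classification matches generative cut
  est <- classify_events(et, list(gate("M")), c(M = thr))
  ref <- classify_events(et, list(gate("M")), c(M = gen))
  expect_gt(mean(est == ref), 0.999)
  # unimodal columns yield an everything-negative threshold
  uni <- et$intensities[et$truth != "hi", "M", drop = TRUE]
  expect_gt(estimate_threshold(uni), max(uni))
})

test_that("gate trees round-trip through JSON", {
  tree <- tcell_tree()
  path <- withr::local_tempfile(fileext = ".json")
  gate_tree_to_json(tree, path)
  back <- gate_tree_from_json(path)
  expect_equal(back, tree)
})
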