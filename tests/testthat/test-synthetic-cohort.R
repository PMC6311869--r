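# Cohort simulator: per-animal sampling, event generation, presets.

test_that("zero SD collapses every animal onto the cohort means", {
  st <- data.frame(population = c("CTLs", "Ths"), mean = c(10, 20), sd = 0)
  spec <- cohort_spec("TF", "3", 3, st, seed = 11)
  for (i in 1:3)
    expect_equal(unname(sample_animal_fractions(spec, i)), c(0.10, 0.20))
})

test_that("animal fraction draws are deterministic in (seed, animal_index)", {
  spec <- preset("TF", "3", seed = 17)
  expect_identical(sample_animal_fractions(spec, 2),
                   sample_animal_fractions(spec, 2))
  expect_false(identical(sample_animal_fractions(spec, 1),
                         sample_animal_fractions(spec, 2)))
  spec2 <- preset("TF", "3", seed = 18)
  expect_false(identical(sample_animal_fractions(spec, 1),
                         sample_animal_fractions(spec2, 1)))
})

test_that("sampled fractions recover the printed Treg moments at large n", {
  # Tregs 21.09 +/- 5.12 in the TF exhaustion-panel cohort
  spec <- preset("TF", "3", seed = 4)
  tregs <- vapply(1:1500,
                  function(i) sample_animal_fractions(spec, i)[["Tregs"]],
                  numeric(1L)) * 100
  expect_lt(abs(mean(tregs) - 21.09), 0.5)
  expect_lt(abs(sd(tregs) - 5.12), 0.4)
})

test_that("cohort-level moments are recovered across 200 animals", {
  spec <- preset("TF", "3", seed = 42)
  draws <- t(vapply(1:200, function(i) sample_animal_fractions(spec, i),
                    numeric(nrow(spec$population_stats)))) * 100
  st <- spec$population_stats
  # At n = 200 the Monte-Carlo SE of a sample SD is ~5% of the SD, so the
  # 10%-relative band is a ~2-sigma test per statistic; across 9 statistics
  # a single excursion is expected behaviour, two are not.
  sd_excursions <- 0L
  for (j in seq_len(ncol(draws))) {
    expect_lt(abs(mean(draws[, j]) - st$mean[j]), 0.1 * st$mean[j] + 1e-9,
              label = sprintf("mean of %s (%.2f vs %.2f)", st$population[j],
                              mean(draws[, j]), st$mean[j]))
    if (abs(sd(draws[, j]) - st$sd[j]) >= 0.1 * st$sd[j])
      sd_excursions <- sd_excursions + 1L
  }
  expect_lte(sd_excursions, 1L)
})

test_that("over-full sibling population fractions are rescaled proportionally", {
  st <- data.frame(population = c("CTLs", "Ths"), mean = c(70, 50), sd = 0)
  spec <- cohort_spec("X", "3", 3, st)
  fr <- sample_animal_fractions(spec, 1)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr[["CTLs"]] / fr[["Ths"]]), 70 / 50)
})

test_that("unknown population labels are a configuration error", {
  st <- data.frame(population = "Basophils", mean = 1, sd = 0)
  expect_error(cohort_spec("TF", "3", 3, st), "unknown population label")
  expect_error(cohort_spec("TF", "3", 2, preset("TF", "3")$population_stats),
               "at least 3")
})

test_that("a single population with fraction 1 owns every event", {
  models <- default_marker_models("M1")
  spec <- population_spec("only", "root", 1, c(M1 = 1))
  et <- generate_events(NULL, models, list(spec), 500, seed = 1)
  expect_identical(unique(et$truth), "only")
  expect_equal(nrow(et$intensities), 500)
})

test_that("event generation is bit-identical under a fixed seed", {
  case <- random_tree_case(3)
  a <- generate_events(NULL, case$models, case$specs, 2000, seed = 99)
  b <- generate_events(NULL, case$models, case$specs, 2000, seed = 99)
  expect_identical(a, b)
  c <- generate_events(NULL, case$models, case$specs, 2000, seed = 100)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("population event counts conserve n_events", {
  case <- random_tree_case(7)
  et <- generate_events(NULL, case$models, case$specs, 12345, seed = 5)
  expect_equal(length(et$truth), 12345)
  expect_equal(sum(table(et$truth)), 12345)
})

test_that("a 50/50 split is recovered within 3 binomial SEs at 50k events", {
  models <- default_marker_models(c("MA", "MB"))
  specs <- list(population_spec("A", "root", 0.5, c(MA = 1)),
                population_spec("B", "root", 0.5, c(MB = 1)))
  et <- generate_events(NULL, models, specs, 50000, seed = 21)
  thr <- generative_thresholds(models)
  phat <- mean(classify_events(et, list(gate("MA")), thr))
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 50000))
})

test_that("gating recovers target fractions over 20 random trees (3 SE at 50k)", {
  for (s in 1:20) {
    case <- random_tree_case(s)
    et <- generate_events(NULL, case$models, case$specs, 50000, seed = 1000 + s)
    res <- apply_gate_tree(et, case$tree, generative_thresholds(case$models))
    parent_n <- c(all = 50000,
                  stats::setNames(res$n_events, res$population))
    for (k in seq_len(nrow(res))) {
      lab <- res$population[k]
      p <- case$frac[[lab]]
      n_par <- parent_n[[res$parent[k]]]
      se <- sqrt(p * (1 - p) / n_par)
      expect_lt(abs(res$pct_of_parent[k] / 100 - p), 3 * se + 1e-12,
                label = sprintf("tree %d node %s", s, lab))
    }
  }
})

test_that("markers referenced but not modelled are a configuration error", {
  spec <- population_spec("A", "root", 1, c(Mystery = 1))
  expect_error(generate_events(NULL, default_marker_models("M1"), list(spec),
                               10, seed = 1),
               "absent from marker_models.*Mystery")
})

test_that("marker model invariants are enforced", {
  expect_error(marker_model("X", negative = c(5, 0.5), positive = c(4, 0.5)),
               "exceed")
  expect_error(marker_model("X", negative = c(1, 1), positive = c(3, 1)),
               "not separable")
  expect_error(marker_model("X", negative = c(1, 0), positive = c(5, 0.3)),
               "scales")
})

test_that("built-in presets transcribe the published summary statistics", {
  sh3 <- preset("SH", "3")
  expect_equal(sh3$n_animals, 4L)
  tr <- sh3$population_stats[sh3$population_stats$population == "Tregs", ]
  expect_equal(c(tr$mean, tr$sd), c(7.25, 0.23))

  tf4 <- preset("TF", "4")
  expect_equal(tf4$n_animals, 5L)
  nos2 <- tf4$population_stats[
    tf4$population_stats$population == "Nos2+ macrophages", ]
  expect_equal(c(nos2$mean, nos2$sd), c(97.99, 1.62))

  ap4 <- preset("TF_aPDL1", "4")
  expect_equal(ap4$n_animals, 3L)
  mono <- ap4$population_stats[
    ap4$population_stats$population == "Monocytes/macrophages", ]
  expect_equal(c(mono$mean, mono$sd), c(12.8, 2.92))

  # hidden exhaustion-marker stats reconstruct the printed TCES mean
  tf3 <- preset("TF", "3")$population_stats
  g <- function(p) tf3$mean[tf3$population == p]
  tces <- (g("PD-1+ CTLs") + g("Tim-3+ CTLs") + g("PD-1+ Ths") +
             g("Tim-3+ Ths")) / (g("CTLs") + g("Ths"))
  expect_equal(tces, 18.23)
})

test_that("simulated cohorts are reproducible and exportable", {
  spec <- preset("SH", "3", seed = 8, events_per_animal = 600)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$animals, b$animals)
  expect_identical(a$truth, b$truth)

  dir <- withr::local_tempdir()
  simulate_cohort(spec, out_dir = dir)
  man <- jsonlite::fromJSON(file.path(dir, "cohort_manifest.json"))
  expect_equal(man$n_animals, 4)
  expect_true(all(file.exists(file.path(dir, man$files))))
  rt <- read_event_table(file.path(dir, man$files[1]))
  expect_equal(rt$intensities, a$animals[[1]]$intensities,
               ignore_attr = FALSE, tolerance = 1e-12)
  expect_identical(rt$truth, a$animals[[1]]$truth)
})
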