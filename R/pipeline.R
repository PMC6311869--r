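#' Configuration of a full barometer run
#'
#' @param comparisons Data frame of comparisons to run; defaults to
#'   [builtin_comparisons()], the seven published two-group tables.
#' @param mode `"summary"` recomputes each table deterministically from the
#'   printed summary statistics; `"simulation"` generates event-level
#'   cohorts from the built-in presets, gates them, and compares the gated
#'   per-animal statistics.
#' @param seed Root seed; every source of randomness in a run flows from
#'   it.
#' @param events_per_animal Events per simulated animal (simulation mode;
#'   `NULL` keeps the preset default of 50000).
#' @param out_dir Optional output directory for rendered tables and the run
#'   manifest.
#' @param digits Significant digits used by table renderers (display only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(comparisons = builtin_comparisons(),
                       mode = c("summary", "simulation"), seed = 1L,
                       events_per_animal = NULL, out_dir = NULL,
                       digits = 4L) {
  mode <- match.arg(mode)
  comparisons <- as.data.frame(comparisons)
  need <- c("id", "table", "panel", "tissue", "cohort_a", "cohort_b")
  if (!all(need %in% names(comparisons)))
    stop("'comparisons' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(comparisons) < 1L)
    stop("at least one comparison is required", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(list(comparisons = comparisons, mode = mode, seed = seed,
                 events_per_animal = events_per_animal, out_dir = out_dir,
                 digits = as.integer(digits)),
            class = "run_config")
}

#' The seven published two-group comparisons
#'
#' @return Data frame with one row per comparison: `id`, the published
#'   `table` it mirrors, `panel`, `tissue` and the two cohort labels.
#' @export
builtin_comparisons <- function() {
  data.frame(
    id = c("tumor_wbc", "tumor_pdl1", "spleen_wbc",
           "spleen_llc", "spleen_mlc", "spleen_llc_apdl1",
           "spleen_mlc_apdl1"),
    table = paste0("table", c(2, 3, 4, 5, 6, 7, 8)),
    panel = c("1", "2", "1", "3", "4", "3mod", "4"),
    tissue = c("tumor", "tumor", "spleen", "spleen", "spleen", "spleen",
               "spleen"),
    cohort_a = c("WT", "WT", "WT", "TF", "TF", "TF", "TF"),
    cohort_b = c("TF", "TF", "TF", "SH", "SH", "TF_aPDL1", "TF_aPDL1"))
}

#' Run the simulate -> gate -> score -> compare pipeline
#'
#' In summary mode each requested comparison is recomputed from the printed
#' group summaries, reproducing the published tables row for row.  In
#' simulation mode both cohorts are generated event-level from their
#' presets (all randomness derived from `config$seed`), gated with the
#' generative thresholds, scored (TCES for panels 3/3mod), summarized and
#' compared.  Any stage failure aborts with the comparison and stage named.
#'
#' @param config A [run_config()].
#' @return Named list of report tables (class `report_table`), one per
#'   comparison: `title`, `rows` (a [compare_panels()] data frame),
#'   `footnote`, `corrected_alpha`, `mode`, `seed`.  When
#'   `config$out_dir` is set, each report is also rendered to CSV, JSON
#'   and Markdown and a JSON run manifest is written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tabs <- printed_tables()
  reports <- list()
  for (i in seq_len(nrow(config$comparisons))) {
    cmp <- config$comparisons[i, ]
    reports[[cmp$id]] <- tryCatch(
      run_one_comparison(cmp, config, tabs[[cmp$table]]),
      error = function(e) stop(sprintf("comparison '%s' failed: %s",
                                       cmp$id, conditionMessage(e)),
                               call. = FALSE))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(reports)) {
      for (fmt in c("csv", "json", "markdown")) {
        ext <- c(csv = "csv", json = "json", markdown = "md")[[fmt]]
        render_table(reports[[id]], fmt,
                     file.path(config$out_dir, paste0(id, ".", ext)))
      }
    }
    manifest <- list(
      package = "immunoBarometer",
      version = as.character(utils::packageVersion("immunoBarometer")),
      mode = config$mode, seed = config$seed,
      events_per_animal = config$events_per_animal,
      comparisons = config$comparisons$id,
      conventions = list(
        test = "two-tailed pooled-variance Student's t",
        correction = "Bonferroni, family = table rows",
        basis = "percent-of-parent; Tregs of Ths, myeloid subsets of MLCs"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  reports
}

run_one_comparison <- function(cmp, config, printed) {
  rows <- report_rows(cmp$panel)
  family_size <- length(rows)
  if (config$mode == "summary") {
    if (is.null(printed))
      stop("stage summary-input: no printed table for '", cmp$table, "'")
    pr <- printed$rows
    stats_a <- data.frame(population = pr$population, mean = pr$mean_a,
                          sd = pr$sd_a, n = printed$n_a)
    stats_b <- data.frame(population = pr$population, mean = pr$mean_b,
                          sd = pr$sd_b, n = printed$n_b)
    family_size <- printed$family_size
  } else {
    sim_one <- function(label, which) {
      spec <- preset(label, cmp$panel, cmp$tissue,
                     seed = derive_stream_seed(config$seed, which))
      if (!is.null(config$events_per_animal))
        spec$events_per_animal <- as.integer(config$events_per_animal)
      simulate_cohort(spec)
    }
    sim_a <- sim_one(cmp$cohort_a, 1L)
    sim_b <- sim_one(cmp$cohort_b, 2L)
    pa <- per_animal_stats(sim_a)
    pb <- per_animal_stats(sim_b)
    stats_a <- summarize_cohort(pa[pa$population %in% rows, ])
    stats_b <- summarize_cohort(pb[pb$population %in% rows, ])
  }
  res <- compare_panels(stats_a, stats_b, family_size = family_size)
  res <- res[match(intersect(rows, res$population), res$population), ]
  rownames(res) <- NULL
  alpha <- res$corrected_alpha[1L]
  structure(list(
    title = sprintf("%s vs %s, panel %s (%s), %s mode",
                    cmp$cohort_a, cmp$cohort_b, cmp$panel, cmp$tissue,
                    config$mode),
    rows = res,
    footnote = sprintf(
      paste0("Significance assigned to populations presenting p values < ",
             "%s (two-tailed pooled-variance Student's t-test, Bonferroni ",
             "correction over %d comparisons, family alpha 0.05)."),
      format(signif(alpha, 3)), family_size),
    corrected_alpha = alpha, mode = config$mode, seed = config$seed),
    class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat("<report_table>", x$title, "\n")
  print(x$rows, row.names = FALSE, digits = 4)
  cat(x$footnote, "\n")
  invisible(x)
}

#' Render a report table to CSV, JSON or Markdown
#'
#' Significant rows carry an asterisk marker, mirroring the published
#' tables; the footnote states the corrected alpha in use.  The CSV form
#' round-trips: reading it back recovers the comparison rows exactly.
#'
#' @param report A `report_table` from [run_pipeline()].
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param path Output file; when `NULL` the rendered text is returned as a
#'   character vector.
#' @param digits Significant digits for the Markdown display (CSV/JSON keep
#'   full precision).
#' @return `path` invisibly, or the rendered lines.
#' @export
render_table <- function(report, format = c("csv", "json", "markdown"),
                         path = NULL, digits = 4L) {
  stopifnot(inherits(report, "report_table"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format '",
                                              paste(format, collapse = ","),
                                              "'", call. = FALSE))
  rows <- report$rows
  text <- switch(format,
    csv = {
      out <- rows
      out$star <- ifelse(out$significant, "*", "")
      con <- textConnection("csvout", "w", local = TRUE)
      utils::write.csv(out, con, row.names = FALSE)
      close(con)
      csvout
    },
    json = {
      as.character(jsonlite::toJSON(
        list(title = report$title, footnote = report$footnote,
             corrected_alpha = report$corrected_alpha, rows = rows),
        dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA))
    },
    markdown = {
      fmt <- function(x) format(signif(x, digits), trim = TRUE)
      hdr <- c("| Population | Group A | Group B | t | df | p | sig |",
               "|---|---|---|---|---|---|---|")
      body <- vapply(seq_len(nrow(rows)), function(i) {
        r <- rows[i, ]
        sprintf("| %s%s | %s +/- %s (n=%d) | %s +/- %s (n=%d) | %s | %d | %s | %s |",
                r$population, if (r$significant) " *" else "",
                fmt(r$mean_a), fmt(r$sd_a), r$n_a,
                fmt(r$mean_b), fmt(r$sd_b), r$n_b,
                fmt(r$t), r$df, fmt(r$p_value),
                if (r$significant) "*" else "")
      }, character(1L))
      c(paste("###", report$title), "", hdr, body, "", report$footnote)
    })
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(path)
}

#' Read a rendered CSV report back into comparison rows
#'
#' @param path CSV written by [render_table()].
#' @return Data frame of comparison rows (the `star` display column is
#'   dropped).
#' @export
read_report_csv <- function(path) {
  df <- utils::read.csv(path)
  df$star <- NULL
  df
}
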