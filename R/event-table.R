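#' Per-animal table of flow-cytometry events
#'
#' A matrix of marker intensities, one row per acquired event, plus an
#' optional ground-truth population label per event (available for simulated
#' animals, absent for external data).
#'
#' @param animal_id Identifier of the animal the events belong to.
#' @param intensities Numeric events x markers matrix with marker column
#'   names; no missing values allowed.
#' @param truth Optional character vector of per-event population labels.
#' @return An object of class `event_table`.
#' @export
event_table <- function(animal_id, intensities, truth = NULL) {
  if (!is.character(animal_id) || length(animal_id) != 1L || !nzchar(animal_id))
    stop("'animal_id' must be a single non-empty string", call. = FALSE)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix", call. = FALSE)
  if (nrow(intensities) < 1L)
    stop("event table must contain at least one event", call. = FALSE)
  if (is.null(colnames(intensities)) || any(!nzchar(colnames(intensities))))
    stop("'intensities' must have marker column names", call. = FALSE)
  if (anyNA(intensities))
    stop("'intensities' must not contain missing values", call. = FALSE)
  if (!is.null(truth)) {
    truth <- as.character(truth)
    if (length(truth) != nrow(intensities))
      stop("'truth' must have one label per event", call. = FALSE)
  }
  structure(list(animal_id = animal_id, intensities = intensities,
                 truth = truth),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> animal %s: %d events x %d markers (%s)%s\n",
              x$animal_id, nrow(x$intensities), ncol(x$intensities),
              paste(colnames(x$intensities), collapse = ", "),
              if (is.null(x$truth)) "" else ", with truth labels"))
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$intensities)

#' Write an event table as delimited text
#'
#' One header row of marker names, one row per event, comma separated.
#' Truth labels, when present, are written alongside as
#' `<path base>.truth.csv` so the intensity file stays a plain marker
#' matrix that any cytometry tool can ingest.
#'
#' @param x An `event_table`.
#' @param path Output file path (`.csv`).
#' @param write_truth Also write truth labels if present (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path, write_truth = TRUE) {
  stopifnot(inherits(x, "event_table"))
  utils::write.csv(as.data.frame(x$intensities), path, row.names = FALSE)
  if (write_truth && !is.null(x$truth)) {
    tpath <- sub("\\.csv$", "", path)
    utils::write.csv(data.frame(population = x$truth),
                     paste0(tpath, ".truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path CSV file of intensities (header = marker names).
#' @param animal_id Animal identifier to attach; defaults to the file base
#'   name.
#' @return An `event_table` (truth labels are re-attached when the sibling
#'   `.truth.csv` file exists).
#' @export
read_event_table <- function(path, animal_id = NULL) {
  if (is.null(animal_id))
    animal_id <- sub("\\.csv$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE)
  tpath <- paste0(sub("\\.csv$", "", path), ".truth.csv")
  truth <- if (file.exists(tpath))
    utils::read.csv(tpath)$population else NULL
  event_table(animal_id, as.matrix(df), truth = truth)
}
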