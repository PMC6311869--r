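#' A boolean marker gate
#'
#' Events are marker-positive when their intensity is strictly greater than
#' the threshold and marker-negative otherwise, so a `"+"` gate and a `"-"`
#' gate at the same threshold partition their parent exactly.
#'
#' @param marker Marker name.
#' @param sign `"+"` (keep events above threshold) or `"-"` (keep events at
#'   or below threshold).
#' @param threshold Intensity cutoff; `NA` defers the choice to gating time.
#' @return An object of class `gate_definition`.
#' @export
gate <- function(marker, sign = c("+", "-"), threshold = NA_real_) {
  if (!is.character(marker) || length(marker) != 1L || !nzchar(marker))
    stop("'marker' must be a single non-empty string", call. = FALSE)
  sign <- match.arg(sign)
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || is.infinite(threshold))
    stop("'threshold' must be a finite scalar or NA", call. = FALSE)
  structure(list(marker = marker, sign = sign, threshold = threshold),
            class = "gate_definition")
}

#' A hierarchy of gated populations
#'
#' Nodes are named by population; each node lists its parent (another node
#' or `"all"`, the root holding every event) and the gates conjoined with
#' the parent's membership.  The tree must be acyclic with every node
#' reachable from the root.
#'
#' @param nodes Named list; each element is `list(parent =, gates =)` where
#'   `gates` is a list of [gate()] definitions.
#' @param root Label of the root population (default `"all"`).
#' @return An object of class `gate_tree`.
#' @export
#' @examples
#' tree <- gate_tree(list(
#'   leukocytes = list(parent = "all", gates = list(gate("CD45"))),
#'   CTLs = list(parent = "leukocytes", gates = list(gate("CD8")))))
gate_tree <- function(nodes, root = "all") {
  if (!is.list(nodes) || is.null(names(nodes)) || any(!nzchar(names(nodes))))
    stop("'nodes' must be a named list", call. = FALSE)
  if (anyDuplicated(names(nodes)))
    stop("population labels must be unique", call. = FALSE)
  if (root %in% names(nodes))
    stop("the root label cannot be a node", call. = FALSE)
  for (lab in names(nodes)) {
    n <- nodes[[lab]]
    if (!is.list(n) || !all(c("parent", "gates") %in% names(n)))
      stop(sprintf("node '%s' must have 'parent' and 'gates'", lab),
           call. = FALSE)
    if (!all(vapply(n$gates, inherits, logical(1L), "gate_definition")))
      stop(sprintf("node '%s': gates must be gate definitions", lab),
           call. = FALSE)
  }
  tree <- structure(list(nodes = nodes, root = root), class = "gate_tree")
  gate_tree_order(tree)  # validates acyclicity / reachability
  tree
}

# Topological order of a gate tree; errors on cycles or orphans.
gate_tree_order <- function(tree) {
  labels <- names(tree$nodes)
  parents <- vapply(tree$nodes, function(n) n$parent, character(1L))
  order <- character(0L)
  frontier <- tree$root
  while (length(frontier)) {
    nxt <- labels[parents %in% frontier]
    order <- c(order, nxt)
    frontier <- nxt
  }
  if (length(order) != length(labels))
    stop("configuration error: gate tree has a cycle or orphan node(s): ",
         paste(setdiff(labels, order), collapse = ", "), call. = FALSE)
  order
}

#' @export
print.gate_tree <- function(x, ...) {
  cat(sprintf("<gate_tree> %d populations under root '%s'\n",
              length(x$nodes), x$root))
  for (lab in gate_tree_order(x)) {
    n <- x$nodes[[lab]]
    gs <- vapply(n$gates, function(g) paste0(g$marker, g$sign), character(1L))
    cat(sprintf("  %s <- %s  [%s]\n", lab, n$parent,
                paste(gs, collapse = " & ")))
  }
  invisible(x)
}

#' Classify events against a conjunction of gates
#'
#' @param events An [event_table()].
#' @param gates List of [gate()] definitions; an empty list is the vacuous
#'   conjunction (all events pass).
#' @param thresholds Optional named vector of per-marker thresholds used for
#'   gates whose own threshold is `NA`.  Markers still lacking a threshold
#'   get one from [estimate_threshold()] on their full intensity column.
#' @return Logical vector, `TRUE` where every gate is satisfied.
#' @export
classify_events <- function(events, gates, thresholds = NULL) {
  stopifnot(inherits(events, "event_table"))
  X <- events$intensities
  mask <- rep(TRUE, nrow(X))
  for (g in gates) {
    if (!inherits(g, "gate_definition"))
      stop("gates must be gate definitions", call. = FALSE)
    if (!g$marker %in% colnames(X))
      stop(sprintf("gating error: marker '%s' is not in the event table (has: %s)",
                   g$marker, paste(colnames(X), collapse = ", ")),
           call. = FALSE)
    thr <- g$threshold
    if (is.na(thr) && g$marker %in% names(thresholds))
      thr <- thresholds[[g$marker]]
    if (is.na(thr)) thr <- estimate_threshold(X[, g$marker])
    mask <- mask & (if (g$sign == "+") X[, g$marker] > thr
                    else X[, g$marker] <= thr)
  }
  mask
}

#' Evaluate a gate tree on an event table
#'
#' Each node's membership is the conjunction of its own gates with its
#' parent's membership.  Percentages are percent-of-parent and
#' percent-of-root; an empty parent yields 0, never a division error.
#'
#' @inheritParams classify_events
#' @param tree A [gate_tree()].
#' @param thresholds Named per-marker thresholds.  `NULL` estimates every
#'   needed threshold from the data ([estimate_thresholds()]); pass
#'   [generative_thresholds()] of the simulation's marker models to gate
#'   synthetic data exactly.
#' @return Data frame with one row per population: `population`, `parent`,
#'   `n_events`, `pct_of_parent`, `pct_of_root`.
#' @export
apply_gate_tree <- function(events, tree, thresholds = NULL) {
  stopifnot(inherits(events, "event_table"), inherits(tree, "gate_tree"))
  if (is.null(thresholds)) {
    used <- unique(unlist(lapply(tree$nodes, function(n)
      vapply(n$gates, function(g) g$marker, character(1L)))))
    thresholds <- estimate_thresholds(events, used)
  }
  ord <- gate_tree_order(tree)
  n_total <- nrow(events$intensities)
  masks <- stats::setNames(list(rep(TRUE, n_total)), tree$root)
  counts <- c(stats::setNames(n_total, tree$root))
  out <- data.frame(population = ord, parent = NA_character_,
                    n_events = NA_integer_, pct_of_parent = NA_real_,
                    pct_of_root = NA_real_)
  for (i in seq_along(ord)) {
    lab <- ord[i]
    node <- tree$nodes[[lab]]
    m <- masks[[node$parent]] & classify_events(events, node$gates, thresholds)
    masks[[lab]] <- m
    cnt <- sum(m)
    counts[lab] <- cnt
    pcnt <- counts[[node$parent]]
    out$parent[i] <- node$parent
    out$n_events[i] <- cnt
    out$pct_of_parent[i] <- if (pcnt > 0) 100 * cnt / pcnt else 0
    out$pct_of_root[i] <- 100 * cnt / n_total
  }
  out
}

#' Estimate a gating threshold from one intensity column
#'
#' Deterministic stand-in for manual gating: on the log-intensity scale, the
#' threshold is placed at the minimum-density valley between the two largest
#' modes of a kernel density estimate.  If the column is unimodal the
#' threshold is placed above the maximum observed intensity, i.e. everything
#' is called negative -- estimation is only meaningful for markers that
#' actually resolve two populations.
#'
#' @param x Numeric vector of intensities (positive).
#' @return Threshold on the raw intensity scale.
#' @export
estimate_threshold <- function(x) {
  lx <- log(x[x > 0])
  if (length(lx) < 10L)
    stop("too few positive intensities to estimate a threshold", call. = FALSE)
  d <- stats::density(lx, n = 512L)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2L) + 1L
  if (length(peaks) >= 2L) {
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
    valley <- top2[1L] + which.min(y[top2[1L]:top2[2L]]) - 1L
    # genuine bimodality: the valley must dip well below the smaller mode,
    # otherwise the "peaks" are kernel wiggles on a unimodal hump
    if (y[valley] < 0.5 * min(y[top2])) return(exp(d$x[valley]))
  }
  exp(max(lx) + 1)
}

#' Estimate thresholds for several markers of an event table
#'
#' @param events An [event_table()].
#' @param markers Markers to estimate (default: all columns).
#' @return Named numeric vector of thresholds.
#' @export
estimate_thresholds <- function(events, markers = NULL) {
  stopifnot(inherits(events, "event_table"))
  if (is.null(markers)) markers <- colnames(events$intensities)
  missing <- setdiff(markers, colnames(events$intensities))
  if (length(missing))
    stop("gating error: marker(s) not in the event table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(markers, function(m) estimate_threshold(events$intensities[, m]),
         numeric(1L))
}

#' Serialize a gate tree to JSON
#'
#' @param tree A [gate_tree()].
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
gate_tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "gate_tree"))
  obj <- list(root = tree$root, nodes = lapply(tree$nodes, function(n) {
    list(parent = n$parent, gates = lapply(n$gates, function(g)
      list(marker = g$marker, sign = g$sign, threshold = g$threshold)))
  }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a gate tree from JSON written by [gate_tree_to_json()]
#'
#' @param path JSON file path (or a JSON string).
#' @return A [gate_tree()].
#' @export
gate_tree_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(n) {
    list(parent = n$parent, gates = lapply(n$gates, function(g)
      gate(g$marker, g$sign,
           if (is.null(g$threshold)) NA_real_ else g$threshold)))
  })
  gate_tree(nodes, root = obj$root)
}
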