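#' Specification of one simulated cell population
#'
#' A population lives in a tree rooted at `"root"` (all acquired events).
#' `target_fraction` is the expected fraction of the *parent* population its
#' events occupy, and `marker_profile` gives, for each marker, the
#' probability that an event of this population is marker-positive.  Marker
#' probabilities are inherited from the parent and can be overridden, so a
#' `"Ths"` population defined under `"leukocytes"` keeps CD45 positivity
#' without restating it.
#'
#' @param label Unique population label.
#' @param parent Label of the parent population, or `"root"`.
#' @param target_fraction Expected fraction of the parent population in
#'   `[0, 1]`.
#' @param marker_profile Named list/vector of marker-positivity
#'   probabilities in `[0, 1]`.
#' @return An object of class `population_spec`.
#' @export
#' @examples
#' population_spec("CTLs", "leukocytes", 0.03, c(CD8 = 1))
population_spec <- function(label, parent = "root", target_fraction,
                            marker_profile = list()) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a single non-empty string", call. = FALSE)
  if (!is.character(parent) || length(parent) != 1L)
    stop("'parent' must be a single string", call. = FALSE)
  target_fraction <- as.numeric(target_fraction)
  if (length(target_fraction) != 1L || is.na(target_fraction) ||
      target_fraction < 0 || target_fraction > 1)
    stop(sprintf("target_fraction of '%s' must be in [0, 1]", label),
         call. = FALSE)
  marker_profile <- as.list(marker_profile)
  if (length(marker_profile)) {
    if (is.null(names(marker_profile)) || any(!nzchar(names(marker_profile))))
      stop("marker_profile must be named by marker", call. = FALSE)
    p <- unlist(marker_profile)
    if (anyNA(p) || any(p < 0) || any(p > 1))
      stop(sprintf("marker probabilities of '%s' must be in [0, 1]", label),
           call. = FALSE)
  }
  structure(list(label = label, parent = parent,
                 target_fraction = target_fraction,
                 marker_profile = marker_profile),
            class = "population_spec")
}

# Resolve a list of population_spec objects into a flat tree description:
# validates labels/parents/sibling sums, inherits marker profiles down the
# tree, appends an implicit "<parent>/other" leaf wherever children leave
# probability mass unclaimed, and computes absolute (of-root) fractions.
#
# `fractions`, if given, is a named vector overriding target_fraction per
# label (values are fractions of the parent, in [0, 1]).
resolve_population_tree <- function(specs, fractions = NULL) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  if (!length(specs)) stop("no population specs given", call. = FALSE)
  labels <- vapply(specs, function(s) s$label, character(1L))
  if (anyDuplicated(labels))
    stop("population labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(fractions)) {
    unknown <- setdiff(names(fractions), labels)
    if (length(unknown))
      stop("configuration error: unknown population label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  parents <- vapply(specs, function(s) s$parent, character(1L))
  bad <- setdiff(parents, c("root", labels))
  if (length(bad))
    stop("configuration error: unknown parent(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  frac_of_parent <- vapply(specs, function(s) s$target_fraction, numeric(1L))
  names(frac_of_parent) <- labels
  if (!is.null(fractions)) frac_of_parent[names(fractions)] <- fractions
  if (any(frac_of_parent < 0 | frac_of_parent > 1))
    stop("fractions must be in [0, 1]", call. = FALSE)

  # topological order from root; also detects cycles / unreachable nodes
  order <- character(0L)
  frontier <- "root"
  while (length(frontier)) {
    nxt <- labels[parents %in% frontier]
    order <- c(order, nxt)
    frontier <- nxt
  }
  if (length(order) != length(labels))
    stop("configuration error: population tree has a cycle or orphan node(s): ",
         paste(setdiff(labels, order), collapse = ", "), call. = FALSE)

  nodes <- list()
  abs_frac <- c(root = 1)
  profiles <- list(root = list())
  for (lab in order) {
    s <- specs[[match(lab, labels)]]
    sibs <- labels[parents == s$parent]
    ssum <- sum(frac_of_parent[sibs])
    if (ssum > 1 + 1e-9)
      stop(sprintf("sibling fractions under '%s' sum to %.4f > 1",
                   s$parent, ssum), call. = FALSE)
    prof <- profiles[[s$parent]]
    prof[names(s$marker_profile)] <- s$marker_profile
    profiles[[lab]] <- prof
    abs_frac[lab] <- abs_frac[[s$parent]] * frac_of_parent[[lab]]
    nodes[[lab]] <- list(label = lab, parent = s$parent,
                         frac_of_parent = frac_of_parent[[lab]],
                         abs_frac = abs_frac[[lab]], profile = prof)
  }

  # implicit remainder leaves so that every parent's mass is fully assigned
  internal <- unique(c("root", parents))
  for (par in internal) {
    kids <- labels[parents == par]
    rem <- 1 - sum(frac_of_parent[kids])
    if (rem > 1e-9) {
      lab <- paste0(par, "/other")
      nodes[[lab]] <- list(label = lab, parent = par, frac_of_parent = rem,
                           abs_frac = abs_frac[[par]] * rem,
                           profile = profiles[[par]])
    }
  }
  leaves <- Filter(function(n) {
    !n$label %in% vapply(nodes, function(m) m$parent, character(1L))
  }, nodes)
  list(nodes = nodes, leaves = leaves)
}
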