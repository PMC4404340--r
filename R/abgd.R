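## Automatic Barcode Gap Discovery: locate the gap between intra- and
## inter-specific pairwise distances and partition recursively over a range
## of prior intraspecific divergence limits.

#' Pairwise distance histogram and ranked list
#'
#' @param d labeled distance matrix.
#' @param bins number of histogram bins.
#' @return List with `counts`, `edges` (bin breaks) and `ranked` (ascending
#'   off-diagonal lower-triangle distances).
#' @export
distance_histogram <- function(d, bins = 20) {
  x <- d[lower.tri(d)]
  ranked <- sort(x)
  h <- graphics::hist(x, breaks = seq(0, max(x) * (1 + 1e-9),
                                      length.out = bins + 1), plot = FALSE)
  list(counts = h$counts, edges = h$breaks, ranked = ranked)
}

#' Locate a barcode gap in a ranked distance list
#'
#' Scans successive gaps `g_i = d_(i+1) - d_(i)` between the distinct
#' ranked distances, restricted to gaps whose right edge exceeds the prior
#' intraspecific limit `P`, and accepts the first gap wider than `X` times
#' the putative intraspecific divergence below it (`d_(i)`, the largest
#' distance under the gap). This relative-width criterion is what makes a
#' "barcode gap": between-group divergence must dwarf the within-group
#' maximum, not merely the local spacing of ranked distances, which for
#' discrete mutation-count data collapses to the reciprocal sequence
#' length. Returns the gap midpoint as the candidate species threshold, or
#' `NULL` when no qualifying gap exists.
#'
#' @param ranked ascending numeric distances.
#' @param P prior limit to intraspecific divergence.
#' @param X relative gap width (> 1).
#' @return Threshold distance `t`, or `NULL`.
#' @export
find_gap <- function(ranked, P, X = 1.5) {
  stopifnot(!is.unsorted(ranked), X > 1)
  ranked <- unique(ranked)
  m <- length(ranked)
  if (m < 2) return(NULL)
  for (i in seq_len(m - 1)) {
    if (ranked[i + 1] <= P) next
    if (i < 2) next                      # no intraspecific baseline yet
    g <- ranked[i + 1] - ranked[i]
    if (g > X * ranked[i]) return((ranked[i] + ranked[i + 1]) / 2)
  }
  NULL
}

# split ids into connected components of the graph with edges d < t
components_below <- function(d, ids, t) {
  sub <- d[ids, ids, drop = FALSE]
  adj <- sub < t
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  split(ids, comp)
}

recursive_partition <- function(d, ids, P, X) {
  if (length(ids) < 3) return(list(ids))
  ranked <- sort(d[ids, ids][lower.tri(diag(length(ids)))])
  t <- find_gap(ranked, P, X)
  if (is.null(t)) return(list(ids))
  parts <- components_below(d, ids, t)
  if (length(parts) == 1) return(parts)
  out <- list()
  for (p in parts) out <- c(out, recursive_partition(d, p, P, X))
  out
}

#' ABGD partitions over a range of priors
#'
#' For each prior `P` (log-spaced between `P_min` and `P_max`): find the
#' barcode gap on the ranked pairwise distances, split the sequences into
#' connected components of the sub-threshold graph, and re-apply the gap
#' search within every component of size >= 3 until no component splits.
#' The partition is invariant to sequence order; group numbers follow the
#' matrix label order of each group's first member.
#'
#' @param d labeled distance matrix (typically K2P).
#' @param P_min,P_max prior limits to intraspecific divergence.
#' @param n_priors number of log-spaced priors.
#' @param X relative gap width.
#' @return List of class `abgd_scan`; per prior a `Partition` list with
#'   `P`, `threshold` (top-level gap, `NA` if none), `groups` (named integer
#'   vector id -> group) and `n_groups`.
#' @export
abgd_partition <- function(d, P_min = 0.001, P_max = 0.1, n_priors = 10,
                           X = 1.5) {
  stopifnot(P_min > 0, P_min < P_max, P_max < 1)
  labels <- rownames(d)
  # stable processing order: sorted labels, then map back
  ord <- order(labels)
  priors <- 10^seq(log10(P_min), log10(P_max), length.out = n_priors)
  out <- lapply(priors, function(P) {
    ranked <- sort(d[lower.tri(d)])
    t <- find_gap(ranked, P, X)
    parts <- recursive_partition(d, labels[ord], P, X)
    # number groups by the first member's position in the original labels
    firsts <- vapply(parts, function(g) min(match(g, labels)), 1L)
    parts <- parts[order(firsts)]
    groups <- integer(length(labels))
    names(groups) <- labels
    for (k in seq_along(parts)) groups[parts[[k]]] <- k
    list(P = P, threshold = if (is.null(t)) NA_real_ else t,
         groups = groups, n_groups = length(parts))
  })
  structure(out, class = "abgd_scan")
}

#' @export
print.abgd_scan <- function(x, ...) {
  cat("ABGD scan:\n")
  for (p in x)
    cat(sprintf("  P = %-8.5f groups = %d\n", p$P, p$n_groups))
  invisible(x)
}
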