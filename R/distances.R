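#' Pairwise mismatch proportions for two sequences
#'
#' Comparison is restricted to columns where both sequences carry an
#' unambiguous base (pairwise deletion). `P` is the transition mismatch
#' proportion (A<->G, C<->T), `Q` the transversion proportion; `P + Q` is
#' the p-distance.
#'
#' @param a,b equal-length character vectors (one base per element) or
#'   single strings.
#' @return List with `P`, `Q`, `p_dist`, `sites_compared`.
#' @export
pair_counts <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(a) == length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  m <- sum(ok)
  if (m == 0L) stop("no comparable sites between the two sequences")
  diff <- ok & a != b
  ts <- sum(diff & is_transition(a, b))
  list(P = ts / m, Q = (sum(diff) - ts) / m,
       p_dist = sum(diff) / m, sites_compared = m)
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, correcting separately for
#' transition (`P`) and transversion (`Q`) mismatch proportions. Always
#' `>= P + Q`, with equality only at zero divergence.
#'
#' @param P,Q mismatch proportions, or a [pair_counts()] list as first
#'   argument.
#' @return The distance, or `NA` with a warning for a saturated pair
#'   (a log argument <= 0).
#' @export
k2p <- function(P, Q = NULL) {
  if (is.list(P)) { Q <- P$Q; P <- P$P }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("saturated pair: K2P distance undefined (P = ", P, ", Q = ", Q, ")")
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise distance matrix
#'
#' Builds the symmetric matrix of p or K2P distances among the sequences of
#' an alignment or the representative sequences of a haplotype set, using
#' pairwise deletion per pair. `NA` entries arise only from saturation.
#'
#' @param x a `mito_aln` or `haploset`.
#' @param model `"p"` or `"k2p"`.
#' @return Labeled symmetric matrix, zero diagonal.
#' @export
distance_matrix <- function(x, model = c("k2p", "p")) {
  model <- match.arg(model)
  if (inherits(x, "haploset")) {
    mat <- x$rep_mat; labels <- x$ids
  } else if (inherits(x, "mito_aln")) {
    mat <- x$mat; labels <- x$ids
  } else stop("x must be an alignment or a haploset")
  n <- nrow(mat)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pc <- pair_counts(mat[i, ], mat[j, ])
    d[i, j] <- d[j, i] <- if (model == "p") pc$p_dist else k2p(pc)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou–Nei neighbor joining (via \pkg{ape}), optionally rooted on an
#' outgroup. Negative branch lengths are clamped to zero (the
#' Kuhner–Felsenstein convention); clamping is reported with a message.
#'
#' @param m complete labeled distance matrix (no `NA`).
#' @param outgroup optional tip label to root on.
#' @return An \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(m, outgroup = NULL) {
  if (anyNA(m)) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    stop("distance matrix has NA (saturated) entries: ",
         paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]],
               sep = "~", collapse = ", "))
  }
  stopifnot(nrow(m) >= 3)
  tr <- ape::nj(stats::as.dist(m))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative NJ branch length(s) to 0")
    tr$edge.length[neg] <- 0
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not in matrix: ", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}
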