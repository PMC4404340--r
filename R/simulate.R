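## Synthetic sequence generators with known truth: a star-expansion model
## (founder haplotypes plus private mutations per individual, the genealogy
## expected after a recent demographic expansion) and a neutral Kingman
## coalescent, both under infinite sites so segregating-site counts are
## exact.

BASES <- c("A", "C", "G", "T")

# draw a derived base: transition with prob 1 - tv_fraction, otherwise one
# of the two transversions at random
mutate_base <- function(base, tv_fraction) {
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < tv_fraction) {
    sample(setdiff(BASES, c(base, ts_of[[base]])), 1)
  } else ts_of[[base]]
}

#' Configuration for the star-expansion simulator
#'
#' @param L alignment length (sites).
#' @param clades list of clades, each a list with `name`, `divergence`
#'   (substitutions separating the clade founder from the shared root
#'   sequence) and `populations`: a list of `list(name, n, lat, lon)`.
#' @param lambda mean number of private mutations per sampled individual
#'   (Poisson); the star-expansion mutation load.
#' @param tv_fraction probability that a simulated mutation is a
#'   transversion. The default 0.1 mirrors the strongly
#'   transition-dominated spectrum typical of insect mitochondrial barcodes.
#' @param seed integer seed (mandatory: simulations are bit-reproducible
#'   given the configuration and seed).
#' @export
star_config <- function(L = 600, clades, lambda = 0.8, tv_fraction = 0.1,
                        seed) {
  stopifnot(L > 0, lambda >= 0, tv_fraction >= 0, tv_fraction <= 1,
            !missing(seed))
  structure(list(L = L, clades = clades, lambda = lambda,
                 tv_fraction = tv_fraction, seed = as.integer(seed)),
            class = "star_config")
}

#' Simulate a star-expansion sample
#'
#' One founder per clade is placed `divergence` mutations away from a
#' random root sequence; every sampled individual then carries a
#' Poisson(`lambda`) number of private mutations at fresh sites (infinite
#' sites: each site is mutated at most once across the whole simulation).
#' The result is the star-like haplotype cloud -- many singletons around
#' high-frequency founders -- expected after a recent expansion, and
#' clades separated by `divergence` create a between-group "barcode gap".
#'
#' @param config a [star_config()].
#' @return List with `aln` (alignment), `samples` (metadata table) and
#'   `truth` (root, founder sequences, every mutation placement).
#' @export
simulate_star_expansion <- function(config) {
  stopifnot(inherits(config, "star_config"))
  set.seed(config$seed)
  L <- config$L
  root <- sample(BASES, L, replace = TRUE)
  used <- logical(L)
  draw_sites <- function(k) {
    free <- which(!used)
    if (k > length(free))
      stop("mutation load exceeds alignment length under infinite sites")
    s <- if (k > 0) sample(free, k) else integer(0)
    used[s] <<- TRUE
    s
  }
  ids <- character(0); pops <- character(0); clades_of <- character(0)
  lat <- numeric(0); lon <- numeric(0)
  seqs <- list()
  truth <- list(root = paste(root, collapse = ""), founders = list(),
                mutations = list())
  for (cl in config$clades) {
    founder <- root
    s <- draw_sites(cl$divergence)
    for (site in s) founder[site] <- mutate_base(founder[site],
                                                 config$tv_fraction)
    truth$founders[[cl$name]] <- paste(founder, collapse = "")
    for (p in cl$populations) {
      for (i in seq_len(p$n)) {
        id <- paste0(p$name, "_", i)
        k <- stats::rpois(1, config$lambda)
        ind <- founder
        s <- draw_sites(k)
        for (site in s) ind[site] <- mutate_base(ind[site],
                                                 config$tv_fraction)
        truth$mutations[[id]] <- s
        ids <- c(ids, id); pops <- c(pops, p$name)
        clades_of <- c(clades_of, cl$name)
        lat <- c(lat, p$lat %||% NA_real_); lon <- c(lon, p$lon %||% NA_real_)
        seqs[[id]] <- ind
      }
    }
  }
  aln <- alignment(ids, do.call(rbind, seqs))
  samples <- data.frame(sample_id = ids, population = pops,
                        country = clades_of, group = clades_of,
                        host_plant = "synthetic", lat = lat, lon = lon,
                        stringsAsFactors = FALSE)
  list(aln = aln, samples = samples, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate sequences under the neutral Kingman coalescent
#'
#' Coalescent waiting times are exponential with rate `choose(k, 2)` while
#' `k` lineages remain; mutations fall on branches as Poisson(`theta / 2 *`
#' branch length) and each hits a previously unmutated site (infinite
#' sites). The generator provides the neutral null against which Tajima's D
#' and Fu's Fs are calibrated: both have expectation near zero here.
#'
#' @param n sample size (>= 2).
#' @param theta scaled population mutation rate (expected pairwise
#'   differences between two sequences).
#' @param L alignment length; must exceed the realised mutation count.
#' @param seed integer seed.
#' @param tv_fraction transversion probability per mutation.
#' @return A [alignment()] of `n` sequences.
#' @export
simulate_coalescent <- function(n, theta, L = 1000, seed, tv_fraction = 0.1) {
  stopifnot(n >= 2, theta > 0, !missing(seed))
  set.seed(seed)
  # lineages: list of tip index vectors; mutations accumulate per lineage
  lineages <- as.list(seq_len(n))
  blen <- numeric(n) # pending branch length per active lineage
  muts <- list()     # list of (tips)
  while (length(lineages) > 1) {
    k <- length(lineages)
    t <- stats::rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + t
    pair <- sample.int(k, 2)
    for (li in pair) {
      nm <- stats::rpois(1, theta / 2 * blen[li])
      if (nm > 0) muts <- c(muts, rep(list(lineages[[li]]), nm))
    }
    merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages <- c(lineages[-pair], list(merged))
    blen <- c(blen[-pair], 0)
  }
  nmut <- length(muts)
  if (nmut > L)
    stop("saturated: ", nmut, " mutations exceed L = ", L,
         " under infinite sites")
  root <- matrix(sample(BASES, L, replace = TRUE), nrow = n, ncol = L,
                 byrow = TRUE)
  sites <- if (nmut > 0) sample.int(L, nmut) else integer(0)
  for (m in seq_len(nmut)) {
    s <- sites[m]
    derived <- mutate_base(root[1, s], tv_fraction)
    root[muts[[m]], s] <- derived
  }
  alignment(paste0("t", seq_len(n)), root)
}
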