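#' Haplotype (gene) diversity
#'
#' Nei's unbiased haplotype diversity `h = n (1 - sum p_i^2) / (n - 1)`,
#' the probability that two individuals drawn without replacement carry
#' different haplotypes.
#'
#' @param x a `haploset`, or a numeric vector of haplotype counts.
#' @return `h` in `[0, 1]`; `NA` with a warning if `n < 2`.
#' @export
haplotype_diversity <- function(x) {
  freq <- if (inherits(x, "haploset")) x$freq else x
  stopifnot(is.numeric(freq), all(freq >= 1))
  n <- sum(freq)
  if (n < 2) {
    warning("haplotype diversity undefined for n < 2")
    return(NA_real_)
  }
  p <- freq / n
  n * (1 - sum(p^2)) / (n - 1)
}

# per-site p-distance between haplotype rows i, j over analysis sites
hap_pdist <- function(hset) {
  K <- hset$K
  d <- matrix(0, K, K)
  if (K > 1) {
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      d[i, j] <- d[j, i] <- sum(hset$mat[i, ] != hset$mat[j, ]) / hset$L_used
    }
  }
  d
}

#' Nucleotide diversity
#'
#' Nei's pi with small-sample correction,
#' `pi = n/(n-1) * sum_{i<j} 2 p_i p_j d_ij`, where `d_ij` is the per-site
#' p-distance between haplotypes over the analysis sites. Equals the mean
#' per-site difference over all C(n,2) individual pairs. `kbar = pi * L_used`
#' is the mean number of pairwise differences.
#'
#' @param hset a `haploset`.
#' @return A list with `pi` and `kbar`.
#' @export
nucleotide_diversity <- function(hset) {
  stopifnot(inherits(hset, "haploset"))
  n <- hset$n
  if (n < 2) return(list(pi = NA_real_, kbar = NA_real_))
  p <- hset$freq / n
  d <- hap_pdist(hset)
  pi <- n / (n - 1) * sum((p %o% p) * d) # full matrix = 2 * sum over i<j
  list(pi = pi, kbar = pi * hset$L_used)
}

#' Tajima's neutrality-test constants
#'
#' The standard constants `a1, a2, b1, b2, c1, c2, e1, e2` entering the
#' variance normalisation of Tajima's D, for sample size `n`.
#'
#' @param n number of sequences (>= 2).
#' @return Named list of constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (kbar - S/a1) / sqrt(e1 S + e2 S (S-1))`: the normalised difference
#' between the pairwise-difference and segregating-site estimators of the
#' population mutation rate. Negative values indicate an excess of rare
#' variants (recent expansion or purifying selection); positive values an
#' excess of intermediate frequencies.
#'
#' @param S number of segregating sites.
#' @param kbar mean pairwise differences.
#' @param n sample size (>= 4).
#' @return `D`, or `NA` with a warning when `S = 0` (undefined).
#' @export
tajimas_d <- function(S, kbar, n) {
  stopifnot(n >= 4)
  if (S == 0) {
    warning("Tajima's D undefined for S = 0")
    return(NA_real_)
  }
  k <- tajima_constants(n)
  (kbar - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# log |s(n, k)| (unsigned Stirling numbers of the first kind), row n,
# by the recurrence |s(n,k)| = |s(n-1,k-1)| + (n-1) |s(n-1,k)| carried in
# log space with log-sum-exp; supports n in the low thousands.
log_stirling_row <- function(n) {
  row <- 0 # log |s(1,1)|
  if (n == 1) return(row)
  for (m in 2:n) {
    prev <- row
    row <- numeric(m)
    row[1] <- log(m - 1) + prev[1]          # k = 1
    row[m] <- 0                              # k = m
    if (m > 2) {
      k <- 2:(m - 1)
      a <- prev[k - 1]
      b <- log(m - 1) + prev[k]
      hi <- pmax(a, b)
      row[k] <- hi + log1p(exp(pmin(a, b) - hi))
    }
  }
  row
}

#' Fu's Fs
#'
#' Under the Ewens sampling distribution with theta estimated by the mean
#' pairwise difference, `S' = P(K >= K_obs)` is the probability of observing
#' at least as many haplotypes as seen; `Fs = ln(S' / (1 - S'))`. Large
#' negative values indicate an excess of haplotypes (singletons), the
#' signature of demographic expansion. Everything is computed in log space
#' via a log-scale table of unsigned Stirling numbers of the first kind.
#'
#' @param n sample size.
#' @param K_obs observed number of haplotypes.
#' @param theta diversity estimate (mean pairwise differences, `kbar`).
#' @return `Fs`; `+Inf` when `K_obs = 1` (S' = 1); `NA` with a warning when
#'   `theta = 0`.
#' @export
fus_fs <- function(n, K_obs, theta) {
  stopifnot(n >= 2, K_obs >= 1, K_obs <= n)
  if (theta <= 0) {
    warning("Fu's Fs undefined for theta = 0")
    return(NA_real_)
  }
  if (K_obs == 1) return(Inf)
  ls <- log_stirling_row(n)
  k <- seq_len(n)
  logterm <- ls + k * log(theta) # unnormalised log P(K = k)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  # Fs = log S' - log(1 - S'); the Ewens normalising constant cancels
  lse(logterm[K_obs:n]) - lse(logterm[1:(K_obs - 1)])
}

#' Ewens haplotype-count probability `P(K >= K_obs)`
#'
#' The tail probability underlying Fu's Fs, on the probability scale.
#'
#' @inheritParams fus_fs
#' @export
ewens_tail <- function(n, K_obs, theta) {
  stopifnot(theta > 0, K_obs >= 1, K_obs <= n)
  if (K_obs == 1) return(1)
  ls <- log_stirling_row(n)
  k <- seq_len(n)
  logterm <- ls + k * log(theta)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  exp(lse(logterm[K_obs:n]) - lse(logterm))
}

#' All diversity and neutrality statistics for one sample
#'
#' @param hset a `haploset`.
#' @return A one-row data frame with `n`, `K`, `h`, `pi`, `kbar`, `S`, `D`
#'   (Tajima) and `Fs` (Fu). `D` requires `n >= 4` and `S >= 1`; undefined
#'   statistics are `NA`.
#' @export
diversity_summary <- function(hset) {
  stopifnot(inherits(hset, "haploset"))
  nd <- nucleotide_diversity(hset)
  ss <- site_summary(hset)
  D <- if (hset$n >= 4 && ss$S >= 1)
    tajimas_d(ss$S, nd$kbar, hset$n) else NA_real_
  Fs <- if (!is.na(nd$kbar) && nd$kbar > 0)
    fus_fs(hset$n, hset$K, nd$kbar) else NA_real_
  data.frame(n = hset$n, K = hset$K, h = haplotype_diversity(hset),
             pi = nd$pi, kbar = nd$kbar, S = ss$S, D = D, Fs = Fs)
}

#' Diversity statistics per stratum
#'
#' Splits an alignment by a metadata column (`population`, `country`,
#' `group`) and computes [diversity_summary()] per stratum plus the pooled
#' `all` row, mirroring per-country / per-region diversity tables.
#'
#' @param aln alignment.
#' @param samples sample table (see [read_samples()]).
#' @param by grouping column name, or `"all"` for the pooled sample only.
#' @return Data frame with one row per stratum.
#' @export
diversity_by <- function(aln, samples, by = "population") {
  samples <- validate_samples(samples)
  idx <- match(aln$ids, samples$sample_id)
  if (anyNA(idx)) stop("samples table is missing ids: ",
                       paste(aln$ids[is.na(idx)], collapse = ", "))
  strata <- if (by == "all") list(all = seq_along(aln$ids))
            else split(seq_along(aln$ids), samples[[by]][idx])
  out <- do.call(rbind, lapply(names(strata), function(s) {
    rows <- strata[[s]]
    sub <- alignment(aln$ids[rows], aln$mat[rows, , drop = FALSE])
    cbind(stratum = s, diversity_summary(collapse_haplotypes(sub)))
  }))
  if (by != "all") {
    pooled <- cbind(stratum = "all", diversity_summary(collapse_haplotypes(aln)))
    out <- rbind(out, pooled)
  }
  rownames(out) <- NULL
  out
}
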