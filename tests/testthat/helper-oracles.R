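# Independent oracles used across the suite. These deliberately share no
# code with the package: brute-force enumerations, direct formula
# evaluations, and a small exact big-integer arithmetic for the Ewens
# distribution.

## --- big integers (non-negative), little-endian digits base 1e7 ----------

BI_BASE <- 1e7

bi <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) { d <- c(d, x %% BI_BASE); x <- x %/% BI_BASE }
  d
}

bi_norm <- function(d) {
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% BI_BASE
    carry <- v %/% BI_BASE
  }
  while (carry > 0) { d <- c(d, carry %% BI_BASE); carry <- carry %/% BI_BASE }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

bi_mul_small <- function(a, k) {      # k a plain integer < 1e7
  stopifnot(k >= 0, k < BI_BASE)
  if (k == 0) return(0)
  bi_norm(a * k)
}

bi_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
    out <- bi_norm(out) # keep partial sums well inside double precision
    out <- c(out, numeric(length(a) + length(b) - length(out)))
  }
  bi_norm(out)
}

bi_log <- function(a) {               # natural log of a big integer
  nd <- length(a)
  top <- a[nd]
  if (nd >= 2) top <- top + a[nd - 1] / BI_BASE
  if (nd >= 3) top <- top + a[nd - 2] / BI_BASE^2
  log(top) + (nd - 1) * log(BI_BASE)
}

## --- exact Ewens / Fu's Fs oracle ----------------------------------------

# unsigned Stirling numbers of the first kind, row n, as a list of big
# integers, via |s(n,k)| = |s(n-1,k-1)| + (n-1) |s(n-1,k)|
stirling_row_exact <- function(n) {
  row <- list(bi(1))
  if (n == 1) return(row)
  for (m in 2:n) {
    new <- vector("list", m)
    for (k in seq_len(m)) {
      t1 <- if (k > 1) row[[k - 1]] else 0
      t2 <- if (k <= m - 1) bi_mul_small(row[[k]], m - 1) else 0
      new[[k]] <- bi_add(t1, t2)
    }
    row <- new
  }
  row
}

# Fu's Fs for rational theta = p/q, by exact integer sums:
# Fs = log(sum_{k>=K} |s(n,k)| p^k q^(n-k)) - log(sum_{k<K} ...)
# (the Ewens normalising constant cancels between numerator and denominator)
fs_exact <- function(n, K, p, q) {
  stopifnot(K >= 2, K <= n, p > 0, q > 0, p < BI_BASE, q < BI_BASE)
  st <- stirling_row_exact(n)
  ppow <- vector("list", n + 1); qpow <- vector("list", n + 1)
  ppow[[1]] <- bi(1); qpow[[1]] <- bi(1)
  for (k in seq_len(n)) {
    ppow[[k + 1]] <- bi_mul_small(ppow[[k]], p)
    qpow[[k + 1]] <- bi_mul_small(qpow[[k]], q)
  }
  hi <- 0; lo <- 0
  for (k in seq_len(n)) {
    term <- bi_mul(st[[k]], bi_mul(ppow[[k + 1]], qpow[[n - k + 1]]))
    if (k >= K) hi <- bi_add(hi, term) else lo <- bi_add(lo, term)
  }
  bi_log(hi) - bi_log(lo)
}

## --- brute-force population-genetic oracles ------------------------------

# mean pairwise per-site difference over all expanded individual pairs
pi_bruteforce <- function(seqmat, freq) {
  rows <- rep(seq_len(nrow(seqmat)), freq)
  n <- length(rows)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(seqmat[rows[i], ] != seqmat[rows[j], ])
  }
  tot / choose(n, 2)
}

# column-by-column site summary over an expanded individual matrix
site_summary_bruteforce <- function(seqmat, freq) {
  ind <- seqmat[rep(seq_len(nrow(seqmat)), freq), , drop = FALSE]
  S <- 0; PI <- 0; ts <- 0; tv <- 0
  transitions <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  for (j in seq_len(ncol(ind))) {
    tab <- table(ind[, j])
    if (length(tab) < 2) next
    S <- S + 1
    if (sum(tab >= 2) >= 2) PI <- PI + 1
    maj <- names(tab)[order(-tab, names(tab))][1]
    for (st in setdiff(names(tab), maj)) {
      if (isTRUE(transitions[paste0(maj, st)])) ts <- ts + 1 else tv <- tv + 1
    }
  }
  list(S = S, PI = PI, n_ts = ts, n_tv = tv)
}

# direct AMOVA variance components: explicit SSD loops plus the expected
# mean-square equations solved as a linear system
amova_oracle <- function(delta2, pop, group = NULL) {
  N <- length(pop)
  ssd <- function(idx) {
    s <- 0
    if (length(idx) >= 2)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + delta2[idx[a], idx[b]]
    s / length(idx)
  }
  sst <- ssd(seq_len(N))
  pops <- unique(pop)
  ssw <- sum(sapply(pops, function(p) ssd(which(pop == p))))
  np <- sapply(pops, function(p) sum(pop == p))
  if (is.null(group)) {
    P <- length(pops)
    ms <- c((sst - ssw) / (P - 1), ssw / (N - P))
    n1 <- (N - sum(np^2) / N) / (P - 1)
    A <- rbind(c(n1, 1), c(0, 1))       # E[MS] = A %*% c(sigma_b, sigma_c)
    sig <- solve(A, ms)
    list(sigma = sig, phi = sig[1] / sum(sig))
  } else {
    grps <- unique(group)
    G <- length(grps)
    P <- length(pops)
    ssg <- sum(sapply(grps, function(g) ssd(which(group == g))))
    ms <- c((sst - ssg) / (G - 1), (ssg - ssw) / (P - G), ssw / (N - P))
    gof <- sapply(pops, function(p) group[which(pop == p)[1]])
    ng <- sapply(grps, function(g) sum(group == g))
    A1 <- sum(sapply(grps, function(g) sum(np[gof == g]^2) / ng[grps == g]))
    n1 <- (N - A1) / (P - G)
    n2 <- (A1 - sum(np^2) / N) / (G - 1)
    n3 <- (N - sum(ng^2) / N) / (G - 1)
    A <- rbind(c(n3, n2, 1), c(0, n1, 1), c(0, 0, 1))
    sig <- solve(A, ms)                  # sigma_a, sigma_b, sigma_c
    tot <- sum(sig)
    list(sigma = sig,
         phi = c(CT = sig[1] / tot, SC = sig[2] / (sig[2] + sig[3]),
                 ST = (sig[1] + sig[2]) / tot))
  }
}

# exhaustive Steiner-point search: minimum spanning-tree cost over the
# terminals plus any subset (size <= n_terminals - 2) of candidate interior
# sequences from the per-site observed-state product space
steiner_optimum <- function(seqmat, tv_weight = 1) {
  wdist <- function(a, b) {
    d <- which(a != b)
    if (!length(d)) return(0)
    transitions <- c(AG = 1, GA = 1, CT = 1, TC = 1)
    sum(ifelse(paste0(a[d], b[d]) %in% names(transitions), 1, tv_weight))
  }
  kruskal_cost <- function(mat) {
    n <- nrow(mat)
    if (n < 2) return(0)
    ed <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      ed <- rbind(ed, c(i, j, wdist(mat[i, ], mat[j, ])))
    ed <- ed[order(ed[, 3]), , drop = FALSE]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    cost <- 0; used <- 0
    for (r in seq_len(nrow(ed))) {
      a <- find(ed[r, 1]); b <- find(ed[r, 2])
      if (a != b) { parent[a] <- b; cost <- cost + ed[r, 3]; used <- used + 1 }
      if (used == n - 1) break
    }
    cost
  }
  states <- lapply(seq_len(ncol(seqmat)), function(j) unique(seqmat[, j]))
  cand <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  keys <- apply(seqmat, 1, paste, collapse = "")
  cand <- cand[!apply(cand, 1, paste, collapse = "") %in% keys, , drop = FALSE]
  best <- kruskal_cost(seqmat)
  kmax <- min(nrow(seqmat) - 2, nrow(cand))
  if (kmax >= 1) for (k in seq_len(kmax)) {
    subs <- utils::combn(nrow(cand), k)
    for (ci in seq_len(ncol(subs))) {
      cost <- kruskal_cost(rbind(seqmat, cand[subs[, ci], , drop = FALSE]))
      if (cost < best) best <- cost
    }
  }
  best
}

## --- misc helpers ---------------------------------------------------------

random_alignment <- function(n, L, seed, states = c("A", "C", "G", "T")) {
  set.seed(seed)
  mat <- matrix(sample(states, n * L, replace = TRUE), nrow = n)
  alignment(paste0("s", seq_len(n)), mat)
}

# mildly diverged sequences (a shared ancestor plus `muts` changes each),
# so corrected distances stay well below saturation
diverged_alignment <- function(n, L, muts, seed) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(base, n), nrow = n, byrow = TRUE)
  for (i in seq_len(n)) {
    s <- sample(L, muts)
    for (j in s) mat[i, j] <- sample(setdiff(c("A", "C", "G", "T"),
                                             mat[i, j]), 1)
  }
  alignment(paste0("s", seq_len(n)), mat)
}

# four star clades with a planted barcode gap, shared by several tests
four_clade_sim <- function(seed, n = 20, lambda = 1, delta = 20, L = 600) {
  cl <- lapply(1:4, function(i)
    list(name = paste0("c", i), divergence = delta,
         populations = list(list(name = paste0("p", i), n = n))))
  simulate_star_expansion(
    star_config(L = L, clades = cl, lambda = lambda, seed = seed))
}
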