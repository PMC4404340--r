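test_that("distance histogram covers all pairs; ranked list ascending", {
  aln <- random_alignment(6, 30, seed = 61)
  d <- distance_matrix(aln, model = "p")
  h <- distance_histogram(d, bins = 10)
  expect_equal(sum(h$counts), choose(6, 2))
  expect_false(is.unsorted(h$ranked))
  # bimodal two-clade set shows an empty stretch between modes
  sim <- four_clade_sim(62, n = 6)
  d2 <- distance_matrix(collapse_haplotypes(sim$aln), model = "k2p")
  h2 <- distance_histogram(d2, bins = 30)
  mid <- h2$counts[10:20]
  expect_true(any(mid == 0))
})

test_that("find_gap detects constructed gaps and rejects continua", {
  # cloud up to 0.01, then a cloud at 0.10: threshold falls inside the gap
  ranked <- sort(c(seq(0.001, 0.01, by = 0.001), seq(0.10, 0.11, by = 0.002)))
  t <- find_gap(ranked, P = 0.005, X = 1.5)
  expect_true(t > 0.01 && t < 0.10)
  # uniform tightly spaced distances: no gap
  expect_null(find_gap(seq(0.01, 0.03, by = 0.001), P = 0.005, X = 1.5))
  # prior above the maximum distance: no candidates
  expect_null(find_gap(ranked, P = 0.2, X = 1.5))
  expect_null(find_gap(rep(0.01, 5), P = 0.001, X = 1.5))
})

test_that("partitions recover planted clades and respect the prior", {
  sim <- four_clade_sim(1)
  d <- distance_matrix(collapse_haplotypes(sim$aln), model = "k2p")
  scan <- abgd_partition(d, 0.001, 0.1, 10, 1.5)
  ng <- sapply(scan, function(p) p$n_groups)
  small <- sapply(scan, function(p) p$P) <= 0.008
  expect_true(all(ng[small] == 4))
  expect_equal(ng[length(ng)], 1)        # prior beyond the gap: one group
  # groups must coincide with the true clades at small priors
  truth <- sim$samples$population[match(
    sapply(collapse_haplotypes(sim$aln)$members, `[`, 1),
    sim$samples$sample_id)]
  got <- scan[[1]]$groups
  expect_equal(length(unique(paste(got, truth))), 4)
})

test_that("partition is invariant under reordering and recursion reaches a fixed point", {
  sim <- four_clade_sim(8, n = 8)
  hs <- collapse_haplotypes(sim$aln)
  d <- distance_matrix(hs, model = "k2p")
  scan <- abgd_partition(d, 0.002, 0.05, 5, 1.5)
  perm <- sample(nrow(d))
  scan2 <- abgd_partition(d[perm, perm], 0.002, 0.05, 5, 1.5)
  for (k in seq_along(scan)) {
    g1 <- scan[[k]]$groups
    g2 <- scan2[[k]]$groups[names(g1)]
    # same partition as a set of sets (group indices may differ)
    expect_equal(length(unique(paste(g1, g2))), length(unique(g1)))
  }
  # rerunning within any recovered group yields no further split
  p1 <- scan[[1]]
  for (g in unique(p1$groups)) {
    ids <- names(p1$groups)[p1$groups == g]
    if (length(ids) < 3) next
    sub <- abgd_partition(d[ids, ids, drop = FALSE],
                          p1$P, p1$P * 1.0001, 2, 1.5)
    expect_equal(sub[[1]]$n_groups, 1)
  }
})

test_that("the number of groups never increases with the prior", {
  set.seed(63)
  for (rep in 1:10) {
    k <- sample(4:9, 1)
    seqs <- replicate(k, paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                               collapse = ""))
    hs <- haploset_from_freq(seqs, rep(1, k))
    d <- distance_matrix(hs, model = "p")
    ng <- sapply(abgd_partition(d, 0.001, 0.4, 8, 1.5),
                 function(p) p$n_groups)
    expect_true(all(diff(ng) <= 0))
  }
})

test_that("nested clades split finely at small priors, coarsely at large", {
  # two clades; the first contains two subclades separated by ~3x the
  # intra spacing; inter-clade distance dwarfs both
  mk <- function(base, k, step) {
    sapply(0:(k - 1), function(i) {
      s <- strsplit(base, "")[[1]]
      if (i > 0) s[seq_len(i * step)] <- "T"
      paste(s, collapse = "")
    })
  }
  ref <- paste(rep("A", 60), collapse = "")
  sub1 <- mk(ref, 3, 1)                              # spacing 1 site
  ref2 <- ref; substr(ref2, 46, 55) <- "TTTTTTTTTT"  # subclade 2: +10 sites
  sub2 <- mk(ref2, 3, 1)
  ref3 <- paste(rep("G", 60), collapse = "")         # distant clade
  cl2 <- mk(ref3, 3, 1)
  hs <- haploset_from_freq(c(sub1, sub2, cl2), rep(1, 9))
  d <- distance_matrix(hs, model = "p")
  fine <- abgd_partition(d, 0.005, 0.005 * 1.01, 2, 1.5)[[1]]
  coarse <- abgd_partition(d, 0.2, 0.2 * 1.01, 2, 1.5)[[1]]
  expect_equal(fine$n_groups, 3)
  expect_equal(coarse$n_groups, 2)
})
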