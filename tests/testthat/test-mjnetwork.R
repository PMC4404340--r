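test_that("weighted Hamming applies transversion and site weights", {
  expect_equal(weighted_hamming("ACGT", "ACGT"), 0)
  expect_equal(weighted_hamming("ACGT", "GCGT"), 1)     # A<->G transition
  expect_equal(weighted_hamming("ACGT", "TCGT"), 3)     # A<->T transversion
  expect_equal(weighted_hamming("AA", "GT", tv_weight = 3), 4)
  expect_equal(weighted_hamming("AA", "GA", tv_weight = 3,
                                site_weights = c(5, 1)), 5)
})

test_that("two haplotypes give a single edge of their weighted distance", {
  hs <- haploset_from_freq(c("AAAA", "AGTA"), c(2, 1))
  net <- build_mjn(hs)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1 + 3)
  expect_equal(sum(net$nodes$type == "median"), 0)
})

test_that("the classic three-star resolves through one median vector", {
  hs <- haploset_from_freq(c("AAT", "ATA", "TAA"), c(3, 2, 1))
  net <- build_mjn(hs, tv_weight = 1)
  mv <- net$nodes[net$nodes$type == "median", ]
  expect_equal(nrow(mv), 1)
  expect_equal(mv$sequence, "AAA")
  expect_equal(net$cost, 3)              # star beats any 2-edge chain (cost 4)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[mv$id]), 3)    # median degree >= 3 after pruning
})

test_that("network spanning cost is Steiner-optimal on exhaustive instances", {
  set.seed(71)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    nsites <- sample(4:6, 1)
    # binary states per site keep the exhaustive candidate space tractable
    mat <- matrix(sample(c("A", "G"), k * nsites, replace = TRUE), nrow = k)
    keys <- apply(mat, 1, paste, collapse = "")
    if (anyDuplicated(keys)) next
    hs <- haploset_from_freq(keys, rep(1, k))
    net <- build_mjn(hs, tv_weight = 1)
    opt <- steiner_optimum(mat, tv_weight = 1)
    expect_equal(net$cost, opt,
                 label = sprintf("instance %d (k=%d, sites=%d)", rep, k, nsites))
  }
})

test_that("epsilon never removes links and the MST is always contained", {
  sim <- four_clade_sim(72, n = 5)
  hs <- collapse_haplotypes(sim$aln)
  key <- function(net) paste(pmin(net$edges$from, net$edges$to),
                             pmax(net$edges$from, net$edges$to))
  n0 <- build_mjn(hs, epsilon = 0)
  n5 <- build_mjn(hs, epsilon = 5)
  # compare over the shared observed-node pairs
  obs_edges <- function(net) {
    e <- net$edges[grepl("^H", net$edges$from) & grepl("^H", net$edges$to), ]
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  expect_true(all(obs_edges(n0) %in% obs_edges(n5)))
  # observed haplotypes stay connected after post-processing
  g <- igraph::graph_from_data_frame(n0$edges, directed = FALSE,
                                     vertices = n0$nodes$id)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("annotation composes populations and identifies the founder", {
  sim <- four_clade_sim(73, n = 10, lambda = 0.6)
  hs <- collapse_haplotypes(sim$aln)
  net <- build_mjn(hs, epsilon = 0)
  ann <- annotate_network(net, hs, sim$samples, by = "population")
  expect_equal(unname(rowSums(ann$composition)),
               hs$freq[match(rownames(ann$composition), hs$ids)])
  # the founder is the highest-frequency haplotype
  expect_equal(ann$founder, hs$ids[which.max(hs$freq)])
  expect_error(annotate_network(net, hs, sim$samples[-1, ]), "unknown sample")
  # single-population set: composition has one column
  one <- sim$samples
  one$population <- "only"; one$country <- "c"; one$group <- "g"
  ann1 <- annotate_network(net, hs, one)
  expect_equal(ncol(ann1$composition), 1)
})

test_that("star expansions yield star-like networks around the founder", {
  cfg <- star_config(L = 400, clades = list(
    list(name = "A", divergence = 0,
         populations = list(list(name = "p1", n = 40)))),
    lambda = 0.5, seed = 74)
  sim <- simulate_star_expansion(cfg)
  hs <- collapse_haplotypes(sim$aln)
  net <- build_mjn(hs, epsilon = 0)
  ann <- annotate_network(net, hs, sim$samples)
  # founder node = the untouched founder sequence = modal haplotype
  expect_equal(ann$founder, hs$ids[which.max(hs$freq)])
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(names(which.max(deg)), ann$founder)
})
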