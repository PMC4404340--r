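test_that("AMOVA variance components match the independent oracle", {
  set.seed(11)
  for (rep in 1:6) {
    N <- sample(9:15, 1)
    pop <- sample(paste0("p", 1:3), N, replace = TRUE)
    while (length(unique(pop)) < 3 || min(table(pop)) < 2)
      pop <- sample(paste0("p", 1:3), N, replace = TRUE)
    d <- as.matrix(dist(matrix(rnorm(N * 4), N)))
    res <- amova(d, pop, B = 0)
    orc <- amova_oracle(d, pop)
    expect_equal(unname(res$phi["Phi_ST"]), unname(orc$phi), tolerance = 1e-9)
    expect_equal(unname(res$sigma), unname(orc$sigma), tolerance = 1e-9)
  }
})

test_that("three-level AMOVA matches the oracle and its SSDs add up", {
  set.seed(12)
  for (rep in 1:4) {
    pops <- c("a1", "a2", "b1", "b2", "b3")
    grp_of <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", b3 = "B")
    pop <- sample(pops, 20, replace = TRUE)
    while (length(unique(pop)) < 5) pop <- sample(pops, 20, replace = TRUE)
    group <- unname(grp_of[pop])
    d <- as.matrix(dist(matrix(rnorm(20 * 3), 20)))
    res <- amova(d, pop, group, B = 0)
    orc <- amova_oracle(d, pop, group)
    expect_equal(unname(res$sigma), unname(orc$sigma), tolerance = 1e-9)
    expect_equal(unname(res$phi),
                 unname(orc$phi[c("CT", "SC", "ST")]), tolerance = 1e-9)
    lev <- res$table$SSD[res$table$source != "total"]
    expect_equal(sum(lev), res$table$SSD[res$table$source == "total"],
                 tolerance = 1e-9)
    expect_equal(sum(res$table$percent[res$table$source != "total"]), 100,
                 tolerance = 1e-6)
  }
})

test_that("label-shuffled identical populations give Phi_ST near zero", {
  set.seed(13)
  d <- as.matrix(dist(matrix(rnorm(16 * 3), 16)))
  pop <- rep(c("x", "y"), 8)            # arbitrary split of one population
  res <- amova(d, pop, B = 199, seed = 5)
  expect_lt(abs(res$phi["Phi_ST"]), 0.25)
  expect_gt(res$p["Phi_ST"], 0.05)
})

test_that("two fixed distinct haplotypes give Phi_ST = 1", {
  aln <- alignment(paste0("s", 1:8),
                   c(rep("AAAAAAAA", 4), rep("AAGGGAAA", 4)))
  d <- distance_matrix(aln, model = "p")
  pop <- rep(c("p1", "p2"), each = 4)
  res <- amova(d, pop, B = 0)
  expect_equal(unname(res$phi["Phi_ST"]), 1, tolerance = 1e-12)
})

test_that("pairwise Phi_ST is the per-pair two-level AMOVA", {
  sim <- four_clade_sim(9, n = 6)
  d <- distance_matrix(sim$aln, model = "k2p")
  pop <- sim$samples$population
  pw <- pairwise_fst(d, pop, B = 0)
  for (pair in list(c("p1", "p2"), c("p2", "p4"))) {
    ix <- which(pop %in% pair)
    ref <- amova(d[ix, ix], pop[ix], B = 0)
    expect_equal(pw$fst[pair[1], pair[2]], unname(ref$phi["Phi_ST"]),
                 tolerance = 1e-12)
  }
  expect_identical(pw$fst, t(pw$fst))
  sm <- c(pop, "solo")
  d2 <- rbind(cbind(d, 0.01), 0.01); diag(d2) <- 0
  rownames(d2) <- colnames(d2) <- c(rownames(d), "x")
  expect_warning(pw2 <- pairwise_fst(d2, sm, B = 0), "single member")
  expect_true(all(is.na(pw2$fst["solo", setdiff(colnames(pw2$fst), "solo")])))
})

test_that("permutation p-values are uniform under the null", {
  set.seed(14)
  ps <- replicate(200, {
    d <- as.matrix(dist(matrix(rnorm(12 * 2), 12)))
    pop <- rep(c("u", "v"), each = 6)
    amova(d, pop, B = 199, seed = sample.int(1e6, 1))$p[["Phi_ST"]]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("great-circle distances match closed-form arcs", {
  pts <- data.frame(label = c("o", "e", "anti"),
                    lat = c(0, 0, 0), lon = c(0, 1, 180))
  m <- geo_distance(pts)
  expect_equal(m["o", "e"], 111.195080233533, tolerance = 1e-6)
  expect_equal(m["o", "anti"], 20015.1144420359, tolerance = 1e-6)
  expect_equal(m["o", "o"], 0)
  # centroid aggregation from a sample table
  st <- data.frame(sample_id = paste0("s", 1:4),
                   population = c("p", "p", "q", "q"),
                   country = "C", group = "G", host_plant = "h",
                   lat = c(0, 2, 10, 10), lon = c(0, 0, 5, 7))
  mq <- geo_distance(st)
  expect_equal(dim(mq), c(2, 2))
  st$lat[1] <- NA
  expect_error(geo_distance(st), "p")
})

test_that("Mantel exact mode enumerates all permutations; matches vegan", {
  set.seed(15)
  a <- as.matrix(dist(matrix(rnorm(8), 4)))
  b <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(a) <- dimnames(b) <- list(letters[1:4], letters[1:4])
  ex <- mantel_test(a, b)               # n = 4 -> exact
  expect_true(ex$exact)
  expect_equal(ex$B, 24)
  # self-comparison is a perfect correlation
  self <- mantel_test(a, a, exact = FALSE, B = 99)
  expect_equal(self$r, 1)
  expect_equal(self$R2, 1)
  # r statistic agrees with vegan on a bigger instance
  x <- as.matrix(dist(matrix(rnorm(30), 10)))
  y <- as.matrix(dist(matrix(rnorm(30), 10)))
  dimnames(x) <- dimnames(y) <- list(letters[1:10], letters[1:10])
  got <- mantel_test(x, y, B = 99, seed = 2)
  ref <- vegan::mantel(x, y, permutations = 99)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
  expect_error(mantel_test(x, y[10:1, 10:1]), "labels")
})

test_that("exact Mantel p equals an independent full enumeration", {
  set.seed(16)
  a <- as.matrix(dist(matrix(rnorm(8), 4)))
  b <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(a) <- dimnames(b) <- list(letters[1:4], letters[1:4])
  ex <- mantel_test(a, b)
  # independent enumeration via recursive permutation generation
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  low <- lower.tri(a)
  robs <- cor(a[low], b[low])
  rs <- sapply(perms(1:4), function(pm) cor(a[low], b[pm, pm][low]))
  expect_equal(ex$p, mean(abs(rs) >= abs(robs) - 1e-12))
})
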