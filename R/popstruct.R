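## Distance-based AMOVA (Excoffier-style sums of squared deviations computed
## directly from a pairwise distance matrix), permutation Phi-statistics,
## pairwise FST, great-circle distances and the Mantel test.

# sum of squared deviations for one set of individuals: sum_{i<j} delta2 / n
ssd_of <- function(delta2, idx) {
  if (length(idx) < 2) return(0)
  sum(delta2[idx, idx]) / 2 / length(idx)
}

# variance components; delta2 is the (optionally squared) distance matrix
amova_components <- function(delta2, pop, group = NULL) {
  N <- length(pop)
  pops <- split(seq_len(N), pop)
  P <- length(pops)
  Np <- lengths(pops)
  ssd_total <- ssd_of(delta2, seq_len(N))
  ssd_wp <- sum(vapply(pops, function(ix) ssd_of(delta2, ix), 0))
  if (is.null(group)) {
    df_ap <- P - 1L; df_wp <- N - P
    if (df_ap < 1 || df_wp < 1)
      stop("degrees of freedom exhausted at level: ",
           if (df_ap < 1) "among populations" else "within populations")
    ssd_ap <- ssd_total - ssd_wp
    sigma_c <- ssd_wp / df_wp
    n1 <- (N - sum(Np^2) / N) / df_ap
    sigma_b <- (ssd_ap / df_ap - sigma_c) / n1
    tot <- sigma_b + sigma_c
    list(
      df = c(among_populations = df_ap, within_populations = df_wp),
      ssd = c(among_populations = ssd_ap, within_populations = ssd_wp,
              total = ssd_total),
      sigma = c(among_populations = sigma_b, within_populations = sigma_c),
      coef = c(n = n1),
      phi = c(Phi_ST = sigma_b / tot)
    )
  } else {
    pop2group <- tapply(as.character(group), pop, function(g) g[1])
    groups <- split(seq_len(N), group)
    G <- length(groups)
    Ng <- lengths(groups)
    df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
    if (df_ag < 1) stop("degrees of freedom exhausted at level: among groups")
    if (df_ap < 1) stop("degrees of freedom exhausted at level: among populations within groups")
    if (df_wp < 1) stop("degrees of freedom exhausted at level: within populations")
    ssd_wg <- sum(vapply(groups, function(ix) ssd_of(delta2, ix), 0))
    ssd_ap <- ssd_wg - ssd_wp
    ssd_ag <- ssd_total - ssd_wg
    sigma_c <- ssd_wp / df_wp
    # sums of squared population sizes within each group
    sum_np2_by_g <- tapply(Np, pop2group[names(pops)], function(x) sum(x^2))
    A <- sum(sum_np2_by_g / Ng[names(sum_np2_by_g)])
    n1 <- (N - A) / df_ap
    n2 <- (A - sum(Np^2) / N) / df_ag
    n3 <- (N - sum(Ng^2) / N) / df_ag
    sigma_b <- (ssd_ap / df_ap - sigma_c) / n1
    sigma_a <- (ssd_ag / df_ag - sigma_c - n2 * sigma_b) / n3
    tot <- sigma_a + sigma_b + sigma_c
    list(
      df = c(among_groups = df_ag, among_populations = df_ap,
             within_populations = df_wp),
      ssd = c(among_groups = ssd_ag, among_populations = ssd_ap,
              within_populations = ssd_wp, total = ssd_total),
      sigma = c(among_groups = sigma_a, among_populations = sigma_b,
                within_populations = sigma_c),
      coef = c(n = n1, n2 = n2, n3 = n3),
      phi = c(Phi_CT = sigma_a / tot,
              Phi_SC = sigma_b / (sigma_b + sigma_c),
              Phi_ST = (sigma_a + sigma_b) / tot)
    )
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical decomposition of molecular variance from a pairwise distance
#' matrix over individuals, with two levels (among / within populations) or
#' three (among groups / among populations within groups / within
#' populations). Following the convention of molecular-distance AMOVA, the
#' distance itself is used as the squared deviation; set
#' `square_distances = TRUE` to square it first.
#'
#' Permutation p-values use the scheme appropriate to each statistic:
#' `Phi_ST` permutes individuals among populations, `Phi_SC` permutes
#' individuals among populations within their group, and `Phi_CT` permutes
#' whole populations among groups. `p = (b + 1) / (B + 1)` where `b` counts
#' permuted statistics `>=` the observed one.
#'
#' @param d labeled distance matrix over individuals.
#' @param pop population label per individual (parallel to rows of `d`).
#' @param group optional group label per individual; every population must
#'   lie in exactly one group.
#' @param B number of permutations (0 skips the test).
#' @param seed integer seed for the permutations.
#' @param square_distances square `d` before decomposing.
#' @return An object of class `amova_result`: `table` (df, SSD, variance
#'   components, percentages), `phi`, `p`, `B`.
#' @export
amova <- function(d, pop, group = NULL, B = 1000, seed = 1,
                  square_distances = FALSE) {
  stopifnot(nrow(d) == length(pop), nrow(d) >= 3)
  pop <- as.character(pop)
  if (length(unique(pop)) < 2) stop("need at least two populations")
  if (!is.null(group)) {
    group <- as.character(group)
    stopifnot(length(group) == length(pop))
    map <- unique(data.frame(pop, group))
    if (anyDuplicated(map$pop)) stop("a population is assigned to two groups")
  }
  delta2 <- if (square_distances) d^2 else d
  obs <- amova_components(delta2, pop, group)

  # internal consistency: SSD additivity and percentage normalisation
  lev <- setdiff(names(obs$ssd), "total")
  stopifnot(abs(sum(obs$ssd[lev]) - obs$ssd[["total"]]) < 1e-9)
  pct <- 100 * obs$sigma / sum(obs$sigma)
  stopifnot(abs(sum(pct) - 100) < 1e-6)

  p <- setNames(rep(NA_real_, length(obs$phi)), names(obs$phi))
  if (B > 0) {
    set.seed(seed)
    N <- length(pop)
    cnt <- setNames(numeric(length(obs$phi)), names(obs$phi))
    perm_phi <- function(pp, gg) {
      tryCatch(amova_components(delta2, pp, gg)$phi,
               error = function(e) setNames(rep(NA_real_, length(obs$phi)),
                                            names(obs$phi)))
    }
    for (b in seq_len(B)) {
      if (is.null(group)) {
        ph <- perm_phi(pop[sample.int(N)], NULL)
        cnt["Phi_ST"] <- cnt["Phi_ST"] +
          (!is.na(ph["Phi_ST"]) && ph["Phi_ST"] >= obs$phi["Phi_ST"])
      } else {
        # Phi_ST: individuals among all populations
        ph <- perm_phi(pop[sample.int(N)], group)
        cnt["Phi_ST"] <- cnt["Phi_ST"] +
          (!is.na(ph["Phi_ST"]) && ph["Phi_ST"] >= obs$phi["Phi_ST"])
        # Phi_SC: individuals among populations within their group
        pp <- pop
        for (g in unique(group)) {
          ix <- which(group == g)
          pp[ix] <- pop[ix][sample.int(length(ix))]
        }
        ph <- perm_phi(pp, group)
        cnt["Phi_SC"] <- cnt["Phi_SC"] +
          (!is.na(ph["Phi_SC"]) && ph["Phi_SC"] >= obs$phi["Phi_SC"])
        # Phi_CT: whole populations among groups
        map <- unique(data.frame(pop, group))
        map$group <- map$group[sample.int(nrow(map))]
        gg <- map$group[match(pop, map$pop)]
        ph <- perm_phi(pop, gg)
        cnt["Phi_CT"] <- cnt["Phi_CT"] +
          (!is.na(ph["Phi_CT"]) && ph["Phi_CT"] >= obs$phi["Phi_CT"])
      }
    }
    p <- (cnt + 1) / (B + 1)
  }

  tab <- data.frame(
    source = c(lev, "total"),
    df = c(obs$df[lev], sum(obs$df[lev])),
    SSD = obs$ssd[c(lev, "total")],
    variance = c(obs$sigma[lev], sum(obs$sigma)),
    percent = c(pct[lev], 100),
    row.names = NULL
  )
  structure(list(table = tab, phi = obs$phi, p = p, B = B,
                 coef = obs$coef, sigma = obs$sigma),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (distance-based)\n")
  print(x$table, row.names = FALSE, digits = 5)
  cat("\nPhi statistics:\n")
  for (nm in names(x$phi))
    cat(sprintf("  %-7s = %8.4f  (p = %s)\n", nm, x$phi[nm],
                format(x$p[nm], digits = 3)))
  invisible(x)
}

#' Pairwise population Phi_ST
#'
#' `fst[p, q]` is `Phi_ST` from the two-population AMOVA restricted to the
#' individuals of `p` and `q` (identical to [amova()] on that subset).
#' Slightly negative values are possible and preserved: they indicate no
#' detectable differentiation. Populations with a single member give `NA`
#' rows with a warning.
#'
#' @param d labeled distance matrix over individuals.
#' @param pop population label per individual.
#' @param B permutations per pair for the p-value matrix.
#' @param seed integer seed.
#' @return List with `fst` and `pvals`, labeled square matrices over
#'   populations.
#' @export
pairwise_fst <- function(d, pop, B = 1000, seed = 1) {
  pop <- as.character(pop)
  pops <- unique(pop)
  stopifnot(length(pops) >= 2)
  sizes <- table(pop)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("population(s) with a single member give NA: ",
            paste(small, collapse = ", "))
  P <- length(pops)
  fst <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pv <- fst
  diag(fst) <- 0
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    if (pops[i] %in% small || pops[j] %in% small) next
    ix <- which(pop %in% pops[c(i, j)])
    res <- amova(d[ix, ix, drop = FALSE], pop[ix], B = B,
                 seed = seed + i * P + j)
    fst[i, j] <- fst[j, i] <- unname(res$phi["Phi_ST"])
    pv[i, j] <- pv[j, i] <- unname(res$p["Phi_ST"])
  }
  list(fst = fst, pvals = pv)
}

#' Great-circle distance matrix (km)
#'
#' Haversine distances on a sphere of radius 6371.0088 km. Given a sample
#' table, population centroids default to the mean of the member
#' coordinates; alternatively pass a data frame with `label`, `lat`, `lon`.
#'
#' @param x sample table (see [read_samples()]) or a `label`/`lat`/`lon`
#'   data frame.
#' @return Labeled symmetric matrix of distances in km.
#' @export
geo_distance <- function(x) {
  if (all(c("label", "lat", "lon") %in% names(x))) {
    pts <- x
  } else {
    x <- validate_samples(x)
    if (!all(c("lat", "lon") %in% names(x)))
      stop("sample table has no coordinates")
    bad <- unique(x$population[is.na(x$lat) | is.na(x$lon)])
    if (length(bad))
      stop("missing coordinates for: ", paste(bad, collapse = ", "))
    pts <- do.call(rbind, lapply(split(x, x$population), function(df)
      data.frame(label = df$population[1], lat = mean(df$lat),
                 lon = mean(df$lon))))
  }
  if (anyNA(pts$lat) || anyNA(pts$lon))
    stop("missing coordinates for: ",
         paste(pts$label[is.na(pts$lat) | is.na(pts$lon)], collapse = ", "))
  m <- geosphere::distm(cbind(pts$lon, pts$lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371008.8))
  m <- m / 1000
  dimnames(m) <- list(pts$label, pts$label)
  diag(m) <- 0
  m
}

# all permutations of 1..n (n small), used by the exact Mantel mode
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Mantel matrix-correlation test
#'
#' Pearson correlation between the lower-triangle entries of two labeled
#' distance matrices, with significance from random joint row/column
#' permutations of the second matrix (two-sided on `|r|`,
#' `p = (b + 1)/(B + 1)`). For `n <= 7` labels an exact mode enumerates all
#' `n!` permutations instead.
#'
#' @param m1,m2 labeled square matrices with identical labels in identical
#'   order; at least 4 labels.
#' @param B random permutations.
#' @param seed integer seed.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default enumerates when `n <= 7`.
#' @return List of class `mantel_result`: `r`, `R2`, `p`, `B`, `exact`.
#' @export
mantel_test <- function(m1, m2, B = 1000, seed = 1, exact = NULL) {
  if (!identical(rownames(m1), rownames(m2)))
    stop("matrix labels differ or are ordered differently")
  n <- nrow(m1)
  stopifnot(n >= 4)
  low <- lower.tri(m1)
  r_obs <- stats::cor(m1[low], m2[low])
  if (is.null(exact)) exact <- n <= 7
  if (exact) {
    perms <- all_perms(n)
    rs <- apply(perms, 1, function(pm) {
      mp <- m2[pm, pm]
      stats::cor(m1[low], mp[low])
    })
    p <- mean(abs(rs) >= abs(r_obs) - 1e-12)
    B <- nrow(perms)
  } else {
    set.seed(seed)
    b <- 0L
    for (i in seq_len(B)) {
      pm <- sample.int(n)
      mp <- m2[pm, pm]
      if (abs(stats::cor(m1[low], mp[low])) >= abs(r_obs) - 1e-12) b <- b + 1L
    }
    p <- (b + 1) / (B + 1)
  }
  structure(list(r = r_obs, R2 = r_obs^2, p = p, B = B, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, R2 = %.4f, p = %s (%s, B = %d)\n",
              x$r, x$R2, format(x$p, digits = 3),
              if (x$exact) "exact" else "permutation", x$B))
  invisible(x)
}

#' Transform an FST matrix for isolation-by-distance regression
#'
#' Rousset's linearisation `FST / (1 - FST)`, offered because web IBD tools
#' commonly provide it alongside untransformed matrices.
#'
#' @param fst labeled FST matrix.
#' @export
fst_linearized <- function(fst) {
  out <- fst / (1 - fst)
  diag(out) <- 0
  out
}
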