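## Median-joining haplotype networks: epsilon-relaxed minimum spanning
## network over weighted Hamming distances, consensus median vectors added
## while they reduce the cost of spanning the node set, and a
## maximum-parsimony post-processing step that removes superfluous median
## vectors and links.

#' Weighted Hamming distance between two sequences
#'
#' Each differing site contributes its site weight times the substitution
#' weight: `tv_weight` when the observed state pair is a transversion
#' (purine vs pyrimidine), 1 for a transition. Multi-state sites use the
#' weight of the specific pair compared.
#'
#' @param a,b equal-length character vectors or single strings.
#' @param tv_weight transversion weight (3 reflects the common practice of
#'   weighting transversions three times as high as transitions).
#' @param site_weights optional positive per-site weights (default 1),
#'   e.g. to downweight hypervariable positions.
#' @export
weighted_hamming <- function(a, b, tv_weight = 3, site_weights = NULL) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(a) == length(b))
  if (is.null(site_weights)) site_weights <- rep(1, length(a))
  diff <- which(a != b)
  if (!length(diff)) return(0)
  sub_w <- ifelse(is_transition(a[diff], b[diff]), 1, tv_weight)
  sum(site_weights[diff] * sub_w)
}

# pairwise weighted-hamming matrix over rows of a character matrix
wh_matrix <- function(mat, tv_weight, site_weights) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- weighted_hamming(mat[i, ], mat[j, ],
                                           tv_weight, site_weights)
  d
}

# minimax (bottleneck) path weights by Floyd-Warshall relaxation
bottleneck <- function(D) {
  n <- nrow(D)
  B <- D
  for (k in seq_len(n)) {
    Bk <- pmax(matrix(B[, k], n, n), matrix(B[k, ], n, n, byrow = TRUE))
    B <- pmin(B, Bk)
  }
  B
}

# total weight of a minimum spanning tree (Prim)
mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  cost <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]
    cost <- cost + best[j]
    intree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  cost
}

# edges of the epsilon-relaxed minimum spanning network:
# (i, j) included iff D_ij <= bottleneck_ij + eps
msn_edges <- function(D, eps) {
  B <- bottleneck(D)
  keep <- which(D <= B + eps + 1e-12 & upper.tri(D), arr.ind = TRUE)
  keep
}

# consensus median candidates of a sequence triplet: site-wise majority;
# a three-way tie yields one candidate per state (capped combinatorially,
# resolved in lexicographic order)
median_candidates <- function(m3, max_tie_sites = 5) {
  L <- ncol(m3)
  cons <- character(L)
  tie_sites <- integer(0)
  for (s in seq_len(L)) {
    st <- m3[, s]
    tab <- sort(table(st), decreasing = TRUE)
    if (tab[1] >= 2) cons[s] <- names(tab)[1]
    else { cons[s] <- NA; tie_sites <- c(tie_sites, s) }
  }
  if (!length(tie_sites)) return(matrix(cons, nrow = 1))
  if (length(tie_sites) > max_tie_sites) {
    # too many ties: take the lexicographically smallest state per site
    for (s in tie_sites) cons[s] <- sort(m3[, s])[1]
    return(matrix(cons, nrow = 1))
  }
  grids <- lapply(tie_sites, function(s) sort(unique(m3[, s])))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  out <- matrix(rep(cons, nrow(combos)), nrow = nrow(combos), byrow = TRUE)
  for (k in seq_along(tie_sites)) out[, tie_sites[k]] <- combos[[k]]
  out
}

#' Build a median-joining haplotype network
#'
#' Constructs the epsilon-relaxed minimum spanning network over the
#' haplotypes' weighted Hamming distances (an edge is kept when its length
#' is within `epsilon` of the cheapest connection between its endpoints'
#' clusters), inserts consensus median vectors of sequence triplets while
#' doing so reduces the cost of spanning the node set, and finally removes
#' median vectors and links that lie on no minimal-cost path between a pair
#' of observed haplotypes.
#'
#' @param hset a `haploset`.
#' @param epsilon relaxation parameter (weighted-distance units); larger
#'   values admit more alternative links.
#' @param tv_weight transversion weight, see [weighted_hamming()].
#' @param site_weights optional per-site weights over the analysis sites.
#' @param max_medians safety cap on inserted median vectors.
#' @return Object of class `haplonet`: `nodes` (id, sequence, type, freq),
#'   `edges` (from, to, weight, differing sites), `cost` (minimum cost of
#'   spanning the final node set), `epsilon`.
#' @export
build_mjn <- function(hset, epsilon = 0, tv_weight = 3, site_weights = NULL,
                      max_medians = 200) {
  stopifnot(inherits(hset, "haploset"), hset$K >= 2)
  mat <- hset$mat
  ids <- hset$ids
  freq <- hset$freq
  obs_n <- nrow(mat)
  type <- rep("observed", obs_n)

  dfun <- function(m) wh_matrix(m, tv_weight, site_weights)
  D <- dfun(mat)
  cost <- mst_cost(D)
  n_mv <- 0L

  repeat {
    n <- nrow(mat)
    edges <- msn_edges(D, epsilon)
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj <- adj | t(adj)
    # candidate triplets: all triples for small networks, otherwise only
    # triples already connected by at least two network links
    trips <- if (n >= 3) utils::combn(n, 3) else matrix(integer(0), 3, 0)
    if (n > 12) {
      keep <- apply(trips, 2, function(t3)
        sum(adj[t3[1], t3[2]], adj[t3[1], t3[3]], adj[t3[2], t3[3]]) >= 2)
      trips <- trips[, keep, drop = FALSE]
    }
    seen <- apply(mat, 1, paste, collapse = "")
    best_gain <- 0
    best_seq <- NULL
    if (ncol(trips) > 0) for (ti in seq_len(ncol(trips))) {
      cands <- median_candidates(mat[trips[, ti], , drop = FALSE])
      for (ci in seq_len(nrow(cands))) {
        key <- paste(cands[ci, ], collapse = "")
        if (key %in% seen) next
        m2 <- rbind(mat, cands[ci, ])
        gain <- cost - mst_cost(dfun(m2))
        if (gain > best_gain + 1e-12 ||
            (gain > 1e-12 && abs(gain - best_gain) <= 1e-12 &&
             !is.null(best_seq) && key < paste(best_seq, collapse = ""))) {
          best_gain <- gain
          best_seq <- cands[ci, ]
        }
      }
    }
    if (is.null(best_seq) || n_mv >= max_medians) break
    n_mv <- n_mv + 1L
    mat <- rbind(mat, best_seq)
    ids <- c(ids, paste0("mv", n_mv))
    freq <- c(freq, 0L)
    type <- c(type, "median")
    D <- dfun(mat)
    cost <- cost - best_gain
  }

  # final relaxed spanning network over the full node set
  edges <- msn_edges(D, epsilon)
  net <- prune_mp(mat, ids, type, D, edges, tv_weight, site_weights)
  mat <- net$mat; ids <- net$ids; type <- net$type; edges <- net$edges
  D <- net$D
  freq <- freq[match(ids, c(hset$ids, paste0("mv", seq_len(n_mv))))]
  freq[type == "median"] <- 0L

  ediff <- vapply(seq_len(nrow(edges)), function(k) {
    paste(which(mat[edges[k, 1], ] != mat[edges[k, 2], ]), collapse = ",")
  }, "")
  nodes <- data.frame(id = ids,
                      sequence = apply(mat, 1, paste, collapse = ""),
                      type = type, freq = freq, stringsAsFactors = FALSE)
  edf <- data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                    weight = D[edges], sites = ediff,
                    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edf, cost = mst_cost(D),
                 epsilon = epsilon, tv_weight = tv_weight),
            class = "haplonet")
}

# maximum-parsimony post-processing: keep only edges on a minimal-cost path
# between observed haplotypes, then eliminate median vectors of degree <= 2
prune_mp <- function(mat, ids, type, D, edges, tv_weight, site_weights) {
  repeat {
    n <- nrow(mat)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2], weight = D[edges]),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    sp <- igraph::distances(g)
    obs <- which(type == "observed")
    keep <- logical(nrow(edges))
    for (k in seq_len(nrow(edges))) {
      x <- edges[k, 1]; y <- edges[k, 2]; w <- D[x, y]
      for (o1 in obs) {
        hit <- any(abs(sp[o1, x] + w + sp[y, obs] - sp[o1, obs]) < 1e-9) ||
               any(abs(sp[o1, y] + w + sp[x, obs] - sp[o1, obs]) < 1e-9)
        if (hit) { keep[k] <- TRUE; break }
      }
    }
    edges <- edges[keep, , drop = FALSE]
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    drop <- which(type == "median" & deg <= 2)
    if (!length(drop)) break
    # contract degree-2 medians with a direct link; discard degree<=1 ones
    v <- drop[1]
    if (deg[v] == 2) {
      nb <- setdiff(unique(c(edges[edges[, 1] == v, 2],
                             edges[edges[, 2] == v, 1],
                             edges[edges[, 1] == v, 1],
                             edges[edges[, 2] == v, 2])), v)
      if (length(nb) == 2 && D[nb[1], nb[2]] > 0) {
        has <- any((edges[, 1] == min(nb) & edges[, 2] == max(nb)) |
                   (edges[, 1] == max(nb) & edges[, 2] == min(nb)))
        if (!has) edges <- rbind(edges, matrix(c(min(nb), max(nb)), 1))
      }
    }
    stay <- setdiff(seq_len(n), v)
    remap <- match(seq_len(n), stay)
    edges <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    edges <- cbind(remap[edges[, 1]], remap[edges[, 2]])
    mat <- mat[stay, , drop = FALSE]
    ids <- ids[stay]; type <- type[stay]
    D <- D[stay, stay, drop = FALSE]
  }
  # observed haplotypes must remain connected
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(mat))))
  stopifnot(igraph::components(g)$no == 1)
  list(mat = mat, ids = ids, type = type, D = D, edges = edges)
}

#' @export
print.haplonet <- function(x, ...) {
  cat("median-joining network:", sum(x$nodes$type == "observed"),
      "haplotypes +", sum(x$nodes$type == "median"), "median vectors,",
      nrow(x$edges), "links; spanning cost", x$cost, "\n")
  invisible(x)
}

#' Annotate a network with frequencies and population composition
#'
#' Joins the haplotype membership lists with a sample table to give, per
#' node, its total frequency and composition over a metadata column, plus
#' the founder candidates (maximum frequency, ties broken by degree) --
#' high-frequency, high-degree nodes are the classic signature of the
#' ancestral haplotype of a radiation.
#'
#' @param net a `haplonet`.
#' @param hset the `haploset` the network was built from.
#' @param samples sample table; `NULL` gives frequencies only.
#' @param by metadata column for the composition (default `"population"`).
#' @return List with `composition` (node x category counts) and `founder`
#'   (node id).
#' @export
annotate_network <- function(net, hset, samples = NULL, by = "population") {
  obs <- net$nodes$id[net$nodes$type == "observed"]
  hix <- match(obs, hset$ids)
  comp <- NULL
  if (!is.null(samples)) {
    samples <- validate_samples(samples)
    cats <- sort(unique(samples[[by]]))
    comp <- matrix(0L, length(obs), length(cats),
                   dimnames = list(obs, cats))
    for (i in seq_along(obs)) {
      mem <- hset$members[[hix[i]]]
      ix <- match(mem, samples$sample_id)
      if (anyNA(ix)) stop("unknown sample ids: ",
                          paste(mem[is.na(ix)], collapse = ", "))
      tab <- table(samples[[by]][ix])
      comp[i, names(tab)] <- as.integer(tab)
    }
    stopifnot(all(rowSums(comp) == hset$freq[hix]))
  }
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$id))
  fr <- hset$freq[hix]
  founder <- obs[order(-fr, -as.integer(deg[obs]))][1]
  list(composition = comp, founder = founder,
       degree = as.integer(deg[obs]), freq = fr)
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param net a `haplonet`.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` and `<prefix>.graphml`.
#' @export
write_network <- function(net, prefix) {
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
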