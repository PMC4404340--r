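#' Collapse aligned sequences into haplotypes
#'
#' Individuals with identical sequences over the analysis sites are assigned
#' to one haplotype. Analysis sites are the alignment columns containing an
#' unambiguous base (A, C, G or T) in every record ("complete deletion"):
#' dropping columns with any gap or ambiguity gives one consistent site
#' universe for haplotype identity and all site statistics.
#'
#' Haplotype ids are `H1..HK` in order of first appearance; frequency ties
#' are never reordered.
#'
#' @param aln a [alignment()] object.
#' @return An object of class `haploset`: `ids` (haplotype ids), `mat`
#'   (`K x L_used` matrix over analysis sites), `rep_mat` (representative
#'   full-length sequences, first member of each haplotype), `freq`
#'   (member counts), `members` (list of sample ids), `n`, `K`, `L_used`,
#'   `sites` (indices of the analysis columns in the input alignment).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "mito_aln"))
  ok <- colSums(matrix(aln$mat %in% c("A", "C", "G", "T"), nrow = nrow(aln$mat))) ==
    nrow(aln$mat)
  if (!any(ok))
    stop("no analysis sites remain after complete deletion of gapped/ambiguous columns")
  sites <- which(ok)
  sub <- aln$mat[, sites, drop = FALSE]
  key <- apply(sub, 1, paste, collapse = "")
  first <- !duplicated(key)
  hap_of <- match(key, key[first])
  K <- sum(first)
  members <- split(aln$ids, hap_of)
  members <- members[as.character(seq_len(K))]
  structure(list(
    ids = paste0("H", seq_len(K)),
    mat = sub[first, , drop = FALSE],
    rep_mat = aln$mat[first, , drop = FALSE],
    freq = as.integer(lengths(members)),
    members = unname(members),
    n = length(aln$ids),
    K = K,
    L_used = length(sites),
    sites = sites
  ), class = "haploset")
}

#' Expand a haplotype set back into an alignment
#'
#' One record per individual, each carrying its haplotype's representative
#' full-length sequence. Collapsing the result reproduces the input set
#' (collapse is idempotent).
#'
#' @param hset a `haploset`.
#' @export
expand_haplotypes <- function(hset) {
  stopifnot(inherits(hset, "haploset"))
  idx <- rep(seq_len(hset$K), hset$freq)
  alignment(unlist(hset$members), hset$rep_mat[idx, , drop = FALSE])
}

#' Build a haplotype set directly from sequences and frequencies
#'
#' Convenience constructor for frequency-spectrum data (e.g. a published
#' haplotype table): sequences must already be distinct.
#'
#' @param seqs character vector of distinct equal-length sequences.
#' @param freq integer frequencies (counts), all >= 1.
#' @param ids optional haplotype ids (default `H1..HK`).
#' @export
haploset_from_freq <- function(seqs, freq, ids = NULL) {
  aln <- alignment(paste0("s", seq_along(seqs)), seqs)
  if (anyDuplicated(apply(aln$mat, 1, paste, collapse = "")))
    stop("sequences are not pairwise distinct")
  stopifnot(length(freq) == length(seqs), all(freq >= 1))
  K <- length(seqs)
  if (is.null(ids)) ids <- paste0("H", seq_len(K))
  members <- lapply(seq_len(K), function(i) paste0(ids[i], "_", seq_len(freq[i])))
  structure(list(
    ids = ids, mat = aln$mat, rep_mat = aln$mat,
    freq = as.integer(freq), members = members,
    n = sum(freq), K = K, L_used = ncol(aln$mat),
    sites = seq_len(ncol(aln$mat))
  ), class = "haploset")
}

#' @export
print.haploset <- function(x, ...) {
  cat("haplotype set: K =", x$K, "haplotypes, n =", x$n,
      "individuals,", x$L_used, "analysis sites\n")
  invisible(x)
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Site-level polymorphism summary
#'
#' Counts computed over the analysis sites of a haplotype set, weighting
#' every state by its individual (not haplotype) frequency:
#' \itemize{
#'   \item `S`: segregating sites (columns with >= 2 states);
#'   \item `PI`: parsimony-informative sites (>= 2 states each carried by
#'     >= 2 individuals);
#'   \item `n_ts`, `n_tv`: substitution mutations classified as transition
#'     (A<->G, C<->T) or transversion. A column with `m` states contributes
#'     `m - 1` substitutions, each read as a change from the column's
#'     frequency-weighted majority state to a minor state;
#'   \item `base_comp`: frequency-weighted mean base composition;
#'   \item `L_used`: number of analysis sites.
#' }
#'
#' @param hset a `haploset`.
#' @return A list with the fields above.
#' @export
site_summary <- function(hset) {
  stopifnot(inherits(hset, "haploset"))
  S <- 0L; PI <- 0L; n_ts <- 0L; n_tv <- 0L
  comp <- c(A = 0, C = 0, G = 0, T = 0)
  w <- hset$freq
  for (j in seq_len(hset$L_used)) {
    col <- hset$mat[, j]
    cnt <- tapply(w, col, sum)
    comp[names(cnt)] <- comp[names(cnt)] + cnt
    if (length(cnt) >= 2L) {
      S <- S + 1L
      if (sum(cnt >= 2) >= 2L) PI <- PI + 1L
      # majority state by individual frequency; ties broken alphabetically
      maj <- names(cnt)[order(-cnt, names(cnt))][1]
      for (st in setdiff(names(cnt), maj)) {
        if (is_transition(maj, st)) n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
      }
    }
  }
  comp <- comp / sum(comp)
  list(S = S, PI = PI, n_ts = n_ts, n_tv = n_tv,
       base_comp = comp, L_used = hset$L_used)
}
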