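#' Construct an alignment object
#'
#' An alignment is an ordered set of equal-length DNA sequences with unique
#' sample ids. Sequences are stored upper-case as an `n x L` character matrix;
#' `U` is mapped to `T` on construction so RNA-style input behaves like DNA.
#'
#' @param ids character vector of unique sample identifiers.
#' @param seqs character vector of sequences (strings), or an `n x L`
#'   character matrix with one base per cell.
#' @return An object of class `mito_aln` with elements `ids`, `mat`
#'   (character matrix, rows = samples) and `L` (alignment length).
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- ids[lens != stats::median(lens)]
      stop("unequal sequence lengths; offending record(s): ",
           paste(bad, collapse = ", "))
    }
    if (lens[1] == 0L) stop("alignment has zero length")
    mat <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
                  byrow = TRUE)
  }
  mat[mat == "U"] <- "T"
  if (ncol(mat) == 0L) stop("alignment has zero length")
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, L = ncol(mat)), class = "mito_aln")
}

#' Read a FASTA alignment
#'
#' All records must have identical length; an informative error names the
#' offending record otherwise.
#'
#' @param path path to a FASTA file.
#' @return A [alignment()] object, input order preserved.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("not a parseable FASTA (no records): ", path)
  seqs <- vapply(as.character(recs), function(x) paste(x, collapse = ""), "")
  alignment(names(recs), unname(seqs))
}

#' Write an alignment as FASTA
#'
#' @param aln a [alignment()] object.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "mito_aln"))
  lines <- character(2L * length(aln$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.mito_aln <- function(x, ...) {
  cat("alignment:", length(x$ids), "sequences x", x$L, "sites\n")
  invisible(x)
}

#' Trim an alignment to a site window
#'
#' Explicit coordinate trimming (1-based, inclusive), used to cut records to
#' a common analysis window before collapsing into haplotypes.
#'
#' @param aln alignment.
#' @param start,end 1-based inclusive column range.
#' @export
trim_alignment <- function(aln, start, end) {
  stopifnot(inherits(aln, "mito_aln"), start >= 1, end <= aln$L, start <= end)
  alignment(aln$ids, aln$mat[, start:end, drop = FALSE])
}

#' Read a sample metadata table
#'
#' Expects a TSV with header columns `sample_id`, `population`, `country`,
#' `group`, `host_plant` and optional `lat`/`lon` (decimal degrees). Each
#' population must map to exactly one country and one group.
#'
#' @param path TSV file.
#' @return A validated data frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_samples(df)
}

#' Validate a sample table
#'
#' @param df data frame with the columns described in [read_samples()].
#' @return `df`, invisibly checked.
#' @export
validate_samples <- function(df) {
  need <- c("sample_id", "population", "country", "group", "host_plant")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in c("country", "group")) {
    map <- unique(df[, c("population", col)])
    dup <- map$population[duplicated(map$population)]
    if (length(dup))
      stop("population mapped to multiple ", col, "s: ", paste(dup, collapse = ", "))
  }
  if ("lat" %in% names(df) && any(!is.na(df$lat) & abs(df$lat) > 90))
    stop("latitude out of [-90, 90]")
  if ("lon" %in% names(df) && any(!is.na(df$lon) & abs(df$lon) > 180))
    stop("longitude out of [-180, 180]")
  df
}

#' Read a labeled square matrix from TSV
#'
#' Rows carry a leading label followed by tab-separated numeric cells.
#' `triangle` selects which half of the block is read; the result is always
#' a symmetrized full matrix with a zero diagonal. Blank or dash cells on the
#' unused triangle are ignored. Small negative entries (as found in FST
#' tables) are permitted.
#'
#' @param path TSV file (no header row).
#' @param triangle one of `"lower"`, `"upper"`, `"full"`.
#' @return A symmetric numeric matrix with `dimnames`.
#' @export
read_labeled_matrix <- function(path, triangle = c("lower", "upper", "full")) {
  triangle <- match.arg(triangle)
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  rows <- rows[vapply(rows, length, 1L) > 0L]
  labels <- vapply(rows, `[[`, "", 1L)
  n <- length(labels)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    cells <- rows[[i]][-1]
    # strip thousands separators used in printed distance tables
    cells <- gsub(",", "", cells, fixed = TRUE)
    keep <- switch(triangle,
                   lower = seq_len(i - 1L),
                   upper = if (i < n) (i + 1L):n else integer(0),
                   full  = seq_len(n))
    for (j in keep) {
      if (j > length(cells)) {
        if (triangle == "full") stop("non-square block at row ", labels[i])
        next
      }
      cell <- trimws(cells[j])
      if (cell %in% c("", "-", "–", "NA")) next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v))
        stop("non-numeric cell at row ", labels[i], ", column ", labels[j],
             ": '", cell, "'")
      m[i, j] <- v
    }
  }
  out <- matrix(0, n, n, dimnames = dimnames(m))
  if (triangle == "lower") {
    low <- lower.tri(m)
    out[low] <- m[low]
    out <- out + t(out)
  } else if (triangle == "upper") {
    up <- upper.tri(m)
    out[up] <- m[up]
    out <- out + t(out)
  } else {
    if (any(is.na(m))) stop("non-square or incomplete full matrix")
    out <- (m + t(m)) / 2
  }
  diag(out) <- 0
  out
}

#' Write a labeled matrix as TSV
#'
#' Inverse of [read_labeled_matrix()] with `triangle = "full"`.
#'
#' @param m labeled square matrix.
#' @param path output TSV.
#' @export
write_labeled_matrix <- function(m, path) {
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Merge two matrices into one mixed-triangle table
#'
#' Writes `lower` below the diagonal and `upper` above it, the layout used
#' for joint FST / geographic-distance tables.
#'
#' @param lower,upper labeled matrices over the same labels.
#' @param path output TSV.
#' @export
write_merged_matrix <- function(lower, upper, path) {
  stopifnot(identical(rownames(lower), rownames(upper)))
  m <- upper
  m[lower.tri(m)] <- lower[lower.tri(lower)]
  diag(m) <- 0
  write_labeled_matrix(m, path)
}
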