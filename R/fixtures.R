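## Packaged transcriptions of the published summary tables used as
## desk-scale inputs: the 64-row haplotype frequency spectrum (n = 686) and
## the joint pairwise-FST / geographic-distance matrices for the 20
## country-level populations and the 9 continental regions.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mitopop")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' Haplotype frequency spectrum fixture
#'
#' The 64 haplotype frequencies of the pooled 686-individual barcode
#' sample.
#'
#' @return Data frame with `haplotype` and `frequency`.
#' @export
haplotype_frequency_fixture <- function() {
  utils::read.delim(fixture_path("table1_haplotype_frequencies.tsv"),
                    stringsAsFactors = FALSE)
}

#' Country-level FST / geographic distance fixture
#'
#' The 20-population joint matrix: pairwise Phi_ST below the diagonal,
#' great-circle distances (km) above it.
#'
#' @return List with `fst` and `km`, labeled symmetric matrices.
#' @export
country_matrix_fixture <- function() {
  p <- fixture_path("table4_country_fst_geo.tsv")
  list(fst = read_labeled_matrix(p, "lower"),
       km  = read_labeled_matrix(p, "upper"))
}

#' Region-level FST / geographic distance fixture
#'
#' The 9-region joint matrix, same layout as [country_matrix_fixture()].
#'
#' @export
region_matrix_fixture <- function() {
  p <- fixture_path("table5_region_fst_geo.tsv")
  list(fst = read_labeled_matrix(p, "lower"),
       km  = read_labeled_matrix(p, "upper"))
}

#' Region labels as a sample table
#'
#' The 9 region labels of the region fixture in sample-table form (one
#' pseudo-sample per region), for joins that expect metadata.
#'
#' @export
region_sample_fixture <- function() {
  labs <- rownames(region_matrix_fixture()$fst)
  data.frame(sample_id = labs, population = labs,
             country = labs, group = sub("_.*", "", labs),
             host_plant = NA_character_, stringsAsFactors = FALSE)
}

#' Regenerate the packaged fixtures
#'
#' Writes the three fixture tables to `dir` through the package's own
#' writers; the regenerated files parse back to content identical to the
#' packaged copies.
#'
#' @param dir output directory.
#' @return Paths of the written files, invisibly.
#' @export
make_fixtures <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freq <- haplotype_frequency_fixture()
  p1 <- file.path(dir, "table1_haplotype_frequencies.tsv")
  utils::write.table(freq, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- country_matrix_fixture()
  p2 <- file.path(dir, "table4_country_fst_geo.tsv")
  write_merged_matrix(cm$fst, cm$km, p2)
  rm <- region_matrix_fixture()
  p3 <- file.path(dir, "table5_region_fst_geo.tsv")
  write_merged_matrix(rm$fst, rm$km, p3)
  invisible(c(p1, p2, p3))
}
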