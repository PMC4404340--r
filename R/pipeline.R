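#' Run the full barcode phylogeography workflow
#'
#' Orchestrates the analysis stages in their natural order -- haplotype
#' collapsing, site summary, diversity and neutrality statistics, distance
#' matrix and NJ tree, pairwise FST and AMOVA, geographic distances and
#' Mantel isolation-by-distance, ABGD species delimitation, median-joining
#' network -- writing tabular outputs plus a machine-readable JSON summary
#' and a log of every parameter in force. Deterministic given the seed.
#'
#' Without an alignment the pipeline runs in fixtures-only mode: haplotype
#' diversity on the packaged frequency spectrum and Mantel tests on the
#' packaged country and region matrices.
#'
#' @param config a list or a path to a YAML file. Recognised keys:
#'   `seed` (required), `out_dir` (required), `alignment` (FASTA path),
#'   `samples` (TSV path), `by` (diversity stratum column, default
#'   `"population"`), `group_by` (AMOVA group column, default `"group"`),
#'   `model` (`"k2p"`/`"p"`), `B` (permutations, default 1000), `epsilon`,
#'   `tv_weight`, `square_distances`, `abgd` (list: `pmin`, `pmax`,
#'   `steps`, `x`), `mantel` (list: `log_distance`, `fst_linearized`),
#'   `outgroup`.
#' @return The JSON summary as a list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  B <- config$B %||% 1000
  model <- config$model %||% "k2p"
  stage <- "setup"
  summary <- list(seed = config$seed, model = model, B = B)
  logf <- file.path(out, "run_log.txt")
  logit <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logit("mitopop ", as.character(utils::packageVersion("mitopop")),
        "; R ", R.version.string)
  logit("seed=", config$seed, " B=", B, " model=", model)

  res <- tryCatch({
    if (is.null(config$alignment)) {
      stage <- "fixtures"
      freq <- haplotype_frequency_fixture()
      summary$fixtures <- list(
        n = sum(freq$frequency), K = nrow(freq),
        h = haplotype_diversity(freq$frequency))
      for (nm in c("country", "region")) {
        m <- if (nm == "country") country_matrix_fixture()
             else region_matrix_fixture()
        fst <- m$fst; km <- m$km
        if (isTRUE(config$mantel$fst_linearized)) fst <- fst_linearized(fst)
        if (isTRUE(config$mantel$log_distance)) {
          km <- log(km); diag(km) <- 0
        }
        mt <- mantel_test(fst, km, B = B, seed = config$seed, exact = FALSE)
        summary[[paste0("mantel_", nm)]] <-
          list(r = mt$r, R2 = mt$R2, p = mt$p)
      }
    } else {
      stage <- "haplotypes"
      aln <- read_alignment(config$alignment)
      samples <- read_samples(config$samples)
      hset <- collapse_haplotypes(aln)
      ss <- site_summary(hset)
      hap_tab <- data.frame(haplotype = hset$ids, frequency = hset$freq,
                            members = vapply(hset$members, paste,
                                             "", collapse = ","))
      utils::write.table(hap_tab, file.path(out, "haplotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$haplotypes <- list(n = hset$n, K = hset$K, S = ss$S,
                                 PI = ss$PI, n_ts = ss$n_ts, n_tv = ss$n_tv)

      stage <- "diversity"
      div <- diversity_by(aln, samples, by = config$by %||% "population")
      utils::write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      all_row <- div[div$stratum == "all", ]
      summary$diversity <- list(h = all_row$h, pi = all_row$pi,
                                D = all_row$D, Fs = all_row$Fs)

      stage <- "distances"
      d_ind <- distance_matrix(aln, model = model)
      write_labeled_matrix(d_ind, file.path(out, "distance_matrix.tsv"))
      d_hap <- distance_matrix(hset, model = model)
      if (hset$K >= 3) {
        tr <- nj_tree(d_hap, outgroup = config$outgroup)
        ape::write.tree(tr, file.path(out, "nj_tree.nwk"))
      }

      stage <- "popstruct"
      idx <- match(aln$ids, samples$sample_id)
      pop <- samples$population[idx]
      grp <- samples[[config$group_by %||% "group"]][idx]
      fst <- pairwise_fst(d_ind, pop, B = B, seed = config$seed)
      write_labeled_matrix(fst$fst, file.path(out, "pairwise_fst.tsv"))
      use_groups <- length(unique(grp)) > 1 &&
        length(unique(pop)) > length(unique(grp))
      am <- amova(d_ind, pop, group = if (use_groups) grp else NULL,
                  B = B, seed = config$seed,
                  square_distances = isTRUE(config$square_distances))
      utils::write.table(am$table, file.path(out, "amova.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$amova <- list(phi = as.list(am$phi), p = as.list(am$p))

      stage <- "mantel"
      if (all(c("lat", "lon") %in% names(samples)) &&
          !anyNA(samples$lat) && length(unique(pop)) >= 4) {
        km <- geo_distance(samples)
        km <- km[rownames(fst$fst), rownames(fst$fst)]
        write_merged_matrix(fst$fst, km, file.path(out, "fst_geo.tsv"))
        mt <- mantel_test(fst$fst, km, B = B, seed = config$seed)
        summary$mantel <- list(r = mt$r, R2 = mt$R2, p = mt$p)
      }

      stage <- "abgd"
      ab <- config$abgd %||% list()
      scan <- abgd_partition(d_hap, P_min = ab$pmin %||% 0.001,
                             P_max = ab$pmax %||% 0.1,
                             n_priors = ab$steps %||% 10,
                             X = ab$x %||% 1.5)
      part_tab <- do.call(rbind, lapply(scan, function(p)
        data.frame(P = p$P, n_groups = p$n_groups,
                   threshold = p$threshold)))
      utils::write.table(part_tab, file.path(out, "abgd_partitions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$abgd <- list(n_groups = part_tab$n_groups[1],
                           priors = part_tab$P)

      stage <- "network"
      if (hset$K >= 2 && hset$K <= 100) {
        net <- build_mjn(hset, epsilon = config$epsilon %||% 0,
                         tv_weight = config$tv_weight %||% 3)
        write_network(net, file.path(out, "network"))
        ann <- annotate_network(net, hset, samples)
        summary$network <- list(
          n_medians = sum(net$nodes$type == "median"),
          cost = net$cost, founder = ann$founder)
      }
    }
    summary
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  jsonlite::write_json(res, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logit("completed")
  invisible(res)
}
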