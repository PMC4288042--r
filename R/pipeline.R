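#' Build a pipeline configuration
#'
#' A single nested configuration drives [run_pipeline()]: per-stage
#' parameter blocks whose defaults mirror the documented module defaults,
#' stage toggles, and one global seed that feeds every random stage.
#'
#' @param seed Global seed (default 42).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "profile", "som", "bins", "curate", "stats",
#'   "abundance", "energetics")`. Later stages require their upstream
#'   stages.
#' @param community,profile,som,bins,curate,abundance,energetics Named
#'   lists overriding individual stage parameters (see the corresponding
#'   stage functions for meanings).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42,
                            stages = c("simulate", "profile", "som", "bins",
                                       "curate", "stats", "abundance",
                                       "energetics"),
                            community = list(), profile = list(),
                            som = list(), bins = list(), curate = list(),
                            abundance = list(), energetics = list()) {
  known <- c("simulate", "profile", "som", "bins", "curate", "stats",
             "abundance", "energetics")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  cfg <- list(
    seed = as.integer(seed),
    stages = stages,
    community = modifyList(list(models = NULL, mislabel_rate = 0.1,
                                min_length = 2500, total_reads = 5e6,
                                depth_sigma = 0.25), community),
    profile = modifyList(list(window = 5000, min_length = 2500,
                              collapse_rc = TRUE), profile),
    som = modifyList(list(rows = NULL, cols = NULL, epochs = 20,
                          rate_start = 0.5, rate_end = 0.05), som),
    bins = modifyList(list(quantile = 0.5, connectivity = 8), bins),
    curate = modifyList(list(target_taxon = "Epsilonproteobacteria",
                             rank = "class", threshold = 0.5,
                             gc_window = 0.05, cov_band = 3), curate),
    abundance = modifyList(list(rank = "class"), abundance),
    energetics = modifyList(list(pH = 7, temperature = 298.15), energetics)
  )
  structure(cfg, class = "pipeline_config")
}

output_header <- function(cfg) {
  sprintf("# magsom %s seed=%d params=%s",
          as.character(packageVersion("magsom")), cfg$seed,
          rlang::hash(unclass(cfg)))
}

write_stage_tsv <- function(df, path, cfg) {
  writeLines(output_header(cfg), path)
  suppressWarnings(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Run the binning and energetics pipeline
#'
#' Executes the requested stages in dependency order — simulate a
#' community, profile its contigs, train the map, extract and curate bins,
#' compute per-bin statistics and completeness, tabulate functional-gene
#' abundance — plus the (independent) sulfide-oxidation energetics table.
#' Every output file starts with a header line carrying the package
#' version, the seed and a digest of the full parameter set; a rerun with
#' an identical config writes byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param dir Run directory (created; existing files overwritten).
#' @return Invisibly, a list with the in-memory stage results and
#'   `summary` (also written to `summary.json`): per-bin statistics, ARI
#'   against ground truth, and file inventory.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("magsom_run_")) {
  stopifnot(is(config, "pipeline_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  on <- function(s) s %in% config$stages
  need <- function(s, what) if (is.null(what))
    abort(sprintf("stage '%s' requires an upstream stage that was not run", s))
  res <- list()
  summary <- list(seed = config$seed, stages = config$stages,
                  params_digest = rlang::hash(unclass(config)))
  log_msg <- function(...) message(sprintf("[magsom] %s", sprintf(...)))

  if (on("simulate")) {
    log_msg("simulate: seed %d", config$seed)
    models <- config$community$models
    if (is.null(models)) models <- community_default_models()
    res$sample <- simulate_community(
      models = models, seed = config$seed,
      mislabel_rate = config$community$mislabel_rate,
      min_length = config$community$min_length,
      total_reads = config$community$total_reads,
      depth_sigma = config$community$depth_sigma)
    write_community(res$sample, dir)
    summary$community <- as.list(glance(res$sample))
  }
  if (on("profile")) {
    need("profile", res$sample)
    log_msg("profile: window %d, floor %d", config$profile$window,
            config$profile$min_length)
    res$profiles <- tetra_profiles(
      res$sample$contigs, window = config$profile$window,
      min_length = config$profile$min_length,
      collapse_rc = config$profile$collapse_rc)
    write_stage_tsv(res$profiles, file.path(dir, "profiles.tsv"), config)
    summary$profile <- list(n_windows = nrow(res$profiles),
                            n_features = length(attr(res$profiles, "features")))
  }
  if (on("som")) {
    need("som", res$profiles)
    log_msg("som: training (%d epochs)", config$som$epochs)
    res$grid <- som_train(res$profiles, rows = config$som$rows,
                          cols = config$som$cols, epochs = config$som$epochs,
                          rate_start = config$som$rate_start,
                          rate_end = config$som$rate_end, seed = config$seed)
    write_som_weights(res$grid, file.path(dir, "som_weights.tsv"))
    write_umatrix(res$grid, file.path(dir, "umatrix.tsv"))
    summary$som <- as.list(glance(res$grid))
  }
  if (on("bins")) {
    need("bins", res$grid)
    res$bins <- som_bins(res$grid, res$profiles,
                         quantile = config$bins$quantile,
                         connectivity = config$bins$connectivity)
    write_bins(res$bins, file.path(dir, "bins.tsv"))
    summary$bins <- as.list(glance(res$bins))
    summary$bins$ari_vs_truth <- bin_ari(res$bins, res$sample$truth)
    log_msg("bins: %d bins, ARI vs truth %.3f", summary$bins$n_bins,
            summary$bins$ari_vs_truth)
  }
  if (on("curate")) {
    need("curate", res$bins)
    log_msg("curate: majority vote on %s, gc window %.2f, cov band %.1fx",
            config$curate$target_taxon, config$curate$gc_window,
            config$curate$cov_band)
    res$curation <- curate_bins(res$bins, res$sample,
                                target_taxon = config$curate$target_taxon,
                                rank = config$curate$rank,
                                threshold = config$curate$threshold,
                                gc_window = config$curate$gc_window,
                                cov_band = config$curate$cov_band)
    write_stage_tsv(res$curation, file.path(dir, "curation.tsv"), config)
  }
  if (on("stats")) {
    need("stats", res$curation)
    res$bin_stats <- pipeline_bin_stats(res$curation, res$sample)
    write_stage_tsv(res$bin_stats, file.path(dir, "bin_stats.tsv"), config)
    summary$bin_stats <- purrr::transpose(res$bin_stats)
  }
  if (on("abundance")) {
    need("abundance", res$sample)
    res$abundance <- abundance_table(res$sample$hits,
                                     total_reads = res$sample$total_reads,
                                     rank = config$abundance$rank)
    write_stage_tsv(res$abundance, file.path(dir, "abundance.tsv"), config)
    summary$abundance <- list(n_families = dplyr::n_distinct(res$abundance$gene_family))
  }
  if (on("energetics")) {
    res$energetics <- sulfide_oxidation_table(
      pH = config$energetics$pH, temperature = config$energetics$temperature)
    write_stage_tsv(res$energetics, file.path(dir, "energetics.tsv"), config)
    summary$energetics <- setNames(
      as.list(round(res$energetics$delta_g_prime, 1)), res$energetics$equation)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  res$dir <- dir
  invisible(res)
}

#' Curate extracted bins by taxonomy, GC and coverage
#'
#' Chains the two curation rules over every extracted bin: the per-scaffold
#' taxonomic majority vote (against `target_taxon` at `rank`) is applied to
#' bins whose member contigs' genes predominantly match the target taxon
#' (for other bins the vote is taken against the bin's own plurality
#' taxon), then the GC/coverage outlier filter.
#'
#' @param bins A [som_bins()] result.
#' @param sample The `community_sample` the bins came from (supplies gene
#'   calls, GC and depth).
#' @param target_taxon,rank,threshold See [majority_vote_filter()]. The
#'   vote target for each bin is its own plurality gene taxon (so curation
#'   works for every bin, not just the focal taxon); `target_taxon` is kept
#'   as the fallback for bins without genes.
#' @param gc_window,cov_band See [gc_coverage_filter()].
#' @return Tibble, one row per (bin, contig): vote and outlier columns plus
#'   the final `retained` flag and `reason`.
#' @export
curate_bins <- function(bins, sample, target_taxon = "Epsilonproteobacteria",
                        rank = "class", threshold = 0.5, gc_window = 0.05,
                        cov_band = 3) {
  col <- paste0("best_hit_taxon_", rank)
  contig_info <- sample$contigs %>%
    mutate(gc = gc_content(.data$sequence)) %>%
    select("contig_id", "gc", "depth")
  assigned <- filter(bins$contigs, !is.na(.data$bin_id))
  purrr::map_dfr(split(assigned$contig_id, assigned$bin_id), function(ids) {
    genes <- filter(sample$gene_calls, .data$contig_id %in% ids)
    bin_taxon <- if (nrow(genes) > 0) {
      names(sort(table(genes[[col]]), decreasing = TRUE))[1]
    } else {
      target_taxon
    }
    vote <- majority_vote_filter(ids, sample$gene_calls, bin_taxon,
                                 rank = rank, threshold = threshold)
    surv <- vote$contig_id[vote$retained]
    gcf <- contig_info %>% filter(.data$contig_id %in% surv)
    gcf <- gc_coverage_filter(gcf, gc_window = gc_window, cov_band = cov_band)
    vote %>%
      mutate(vote_taxon = bin_taxon) %>%
      left_join(select(gcf, "contig_id", gc_cov_retained = "retained",
                       gc_cov_reason = "reason"),
                by = "contig_id") %>%
      mutate(
        gc_cov_retained = dplyr::coalesce(.data$gc_cov_retained, FALSE),
        reason = dplyr::case_when(
          !retained ~ if_else(.data$flag == "no_genes", "no_genes", "taxon_vote"),
          !gc_cov_retained & gc_cov_reason != "" ~ gc_cov_reason,
          TRUE ~ ""),
        retained = .data$retained & .data$gc_cov_retained) %>%
      select(-"gc_cov_retained", -"gc_cov_reason")
  }, .id = "bin_id")
}

#' Per-bin assembly statistics and completeness after curation
#'
#' @param curation Output of [curate_bins()].
#' @param sample The originating `community_sample`.
#' @param marker_set Marker identifiers (default [marker_set_default()]).
#' @return Tibble, one row per bin, with [assembly_stats()] columns plus
#'   [completeness()] columns.
#' @export
pipeline_bin_stats <- function(curation, sample,
                               marker_set = marker_set_default()) {
  kept <- filter(curation, .data$retained)
  purrr::map_dfr(split(kept$contig_id, kept$bin_id), function(ids) {
    ctg <- filter(sample$contigs, .data$contig_id %in% ids)
    genes <- filter(sample$gene_calls, .data$contig_id %in% ids)
    dplyr::bind_cols(assembly_stats(ctg, genes),
                     completeness(genes, marker_set))
  }, .id = "bin_id")
}
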