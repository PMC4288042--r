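#' Taxonomic majority-vote scaffold filter
#'
#' Retains a contig in a genome bin only if strictly more than `threshold`
#' of its predicted genes have best hits to the target taxon: with the
#' default threshold of 0.5, "greater than 50% of the genes on the
#' scaffold". The inequality is strict, so exactly half does not qualify.
#' Contigs carrying no genes cannot be voted on and are dropped with a
#' `no_genes` flag.
#'
#' @param contig_ids Character vector of contig ids forming the bin.
#' @param gene_calls Tibble of gene calls with columns `contig_id` and the
#'   taxon column for the chosen rank (`best_hit_taxon_class` or
#'   `best_hit_taxon_genus`).
#' @param target_taxon Taxon name genes must match (e.g.
#'   "Epsilonproteobacteria").
#' @param rank `"class"` or `"genus"`.
#' @param threshold Vote fraction that must be strictly exceeded
#'   (default 0.5).
#' @return Tibble with one row per input contig: `contig_id`, `n_genes`,
#'   `n_match`, `frac_match`, `retained`, `flag` (`""` or `"no_genes"`).
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   contig_id = c(rep("c1", 5), rep("c2", 4)),
#'   best_hit_taxon_class = c(rep("Epsilonproteobacteria", 3), "Other", "Other",
#'                            rep("Epsilonproteobacteria", 2), "Other", "Other"))
#' majority_vote_filter(c("c1", "c2"), genes, "Epsilonproteobacteria")
majority_vote_filter <- function(contig_ids, gene_calls, target_taxon,
                                 rank = c("class", "genus"), threshold = 0.5) {
  rank <- match.arg(rank)
  col <- paste0("best_hit_taxon_", rank)
  if (!col %in% names(gene_calls)) {
    abort(paste0("gene_calls lacks column ", col))
  }
  votes <- gene_calls %>%
    filter(.data$contig_id %in% contig_ids) %>%
    group_by(.data$contig_id) %>%
    summarise(n_genes = dplyr::n(),
              n_match = sum(.data[[col]] == target_taxon),
              .groups = "drop")
  out <- tibble(contig_id = contig_ids) %>%
    left_join(votes, by = "contig_id") %>%
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L),
           n_match = dplyr::coalesce(.data$n_match, 0L),
           frac_match = if_else(.data$n_genes > 0,
                                .data$n_match / .data$n_genes, NA_real_),
           retained = .data$n_genes > 0 &
             .data$n_match / pmax(.data$n_genes, 1L) > threshold,
           flag = if_else(.data$n_genes == 0, "no_genes", ""))
  out
}

#' GC / coverage outlier filter for a genome bin
#'
#' Curates a bin by composition and depth: a contig is retained iff its GC
#' lies within `gc_window` (absolute half-width, GC-fraction units) of the
#' bin median GC AND its depth lies within a multiplicative band
#' \[median / cov_band, median * cov_band\]. Medians are computed on the
#' incoming bin. Bins of fewer than 3 contigs carry no usable median and
#' pass through unfiltered with a warning.
#'
#' @param bin Tibble with columns `contig_id`, `gc` (fraction) and `depth`.
#' @param gc_window Absolute GC half-width (default 0.05, i.e. 5 percentage
#'   points).
#' @param cov_band Multiplicative depth band (default 3).
#' @return The input tibble with added columns `retained` and `reason`
#'   (`""`, `"gc_outlier"`, `"coverage_outlier"` or both comma-joined).
#' @export
gc_coverage_filter <- function(bin, gc_window = 0.05, cov_band = 3) {
  stopifnot(all(c("contig_id", "gc", "depth") %in% names(bin)),
            gc_window > 0, cov_band >= 1)
  if (nrow(bin) < 3) {
    warn("bin has fewer than 3 contigs; GC/coverage filter is a no-op")
    return(mutate(bin, retained = TRUE, reason = ""))
  }
  med_gc <- median(bin$gc)
  med_depth <- median(bin$depth)
  bin %>%
    mutate(
      gc_ok = abs(.data$gc - med_gc) <= gc_window,
      cov_ok = .data$depth >= med_depth / cov_band &
        .data$depth <= med_depth * cov_band,
      retained = .data$gc_ok & .data$cov_ok,
      reason = paste0(if_else(.data$gc_ok, "", "gc_outlier"),
                      if_else(!.data$gc_ok & !.data$cov_ok, ",", ""),
                      if_else(.data$cov_ok, "", "coverage_outlier"))
    ) %>%
    select(-"gc_ok", -"cov_ok")
}

#' N50 of a set of contig lengths
#'
#' The length of the shortest contig in the minimal descending-sorted
#' prefix whose cumulative length reaches half the total assembly size.
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return N50 in bases.
#' @export
#' @examples
#' n50(c(10, 8, 6, 4, 2))  # 8
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly statistics of a genome bin
#'
#' @param contigs Tibble with `contig_id` and either `sequence` (GC computed
#'   from the bases) or a precomputed `gc` column plus a `length` column.
#' @param gene_calls Optional gene-call tibble; genes on the bin's contigs
#'   are counted.
#' @return One-row tibble: `total_bp`, `n_scaffolds`, `longest`, `n50`,
#'   `gc_percent` (length-weighted), `n_genes` (`NA` when no gene calls are
#'   given).
#' @export
assembly_stats <- function(contigs, gene_calls = NULL) {
  stopifnot(is.data.frame(contigs))
  if (nrow(contigs) == 0) {
    abort("assembly_stats needs a non-empty contig set")
  }
  if ("sequence" %in% names(contigs)) {
    len <- nchar(contigs$sequence)
    gc <- gc_content(contigs$sequence)
  } else {
    stopifnot(all(c("length", "gc") %in% names(contigs)))
    len <- contigs$length
    gc <- contigs$gc
  }
  n_genes <- if (is.null(gene_calls)) NA_integer_ else
    sum(gene_calls$contig_id %in% contigs$contig_id)
  tibble(
    total_bp = sum(len),
    n_scaffolds = nrow(contigs),
    longest = max(len),
    n50 = n50(len),
    gc_percent = 100 * sum(gc * len, na.rm = TRUE) / sum(len[!is.na(gc)]),
    n_genes = n_genes
  )
}

#' Marker-based genome completeness
#'
#' Completeness is the percentage of a reference single-copy marker set
#' observed at least once among a bin's gene calls; markers seen more than
#' once are tallied as duplicates but never raise completeness.
#'
#' @param gene_calls Tibble with an `is_marker` column (marker identifier,
#'   `NA` for non-marker genes).
#' @param marker_set Character vector of expected marker identifiers
#'   (default [marker_set_default()], 19 universal ribosomal proteins).
#' @return One-row tibble: `completeness_percent`, `n_markers_found`,
#'   `duplicated_markers` (total surplus copies).
#' @export
#' @examples
#' calls <- tibble::tibble(is_marker = c("rpL2", "rpL2", "rpS3", NA))
#' completeness(calls, c("rpL2", "rpS3", "rpS7"))
completeness <- function(gene_calls, marker_set = marker_set_default()) {
  stopifnot(length(marker_set) > 0)
  found <- gene_calls$is_marker[!is.na(gene_calls$is_marker)]
  found <- found[found %in% marker_set]
  counts <- table(found)
  tibble(
    completeness_percent = 100 * length(counts) / length(unique(marker_set)),
    n_markers_found = length(counts),
    duplicated_markers = sum(pmax(as.integer(counts) - 1L, 0L))
  )
}

#' Default single-copy marker set
#'
#' Nineteen universal ribosomal proteins widely used for concatenated
#' phylogenies and completeness estimation of draft genomes. The marker set
#' is an input everywhere it is consumed; this default only fixes the set
#' size and membership for the synthetic fixtures.
#'
#' @return Character vector of 19 marker identifiers.
#' @export
marker_set_default <- function() {
  c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15", "rpL16",
    "rpL18", "rpL22", "rpL24", "rpS3", "rpS7", "rpS8", "rpS10", "rpS11",
    "rpS12", "rpS17", "rpS19")
}

#' Select the best reassembly among candidates
#'
#' Candidates are ranked on three criteria — longest contig (descending),
#' N50 (descending) and number of scaffolds (ascending) — and the candidate
#' with the minimal rank-sum wins ("longest contigs, highest N50, lowest
#' number of contigs"). Rank-sum ties are broken by the higher N50, then by
#' input order.
#'
#' @param candidates Tibble with columns `longest`, `n50`, `n_scaffolds`
#'   (one row per candidate assembly).
#' @return Integer index of the selected candidate.
#' @export
#' @examples
#' select_best_assembly(tibble::tibble(
#'   longest = c(400e3, 300e3), n50 = c(70e3, 50e3), n_scaffolds = c(68, 120)))
select_best_assembly <- function(candidates) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1,
            all(c("longest", "n50", "n_scaffolds") %in% names(candidates)))
  if (nrow(candidates) == 1) {
    return(1L)
  }
  rs <- rank(-candidates$longest) + rank(-candidates$n50) +
    rank(candidates$n_scaffolds)
  best <- which(rs == min(rs))
  if (length(best) > 1) {
    best <- best[order(-candidates$n50[best])]
  }
  as.integer(best[1])
}
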