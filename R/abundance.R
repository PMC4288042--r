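#' Threshold filter for functional-gene best hits
#'
#' Applies the functional-gene quantification profile: keep a hit iff
#' e-value <= 1e-4 AND query coverage strictly greater than 0.70 AND bit
#' score strictly greater than 100. Coverage of exactly 70% or a bit score
#' of exactly 100 is dropped. The filter is idempotent and order-invariant.
#'
#' @param hits Tibble with columns `evalue`, `query_coverage` (fraction in
#'   \[0, 1\]) and `bit_score`.
#' @param max_evalue,min_coverage,min_bit_score Threshold values; coverage
#'   and bit score are strict inequalities, the e-value is inclusive.
#' @return The surviving rows, order preserved.
#' @export
filter_hits_functional <- function(hits, max_evalue = 1e-4,
                                   min_coverage = 0.70, min_bit_score = 100) {
  stopifnot(all(c("evalue", "query_coverage", "bit_score") %in% names(hits)))
  hits %>%
    filter(.data$evalue <= max_evalue,
           .data$query_coverage > min_coverage,
           .data$bit_score > min_bit_score)
}

#' Class-level taxonomy assignment from best hits
#'
#' The whole-metagenome assignment profile: a record is assigned the class
#' of its best hit iff e-value < 1e-4 (strict) AND query coverage >= 0.75
#' (inclusive, "at least 75%"); otherwise it is labelled "unassigned". Note
#' the thresholds deliberately differ from [filter_hits_functional()]; both
#' profiles are kept as stated rather than unified.
#'
#' @param hits Tibble with columns `evalue`, `query_coverage`,
#'   `subject_taxon_class`.
#' @param max_evalue,min_coverage Thresholds (e-value strict, coverage
#'   inclusive).
#' @return The input with an added `taxon_class_assigned` column.
#' @export
assign_taxonomy_class <- function(hits, max_evalue = 1e-4, min_coverage = 0.75) {
  stopifnot(all(c("evalue", "query_coverage", "subject_taxon_class") %in% names(hits)))
  hits %>%
    mutate(taxon_class_assigned = if_else(
      .data$evalue < max_evalue & .data$query_coverage >= min_coverage,
      .data$subject_taxon_class, "unassigned"))
}

#' Length- and library-size-normalized gene abundance
#'
#' Hits per kilobase of gene per million reads:
#' `raw_count / ((gene_length/1000) * (total_reads/1e6))`. Linear in the
#' raw count; halves when the library size doubles.
#'
#' @param raw_count Non-negative hit counts (vectorised).
#' @param gene_length Gene length in bases (> 0).
#' @param total_reads Total reads in the dataset (> 0).
#' @return Normalized abundance (numeric).
#' @export
#' @examples
#' normalize_abundance(10, 2000, 5e6)  # 1.0
normalize_abundance <- function(raw_count, gene_length, total_reads) {
  if (any(gene_length <= 0)) abort("gene_length must be positive")
  if (any(total_reads <= 0)) abort("total_reads must be positive")
  if (any(raw_count < 0)) abort("raw_count must be non-negative")
  raw_count / ((gene_length / 1000) * (total_reads / 1e6))
}

#' Per-family, per-taxon abundance table
#'
#' Filters hits with [filter_hits_functional()], then tallies surviving
#' records by gene family and best-hit taxon and normalizes counts to the
#' family's mean gene length and the library size.
#'
#' @param hits Tibble of hit records with columns `gene_family`,
#'   `gene_length`, the threshold columns, and the taxon column selected by
#'   `rank`.
#' @param total_reads Library size (reads).
#' @param rank `"class"` or `"genus"` — which subject-taxon column to group
#'   by.
#' @return Tidy tibble: `gene_family`, `taxon_group`, `raw_count`,
#'   `normalized_abundance`.
#' @export
abundance_table <- function(hits, total_reads, rank = c("class", "genus")) {
  rank <- match.arg(rank)
  col <- paste0("subject_taxon_", rank)
  stopifnot(col %in% names(hits), total_reads > 0)
  filter_hits_functional(hits) %>%
    group_by(gene_family = .data$gene_family, taxon_group = .data[[col]]) %>%
    summarise(raw_count = dplyr::n(),
              mean_gene_length = mean(.data$gene_length),
              .groups = "drop") %>%
    mutate(normalized_abundance = normalize_abundance(
      .data$raw_count, .data$mean_gene_length, total_reads)) %>%
    select("gene_family", "taxon_group", "raw_count", "normalized_abundance")
}

#' Abundance floor for reconstructed 16S sequences
#'
#' Removes entries with an estimated relative abundance strictly below
#' 0.01% (0.0001 as a fraction); an entry exactly at the floor is retained.
#' Remaining abundances are left unchanged by default — the analysis
#' proceeds on the filtered, unrenormalized values — with renormalization
#' available behind a flag.
#'
#' @param otu_table Tibble with columns `otu_id` and `abundance` (fractions,
#'   need not sum to 1).
#' @param floor Minimum abundance retained (default 1e-4 = 0.01%).
#' @param renormalize Rescale surviving abundances to sum to 1?
#' @return Filtered tibble.
#' @export
#' @examples
#' abundance_floor_16s(tibble::tibble(otu_id = c("a", "b"),
#'                                    abundance = c(0.5, 0.00009)))
abundance_floor_16s <- function(otu_table, floor = 1e-4, renormalize = FALSE) {
  stopifnot(all(c("otu_id", "abundance") %in% names(otu_table)),
            all(otu_table$abundance >= 0))
  out <- filter(otu_table, .data$abundance >= floor)
  if (renormalize && nrow(out) > 0 && sum(out$abundance) > 0) {
    out <- mutate(out, abundance = .data$abundance / sum(.data$abundance))
  }
  out
}

#' Reduce a hit table to best hits per query
#'
#' One record per query: highest bit score, ties broken by lower e-value,
#' then by input order.
#'
#' @param hits Tibble with `query_id`, `bit_score`, `evalue`.
#' @return Tibble of best hits, one row per query, in first-appearance order.
#' @export
best_hits <- function(hits) {
  stopifnot(all(c("query_id", "bit_score", "evalue") %in% names(hits)))
  hits %>%
    mutate(.ord = row_number()) %>%
    group_by(.data$query_id) %>%
    arrange(desc(.data$bit_score), .data$evalue, .data$.ord, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$.ord) %>%
    select(-".ord")
}

#' Read/write BLAST-style tabular hit files
#'
#' Twelve-column BLAST tabular layout (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) with two
#' appended taxon columns and the query-coverage fraction and gene length
#' used by the abundance machinery.
#'
#' @param hits Hit tibble as produced by [simulate_hit_table()].
#' @param path File path.
#' @return `read_hit_table()`: a tibble; `write_hit_table()`: the path,
#'   invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}
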