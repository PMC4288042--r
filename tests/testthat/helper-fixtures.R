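# Fixtures shared across test files; the expensive ones are computed once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default 5-genome community (seed 42) with profiles and a trained map
default_fixture <- function() {
  cached("default_fixture", {
    sample <- simulate_community(seed = 42)
    profiles <- tetra_profiles(sample$contigs)
    grid <- som_train(profiles, seed = 42)
    list(sample = sample, profiles = profiles, grid = grid)
  })
}

# a small, fast two-genome community for unit tests
small_community <- function(seed = 7) {
  cached(paste0("small_community_", seed), {
    models <- list(
      genome_model("epsA", "Epsilonproteobacteria", "Sulfurovum", 0.35,
                   80000, abundance = 6),
      genome_model("gamA", "Gammaproteobacteria", "Thiothrix", 0.60,
                   80000, abundance = 2))
    simulate_community(models, seed = seed)
  })
}

# native + contaminant bin for the curation-chain fixture: contaminants are
# ~10% of the bin bp at +0.15 GC and 4x depth
contaminated_bin <- function(seed) {
  nat <- genome_model("native", "Epsilonproteobacteria", "Sulfurovum", 0.40,
                      120000, abundance = 2)
  con <- genome_model("foreign", "Gammaproteobacteria", "Beggiatoa", 0.55,
                      60000, abundance = 8)
  gn <- simulate_genome(nat, seed = seed)
  gf <- simulate_genome(con, seed = seed + 500)
  cn <- fragment_genome(gn$sequence, "native", abundance = 2, seed = seed + 1)
  cf <- fragment_genome(gf$sequence, "foreign", abundance = 8, seed = seed + 2)
  cf <- cf[cumsum(cf$length) <= 0.111 * sum(cn$length), ]
  hits <- dplyr::bind_rows(
    simulate_hit_table(gn$genes, 0.1, seed = seed + 3),
    simulate_hit_table(gf$genes, 0.1, seed = seed + 4))
  genes <- dplyr::bind_rows(
    magsom:::lift_genes_to_contigs(gn$genes, cn),
    magsom:::lift_genes_to_contigs(gf$genes, cf)) |>
    dplyr::left_join(dplyr::select(hits, query_id, subject_taxon_class),
                     by = c(gene_id = "query_id")) |>
    dplyr::rename(best_hit_taxon_class = subject_taxon_class)
  list(native = cn, foreign = cf, contigs = dplyr::bind_rows(cn, cf),
       genes = genes)
}

# majority vote -> GC/coverage chain on a contaminated bin; returns bp
# fractions removed/lost
curation_chain_metrics <- function(seed) {
  fx <- contaminated_bin(seed)
  vote <- majority_vote_filter(fx$contigs$contig_id, fx$genes,
                               "Epsilonproteobacteria", rank = "class")
  surv <- dplyr::filter(fx$contigs, contig_id %in% vote$contig_id[vote$retained])
  surv$gc <- gc_content(surv$sequence)
  gcf <- gc_coverage_filter(dplyr::select(surv, contig_id, gc, depth))
  kept <- gcf$contig_id[gcf$retained]
  c(contaminant_removed =
      1 - sum(fx$foreign$length[fx$foreign$contig_id %in% kept]) /
        sum(fx$foreign$length),
    native_lost =
      1 - sum(fx$native$length[fx$native$contig_id %in% kept]) /
        sum(fx$native$length))
}

# gene-call table shaped like simulate_genome() output, for hit-table tests
fake_gene_calls <- function(n, taxon_class = "Epsilonproteobacteria",
                            taxon_genus = "Sulfurovum") {
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    start = seq(1L, by = 1000L, length.out = n),
    end = seq(900L, by = 1000L, length.out = n),
    function_label = "sqr",
    true_taxon_class = taxon_class,
    true_taxon_genus = taxon_genus)
}
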