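test_that("genome model invariants are enforced", {
  expect_error(genome_model("g", "C", "G", gc_target = 0.15,
                            genome_length = 1e5), "gc_target")
  expect_error(genome_model("g", "C", "G", gc_target = 0.4,
                            genome_length = 10000), "genome_length")
  expect_error(genome_model("g", "C", "G", 0.4, 1e5, gene_density = 0),
               "gene_density")
  expect_error(genome_model("g", "C", "G", 0.4, 1e5, abundance = -1),
               "abundance")
  expect_error(genome_model("g", "C", "G", 0.4, 1e5,
                            marker_set = character(0)), "marker_set")
})

test_that("genome simulation is deterministic and respects its model", {
  m <- genome_model("g1", "Epsilonproteobacteria", "Sulfurovum", 0.35, 100000)
  a <- simulate_genome(m, seed = 3)
  b <- simulate_genome(m, seed = 3)
  expect_identical(a, b)                       # byte-identical under one seed
  c <- simulate_genome(m, seed = 4)
  expect_false(identical(a$sequence, c$sequence))
  expect_equal(nchar(a$sequence), 100000)
  # ~gene_density genes/kb: 100 +- 10 at 1/kb over 100 kb
  expect_gte(nrow(a$genes), 90)
  expect_lte(nrow(a$genes), 110)
  # genes tile without overlap, inside the genome
  expect_true(all(a$genes$start <= a$genes$end))
  expect_true(all(a$genes$end <= 100000))
  expect_true(all(diff(a$genes$start) > 0))
  expect_true(all(a$genes$start[-1] > a$genes$end[-nrow(a$genes)]))
  # every marker placed exactly once
  placed <- a$genes$is_marker[!is.na(a$genes$is_marker)]
  expect_setequal(placed, m$marker_set)
  expect_equal(anyDuplicated(placed), 0)
})

test_that("realized GC approaches the target as genomes grow", {
  m6 <- genome_model("g", "C", "G", 0.35, 1e6)
  g6 <- simulate_genome(m6, seed = 2)
  expect_lt(abs(gc_content(g6$sequence) - 0.35), 0.02)
  errs <- sapply(c(5e4, 2.5e5, 1e6), function(L) {
    mean(sapply(1:3, function(s) {
      m <- genome_model("g", "C", "G", 0.42, L)
      abs(gc_content(simulate_genome(m, seed = s)$sequence) - 0.42)
    }))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("fragmentation tiles, respects the floor, and models depth noise", {
  seqc <- strrep("ACGT", 2500)   # 10 kb
  # fixed fragment length 2500: exact tiling into 4 contigs
  f <- fragment_genome(seqc, "g", meanlog = log(2500), sdlog = 0,
                       min_length = 2500, seed = 1)
  expect_equal(nrow(f), 4)
  expect_equal(f$length, rep(2500L, 4))
  expect_equal(paste(f$sequence, collapse = ""), seqc)
  # zero depth noise: identical depths equal to the abundance
  f0 <- fragment_genome(seqc, "g", meanlog = log(2500), sdlog = 0,
                        abundance = 4.2, depth_sigma = 0, seed = 1)
  expect_equal(f0$depth, rep(4.2, 4))
  # impossible floor: empty result with a warning
  expect_warning(
    none <- fragment_genome(strrep("ACGT", 200), "g", meanlog = log(100),
                            sdlog = 0, min_length = 5000, seed = 1),
    "no contig")
  expect_equal(nrow(none), 0)
})

test_that("fragments never overlap nor exceed the genome over many seeds", {
  seqc <- strrep("ACGTA", 2000)  # 10 kb
  for (s in 1:100) {
    f <- fragment_genome(seqc, "g", meanlog = log(1500), sdlog = 0.6,
                         min_length = 500, seed = s)
    expect_lte(sum(f$length), nchar(seqc))
    if (nrow(f) > 1) {
      expect_true(all(f$offset[-1] >= (f$offset + f$length)[-nrow(f)]))
    }
    expect_true(all(f$length >= 500))
    expect_true(all(f$depth > 0))
  }
})

test_that("hit tables respect the mislabeling rate", {
  gc0 <- fake_gene_calls(10000)
  ht <- simulate_hit_table(gc0, mislabel_rate = 0.2, seed = 8)
  frac <- mean(ht$subject_taxon_genus != "Sulfurovum")
  expect_lt(abs(frac - 0.2), 0.012)  # 3x binomial SE at n = 10,000
  expect_equal(frac, mean(ht$mislabeled))
  # rate zero: labels all true
  ht0 <- simulate_hit_table(fake_gene_calls(200), mislabel_rate = 0, seed = 8)
  expect_true(all(ht0$subject_taxon_genus == "Sulfurovum"))
  # empty input -> empty table
  expect_equal(nrow(simulate_hit_table(fake_gene_calls(0))), 0)
  expect_error(simulate_hit_table(gc0, mislabel_rate = 1), "mislabel_rate")
  # scores populated from the generators
  expect_true(all(ht$evalue > 0 & ht$evalue < 1))
  expect_true(all(ht$query_coverage >= 0 & ht$query_coverage <= 1))
  expect_true(all(ht$bit_score > 0))
})

test_that("community samples are reproducible with total ground truth", {
  s1 <- small_community()
  s2 <- simulate_community(s1$models, seed = s1$seed)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$gene_calls, s2$gene_calls)
  gt <- ground_truth(s1)
  expect_equal(nrow(gt), nrow(s1$contigs))
  expect_setequal(gt$contig_id, s1$contigs$contig_id)
  expect_equal(anyDuplicated(gt$contig_id), 0)
  expect_true(all(s1$contigs$depth > 0))
  # single-genome community: every contig maps to that genome
  solo <- simulate_community(list(genome_model(
    "only", "Epsilonproteobacteria", "Sulfurovum", 0.4, 60000)), seed = 3)
  expect_true(all(ground_truth(solo)$genome_id == "only"))
})

test_that("between-genome 4-mer distance exceeds within-genome distance", {
  s <- small_community()
  p <- tetra_profiles(s$contigs)
  m <- profile_matrix(p)
  genome <- s$truth$genome_id[match(p$contig_id, s$truth$contig_id)]
  d <- as.matrix(dist(m))
  same <- outer(genome, genome, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
})

test_that("community files round-trip through FASTA/GFF3/TSV", {
  s <- small_community()
  dir <- withr::local_tempdir()
  write_community(s, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fasta"))
  expect_equal(length(fa), nrow(s$contigs))
  expect_identical(unname(as.character(fa)), s$contigs$sequence)
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(as.data.frame(truth), as.data.frame(s$truth))
  gff <- read_gene_calls_gff3(file.path(dir, "gene_calls.gff3"))
  expect_equal(nrow(gff), nrow(s$gene_calls))
  expect_equal(gff$contig_id, s$gene_calls$contig_id)
  expect_equal(gff$start, s$gene_calls$start)
  expect_equal(gff$end, s$gene_calls$end)
  expect_equal(gff$best_hit_taxon_class, s$gene_calls$best_hit_taxon_class)
  expect_equal(gff$is_marker, s$gene_calls$is_marker)
  expect_equal(gff$query_coverage, s$gene_calls$query_coverage,
               tolerance = 1e-3)
})
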