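test_that("majority vote is strict and reports geneless contigs", {
  genes <- tibble::tibble(
    contig_id = c(rep("keep", 5), rep("drop", 4)),
    best_hit_taxon_class = c(rep("Epsilonproteobacteria", 3), "X", "Y",
                             rep("Epsilonproteobacteria", 2), "X", "Y"))
  v <- majority_vote_filter(c("keep", "drop", "empty"), genes,
                            "Epsilonproteobacteria")
  expect_true(v$retained[v$contig_id == "keep"])    # 3/5 = 0.6 > 0.5
  expect_false(v$retained[v$contig_id == "drop"])   # 2/4 = 0.5, not strict
  expect_false(v$retained[v$contig_id == "empty"])
  expect_equal(v$flag[v$contig_id == "empty"], "no_genes")
  expect_error(majority_vote_filter("c", genes, "X", rank = "kingdom"))
})

test_that("majority vote is monotone in matching genes", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    hits <- sample(c("T", "F"), n, replace = TRUE)
    genes <- tibble::tibble(contig_id = "c",
                            best_hit_taxon_class = hits)
    before <- majority_vote_filter("c", genes, "T")$retained
    genes2 <- dplyr::bind_rows(
      genes, tibble::tibble(contig_id = "c", best_hit_taxon_class = "T"))
    after <- majority_vote_filter("c", genes2, "T")$retained
    expect_true(!before || after)  # adding a matching gene never removes
  }
})

test_that("GC/coverage filter removes constructed outliers only", {
  bin <- tibble::tibble(
    contig_id = sprintf("c%d", 1:10),
    gc = c(rep(0.35, 9), 0.65),
    depth = c(rep(10, 9), 10))
  f <- gc_coverage_filter(bin, gc_window = 0.05)
  expect_false(f$retained[10])
  expect_equal(f$reason[10], "gc_outlier")
  expect_true(all(f$retained[1:9]))
  # identical contigs: nothing removed
  same <- tibble::tibble(contig_id = c("a", "b", "c"), gc = 0.4, depth = 5)
  expect_true(all(gc_coverage_filter(same)$retained))
  # coverage band is multiplicative around the median
  cov <- tibble::tibble(contig_id = sprintf("c%d", 1:5), gc = 0.4,
                        depth = c(10, 10, 10, 35, 2))
  fc <- gc_coverage_filter(cov)
  expect_equal(fc$retained, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(fc$reason[4], "coverage_outlier")
  # tiny bins pass through with a warning
  expect_warning(tiny <- gc_coverage_filter(same[1:2, ]), "no-op")
  expect_true(all(tiny$retained))
})

test_that("assembly statistics match the worked N50 example and the oracle", {
  st <- assembly_stats(tibble::tibble(
    contig_id = letters[1:5], length = c(10, 8, 6, 4, 2), gc = 0.5))
  expect_equal(st$total_bp, 30)
  expect_equal(st$n50, 8)  # cumulative 10, 18 >= 15
  expect_equal(st$longest, 10)
  single <- assembly_stats(tibble::tibble(contig_id = "s", length = 437665,
                                          gc = 0.4))
  expect_equal(single$longest, 437665)
  expect_equal(single$n50, 437665)
  expect_equal(single$total_bp, 437665)
  expect_error(assembly_stats(tibble::tibble(contig_id = character(0))))
  set.seed(9)
  for (i in 1:50) {
    lens <- sample(1:5e4, sample(1:60, 1), replace = TRUE)
    expect_equal(n50(lens), naive_n50(lens))
  }
})

test_that("assembly stats satisfy n50 <= longest <= total and count genes", {
  set.seed(12)
  for (i in 1:30) {
    lens <- sample(100:9999, sample(1:40, 1), replace = TRUE)
    st <- assembly_stats(tibble::tibble(
      contig_id = as.character(seq_along(lens)), length = lens, gc = 0.5))
    expect_lte(st$n50, st$longest)
    expect_lte(st$longest, st$total_bp)
  }
  ctg <- tibble::tibble(contig_id = c("a", "b"), sequence = c("GGCCGG", "ATATAT"))
  genes <- tibble::tibble(contig_id = c("a", "a", "z"))
  st <- assembly_stats(ctg, genes)
  expect_equal(st$n_genes, 2)
  expect_equal(st$gc_percent, 50)
})

test_that("completeness is the distinct-marker fraction, duplicates never help", {
  ms <- marker_set_default()
  expect_length(ms, 19)
  all19 <- tibble::tibble(is_marker = ms)
  expect_equal(completeness(all19, ms)$completeness_percent, 100)
  m18 <- tibble::tibble(is_marker = ms[1:18])
  expect_equal(round(completeness(m18, ms)$completeness_percent, 1), 94.7)
  dup <- tibble::tibble(is_marker = c(ms[1:18], ms[1], ms[1], NA))
  cd <- completeness(dup, ms)
  expect_equal(round(cd$completeness_percent, 1), 94.7)
  expect_equal(cd$duplicated_markers, 2)
  # invariant under gene order
  shuf <- dup[sample(nrow(dup)), , drop = FALSE]
  expect_equal(completeness(shuf, ms), cd)
  # markers outside the reference set don't count
  alien <- tibble::tibble(is_marker = c("weird1", ms[1]))
  expect_equal(completeness(alien, ms)$n_markers_found, 1)
})

test_that("reassembly selection ranks longest/N50/scaffold-count", {
  one <- tibble::tibble(longest = 1e5, n50 = 2e4, n_scaffolds = 50)
  expect_equal(select_best_assembly(one), 1L)
  # dominance: A wins all three criteria
  ab <- tibble::tibble(longest = c(4e5, 3e5), n50 = c(7e4, 5e4),
                       n_scaffolds = c(68, 120))
  expect_equal(select_best_assembly(ab), 1L)
  # A wins longest; B wins N50 and scaffold count -> B by rank-sum 4 vs 5
  ab2 <- tibble::tibble(longest = c(4e5, 3e5), n50 = c(5e4, 7e4),
                        n_scaffolds = c(120, 68))
  expect_equal(select_best_assembly(ab2), 2L)
  # equal rank-sums (scaffold count tied) break by higher N50
  tie <- tibble::tibble(longest = c(4e5, 3e5), n50 = c(5e4, 7e4),
                        n_scaffolds = c(100, 100))
  expect_equal(select_best_assembly(tie), 2L)
})
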