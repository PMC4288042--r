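#' Specify a synthetic genome
#'
#' A genome model for the community simulator: an order-`markov_order`
#' Markov composition model tilted toward a target GC and perturbed
#' per-genome so that each genome carries a distinctive tetranucleotide
#' signature (the statistical structure composition-based binning relies
#' on), plus gene-density, marker and abundance settings.
#'
#' @param genome_id Genome identifier.
#' @param taxon_class,taxon_genus Taxon labels attached to the genome's
#'   genes (e.g. "Epsilonproteobacteria" / "Sulfurovum").
#' @param gc_target Target GC fraction, strictly between 0.2 and 0.8.
#' @param genome_length Genome length in bases (>= 50,000).
#' @param markov_order Order of the composition Markov chain (default 2).
#' @param composition_seedling Scale of the per-genome lognormal
#'   perturbation of transition probabilities (default 0.15); larger values
#'   give more distinctive 4-mer signatures.
#' @param gene_density Genes per kilobase (default 1).
#' @param marker_set Marker identifiers placed once each on the genome
#'   (default [marker_set_default()]).
#' @param abundance Relative abundance (> 0); sets mean coverage depth.
#' @return A `genome_model` list.
#' @export
genome_model <- function(genome_id, taxon_class, taxon_genus, gc_target,
                         genome_length, markov_order = 2,
                         composition_seedling = 0.15, gene_density = 1,
                         marker_set = marker_set_default(), abundance = 1) {
  if (!(gc_target > 0.2 && gc_target < 0.8)) {
    abort("gc_target must lie strictly between 0.2 and 0.8")
  }
  if (genome_length < 50000) abort("genome_length must be >= 50,000 bases")
  if (gene_density <= 0) abort("gene_density must be positive")
  if (abundance <= 0) abort("abundance must be positive")
  if (composition_seedling <= 0) abort("composition_seedling must be positive")
  if (length(marker_set) == 0) abort("marker_set must be non-empty")
  structure(list(
    genome_id = genome_id, taxon_class = taxon_class,
    taxon_genus = taxon_genus, gc_target = gc_target,
    genome_length = as.integer(genome_length),
    markov_order = as.integer(markov_order),
    composition_seedling = composition_seedling,
    gene_density = gene_density, marker_set = marker_set,
    abundance = abundance
  ), class = "genome_model")
}

# Stationary single-base GC of an order-k chain: stationary distribution
# over k-mer contexts (power iteration on the context chain), then the
# expected next-base G+C probability.
stationary_gc <- function(trans, order) {
  n_ctx <- nrow(trans)
  if (order == 0) {
    return(sum(trans[1, c(2, 3)]))
  }
  pow <- 4^(order - 1)
  M <- matrix(0, n_ctx, n_ctx)
  for (b in 1:4) {
    tgt <- ((seq_len(n_ctx) - 1L) %/% 4L) + (b - 1L) * pow + 1L
    M[cbind(seq_len(n_ctx), tgt)] <- M[cbind(seq_len(n_ctx), tgt)] + trans[, b]
  }
  pi_ctx <- rep(1 / n_ctx, n_ctx)
  for (iter in 1:500) {
    new <- as.numeric(pi_ctx %*% M)
    if (max(abs(new - pi_ctx)) < 1e-13) {
      pi_ctx <- new
      break
    }
    pi_ctx <- new
  }
  sum(pi_ctx * (trans[, 2] + trans[, 3]))
}

# Perturbed, GC-calibrated transition matrix: one row per k-order context,
# columns A/C/G/T. A lognormal tilt gives each genome its own 4-mer
# signature; a bisection on a G/C column multiplier then pins the chain's
# stationary GC to the model target, so realized GC converges to gc_target
# as the genome grows.
markov_transitions <- function(model) {
  base_p <- c((1 - model$gc_target) / 2, model$gc_target / 2,
              model$gc_target / 2, (1 - model$gc_target) / 2)
  n_ctx <- 4^model$markov_order
  z <- matrix(rnorm(n_ctx * 4, sd = model$composition_seedling), n_ctx, 4)
  p <- matrix(base_p, n_ctx, 4, byrow = TRUE) * exp(z)
  p <- p / rowSums(p)
  tilt <- function(t) {
    q <- p
    q[, c(2, 3)] <- q[, c(2, 3)] * t
    q / rowSums(q)
  }
  lo <- 0.2; hi <- 5
  for (iter in 1:50) {
    mid <- sqrt(lo * hi)
    if (stationary_gc(tilt(mid), model$markov_order) < model$gc_target) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  tilt(sqrt(lo * hi))
}

# Sample n bases from the context->base transition matrix (contexts indexed
# base-4 over the previous `order` bases).
sample_markov_sequence <- function(trans, n, order) {
  bases <- c("A", "C", "G", "T")
  cum <- t(apply(trans, 1, cumsum))
  out <- integer(n)
  u <- runif(n)
  # warm-up context drawn from the mean composition
  ctx_digits <- sample.int(4, order, replace = TRUE, prob = colMeans(trans))
  ctx <- sum((ctx_digits - 1) * 4^(seq_len(order) - 1)) + 1L
  pow <- 4^(order - 1)
  for (i in seq_len(n)) {
    row <- cum[ctx, ]
    b <- if (u[i] <= row[1]) 1L else if (u[i] <= row[2]) 2L
         else if (u[i] <= row[3]) 3L else 4L
    out[i] <- b
    # shift context: drop oldest digit, append b
    ctx <- ((ctx - 1L) %/% 4L) + (b - 1L) * pow + 1L
  }
  paste(bases[out], collapse = "")
}

#' Simulate one genome sequence with gene calls
#'
#' Draws a `genome_length`-base sequence from the model's perturbed Markov
#' chain and tiles it with non-overlapping gene intervals at roughly
#' `gene_density` genes per kb (gene length ~80% of the mean spacing,
#' exponential intergenic gaps). Each marker in the model's `marker_set` is
#' placed on exactly one gene; remaining genes receive function labels from
#' a pool of sulfur/nitrogen-cycle families. Gene taxon labels are the
#' model's (true) taxa. Deterministic for a fixed seed.
#'
#' @param model A [genome_model()].
#' @param seed Integer seed.
#' @return List with `sequence` (character scalar) and `genes` (tibble:
#'   `gene_id`, `start`, `end` 1-based inclusive, `strand`,
#'   `function_label`, `true_taxon_class`, `true_taxon_genus`, `is_marker`).
#' @export
simulate_genome <- function(model, seed = 1) {
  stopifnot(is(model, "genome_model"))
  out <- withr::with_seed(seed, {
    trans <- markov_transitions(model)
    seq <- sample_markov_sequence(trans, model$genome_length, model$markov_order)
    genes <- place_genes(model)
    list(sequence = seq, genes = genes)
  })
  out
}

gene_family_pool <- function() {
  c("sqr", "fccB", "soxB", "soxC", "soxY", "aclA", "aclB", "napA", "narG",
    "nrfA", "norB", "sat", "dsrA", "dsrB", "psrA", "hydB", "nuoF", "cydA",
    "hyp")
}

place_genes <- function(model) {
  spacing <- 1000 / model$gene_density
  mean_len <- max(150, round(0.8 * spacing))
  pos <- 1
  starts <- integer(0); ends <- integer(0)
  while (TRUE) {
    len <- max(90L, as.integer(round(rnorm(1, mean_len, 0.15 * mean_len))))
    gap <- as.integer(round(rexp(1, rate = 1 / max(1, spacing - mean_len))))
    if (pos + len - 1 > model$genome_length) break
    starts <- c(starts, pos)
    ends <- c(ends, pos + len - 1L)
    pos <- pos + len + gap
  }
  n <- length(starts)
  markers <- rep(NA_character_, n)
  n_mark <- length(model$marker_set)
  if (n >= n_mark) {
    markers[sample.int(n, n_mark)] <- model$marker_set
  } else {
    warn(sprintf("genome %s: only %d genes for %d markers; marker set truncated",
                 model$genome_id, n, n_mark))
    markers[seq_len(n)] <- model$marker_set[seq_len(n)]
  }
  tibble(
    gene_id = sprintf("%s_g%04d", model$genome_id, seq_len(n)),
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    function_label = if_else(is.na(markers),
                             sample(gene_family_pool(), n, replace = TRUE),
                             markers),
    true_taxon_class = model$taxon_class,
    true_taxon_genus = model$taxon_genus,
    is_marker = markers
  )
}

#' Fragment a genome into contigs with noisy depth
#'
#' Walks along the genome drawing lognormal fragment lengths; each fragment
#' of at least `min_length` bases becomes a contig (non-overlapping
#' substrings, jointly covering at most 100% of the genome — shorter draws
#' leave gaps). Each contig's depth is `abundance` times a lognormal
#' multiplicative noise factor.
#'
#' @param sequence Genome sequence (character scalar).
#' @param genome_id Genome identifier (used for contig ids and truth).
#' @param meanlog,sdlog Lognormal fragment-length parameters (defaults
#'   `log(4000)` and 0.35; `sdlog = 0` gives fixed-length tiling).
#' @param min_length Minimum contig length (default 2500).
#' @param abundance Genome relative abundance = mean depth.
#' @param depth_sigma sdlog of the per-contig depth noise (default 0.25;
#'   0 gives identical depths).
#' @param seed Integer seed.
#' @return Tibble of contigs: `contig_id`, `genome_id`, `offset` (0-based
#'   start in the genome), `length`, `sequence`, `depth`. Empty (with a
#'   warning) if no draw reaches `min_length`.
#' @export
fragment_genome <- function(sequence, genome_id = "g", meanlog = log(4000),
                            sdlog = 0.35, min_length = 2500, abundance = 1,
                            depth_sigma = 0.25, seed = 1) {
  stopifnot(min_length >= 1, abundance > 0, depth_sigma >= 0)
  L <- nchar(sequence)
  withr::with_seed(seed, {
    pos <- 1
    starts <- integer(0); lens <- integer(0)
    while (pos <= L - min_length + 1) {
      len <- as.integer(round(rlnorm(1, meanlog, sdlog)))
      len <- min(len, L - pos + 1L)
      if (len >= min_length) {
        starts <- c(starts, pos)
        lens <- c(lens, len)
      }
      pos <- pos + max(len, 1L)
    }
    if (length(starts) == 0) {
      warn(sprintf("genome %s: fragment distribution produced no contig >= %d bp",
                   genome_id, min_length))
      tibble(contig_id = character(0), genome_id = character(0),
             offset = integer(0), length = integer(0),
             sequence = character(0), depth = numeric(0))
    } else {
      tibble(
        contig_id = sprintf("%s_c%04d", genome_id, seq_along(starts)),
        genome_id = genome_id,
        offset = starts - 1L,
        length = lens,
        sequence = substring(sequence, starts, starts + lens - 1L),
        depth = abundance * rlnorm(length(starts), 0, depth_sigma)
      )
    }
  })
}

#' Simulate a best-hit table for gene calls
#'
#' Emulates the output of a homology search: one record per gene with an
#' e-value, bit score and query-coverage fraction drawn from configurable
#' generators, and a reported subject taxon that equals the true taxon
#' except for a `mislabel_rate` fraction of records, which are assigned a
#' taxon drawn from the other community taxa (emulating best-hit
#' misassignment).
#'
#' @param gene_calls Tibble with `gene_id`, `function_label`, `start`,
#'   `end`, `true_taxon_class`, `true_taxon_genus`.
#' @param mislabel_rate Fraction of records mislabeled, in \[0, 1).
#' @param taxon_pool Optional tibble (`taxon_class`, `taxon_genus`) of
#'   alternative taxa for mislabels; defaults to the distinct true taxa in
#'   `gene_calls` plus a generic foreign taxon.
#' @param evalue_gen,bit_gen,coverage_gen Functions of `n` returning the
#'   score draws. Defaults: e-value `10^-runif(4, 60)`, bit score
#'   `80 + rexp(mean 220)`, coverage `rbeta(8, 2)`.
#' @param seed Integer seed.
#' @return Tibble of hit records: `query_id`, `gene_family`,
#'   `subject_taxon_class`, `subject_taxon_genus`, `evalue`, `bit_score`,
#'   `query_coverage`, `gene_length`, `mislabeled`.
#' @export
simulate_hit_table <- function(gene_calls, mislabel_rate = 0.1,
                               taxon_pool = NULL,
                               evalue_gen = function(n) 10^-runif(n, 4, 60),
                               bit_gen = function(n) 80 + rexp(n, 1 / 220),
                               coverage_gen = function(n) rbeta(n, 8, 2),
                               seed = 1) {
  if (mislabel_rate < 0 || mislabel_rate >= 1) {
    abort("mislabel_rate must be in [0, 1)")
  }
  if (nrow(gene_calls) == 0) {
    return(tibble(query_id = character(0), gene_family = character(0),
                  subject_taxon_class = character(0),
                  subject_taxon_genus = character(0), evalue = numeric(0),
                  bit_score = numeric(0), query_coverage = numeric(0),
                  gene_length = integer(0), mislabeled = logical(0)))
  }
  if (is.null(taxon_pool)) {
    # distinct true taxa plus two guaranteed-foreign taxa, so a mislabel
    # target always exists whatever the community composition
    taxon_pool <- gene_calls %>%
      distinct(taxon_class = .data$true_taxon_class,
               taxon_genus = .data$true_taxon_genus) %>%
      bind_rows(tibble(
        taxon_class = c("Gammaproteobacteria", "Deltaproteobacteria"),
        taxon_genus = c("Beggiatoa", "Desulfocapsa"))) %>%
      distinct(.data$taxon_class, .data$taxon_genus)
  }
  n <- nrow(gene_calls)
  withr::with_seed(seed, {
    flip <- runif(n) < mislabel_rate
    cls <- gene_calls$true_taxon_class
    gen <- gene_calls$true_taxon_genus
    for (i in which(flip)) {
      alt <- taxon_pool[taxon_pool$taxon_genus != gen[i], , drop = FALSE]
      j <- sample.int(nrow(alt), 1)
      cls[i] <- alt$taxon_class[j]
      gen[i] <- alt$taxon_genus[j]
    }
    tibble(
      query_id = gene_calls$gene_id,
      gene_family = gene_calls$function_label,
      subject_taxon_class = cls,
      subject_taxon_genus = gen,
      evalue = evalue_gen(n),
      bit_score = bit_gen(n),
      query_coverage = pmin(coverage_gen(n), 1),
      gene_length = gene_calls$end - gene_calls$start + 1L,
      mislabeled = flip
    )
  })
}

#' Default five-genome community
#'
#' The standard test community: three Epsilonproteobacteria genera
#' (Sulfurovum-like at two GC levels, Sulfuricurvum) and two non-target
#' genomes (a Gammaproteobacterium and a Bacteroidetes member), with GC
#' targets spanning 0.34-0.62, 300 kb genomes, and a 15x-to-2x abundance
#' gradient. These settings emulate the GC spread and depth dispersion of a
#' cave-biofilm community at a size that fragments into a few hundred
#' contigs of >= 2.5 kb.
#'
#' @return List of five [genome_model()] objects.
#' @export
community_default_models <- function() {
  list(
    genome_model("sulfurovum_A", "Epsilonproteobacteria", "Sulfurovum",
                 gc_target = 0.34, genome_length = 300000, abundance = 15),
    genome_model("sulfurovum_B", "Epsilonproteobacteria", "Sulfurovum",
                 gc_target = 0.41, genome_length = 300000, abundance = 8),
    genome_model("sulfuricurvum_A", "Epsilonproteobacteria", "Sulfuricurvum",
                 gc_target = 0.47, genome_length = 300000, abundance = 5),
    genome_model("thiothrix_A", "Gammaproteobacteria", "Thiothrix",
                 gc_target = 0.55, genome_length = 300000, abundance = 3),
    genome_model("flavobacterium_A", "Bacteroidetes", "Flavobacterium",
                 gc_target = 0.62, genome_length = 300000, abundance = 2)
  )
}

#' Simulate a multi-genome community sample
#'
#' Runs [simulate_genome()], [fragment_genome()] and [simulate_hit_table()]
#' for each genome model and assembles the results into one sample with
#' per-contig ground truth. Gene calls are lifted from genome to contig
#' coordinates; genes not fully contained in a retained contig are lost
#' (which is also how marker dropout arises naturally). Per-gene best-hit
#' taxa (with mislabeling) are joined onto the gene calls so downstream
#' curation can vote on them.
#'
#' @param models List of [genome_model()] (default
#'   [community_default_models()]).
#' @param seed Integer master seed (default 42); per-genome streams are
#'   derived from it.
#' @param mislabel_rate Fraction of genes whose best-hit taxon is wrong
#'   (default 0.1).
#' @param min_length Minimum contig length (default 2500).
#' @param total_reads Simulated library size (default 5e6).
#' @param depth_sigma Per-contig lognormal depth noise (default 0.25).
#' @param meanlog,sdlog Fragment-length distribution (defaults log(4000),
#'   0.35).
#' @return A `community_sample` list: `contigs` (tibble incl. `sequence`,
#'   `depth`, true `genome_id`), `gene_calls` (contig coordinates, truth and
#'   best-hit fields), `hits` (hit table), `truth` (contig_id -> genome_id),
#'   `total_reads`, `seed`, `models`.
#' @export
simulate_community <- function(models = community_default_models(), seed = 42,
                               mislabel_rate = 0.1, min_length = 2500,
                               total_reads = 5e6, depth_sigma = 0.25,
                               meanlog = log(4000), sdlog = 0.35) {
  stopifnot(length(models) >= 1)
  contigs <- list(); genes <- list(); hits <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    g <- simulate_genome(m, seed = seed + 1000L * i)
    ctg <- fragment_genome(g$sequence, genome_id = m$genome_id,
                           meanlog = meanlog, sdlog = sdlog,
                           min_length = min_length, abundance = m$abundance,
                           depth_sigma = depth_sigma, seed = seed + 1000L * i + 1L)
    if (nrow(ctg) == 0) next
    ht <- simulate_hit_table(g$genes, mislabel_rate = mislabel_rate,
                             seed = seed + 1000L * i + 2L)
    gc2 <- lift_genes_to_contigs(g$genes, ctg) %>%
      left_join(select(ht, "query_id", "subject_taxon_class",
                       "subject_taxon_genus", "evalue", "bit_score",
                       "query_coverage", "mislabeled"),
                by = c(gene_id = "query_id")) %>%
      rename(best_hit_taxon_class = "subject_taxon_class",
             best_hit_taxon_genus = "subject_taxon_genus")
    contigs[[i]] <- ctg
    genes[[i]] <- gc2
    hits[[i]] <- ht %>% filter(.data$query_id %in% gc2$gene_id)
  }
  contigs <- bind_rows(contigs)
  if (nrow(contigs) == 0) abort("community simulation produced no contigs")
  structure(list(
    contigs = contigs,
    gene_calls = bind_rows(genes),
    hits = bind_rows(hits),
    truth = tibble(contig_id = contigs$contig_id,
                   genome_id = contigs$genome_id),
    total_reads = as.integer(total_reads),
    seed = as.integer(seed),
    models = models
  ), class = "community_sample")
}

# Map genome-coordinate gene records onto contigs; genes must fall entirely
# within one contig (contigs never overlap, so containment is unique).
lift_genes_to_contigs <- function(genes, contigs) {
  purrr::pmap_dfr(
    contigs[, c("contig_id", "offset", "length")],
    function(contig_id, offset, length) {
      inside <- genes$start > offset & genes$end <= offset + length
      if (!any(inside)) return(NULL)
      g <- genes[inside, , drop = FALSE]
      g$contig_id <- contig_id
      g$start <- g$start - offset
      g$end <- g$end - offset
      g
    })
}

#' Ground-truth contig-to-genome map
#'
#' @param sample A `community_sample`.
#' @return Tibble `contig_id`, `genome_id` (one row per contig).
#' @export
ground_truth <- function(sample) {
  stopifnot(is(sample, "community_sample"))
  sample$truth
}

#' @export
print.community_sample <- function(x, ...) {
  cat(sprintf(
    "community_sample: %d genomes, %d contigs (%.2f Mb), %d gene calls, seed %d\n",
    length(x$models), nrow(x$contigs), sum(x$contigs$length) / 1e6,
    nrow(x$gene_calls), x$seed))
  invisible(x)
}

#' @export
glance.community_sample <- function(x, ...) {
  tibble(n_genomes = length(x$models), n_contigs = nrow(x$contigs),
         total_bp = sum(x$contigs$length), n_genes = nrow(x$gene_calls),
         total_reads = x$total_reads, seed = x$seed)
}

#' Write a community sample to disk
#'
#' Contigs as FASTA, gene calls as GFF3 (1-based inclusive coordinates,
#' strand in column 7, taxon/score fields as attributes), truth and hit
#' tables as TSV with headers.
#'
#' @param sample A `community_sample`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(setNames(sample$contigs$sequence,
                                            sample$contigs$contig_id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "contigs.fasta"))
  write_gene_calls_gff3(sample$gene_calls, file.path(dir, "gene_calls.gff3"))
  readr::write_tsv(sample$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(select(sample$contigs, -"sequence"),
                   file.path(dir, "contig_depths.tsv"))
  write_hit_table(sample$hits, file.path(dir, "hits.tsv"))
  invisible(dir)
}

#' Write gene calls as GFF3
#'
#' @param gene_calls Gene-call tibble (contig coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_calls_gff3 <- function(gene_calls, path) {
  attr_str <- sprintf(
    "ID=%s;function=%s;taxon_class=%s;taxon_genus=%s;evalue=%g;bit_score=%.1f;query_coverage=%.3f%s",
    gene_calls$gene_id, gene_calls$function_label,
    gene_calls$best_hit_taxon_class, gene_calls$best_hit_taxon_genus,
    gene_calls$evalue, gene_calls$bit_score, gene_calls$query_coverage,
    if_else(is.na(gene_calls$is_marker), "",
            paste0(";marker=", gene_calls$is_marker)))
  lines <- sprintf("%s\tmagsom\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   gene_calls$contig_id, gene_calls$start, gene_calls$end,
                   gene_calls$strand, attr_str)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene calls from a magsom GFF3 file
#'
#' Parses with `rtracklayer::import()` and reshapes the GRanges back into
#' the gene-call tibble layout.
#'
#' @param path GFF3 file written by [write_gene_calls_gff3()].
#' @return Gene-call tibble.
#' @export
read_gene_calls_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else
    rep(NA_character_, length(gr))
  tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = pick("ID"),
    function_label = pick("function"),
    best_hit_taxon_class = pick("taxon_class"),
    best_hit_taxon_genus = pick("taxon_genus"),
    evalue = as.numeric(pick("evalue")),
    bit_score = as.numeric(pick("bit_score")),
    query_coverage = as.numeric(pick("query_coverage")),
    is_marker = pick("marker")
  )
}
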