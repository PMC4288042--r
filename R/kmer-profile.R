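#' Canonical k-mer alphabet
#'
#' All DNA k-mers, optionally collapsed so that a k-mer and its reverse
#' complement share one canonical key (the lexicographically smaller of the
#' pair). For k = 4 this gives 256 keys uncollapsed and 136 collapsed
#' (16 tetramers are their own reverse complement).
#'
#' @param k Word size (positive integer).
#' @param collapse_rc Collapse reverse-complement pairs to one key?
#' @return Character vector of canonical k-mers, sorted.
#' @export
#' @examples
#' length(kmer_alphabet(4))                      # 256
#' length(kmer_alphabet(4, collapse_rc = TRUE))  # 136
kmer_alphabet <- function(k = 4, collapse_rc = FALSE) {
  all <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  if (!collapse_rc) {
    return(sort(all))
  }
  sort(unique(canonical_kmer(all)))
}

canonical_kmer <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' Count k-mers in a DNA sequence
#'
#' Slides a window of width `k` along the sequence; any window containing a
#' non-ACGT base (e.g. N) is skipped, never imputed. With
#' `collapse_rc = TRUE` a k-mer and its reverse complement are pooled under
#' the lexicographically smaller key, making counts invariant to the
#' (arbitrary) strand of an assembled contig.
#'
#' @param sequence A single character string over A/C/G/T/N.
#' @param k Word size; `k` longer than the sequence yields an empty result.
#' @param collapse_rc Pool reverse-complement pairs?
#' @return Named integer vector of counts for the k-mers observed (zero
#'   counts are omitted).
#' @export
#' @examples
#' count_kmers("ACGTACGT")
#' count_kmers("ACGTACGT", collapse_rc = TRUE)
count_kmers <- function(sequence, k = 4, collapse_rc = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1, k >= 1)
  if (nchar(sequence) < k) {
    return(setNames(integer(0), character(0)))
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence), width = k)
  if (collapse_rc) {
    counts <- tapply(counts, canonical_kmer(names(counts)), sum)
    counts <- setNames(as.integer(counts), names(counts))
  }
  counts <- counts[counts > 0]
  counts[order(names(counts))]
}

#' GC content of a DNA sequence
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguous bases (N) are excluded from
#' both numerator and denominator; a sequence with no unambiguous base has
#' undefined GC and returns `NA`, never 0.
#'
#' @param sequence Character vector of DNA strings.
#' @return Numeric vector of GC fractions in \[0, 1\], `NA` where undefined.
#' @export
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGTN"))
gc_content <- function(sequence) {
  stopifnot(is.character(sequence))
  if (length(sequence) == 0) {
    return(numeric(0))
  }
  lf <- Biostrings::letterFrequency(Biostrings::DNAStringSet(sequence),
                                    letters = c("A", "C", "G", "T"))
  denom <- rowSums(lf)
  out <- (lf[, "G"] + lf[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Cut a contig into profiling windows
#'
#' Contigs shorter than `min_length` are excluded entirely. Longer contigs
#' are cut into consecutive non-overlapping windows of `window` bases; a
#' terminal remainder of at least `min_length` stands as its own window,
#' while a shorter remainder is merged into the previous window (so the last
#' window may be up to `window + min_length - 1` bases).
#'
#' @param length Contig length in bases (vectorised over a single value).
#' @param window Window size in bases (default 5000).
#' @param min_length Minimum contig/window length in bases (default 2500,
#'   the binning floor for assembled contigs).
#' @return Tibble with columns `offset` (0-based window start) and `length`.
#' @export
#' @examples
#' tile_windows(12000)  # 5000 + 7000 (trailing 2000 merged)
#' tile_windows(7500)   # 5000 + 2500
#' tile_windows(2400)   # no windows
tile_windows <- function(length, window = 5000, min_length = 2500) {
  stopifnot(length(length) == 1, window >= min_length, min_length >= 1)
  if (length < min_length) {
    return(tibble(offset = integer(0), length = integer(0)))
  }
  n_full <- length %/% window
  if (n_full == 0) {
    return(tibble(offset = 0L, length = as.integer(length)))
  }
  lens <- rep(window, n_full)
  rem <- length - n_full * window
  if (rem >= min_length) {
    lens <- c(lens, rem)
  } else {
    lens[n_full] <- lens[n_full] + rem
  }
  tibble(offset = as.integer(cumsum(c(0, lens[-length(lens)]))),
         length = as.integer(lens))
}

#' Windowed tetranucleotide profiles for a set of contigs
#'
#' Builds the feature matrix consumed by the self-organizing map: each
#' eligible window (see [tile_windows()]) contributes one row of relative
#' 4-mer frequencies plus its GC fraction. Row order is deterministic
#' (contig input order, then offset) and stably keyed by `window_id`.
#'
#' @param contigs Tibble with columns `contig_id` and `sequence` (additional
#'   columns are ignored).
#' @param k Word size (default 4).
#' @param window,min_length Window tiling parameters, see [tile_windows()].
#' @param collapse_rc Pool reverse-complement k-mers (default `TRUE`; the
#'   strand of an assembled contig is arbitrary). Gives 136 features at k = 4.
#' @param standardize Additionally z-score each feature column across
#'   windows (default `FALSE`; raw relative frequencies).
#' @return Tibble with metadata columns `window_id`, `contig_id`, `offset`,
#'   `length`, `gc` followed by one column per canonical k-mer. The feature
#'   column names are recorded in `attr(, "features")`. Each row of the
#'   unstandardized feature block sums to 1 (when the window contains at
#'   least one valid k-mer).
#' @export
tetra_profiles <- function(contigs, k = 4, window = 5000, min_length = 2500,
                           collapse_rc = TRUE, standardize = FALSE) {
  stopifnot(is.data.frame(contigs), all(c("contig_id", "sequence") %in% names(contigs)))
  win <- purrr::map2_dfr(contigs$contig_id, contigs$sequence, function(id, seq) {
    w <- tile_windows(nchar(seq), window = window, min_length = min_length)
    if (nrow(w) == 0) return(NULL)
    w$contig_id <- id
    w$sequence <- substring(seq, w$offset + 1, w$offset + w$length)
    w
  })
  if (is.null(win) || nrow(win) == 0) {
    abort("no contig passes the length filter; no profiling windows to compute")
  }
  alphabet <- kmer_alphabet(k, collapse_rc = collapse_rc)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(win$sequence), width = k)
  if (collapse_rc) {
    key <- canonical_kmer(colnames(counts))
    counts <- t(rowsum(t(counts), group = key))
  }
  counts <- counts[, alphabet, drop = FALSE]
  tot <- rowSums(counts)
  freqs <- counts / ifelse(tot > 0, tot, 1)
  if (standardize) {
    freqs <- scale(freqs)
    freqs[, attr(freqs, "scaled:scale") == 0] <- 0
  }
  out <- tibble(
    window_id = sprintf("%s:%d", win$contig_id, win$offset),
    contig_id = win$contig_id,
    offset = win$offset,
    length = win$length,
    gc = gc_content(win$sequence)
  )
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(freqs)))
  attr(out, "features") <- alphabet
  out
}

#' Extract the numeric feature matrix from a profile tibble
#'
#' @param profiles Output of [tetra_profiles()].
#' @return Numeric matrix, one row per window, rownames = `window_id`.
#' @export
profile_matrix <- function(profiles) {
  feats <- attr(profiles, "features")
  if (is.null(feats)) {
    meta <- c("window_id", "contig_id", "offset", "length", "gc")
    feats <- setdiff(names(profiles), meta)
  }
  m <- as.matrix(profiles[, feats, drop = FALSE])
  rownames(m) <- profiles$window_id
  m
}

#' Write a profile tibble as TSV
#'
#' @param profiles Output of [tetra_profiles()].
#' @param path Output file.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}
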