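# Independent brute-force oracles, deliberately written without the package
# machinery (base string ops only).

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# O(n*k) sliding-window re-scan
naive_count_kmers <- function(sequence, k = 4, collapse_rc = FALSE) {
  n <- nchar(sequence)
  if (n < k) return(setNames(integer(0), character(0)))
  out <- list()
  for (i in seq_len(n - k + 1)) {
    w <- substr(sequence, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    if (collapse_rc) {
      rc <- naive_revcomp(w)
      if (rc < w) w <- rc
    }
    out[[w]] <- (out[[w]] %||% 0L) + 1L
  }
  v <- unlist(out)
  if (is.null(v)) return(setNames(integer(0), character(0)))
  v[order(names(v))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# N50 by direct definition scan
naive_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}
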