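# Independent oracles, deliberately implemented without the package's
# aligner/search code paths.

# Mismatch count of `q` placed at every offset of `s` (plain raw-vector
# comparison).
oracle_mismatch_profile <- function(q, s) {
  w <- nchar(q)
  n <- nchar(s)
  if (w > n) return(integer(0))
  qr <- charToRaw(q)
  sr <- charToRaw(s)
  vapply(0:(n - w), function(off) sum(qr != sr[(off + 1):(off + w)]),
         integer(1))
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Brute-force all-offsets, both-strands aligner with minimal-mismatch
# stratum selection and max-loci suppression.
oracle_align <- function(read, ref, max_mm = 5L, max_loci = 10L) {
  hits <- list()
  for (chrom in names(ref$chromosomes)) {
    s <- as.character(ref$chromosomes[[chrom]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else oracle_revcomp(read)
      mm <- oracle_mismatch_profile(q, s)
      ok <- which(mm <= max_mm)
      if (length(ok) > 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, pos = ok, strand = strand, nm = mm[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[h$nm == min(h$nm), , drop = FALSE]
  if (nrow(h) > max_loci) return(NULL)
  h$nh <- nrow(h)
  h[order(h$chrom, h$pos, h$strand), ]
}

# All offsets of an exact occurrence, by direct scan.
oracle_substring_starts <- function(text, pattern) {
  w <- nchar(pattern)
  n <- nchar(text)
  if (w > n) return(integer(0))
  out <- integer(0)
  for (p in 1:(n - w + 1L)) {
    if (substr(text, p, p + w - 1L) == pattern) out <- c(out, p)
  }
  out
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")
random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                    collapse = "")
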