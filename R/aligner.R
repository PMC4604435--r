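# Toy short-read aligner honouring the stated mapping contract: end-to-end
# ungapped placement, up to `max_mismatches` substitutions per alignment,
# reads reported only when their minimal-mismatch stratum spans
# `max_loci` or fewer loci. Matches STAR's behaviour on the quantities this
# pipeline depends on (unique-mapper selection, NH hit counts) at toy
# reference scale.

#' Align read sequences to the toy reference
#'
#' Brute-force Hamming-distance scan of every end-to-end placement on both
#' strands of every chromosome. Only the minimal-mismatch stratum is
#' reported; a read whose stratum exceeds `max_loci` placements is
#' suppressed entirely (no records). Reads shorter than 15 nt are dropped
#' as unalignable noise; empty reads are an error. Duplicate sequences are
#' aligned once and fanned back out, so runtime scales with the number of
#' distinct sequences.
#'
#' @param reads Character vector of DNA read sequences, or a tibble with
#'   columns `read_id` and `seq` (e.g. a [simulate_library()] result).
#' @param ref A [build_reference()] bundle.
#' @param max_mismatches Mismatch cap per alignment (default 5).
#' @param max_loci Maximum reported loci per read (default 10).
#' @return Alignment tibble with one row per reported placement: `read_id`,
#'   `chrom`, `pos` (1-based), `strand`, `width`, `seq`, `mismatches`
#'   (`nm`), `nh` (hit count), `is_unique`. Rows are ordered by read, then
#'   `(chrom, pos, strand)`.
#' @export
align_reads <- function(reads, ref, max_mismatches = 5L, max_loci = 10L) {
  stopifnot(inherits(ref, "reference_bundle"))
  if (is.data.frame(reads)) {
    read_id <- reads$read_id
    seqs <- reads$seq
  } else {
    read_id <- if (!is.null(names(reads))) names(reads) else
      sprintf("read_%d", seq_along(reads))
    seqs <- unname(as.character(reads))
  }
  if (length(seqs) == 0L) {
    return(empty_alignment())
  }
  if (any(!nzchar(seqs))) {
    stop("validation error: empty read sequence", call. = FALSE)
  }
  seqs <- toupper(seqs)
  keep <- nchar(seqs) >= 15L
  seqs_kept <- seqs[keep]
  ids_kept <- read_id[keep]
  if (length(seqs_kept) == 0L) return(empty_alignment())

  uniq <- unique(seqs_kept)
  hit <- .align_seqs_cpp(uniq, as.character(ref$chromosomes),
                         as.integer(max_mismatches), as.integer(max_loci))
  hits <- tibble::tibble(useq = uniq[hit$read],
                         chrom = names(ref$chromosomes)[hit$chrom],
                         pos = hit$pos,
                         strand = ifelse(hit$strand == 1L, "-", "+"),
                         nm = hit$mismatches, nh = hit$nh)

  per_read <- tibble::tibble(read_id = ids_kept, seq = seqs_kept)
  out <- dplyr::inner_join(per_read, hits,
                           by = c(seq = "useq"), relationship = "many-to-many")
  out$width <- nchar(out$seq)
  out$is_unique <- out$nh == 1L
  chrom_rank <- match(out$chrom, names(ref$chromosomes))
  out <- out[order(match(out$read_id, ids_kept), chrom_rank, out$pos,
                   out$strand), ]
  out <- out[, c("read_id", "chrom", "pos", "strand", "width", "seq",
                 "nm", "nh", "is_unique")]
  tibble::as_tibble(out)
}

empty_alignment <- function() {
  tibble::tibble(read_id = character(), chrom = character(), pos = integer(),
                 strand = character(), width = integer(), seq = character(),
                 nm = integer(), nh = integer(), is_unique = logical())
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#'
#' @param read Character scalar (DNA) or an [rna_seq()] (RNA sequences are
#'   converted U->T before alignment).
#' @param ref,max_mismatches,max_loci See [align_reads()].
#' @return Alignment tibble (possibly zero rows when the read is suppressed
#'   or unmappable).
#' @export
align_read <- function(read, ref, max_mismatches = 5L, max_loci = 10L) {
  if (inherits(read, "rna_seq")) {
    read <- if (read$is_dna) read$residues else chartr("U", "T", read$residues)
  }
  align_reads(stats::setNames(read, "read_1"), ref,
              max_mismatches = max_mismatches, max_loci = max_loci)
}

#' Align a FASTQ library and write SAM
#'
#' Reads a FASTQ file (or takes an in-memory read table), aligns with
#' [align_reads()], and writes one SAM line per reported placement with the
#' `NH:i:` hit-count tag; the header carries the reference dictionary.
#'
#' @param fastq Path to a FASTQ file, or a tibble with `read_id`/`seq`.
#' @param ref A [build_reference()] bundle.
#' @param out Optional SAM output path; when `NULL` no file is written.
#' @param max_mismatches,max_loci Mapping contract parameters.
#' @return The alignment tibble, invisibly when `out` is given.
#' @export
align_library <- function(fastq, ref, out = NULL, max_mismatches = 5L,
                          max_loci = 10L) {
  reads <- if (is.character(fastq) && length(fastq) == 1L) read_fastq(fastq)
           else fastq
  aln <- align_reads(reads, ref, max_mismatches = max_mismatches,
                     max_loci = max_loci)
  if (!is.null(out)) {
    write_sam(aln, ref, out)
    return(invisible(aln))
  }
  aln
}
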