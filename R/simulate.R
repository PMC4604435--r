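#' Simulate a small-RNA sequencing library
#'
#' Draws `read_count` reads multinomially over the (gene, fragment)
#' categories defined by the profile's calibrated truth fractions and
#' fragment models, extracts the corresponding substrings of the reference
#' (all genes are on the `+` strand, so transcript and genomic sequence
#' coincide), and applies independent per-base substitution errors at
#' `error_rate`. Fully deterministic for a given seed: the same seed and
#' profile reproduce the identical read set byte for byte.
#'
#' @param profile A [library_profile()].
#' @param ref The [build_reference()] bundle.
#' @param seed Integer seed (defaults to the profile's own seed).
#' @return A tibble of class `sim_library` with one row per read:
#'   `read_id`, `seq` (DNA), `gene_id`, `chrom`, `gstart`, `gend` (genomic
#'   1-based closed), `tstart`, `tstop` (transcript 1-based closed),
#'   `n_errors`. Attributes: `library_id`, `seed`, `error_rate`.
#' @export
simulate_library <- function(profile, ref, seed = profile$seed) {
  stopifnot(inherits(profile, "library_profile"),
            inherits(ref, "reference_bundle"))
  set.seed(as.integer(seed))

  expressed <- names(profile$truth_fractions)[profile$truth_fractions > 0]
  cats <- dplyr::bind_rows(lapply(expressed, function(g) {
    fm <- profile$fragment_models[[g]]
    tibble::tibble(gene_id = g, start = fm$start, stop = fm$stop,
                   prob = profile$truth_fractions[[g]] * fm$weight)
  }))
  counts <- as.integer(stats::rmultinom(1L, profile$read_count, cats$prob))

  ann <- ref$annotations
  gene_start <- stats::setNames(GenomicRanges::start(ann),
                                S4Vectors::mcols(ann)$gene_id)
  gene_chrom <- stats::setNames(as.character(GenomicRanges::seqnames(ann)),
                                S4Vectors::mcols(ann)$gene_id)
  gene_seq <- stats::setNames(
    vapply(expressed, function(g) gene_sequence(ref, g), character(1)),
    expressed)

  idx <- rep.int(seq_len(nrow(cats)), counts)
  reads <- tibble::tibble(
    gene_id = cats$gene_id[idx],
    tstart = cats$start[idx], tstop = cats$stop[idx])
  reads$chrom <- unname(gene_chrom[reads$gene_id])
  reads$gstart <- unname(gene_start[reads$gene_id]) + reads$tstart - 1L
  reads$gend <- unname(gene_start[reads$gene_id]) + reads$tstop - 1L
  reads$seq <- unname(substr(gene_seq[reads$gene_id], reads$tstart, reads$tstop))

  # per-base substitution errors
  width <- nchar(reads$seq)
  n_err <- stats::rbinom(nrow(reads), width, profile$error_rate)
  err_idx <- which(n_err > 0L)
  if (length(err_idx) > 0L) {
    bases <- c("A", "C", "G", "T")
    for (i in err_idx) {
      s <- strsplit(reads$seq[i], "", fixed = TRUE)[[1L]]
      pos <- sample.int(width[i], n_err[i])
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
      reads$seq[i] <- paste(s, collapse = "")
    }
  }
  reads$n_errors <- n_err

  perm <- sample.int(nrow(reads))
  reads <- reads[perm, ]
  reads$read_id <- sprintf("%s_%07d", profile$name, seq_len(nrow(reads)))
  reads <- reads[, c("read_id", "seq", "gene_id", "chrom", "gstart", "gend",
                     "tstart", "tstop", "n_errors")]
  attr(reads, "library_id") <- profile$name
  attr(reads, "seed") <- as.integer(seed)
  attr(reads, "error_rate") <- profile$error_rate
  class(reads) <- c("sim_library", class(reads))
  reads
}

#' Write the truth alignments of a simulated library as SAM
#'
#' One record per read at its true locus, `NH:i:1`, with the originating
#' gene and transcript coordinates carried in `XG`/`XB`/`XE` tags.
#'
#' @param sim A [simulate_library()] tibble.
#' @param ref The reference bundle (for the header dictionary).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(sim, ref, path) {
  aln <- tibble::tibble(read_id = sim$read_id, chrom = sim$chrom,
                        pos = sim$gstart, strand = "+", seq = sim$seq,
                        nh = 1L, nm = sim$n_errors, gene_id = sim$gene_id,
                        tstart = sim$tstart, tstop = sim$tstop)
  write_sam(aln, ref, path)
}

#' Truth-label abundance of a simulated library
#'
#' @param sim A [simulate_library()] tibble.
#' @return Tibble `gene_id`, `n_reads`, `fraction` (of all simulated reads).
#' @export
truth_abundance <- function(sim) {
  out <- dplyr::count(tibble::as_tibble(sim), .data$gene_id, name = "n_reads")
  out$fraction <- out$n_reads / sum(out$n_reads)
  dplyr::arrange(out, dplyr::desc(.data$fraction))
}
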