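# Fragment profiling: transcript-coordinate start/stop histograms of reads
# attributed to a gene, with pseudogene-aware multimapper inclusion and
# frequent-position calling at an rpm threshold.

#' Profile read start/stop positions over a gene
#'
#' Builds 1-based transcript-coordinate start and stop rpm histograms for
#' reads attributed to `gene_id`. Unique mappers placed within the gene are
#' always included. Multimappers are included only under
#' `policy = "include_pseudogene_set"` and only when every reported locus
#' of the read lies within the gene or one of its annotated pseudogene
#' decoys — such reads are attributed to the gene via their placement at
#' the gene's own locus. Start is the transcript coordinate of the read's
#' 5' end, stop of its 3' end (closed); reads extending past the annotated
#' gene end are clipped to the gene span and flagged. rpm is normalised by
#' the library's total unique-mapper count, so the >1000 rpm
#' frequent-position cut is on the same scale as the gene counting.
#'
#' @param aln Alignment tibble (from [align_reads()] or [read_sam()]) or a
#'   SAM path; all records of the library, not only the gene's.
#' @param ref A [build_reference()] bundle.
#' @param gene_id Gene to profile (must be annotated in `ref`).
#' @param policy `"include_pseudogene_set"` (default) or
#'   `"exclude_multimappers"`.
#' @param threshold rpm threshold for frequent-position calling (strict
#'   `>`; default 1000).
#' @param total_unique Optional rpm denominator override; defaults to the
#'   number of `NH == 1` records in `aln`.
#' @return Object of class `fragment_profile`: fields `gene_id`,
#'   `gene_length`, `policy`, `threshold`, `fragments` (tibble `start`,
#'   `stop`, `n`, `rpm`), `start_hist` / `stop_hist` (tibbles `position`,
#'   `rpm`, `is_frequent`), `frequent_starts`, `frequent_stops`,
#'   `n_reads`, `n_clipped`, `total_unique`.
#' @export
profile_gene <- function(aln, ref, gene_id,
                         policy = c("include_pseudogene_set",
                                    "exclude_multimappers"),
                         threshold = 1000, total_unique = NULL) {
  policy <- match.arg(policy)
  aln <- as_alignment_records(aln)
  stopifnot(inherits(ref, "reference_bundle"))
  gene <- gene_annotation(ref, gene_id)
  gene_chrom <- as.character(GenomicRanges::seqnames(gene))
  gene_start <- GenomicRanges::start(gene)
  gene_end <- GenomicRanges::end(gene)
  gene_len <- gene_end - gene_start + 1L

  if (is.null(total_unique)) total_unique <- sum(aln$nh == 1L)
  if (total_unique <= 0L) {
    stop("no uniquely mapping reads to normalise against", call. = FALSE)
  }

  at_gene <- aln$chrom == gene_chrom &
    aln$pos <= gene_end & (aln$pos + aln$width - 1L) >= gene_start
  uniq_at_gene <- at_gene & aln$nh == 1L

  if (policy == "include_pseudogene_set") {
    decoy_ids <- ref$pseudogene_set[[gene_id]]
    allowed <- gene
    if (length(decoy_ids) > 0L) {
      decoys <- ref$annotations[S4Vectors::mcols(ref$annotations)$gene_id %in%
                                  decoy_ids]
      allowed <- c(GenomicRanges::granges(gene), GenomicRanges::granges(decoys))
    }
    multi <- aln[aln$nh > 1L, ]
    take_multi <- character(0)
    if (nrow(multi) > 0L) {
      rec <- GenomicRanges::GRanges(
        seqnames = multi$chrom,
        ranges = IRanges::IRanges(start = multi$pos, width = multi$width))
      within_allowed <- IRanges::overlapsAny(rec, allowed, type = "within",
                                             ignore.strand = TRUE)
      ok_read <- tapply(within_allowed, multi$read_id, all)
      has_gene_rec <- multi$chrom == gene_chrom & multi$pos <= gene_end &
        (multi$pos + multi$width - 1L) >= gene_start
      gene_reads <- unique(multi$read_id[has_gene_rec])
      take_multi <- intersect(names(ok_read)[ok_read], gene_reads)
    }
    included <- aln[uniq_at_gene |
                      (aln$nh > 1L & at_gene & aln$read_id %in% take_multi), ]
  } else {
    included <- aln[uniq_at_gene, ]
  }

  tstart <- included$pos - gene_start + 1L
  tstop <- tstart + included$width - 1L
  n_clipped <- sum(tstart < 1L | tstop > gene_len)
  tstart <- pmax(tstart, 1L)
  tstop <- pmin(tstop, gene_len)

  frag <- dplyr::count(tibble::tibble(start = tstart, stop = tstop),
                       .data$start, .data$stop, name = "n")
  frag$rpm <- frag$n / total_unique * 1e6

  hist_of <- function(pos_col) {
    h <- dplyr::summarise(dplyr::group_by(frag, position = .data[[pos_col]]),
                          rpm = sum(.data$rpm), .groups = "drop")
    h <- dplyr::arrange(h, .data$position)
    h$is_frequent <- h$rpm > threshold
    h
  }
  start_hist <- hist_of("start")
  stop_hist <- hist_of("stop")

  structure(list(gene_id = gene_id, gene_length = gene_len, policy = policy,
                 threshold = threshold, fragments = frag,
                 start_hist = start_hist, stop_hist = stop_hist,
                 frequent_starts = start_hist$position[start_hist$is_frequent],
                 frequent_stops = stop_hist$position[stop_hist$is_frequent],
                 n_reads = nrow(included), n_clipped = n_clipped,
                 total_unique = total_unique),
            class = "fragment_profile")
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("<fragment_profile> %s (%d nt), %d reads, policy=%s\n",
              x$gene_id, x$gene_length, x$n_reads, x$policy))
  cat(sprintf("  frequent starts (>%g rpm): %s\n", x$threshold,
              paste(x$frequent_starts, collapse = ", ")))
  cat(sprintf("  frequent stops  (>%g rpm): %s\n", x$threshold,
              paste(x$frequent_stops, collapse = ", ")))
  invisible(x)
}

#' Fragment length spectrum
#'
#' Length distribution (`stop - start + 1`) of the attributed fragments,
#' computed from the paired per-read start/stop records (not from the
#' marginal histograms).
#'
#' @param profile A [profile_gene()] result.
#' @return Tibble `length`, `rpm`, sorted by length.
#' @export
fragment_length_spectrum <- function(profile) {
  stopifnot(inherits(profile, "fragment_profile"))
  out <- dplyr::summarise(
    dplyr::group_by(profile$fragments,
                    length = .data$stop - .data$start + 1L),
    rpm = sum(.data$rpm), .groups = "drop")
  dplyr::arrange(out, .data$length)
}

#' Frequent stop positions conditional on a start position
#'
#' Restricts the stop histogram to fragments anchored at `start` and
#' applies the profile's rpm threshold; used to ask which processed-form 3'
#' ends rise above the cut among 5'-anchored reads.
#'
#' @param profile A [profile_gene()] result.
#' @param start Anchor start position (default 1, the gene's 5' end).
#' @param exclude_terminal Drop the stop at the gene's 3' terminus (the
#'   full-length form) before reporting (default `FALSE`).
#' @return Sorted integer vector of stop positions above the threshold.
#' @export
frequent_stops_for_start <- function(profile, start = 1L,
                                     exclude_terminal = FALSE) {
  stopifnot(inherits(profile, "fragment_profile"))
  frag <- profile$fragments[profile$fragments$start == start, ]
  h <- dplyr::summarise(dplyr::group_by(frag, .data$stop),
                        rpm = sum(.data$rpm), .groups = "drop")
  out <- sort(h$stop[h$rpm > profile$threshold])
  if (exclude_terminal) out <- out[out != profile$gene_length]
  out
}

#' Export a fragment profile as a TSV-ready table
#'
#' @param profile A [profile_gene()] result.
#' @return Tibble `position`, `start_rpm`, `stop_rpm`, `start_is_frequent`,
#'   `stop_is_frequent`, one row per transcript position.
#' @export
fragment_profile_table <- function(profile) {
  stopifnot(inherits(profile, "fragment_profile"))
  pos <- seq_len(profile$gene_length)
  s <- profile$start_hist
  e <- profile$stop_hist
  tibble::tibble(
    position = pos,
    start_rpm = ifelse(pos %in% s$position, s$rpm[match(pos, s$position)], 0),
    stop_rpm = ifelse(pos %in% e$position, e$rpm[match(pos, e$position)], 0),
    start_is_frequent = pos %in% profile$frequent_starts,
    stop_is_frequent = pos %in% profile$frequent_stops)
}
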