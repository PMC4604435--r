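#' @useDynLib evrny5, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named list of residue strings (upper-case).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.list(toupper(as.character(set)))
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector/list of residue strings, or a list of
#'   [rna_seq()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) > 0L && inherits(seqs[[1L]], "rna_seq")) {
    nm <- vapply(seqs, function(s) s$id, character(1))
    seqs <- stats::setNames(vapply(seqs, function(s) s$residues, character(1)), nm)
  }
  set <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-per-record parser; malformed records are reported with the
#' offending line number.
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("parse error in %s: truncated FASTQ record starting at line %d (%d trailing lines)",
                 path, (n %/% 4L) * 4L + 1L, n %% 4L), call. = FALSE)
  }
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), seq = character(), qual = character()))
  }
  idx <- seq(1L, n, by = 4L)
  head_ok <- startsWith(lines[idx], "@")
  if (!all(head_ok)) {
    bad <- idx[which(!head_ok)[1L]]
    stop(sprintf("parse error in %s at line %d: expected '@' header, got %s",
                 path, bad, sQuote(lines[bad])), call. = FALSE)
  }
  plus_ok <- startsWith(lines[idx + 2L], "+")
  if (!all(plus_ok)) {
    bad <- idx[which(!plus_ok)[1L]] + 2L
    stop(sprintf("parse error in %s at line %d: expected '+' separator, got %s",
                 path, bad, sQuote(lines[bad])), call. = FALSE)
  }
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  len_ok <- nchar(seqs) == nchar(quals)
  if (!all(len_ok)) {
    bad <- idx[which(!len_ok)[1L]] + 3L
    stop(sprintf("parse error in %s at line %d: quality length differs from sequence length",
                 path, bad), call. = FALSE)
  }
  tibble::tibble(read_id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
                 seq = toupper(seqs), qual = quals)
}

#' Write reads to FASTQ
#'
#' Qualities are constant `'I'` (Phred 40): the downstream pipeline never
#' uses base qualities.
#'
#' @param read_id,seq Character vectors of equal length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(read_id, seq, path) {
  stopifnot(length(read_id) == length(seq))
  qual <- vapply(nchar(seq), function(w) strrep("I", w), character(1))
  lines <- as.vector(rbind(paste0("@", read_id), seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

# SAM flag for strand: 0 forward, 16 reverse.
sam_flag <- function(strand) ifelse(strand == "-", 16L, 0L)

#' Write alignment records to a SAM file
#'
#' Emits a valid header (`@HD`, `@SQ` with the reference dictionary) and one
#' line per record with an `NH:i:` hit-count tag and an `NM:i:`
#' mismatch-count tag. Truth columns (`gene_id`, transcript `tstart`,
#' `tstop`), when present, are carried in `XG:Z:`, `XB:i:`, `XE:i:` tags.
#' Reverse-strand records store the reverse complement of the read, per SAM
#' convention.
#'
#' @param aln Alignment tibble with columns `read_id`, `chrom`, `pos`,
#'   `strand`, `seq`, `nh`, `nm` (and optionally `gene_id`, `tstart`,
#'   `tstop`).
#' @param ref A [build_reference()] bundle (supplies the `@SQ` dictionary).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref, path) {
  stopifnot(all(c("read_id", "chrom", "pos", "strand", "seq", "nh", "nm") %in% names(aln)))
  lens <- Biostrings::width(ref$chromosomes)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$chromosomes), lens))
  if (nrow(aln) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  seq_out <- unname(aln$seq)
  rev_idx <- aln$strand == "-"
  if (any(rev_idx)) {
    seq_out[rev_idx] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq_out[rev_idx])))
  }
  body <- paste(aln$read_id, sam_flag(aln$strand), aln$chrom, aln$pos, 255L,
                paste0(nchar(aln$seq), "M"), "*", 0L, 0L, seq_out, "*",
                paste0("NH:i:", aln$nh), paste0("NM:i:", aln$nm), sep = "\t")
  if (all(c("gene_id", "tstart", "tstop") %in% names(aln))) {
    body <- paste(body, paste0("XG:Z:", aln$gene_id),
                  paste0("XB:i:", aln$tstart), paste0("XE:i:", aln$tstop),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SAM file
#'
#' Parses the plain-text SAM produced by [write_sam()] / [align_library()].
#' The `NH` tag is required (it drives unique-mapper selection downstream).
#'
#' @param path Path to a SAM file.
#' @return Alignment tibble with columns `read_id`, `chrom`, `pos`,
#'   `strand`, `width`, `seq`, `nh`, `nm` plus truth columns when present.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          width = integer(), seq = character(),
                          nh = integer(), nm = integer()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 11L)) {
    bad <- which(nfield < 11L)[1L] + sum(startsWith(lines, "@"))
    stop(sprintf("parse error in %s at line %d: fewer than 11 SAM fields", path, bad),
         call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  tag_val <- function(tag) {
    pre <- paste0(tag, ":")
    vapply(fields, function(f) {
      hit <- f[startsWith(f, pre)]
      if (length(hit) == 0L) NA_character_ else sub("^..:.:", "", hit[1L])
    }, character(1))
  }
  flag <- as.integer(get(2L))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  seq_stored <- get(10L)
  seq_read <- seq_stored
  rev_idx <- strand == "-"
  if (any(rev_idx)) {
    seq_read[rev_idx] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq_stored[rev_idx])))
  }
  nh <- tag_val("NH")
  if (anyNA(nh)) {
    stop(sprintf("format error in %s: missing NH tag on %d record(s)",
                 path, sum(is.na(nh))), call. = FALSE)
  }
  out <- tibble::tibble(read_id = get(1L), chrom = get(3L),
                        pos = as.integer(get(4L)), strand = strand,
                        width = nchar(seq_stored), seq = seq_read,
                        nh = as.integer(nh),
                        nm = as.integer(tag_val("NM")))
  xg <- tag_val("XG")
  if (!anyNA(xg)) {
    out$gene_id <- xg
    out$tstart <- as.integer(tag_val("XB"))
    out$tstop <- as.integer(tag_val("XE"))
  }
  out
}

#' Read a BED6+1 annotation file
#'
#' On disk the intervals are 0-based half-open (BED convention) with a
#' seventh `family` column; they are converted exactly once, here, to the
#' package-internal 1-based closed convention carried by `GRanges`.
#'
#' @param path Path to a BED file written by [write_bed()].
#' @return A `GRanges` with metadata columns `gene_id` and `family`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(family = "character"))
  S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, c("gene_id", "family")]
  gr
}

#' Write annotations to BED6+1
#'
#' @param annotations A `GRanges` with `gene_id` and `family` metadata
#'   columns (1-based closed internally; written 0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotations, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotations)),
    start0 = GenomicRanges::start(annotations) - 1L,
    end = GenomicRanges::end(annotations),
    name = S4Vectors::mcols(annotations)$gene_id,
    score = 0L,
    strand = as.character(GenomicRanges::strand(annotations)),
    family = S4Vectors::mcols(annotations)$family)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV
#'
#' UTF-8, tab-delimited, single header row, deterministic column order.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_file <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
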