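#' Validated RNA/DNA sequence
#'
#' A minimal container for a single-stranded nucleic acid sequence. The
#' alphabet is checked against the `is_dna` flag: RNA sequences must use
#' `{A,C,G,U}`, DNA sequences `{A,C,G,T}`. Mixed alphabets are rejected;
#' U/T interconversion is always explicit (see [probe_complementarity()]).
#'
#' @param id Short label for the sequence.
#' @param residues Character scalar of residues (case-insensitive on input,
#'   stored upper-case).
#' @param is_dna Logical; `TRUE` for DNA, `FALSE` (default) for RNA.
#' @return An object of class `rna_seq` with fields `id`, `residues`,
#'   `is_dna`.
#' @examples
#' rna_seq("motif", "GUUGUGGG")
#' @export
rna_seq <- function(id, residues, is_dna = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L,
            is.logical(is_dna), length(is_dna) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) {
    stop("validation error: 'residues' must be non-empty", call. = FALSE)
  }
  alphabet <- if (is_dna) c("A", "C", "G", "T") else c("A", "C", "G", "U")
  letters_seen <- unique(strsplit(residues, "", fixed = TRUE)[[1L]])
  bad <- setdiff(letters_seen, alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("validation error: residues of '%s' contain %s, not in the %s alphabet {%s}",
                 id, paste(sQuote(bad), collapse = ", "),
                 if (is_dna) "DNA" else "RNA",
                 paste(alphabet, collapse = ",")), call. = FALSE)
  }
  structure(list(id = id, residues = residues, is_dna = is_dna),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq> %s (%s, %d nt)\n  %s\n",
              x$id, if (x$is_dna) "DNA" else "RNA",
              seq_length(x), x$residues))
  invisible(x)
}

#' Length of a sequence in residues
#' @param seq An [rna_seq()] object.
#' @return Integer number of residues.
#' @export
seq_length <- function(seq) {
  stopifnot(inherits(seq, "rna_seq"))
  nchar(seq$residues)
}

# Coerce a bare character or rna_seq to a residue string, checking alphabet
# compatibility with `is_dna`.
as_residues <- function(x, is_dna, what = "sequence") {
  if (inherits(x, "rna_seq")) {
    if (!identical(x$is_dna, is_dna)) {
      stop(sprintf("validation error: %s alphabet (is_dna=%s) does not match (is_dna=%s)",
                   what, x$is_dna, is_dna), call. = FALSE)
    }
    return(x$residues)
  }
  rna_seq(what, x, is_dna = is_dna)$residues
}

# All 1-based offsets at which `pattern` occurs in `text`, including
# overlapping occurrences (gregexpr would miss those).
all_match_starts <- function(text, pattern) {
  n <- nchar(text)
  m <- nchar(pattern)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  hits <- vapply(starts, function(p) substr(text, p, p + m - 1L) == pattern,
                 logical(1))
  starts[hits]
}

#' Find all occurrences of a motif in a sequence
#'
#' Exact string search for a motif, reporting every (possibly overlapping)
#' occurrence. The canonical RNY5 processing motif is the 8-mer
#' `GUUGUGGG` occupying positions 14-21 of the full-length 83-nt transcript
#' (see [rny5_motif()]).
#'
#' @param seq An [rna_seq()] object to search in.
#' @param motif Motif as a character scalar or [rna_seq()]; must use the
#'   same alphabet as `seq`.
#' @return Sorted integer vector of 1-based start positions (empty when the
#'   motif is absent).
#' @examples
#' find_motif(rny5_oligos()$RNY5_83mer, "GUUGUGGG")  # 14
#' @export
find_motif <- function(seq, motif) {
  stopifnot(inherits(seq, "rna_seq"))
  motif <- as_residues(motif, seq$is_dna, what = "motif")
  if (nchar(motif) == 0L) stop("validation error: motif must be non-empty", call. = FALSE)
  all_match_starts(seq$residues, motif)
}

#' Locate a fragment within a reference sequence
#'
#' Returns the smallest 1-based offset at which `fragment` occurs exactly in
#' `reference`. Used to place the printed processing products on the
#' full-length transcript: the 5' 31-mer sits at offset 1, the 3'-side
#' fragment at offset 52.
#'
#' @param fragment,reference [rna_seq()] objects on the same alphabet;
#'   `fragment` must be no longer than `reference`.
#' @return Integer scalar, the 1-based offset of the first exact occurrence.
#'   Signals a lookup error if the fragment does not occur.
#' @export
locate_fragment <- function(fragment, reference) {
  stopifnot(inherits(fragment, "rna_seq"), inherits(reference, "rna_seq"))
  if (!identical(fragment$is_dna, reference$is_dna)) {
    stop("validation error: fragment and reference alphabets differ", call. = FALSE)
  }
  if (seq_length(fragment) > seq_length(reference)) {
    stop("validation error: fragment longer than reference", call. = FALSE)
  }
  hits <- all_match_starts(reference$residues, fragment$residues)
  if (length(hits) == 0L) {
    stop(sprintf("lookup error: '%s' is not a substring of '%s'",
                 fragment$id, reference$id), call. = FALSE)
  }
  hits[1L]
}

#' Perturb a sequence (deletion, replacement, or global shuffle)
#'
#' Implements the oligo perturbations used as processing/phenotype controls:
#' deleting a closed range (the "motif deleted" oligo removes 14-21 from the
#' 5' 31-mer), replacing a closed range in place (the "motif scrambled"
#' oligo substitutes `ACGUACAG` at 14-21), and a seeded permutation of all
#' residues (composition-preserving scramble).
#'
#' @param seq An [rna_seq()] object.
#' @param action One of `"delete_range"`, `"replace_range"`, `"shuffle_all"`.
#' @param start,end 1-based closed range (required for the range actions).
#' @param replacement Replacement string or [rna_seq()] for
#'   `"replace_range"`; must have the same alphabet as `seq` and the same
#'   length as the range.
#' @param seed Integer seed for `"shuffle_all"`.
#' @param id Label for the result (defaults to a derived label).
#' @return A new [rna_seq()] object.
#' @export
perturb <- function(seq, action = c("delete_range", "replace_range", "shuffle_all"),
                    start = NULL, end = NULL, replacement = NULL, seed = NULL,
                    id = NULL) {
  stopifnot(inherits(seq, "rna_seq"))
  action <- match.arg(action)
  n <- seq_length(seq)
  if (action %in% c("delete_range", "replace_range")) {
    if (is.null(start) || is.null(end)) {
      stop("validation error: 'start' and 'end' are required for range actions", call. = FALSE)
    }
    start <- as.integer(start); end <- as.integer(end)
    if (start < 1L || end > n || start > end) {
      stop(sprintf("range out of bounds: [%d,%d] not within [1,%d]", start, end, n),
           call. = FALSE)
    }
  }
  out <- switch(action,
    delete_range = paste0(substr(seq$residues, 1L, start - 1L),
                          substr(seq$residues, end + 1L, n)),
    replace_range = {
      repl <- as_residues(replacement, seq$is_dna, what = "replacement")
      if (nchar(repl) != end - start + 1L) {
        stop("validation error: replacement length does not equal range length",
             call. = FALSE)
      }
      paste0(substr(seq$residues, 1L, start - 1L), repl,
             substr(seq$residues, end + 1L, n))
    },
    shuffle_all = {
      if (is.null(seed)) stop("validation error: 'seed' is required for shuffle_all",
                              call. = FALSE)
      set.seed(as.integer(seed))
      paste(sample(strsplit(seq$residues, "", fixed = TRUE)[[1L]]), collapse = "")
    }
  )
  if (is.null(id)) id <- paste0(seq$id, "_", action)
  rna_seq(id, out, is_dna = seq$is_dna)
}

#' Residue composition of a sequence
#'
#' @param seq An [rna_seq()] object.
#' @return Named integer vector of residue counts over the sequence's full
#'   alphabet (zeros included); counts sum to [seq_length()].
#' @export
seq_composition <- function(seq) {
  stopifnot(inherits(seq, "rna_seq"))
  alphabet <- if (seq$is_dna) c("A", "C", "G", "T") else c("A", "C", "G", "U")
  counts <- table(factor(strsplit(seq$residues, "", fixed = TRUE)[[1L]],
                         levels = alphabet))
  out <- as.integer(counts)
  names(out) <- alphabet
  out
}

#' Reverse complement of a sequence
#'
#' @param seq An [rna_seq()] object.
#' @return An [rna_seq()] on the same alphabet (A pairs with U for RNA, with
#'   T for DNA).
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "rna_seq"))
  out <- if (seq$is_dna) chartr("ACGT", "TGCA", seq$residues) else
    chartr("ACGU", "UGCA", seq$residues)
  out <- paste(rev(strsplit(out, "", fixed = TRUE)[[1L]]), collapse = "")
  rna_seq(paste0(seq$id, "_rc"), out, is_dna = seq$is_dna)
}

#' Match a DNA probe against an RNA target by complementarity
#'
#' Emulates Northern probing: the probe hybridises to the span of the target
#' whose sequence equals the probe's reverse complement (with T mapped to
#' U). The packaged 32-nt probe ([northern_probe()]) matches positions 1-32
#' of the full-length RNY5 transcript, i.e. the 5' region covering the
#' processed 23/29/31-nt products.
#'
#' @param probe A DNA [rna_seq()] (`is_dna = TRUE`).
#' @param target An RNA [rna_seq()].
#' @return Named integer vector `c(start=, end=)` of the 1-based closed span
#'   on the target (first occurrence), or `NULL` when the probe does not
#'   hybridise.
#' @export
probe_complementarity <- function(probe, target) {
  stopifnot(inherits(probe, "rna_seq"), inherits(target, "rna_seq"))
  if (!probe$is_dna) stop("validation error: probe must be DNA", call. = FALSE)
  if (target$is_dna) stop("validation error: target must be RNA", call. = FALSE)
  rc_dna <- reverse_complement(probe)$residues
  rc_rna <- chartr("T", "U", rc_dna)
  hits <- all_match_starts(target$residues, rc_rna)
  if (length(hits) == 0L) return(NULL)
  c(start = hits[1L], end = hits[1L] + nchar(rc_rna) - 1L)
}

#' The RNY5 processing motif
#'
#' The 8-nt single-stranded motif `GUUGUGGG` occupying positions 14-21 of
#' the full-length RNY5 transcript, required for processing of the 5'
#' fragments and for the cell-death phenotype they trigger.
#'
#' @return List with `sequence`, `start_1based`, `end_1based`.
#' @export
rny5_motif <- function() {
  list(sequence = "GUUGUGGG", start_1based = 14L, end_1based = 21L)
}

#' Packaged RNY5 oligonucleotide set
#'
#' Loads the synthetic oligo set used throughout the processing and
#' phenotype analyses: the full-length 83-mer, the 5' 31- and 23-mers, the
#' completely scrambled 31-mer, the motif-deleted and motif-scrambled
#' variants, the 3'-side 32-mer, and the sense strand of the double-stranded
#' 31-mer duplex (its antisense strand is the 3'-side 32-mer).
#'
#' @return Named list of RNA [rna_seq()] objects.
#' @export
rny5_oligos <- function() {
  path <- system.file("extdata", "rny5_oligos.fasta", package = "evrny5",
                      mustWork = TRUE)
  seqs <- read_fasta(path)
  out <- lapply(names(seqs), function(nm) rna_seq(nm, seqs[[nm]], is_dna = FALSE))
  names(out) <- names(seqs)
  out
}

#' Packaged Northern probe
#'
#' The 32-nt DNA oligonucleotide complementary to the 5' end of the RNY5
#' transcript, used to detect the full-length RNA and its 5' processing
#' products.
#'
#' @return A DNA [rna_seq()].
#' @export
northern_probe <- function() {
  path <- system.file("extdata", "northern_probe.fasta", package = "evrny5",
                      mustWork = TRUE)
  seqs <- read_fasta(path)
  rna_seq(names(seqs)[1L], seqs[[1L]], is_dna = TRUE)
}
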