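# Toy reference genome: a main chromosome carrying a small-RNA gene set
# (including the real RNY5 sequence), plus decoy chromosomes carrying
# pseudogene loci that reproduce the multimapping behaviour of short 5'
# RNY5 fragments: reads starting at transcript position 1 and no longer
# than the shared 29-nt prefix map with 100% identity to the perfect
# decoys, while near decoys sit at ~97% identity.

DECOY_PREFIX_LEN <- 29L

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Two bases drawn to differ from `avoid` position-wise, so that reads
# extending past a perfect decoy's 29-nt core pick up guaranteed mismatches
# and stay unique to the parent gene.
rand_avoiding <- function(avoid) {
  vapply(strsplit(avoid, "", fixed = TRUE)[[1L]],
         function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
         character(1)) |> paste(collapse = "")
}

#' Gene set of the toy reference
#'
#' @return Tibble with `gene_id`, `family`, `length`. RNY5 carries the
#'   printed 83-nt transcript; all other genes are seeded random sequences
#'   standing in for typical members of their annotation family.
#' @export
default_gene_table <- function() {
  tibble::tribble(
    ~gene_id,     ~family,          ~length,
    "RNY5",       "miscRNA",        83L,
    "RNY1",       "miscRNA",        112L,
    "RNY3",       "miscRNA",        101L,
    "RNY4",       "miscRNA",        93L,
    "VTRNA1",     "miscRNA",        98L,
    "SCARNA9",    "miscRNA",        120L,
    "MIR21",      "miRNA",          72L,
    "MIR16",      "miRNA",          70L,
    "MIR143",     "miRNA",          68L,
    "TRNA_GLY",   "tRNA",           71L,
    "TRNA_GLU",   "tRNA",           72L,
    "RNA5S",      "rRNA",           121L,
    "RNA5_8S",    "rRNA",           157L,
    "SNORD44",    "snoRNA",         98L,
    "SNORA31",    "snoRNA",         131L,
    "RNU6",       "snRNA",          107L,
    "LINC01",     "lincRNA",        220L,
    "PCG1",       "protein_coding", 260L,
    "ASRNA1",     "antisense",      150L,
    "PSGX",       "pseudogene",     140L
  )
}

#' Configuration for the toy reference
#'
#' @param seed Integer seed controlling the random gene/filler sequences and
#'   near-decoy mismatch placement.
#' @param n_perfect_decoys Number of pseudogene loci carrying the first
#'   29 nt of RNY5 at 100% identity (default 2).
#' @param n_near_decoys Number of pseudogene loci at ~97% identity
#'   (default 3).
#' @param near_identity Fractional identity of near decoys over the 29-nt
#'   core (default 0.97, i.e. one mismatch).
#' @param gap Filler length between annotated loci (default 50).
#' @param genes Gene table as from [default_gene_table()].
#' @return List of class `reference_config`.
#' @export
reference_config <- function(seed = 1103L, n_perfect_decoys = 2L,
                             n_near_decoys = 3L, near_identity = 0.97,
                             gap = 50L, genes = default_gene_table()) {
  stopifnot(n_perfect_decoys >= 0L, n_near_decoys >= 0L,
            near_identity > 0, near_identity <= 1, gap >= 10L,
            all(c("gene_id", "family", "length") %in% names(genes)),
            !anyDuplicated(genes$gene_id), "RNY5" %in% genes$gene_id)
  structure(list(seed = as.integer(seed),
                 n_perfect_decoys = as.integer(n_perfect_decoys),
                 n_near_decoys = as.integer(n_near_decoys),
                 near_identity = near_identity, gap = as.integer(gap),
                 genes = genes),
            class = "reference_config")
}

#' Build the toy reference bundle
#'
#' Assembles the chromosomes, the gene annotations (1-based closed,
#' `GRanges`), and the pseudogene decoy set. RNY5 is embedded on the `+`
#' strand of the main chromosome with its printed 83-nt sequence; perfect
#' decoys share exactly its first 29 nt (the two bases following each decoy
#' are forced to mismatch RNY5 positions 30-31 so that longer reads stay
#' unique); near decoys carry seeded mismatches over the same 29-nt core.
#' Deterministic for a given config.
#'
#' @param config A [reference_config()].
#' @return List of class `reference_bundle` with elements `chromosomes`
#'   (`DNAStringSet`), `annotations` (`GRanges` with `gene_id`, `family`),
#'   `pseudogene_set` (named list: parent gene -> decoy gene ids), `genes`
#'   (the gene table) and `config`.
#' @export
build_reference <- function(config = reference_config()) {
  stopifnot(inherits(config, "reference_config"))
  set.seed(config$seed)
  genes <- config$genes
  rny5_dna <- chartr("U", "T", rny5_oligos()$RNY5_83mer$residues)

  # chr1: gap + gene + gap + gene ...
  pieces <- character(0)
  starts <- integer(nrow(genes))
  offset <- 0L
  for (i in seq_len(nrow(genes))) {
    filler <- rand_dna(config$gap)
    gseq <- if (genes$gene_id[i] == "RNY5") rny5_dna else rand_dna(genes$length[i])
    pieces <- c(pieces, filler, gseq)
    starts[i] <- offset + config$gap + 1L
    offset <- offset + config$gap + nchar(gseq)
  }
  pieces <- c(pieces, rand_dna(config$gap))
  chr1 <- paste(pieces, collapse = "")

  ann <- tibble::tibble(chrom = "chr1", start = starts,
                        end = starts + genes$length - 1L,
                        gene_id = genes$gene_id, family = genes$family)

  core <- substr(rny5_dna, 1L, DECOY_PREFIX_LEN)
  guard <- substr(rny5_dna, DECOY_PREFIX_LEN + 1L, DECOY_PREFIX_LEN + 2L)
  decoy_ids <- character(0)
  chroms <- list(chr1 = chr1)

  place_decoys <- function(chrom_name, cores, id_offset) {
    pieces <- character(0)
    offset <- 0L
    rows <- vector("list", length(cores))
    for (j in seq_along(cores)) {
      filler <- rand_dna(config$gap)
      pieces <- c(pieces, filler, cores[[j]], rand_avoiding(guard),
                  rand_dna(config$gap))
      start <- offset + config$gap + 1L
      offset <- offset + config$gap + DECOY_PREFIX_LEN + 2L + config$gap
      rows[[j]] <- tibble::tibble(chrom = chrom_name, start = start,
                                  end = start + DECOY_PREFIX_LEN - 1L,
                                  gene_id = sprintf("RNY5P%d", id_offset + j),
                                  family = "pseudogene")
    }
    list(seq = paste(pieces, collapse = ""), ann = dplyr::bind_rows(rows))
  }

  if (config$n_perfect_decoys > 0L) {
    perfect <- place_decoys("chr2", rep(list(core), config$n_perfect_decoys), 0L)
    chroms$chr2 <- perfect$seq
    ann <- dplyr::bind_rows(ann, perfect$ann)
    decoy_ids <- c(decoy_ids, perfect$ann$gene_id)
  }
  if (config$n_near_decoys > 0L) {
    n_mm <- max(1L, round(DECOY_PREFIX_LEN * (1 - config$near_identity)))
    near_cores <- lapply(seq_len(config$n_near_decoys), function(j) {
      s <- strsplit(core, "", fixed = TRUE)[[1L]]
      pos <- sample(DECOY_PREFIX_LEN, n_mm)
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      paste(s, collapse = "")
    })
    near <- place_decoys("chr3", near_cores, config$n_perfect_decoys)
    chroms$chr3 <- near$seq
    ann <- dplyr::bind_rows(ann, near$ann)
    decoy_ids <- c(decoy_ids, near$ann$gene_id)
  }

  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = "+", gene_id = ann$gene_id, family = ann$family)
  self <- GenomicRanges::findOverlaps(gr, gr)
  if (length(self) > length(gr)) {
    stop("config error: overlapping annotations in the toy reference", call. = FALSE)
  }
  chrom_set <- Biostrings::DNAStringSet(unlist(chroms))
  if (any(GenomicRanges::end(gr) >
          Biostrings::width(chrom_set)[match(as.character(GenomicRanges::seqnames(gr)),
                                             names(chrom_set))])) {
    stop("config error: annotation outside chromosome bounds", call. = FALSE)
  }

  structure(list(chromosomes = chrom_set, annotations = gr,
                 pseudogene_set = list(RNY5 = decoy_ids),
                 genes = genes, config = config),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("<reference_bundle> %d chromosome(s), %d annotated loci (%d decoys)\n",
              length(x$chromosomes), length(x$annotations),
              length(x$pseudogene_set$RNY5)))
  invisible(x)
}

# DNA sequence of one annotated gene (transcript orientation; all genes are
# on the + strand).
gene_sequence <- function(ref, gene_id) {
  gr <- ref$annotations[S4Vectors::mcols(ref$annotations)$gene_id == gene_id]
  if (length(gr) != 1L) stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  substr(as.character(ref$chromosomes[[chrom]]),
         GenomicRanges::start(gr), GenomicRanges::end(gr))
}

gene_annotation <- function(ref, gene_id) {
  gr <- ref$annotations[S4Vectors::mcols(ref$annotations)$gene_id == gene_id]
  if (length(gr) != 1L) stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  gr
}

#' Write the reference bundle to FASTA + BED
#'
#' @param ref A [build_reference()] bundle.
#' @param fasta_path,bed_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_reference <- function(ref, fasta_path, bed_path) {
  Biostrings::writeXStringSet(ref$chromosomes, fasta_path)
  write_bed(ref$annotations, bed_path)
  invisible(c(fasta = fasta_path, bed = bed_path))
}
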