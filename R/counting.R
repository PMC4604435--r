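# Union-mode gene counting on unique mappers, rpm normalisation, RNA-family
# abundance and EV-versus-cell comparisons.

CANONICAL_FAMILIES <- c("lincRNA", "miRNA", "miscRNA", "rRNA", "tRNA",
                        "snRNA", "snoRNA", "protein_coding")

# Normalise an alignment input (align_reads tibble or read_sam tibble) to
# the columns counting needs; NH is mandatory.
as_alignment_records <- function(aln) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_sam(aln)
  if (!"nh" %in% names(aln)) {
    stop("format error: alignment records lack an NH (hit count) column", call. = FALSE)
  }
  if (!"width" %in% names(aln)) aln$width <- nchar(aln$seq)
  aln
}

#' Union-mode gene counting on unique mappers
#'
#' Counts, per gene, the uniquely mapping reads (`NH == 1`) whose alignment
#' interval overlaps exactly one gene annotation ("union mode"): records
#' overlapping no gene are tallied as `no_feature`, records overlapping
#' more than one as `ambiguous`, and neither is counted. Multimapping
#' records (`NH > 1`) are excluded from counting and from the rpm
#' denominator. `rpm(g) = count(g) / total_unique * 1e6` with
#' `total_unique` the number of uniquely mapping reads in the library
#' (including `no_feature` reads).
#'
#' @param aln Alignment tibble (from [align_reads()] / [read_sam()]) or a
#'   path to a SAM file.
#' @param ref A [build_reference()] bundle, or a `GRanges` of annotations
#'   with `gene_id` and `family` metadata columns.
#' @param library_id Optional library label.
#' @return Tibble of class `gene_counts` with columns `gene_id`, `family`,
#'   `count`, `rpm` (one row per annotated gene). Attributes:
#'   `library_id`, `total_unique`, `n_counted`, `n_no_feature`,
#'   `n_ambiguous`, `n_multimapper`, `n_records`.
#' @export
count_genes <- function(aln, ref, library_id = NULL) {
  aln <- as_alignment_records(aln)
  ann <- if (inherits(ref, "reference_bundle")) ref$annotations else ref
  stopifnot(all(c("gene_id", "family") %in% names(S4Vectors::mcols(ann))))

  uniq <- aln[aln$nh == 1L, ]
  n_multi <- nrow(aln) - nrow(uniq)

  gene_ids <- S4Vectors::mcols(ann)$gene_id
  if (nrow(uniq) > 0L) {
    rec <- GenomicRanges::GRanges(
      seqnames = uniq$chrom,
      ranges = IRanges::IRanges(start = uniq$pos, width = uniq$width))
    ov <- GenomicRanges::findOverlaps(rec, ann, ignore.strand = TRUE)
    n_genes_per_rec <- tabulate(S4Vectors::queryHits(ov), nbins = nrow(uniq))
    assigned <- n_genes_per_rec == 1L
    ov_keep <- ov[assigned[S4Vectors::queryHits(ov)]]
    counts <- tabulate(S4Vectors::subjectHits(ov_keep), nbins = length(ann))
    n_no_feature <- sum(n_genes_per_rec == 0L)
    n_ambiguous <- sum(n_genes_per_rec > 1L)
  } else {
    counts <- integer(length(ann))
    n_no_feature <- 0L
    n_ambiguous <- 0L
  }

  total_unique <- nrow(uniq)
  out <- tibble::tibble(gene_id = gene_ids,
                        family = S4Vectors::mcols(ann)$family,
                        count = as.integer(counts),
                        rpm = if (total_unique > 0)
                          counts / total_unique * 1e6 else rep(0, length(ann)))
  attr(out, "library_id") <- library_id
  attr(out, "total_unique") <- total_unique
  attr(out, "n_counted") <- sum(counts)
  attr(out, "n_no_feature") <- n_no_feature
  attr(out, "n_ambiguous") <- n_ambiguous
  attr(out, "n_multimapper") <- n_multi
  attr(out, "n_records") <- nrow(aln)
  class(out) <- c("gene_counts", class(out))
  out
}

#' RNA-family abundance table
#'
#' Aggregates per-gene rpm into annotation families; families outside the
#' canonical set (lincRNA, miRNA, miscRNA, rRNA, tRNA, snRNA, snoRNA,
#' protein_coding) are folded into an `"Others"` bucket. Fractions are of
#' total gene-assigned rpm and sum to 1.
#'
#' @param counts A [count_genes()] table.
#' @param families Canonical family vocabulary (character vector).
#' @return Tibble `family`, `rpm`, `fraction`, sorted by decreasing rpm;
#'   attribute `others_members` lists the genes folded into `"Others"`.
#' @export
family_table <- function(counts, families = CANONICAL_FAMILIES) {
  if (anyNA(counts$family)) {
    stop("config error: unlabeled gene(s) in the annotation set", call. = FALSE)
  }
  fam <- ifelse(counts$family %in% families, counts$family, "Others")
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(family = fam, rpm = counts$rpm), .data$family),
    rpm = sum(.data$rpm), .groups = "drop")
  total <- sum(agg$rpm)
  agg$fraction <- if (total > 0) agg$rpm / total else 0
  agg <- dplyr::arrange(agg, dplyr::desc(.data$rpm))
  attr(agg, "others_members") <- counts$gene_id[!(counts$family %in% families) &
                                                  counts$count > 0]
  agg
}

#' EV-versus-cell rpm fold enrichment of one gene
#'
#' @param ev_counts,cell_counts Paired [count_genes()] tables from the same
#'   cell line.
#' @param gene Gene id present in both tables.
#' @return Positive numeric fold `rpm_ev / rpm_cell`; `Inf` with a warning
#'   when the whole-cell rpm is zero.
#' @export
enrichment <- function(ev_counts, cell_counts, gene) {
  rpm_ev <- ev_counts$rpm[match(gene, ev_counts$gene_id)]
  rpm_cell <- cell_counts$rpm[match(gene, cell_counts$gene_id)]
  if (is.na(rpm_ev) || is.na(rpm_cell)) {
    stop(sprintf("gene '%s' absent from one of the count tables", gene), call. = FALSE)
  }
  if (rpm_cell == 0) {
    warning(sprintf("zero whole-cell rpm for '%s': enrichment reported as Inf", gene))
    return(Inf)
  }
  rpm_ev / rpm_cell
}

#' Per-gene EV / (EV + cell) rpm ratio
#'
#' The compartment-preference statistic: 1 for genes detected only in EVs,
#' 0.5 for genes at equal rpm in both compartments, 0 for cell-only genes.
#' Genes absent from both libraries are omitted.
#'
#' @param ev_counts,cell_counts Paired [count_genes()] tables.
#' @return Tibble `gene_id`, `rpm_ev`, `rpm_cell`, `ratio` with
#'   `ratio` in `[0, 1]`.
#' @export
ev_cell_ratio <- function(ev_counts, cell_counts) {
  m <- dplyr::full_join(
    tibble::tibble(gene_id = ev_counts$gene_id, rpm_ev = ev_counts$rpm),
    tibble::tibble(gene_id = cell_counts$gene_id, rpm_cell = cell_counts$rpm),
    by = "gene_id")
  m$rpm_ev[is.na(m$rpm_ev)] <- 0
  m$rpm_cell[is.na(m$rpm_cell)] <- 0
  m <- m[m$rpm_ev + m$rpm_cell > 0, ]
  m$ratio <- m$rpm_ev / (m$rpm_ev + m$rpm_cell)
  m
}

#' Replicate correlation on log rpm
#'
#' Pearson correlation of `log10(rpm + 1)` over genes expressed in either
#' library; a reproducibility summary for replicate pairs.
#'
#' @param counts_a,counts_b [count_genes()] tables over the same annotation
#'   set.
#' @return Numeric correlation coefficient.
#' @export
replicate_correlation <- function(counts_a, counts_b) {
  stopifnot(identical(counts_a$gene_id, counts_b$gene_id))
  keep <- counts_a$rpm > 0 | counts_b$rpm > 0
  stats::cor(log10(counts_a$rpm[keep] + 1), log10(counts_b$rpm[keep] + 1),
             method = "pearson")
}
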