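# Rule-based simulator of the in vitro RNY5 processing assay: whole-cell
# protein extracts leave every substrate untouched, while EV extracts cut
# motif-bearing 5'-intact substrates into the canonical 23/29/31-nt forms.

#' Classify a processing substrate
#'
#' Classification drives the rule table of [simulate_processing()]:
#' * `"motif_intact"` — carries the 8-nt motif ([rny5_motif()]) and an
#'   intact RNY5 5' flank (positions 1-13), single-stranded;
#' * `"motif_perturbed"` — intact 5' flank but the motif scrambled or
#'   deleted;
#' * `"double_stranded"` — duplex substrate (the motif is sequestered);
#' * `"unrelated"` — no RNY5 5' flank (fully scrambled oligos, the 3'-side
#'   fragment).
#'
#' @param substrate An RNA [rna_seq()].
#' @param double_stranded Logical; `TRUE` for duplex substrates.
#' @return Character scalar, one of the classes above.
#' @export
classify_substrate <- function(substrate, double_stranded = FALSE) {
  stopifnot(inherits(substrate, "rna_seq"), !substrate$is_dna)
  if (double_stranded) return("double_stranded")
  full <- rny5_oligos()$RNY5_83mer
  flank <- substr(full$residues, 1L, rny5_motif()$start_1based - 1L)
  has_flank <- startsWith(substrate$residues, flank)
  has_motif <- length(find_motif(substrate, rny5_motif()$sequence)) > 0L
  if (has_flank && has_motif) return("motif_intact")
  if (has_flank) return("motif_perturbed")
  "unrelated"
}

#' Simulate in vitro processing of an RNY5 substrate
#'
#' Deterministic rule table over substrate class and extract type:
#' * whole-cell extract: no detectable processing for any substrate;
#' * EV extract, motif-intact substrate: all canonical 5' forms (23, 29,
#'   31 nt) strictly shorter than the substrate appear at full abundance,
#'   plus the remaining substrate;
#' * EV extract, motif-perturbed substrate longer than 23 nt: residual
#'   23-nt product only;
#' * EV extract, double-stranded or unrelated substrate: no products.
#'
#' @param substrate An RNA [rna_seq()].
#' @param extract `"whole_cell"` or `"ev"`.
#' @param double_stranded Logical; `TRUE` for duplex substrates.
#' @return Tibble `length`, `abundance` (`"full"`, `"residual"`, or
#'   `"remaining"` for the uncut substrate); zero rows when no processing
#'   occurs.
#' @export
simulate_processing <- function(substrate, extract = c("whole_cell", "ev"),
                                double_stranded = FALSE) {
  extract <- match.arg(extract)
  cls <- classify_substrate(substrate, double_stranded = double_stranded)
  len <- seq_length(substrate)
  none <- tibble::tibble(length = integer(), abundance = character())

  if (extract == "whole_cell") return(none)
  switch(cls,
    motif_intact = {
      cuts <- c(23L, 29L, 31L)
      cuts <- cuts[cuts < len]
      if (length(cuts) == 0L) return(none)
      tibble::tibble(length = c(cuts, len),
                     abundance = c(rep("full", length(cuts)), "remaining"))
    },
    motif_perturbed = {
      if (len <= 23L) return(none)
      tibble::tibble(length = c(23L, len),
                     abundance = c("residual", "remaining"))
    },
    double_stranded = none,
    unrelated = none
  )
}

#' Run the processing rules over the packaged oligo panel
#'
#' Applies [simulate_processing()] to every printed substrate with both
#' extract types, reproducing the in vitro assay layout.
#'
#' @return Tibble `substrate`, `extract`, `class`, `product_lengths`
#'   (comma-separated), `n_products`.
#' @export
processing_panel <- function() {
  oligos <- rny5_oligos()
  panel <- tibble::tribble(
    ~substrate,             ~ds,
    "RNY5_83mer",           FALSE,
    "RNY5_31mer",           FALSE,
    "RNY5_23mer",           FALSE,
    "RNY5_31mer_scrambled", FALSE,
    "RNY5_motif_scrambled", FALSE,
    "RNY5_motif_deleted",   FALSE,
    "RNY5_3p_32mer",        FALSE,
    "RNY5_ds_sense_32mer",  TRUE
  )
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    s <- oligos[[panel$substrate[i]]]
    dplyr::bind_rows(lapply(c("whole_cell", "ev"), function(ex) {
      prod <- simulate_processing(s, ex, double_stranded = panel$ds[i])
      prod_only <- prod[prod$abundance != "remaining", ]
      tibble::tibble(
        substrate = panel$substrate[i], extract = ex,
        class = classify_substrate(s, double_stranded = panel$ds[i]),
        product_lengths = paste(prod_only$length, collapse = ","),
        n_products = nrow(prod_only))
    }))
  })
  dplyr::bind_rows(rows)
}
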