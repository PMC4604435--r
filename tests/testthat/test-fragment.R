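# Hand-built 8-read fixture over RNY5 (chr1, gene start s):
# five unique mappers at transcript spans (1,31) x3, (52,83) x1, (1,83) x1,
# one multimapper (1,23) explainable by the gene + its decoys,
# one multimapper with a locus outside the pseudogene set,
# one unique mapper on another gene (must be ignored).
make_fragment_fixture <- function(ref) {
  s <- GenomicRanges::start(evrny5:::gene_annotation(ref, "RNY5"))
  decoy1 <- evrny5:::gene_annotation(ref, ref$pseudogene_set$RNY5[1])
  mir <- evrny5:::gene_annotation(ref, "MIR21")
  tibble::tibble(
    read_id = c("u1", "u2", "u3", "u4", "u5",
                "m1", "m1",
                "m2", "m2",
                "x1"),
    chrom = c(rep("chr1", 5),
              "chr1", as.character(GenomicRanges::seqnames(decoy1)),
              "chr1", "chr1",
              "chr1"),
    pos = c(s, s, s, s + 51L, s,
            s, GenomicRanges::start(decoy1),
            s, 1L,
            GenomicRanges::start(mir)),
    strand = "+",
    width = c(31L, 31L, 31L, 32L, 83L,
              23L, 23L,
              23L, 23L,
              22L),
    nh = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L))
}

test_that("fragment histograms match a manual tally of the 8-read fixture", {
  ref <- test_ref()
  fx <- make_fragment_fixture(ref)
  fp <- profile_gene(fx, ref, "RNY5", threshold = 0, total_unique = 6L)
  # include policy: u1..u5 plus m1 (all loci in gene+decoys); m2 has a
  # locus outside the set and x1 is on another gene
  expect_equal(fp$n_reads, 6L)
  frag <- as.data.frame(fp$fragments[order(fp$fragments$start, fp$fragments$stop), ])
  expect_equal(frag$start, c(1L, 1L, 1L, 52L))
  expect_equal(frag$stop, c(23L, 31L, 83L, 83L))
  expect_equal(frag$n, c(1L, 3L, 1L, 1L))
  # rpm normalised by the library's unique-mapper total (6 here)
  expect_equal(frag$rpm, c(1, 3, 1, 1) / 6 * 1e6)
  # start histogram sums equal stop histogram sums
  expect_equal(sum(fp$start_hist$rpm), sum(fp$stop_hist$rpm))
  # exclude policy drops the multimapper
  fpx <- profile_gene(fx, ref, "RNY5", policy = "exclude_multimappers",
                      threshold = 0, total_unique = 6L)
  expect_equal(fpx$n_reads, 5L)
  expect_false(23L %in% fpx$fragments$stop)
  expect_error(profile_gene(fx, ref, "NOPE"), "unknown gene")
})

test_that("positions stay within the gene and clipping is flagged", {
  ref <- test_ref()
  s <- GenomicRanges::start(evrny5:::gene_annotation(ref, "RNY5"))
  over <- tibble::tibble(read_id = "o1", chrom = "chr1", pos = s + 70L,
                         strand = "+", width = 40L, nh = 1L)
  fp <- profile_gene(over, ref, "RNY5", threshold = 0, total_unique = 1L)
  expect_equal(fp$n_clipped, 1L)
  expect_equal(fp$fragments$start, 71L)
  expect_equal(fp$fragments$stop, 83L)
  expect_true(all(fp$start_hist$position >= 1 &
                    fp$start_hist$position <= fp$gene_length))
})

test_that("with no decoys and error-free reads the profile equals the truth model", {
  run <- clean_run()
  truth <- run$sim[run$sim$gene_id == "RNY5", ]
  fp <- profile_gene(run$aln, run$ref, "RNY5",
                     policy = "exclude_multimappers", threshold = 0)
  truth_tab <- dplyr::count(tibble::as_tibble(truth), tstart, tstop, name = "n")
  frag <- fp$fragments[order(fp$fragments$start, fp$fragments$stop), ]
  truth_tab <- truth_tab[order(truth_tab$tstart, truth_tab$tstop), ]
  expect_equal(frag$start, truth_tab$tstart)
  expect_equal(frag$stop, truth_tab$tstop)
  expect_equal(frag$n, truth_tab$n)
})

test_that("threshold monotonicity and include-policy dominance hold", {
  run <- big_bj_ev()
  ref <- test_ref()
  fp_lo <- profile_gene(run$aln, ref, "RNY5", threshold = 500)
  fp_hi <- profile_gene(run$aln, ref, "RNY5", threshold = 5000)
  expect_true(all(fp_hi$frequent_starts %in% fp_lo$frequent_starts))
  expect_true(all(fp_hi$frequent_stops %in% fp_lo$frequent_stops))
  fp_inc <- profile_gene(run$aln, ref, "RNY5", policy = "include_pseudogene_set")
  fp_exc <- profile_gene(run$aln, ref, "RNY5", policy = "exclude_multimappers")
  m <- merge(as.data.frame(fp_exc$start_hist), as.data.frame(fp_inc$start_hist),
             by = "position", all.x = TRUE)
  expect_true(all(m$rpm.x <= m$rpm.y + 1e-9))
})

test_that("length spectrum reflects the paired start/stop records", {
  run <- clean_run()
  fp <- profile_gene(run$aln, run$ref, "RNY5", threshold = 0)
  spec <- fragment_length_spectrum(fp)
  expect_setequal(spec$length, c(23L, 29L, 31L, 32L, 83L))
  # single-read input of span 1-31
  one <- tibble::tibble(read_id = "r", chrom = "chr1",
                        pos = GenomicRanges::start(
                          evrny5:::gene_annotation(run$ref, "RNY5")),
                        strand = "+", width = 31L, nh = 1L)
  fp1 <- profile_gene(one, run$ref, "RNY5", threshold = 0, total_unique = 1L)
  spec1 <- fragment_length_spectrum(fp1)
  expect_equal(spec1$length, 31L)
  expect_equal(spec1$rpm, 1e6)
})

test_that("whole-cell libraries are dominated by the full-length form", {
  ref <- test_ref()
  prof <- default_library_profiles(ref, read_count = 1e5)$bj_cell
  sim <- simulate_library(prof, ref, seed = 88L)
  aln <- align_reads(sim, ref)
  fp <- profile_gene(aln, ref, "RNY5", threshold = 0)
  spec <- fragment_length_spectrum(fp)
  expect_equal(spec$length[which.max(spec$rpm)], 83L)
})
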