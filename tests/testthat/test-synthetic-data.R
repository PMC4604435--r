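test_that("toy reference embeds RNY5 and the configured decoy structure", {
  ref <- test_ref()
  ann <- ref$annotations
  rny5 <- ann[S4Vectors::mcols(ann)$gene_id == "RNY5"]
  expect_equal(GenomicRanges::width(rny5), 83L)
  expect_identical(as.character(GenomicRanges::strand(rny5)), "+")
  # the annotated locus carries the printed transcript (U -> T)
  expect_identical(evrny5:::gene_sequence(ref, "RNY5"),
                   chartr("U", "T", rny5_oligos()$RNY5_83mer$residues))
  # 2 perfect + 3 near decoys by default
  expect_length(ref$pseudogene_set$RNY5, 5L)
  decoys <- ann[S4Vectors::mcols(ann)$gene_id %in% ref$pseudogene_set$RNY5]
  expect_true(all(GenomicRanges::width(decoys) == 29L))
  # perfect decoys share exactly the 29-nt prefix; near decoys differ
  core <- substr(evrny5:::gene_sequence(ref, "RNY5"), 1, 29)
  decoy_seq <- vapply(ref$pseudogene_set$RNY5,
                      function(g) evrny5:::gene_sequence(ref, g), character(1))
  expect_equal(sum(decoy_seq == core), 2L)
  near <- decoy_seq[decoy_seq != core]
  mism <- vapply(near, function(s) sum(charToRaw(s) != charToRaw(core)),
                 integer(1))
  expect_true(all(mism == 1L))  # 97% identity over 29 nt = one mismatch
  # deterministic rebuild
  expect_identical(as.character(ref$chromosomes),
                   as.character(build_reference()$chromosomes))
})

test_that("a 23-nt 5' RNY5 read multimaps on the default reference but is unique without decoys", {
  ref <- test_ref()
  read23 <- substr(evrny5:::gene_sequence(ref, "RNY5"), 1, 23)
  hits <- oracle_align(read23, ref)
  expect_gte(nrow(hits), 3L)
  # and a 31-nt 5' read is unique (post-decoy bases are forced mismatches)
  read31 <- substr(evrny5:::gene_sequence(ref, "RNY5"), 1, 31)
  expect_equal(nrow(oracle_align(read31, ref)), 1L)
  ref0 <- test_ref_nodecoys()
  expect_equal(nrow(oracle_align(read23, ref0)), 1L)
})

test_that("profile construction validates shares and calibrates truth fractions", {
  ref <- test_ref()
  expect_error(
    library_profile("bad", c(RNY5 = 0.6, RNY1 = 0.3), list(), ref),
    "sum to")
  profs <- default_library_profiles(ref)
  for (p in profs) {
    expect_equal(sum(p$gene_shares), 1, tolerance = 1e-12)
    expect_equal(sum(p$truth_fractions), 1, tolerance = 1e-12)
  }
  # EV profiles carry multimapping 5'-fragment mass for RNY5, so the truth
  # fraction is calibrated above the measured-share anchor
  expect_gt(profs$bj_ev$multimap_mass[["RNY5"]], 0)
  expect_gt(profs$bj_ev$truth_fractions[["RNY5"]],
            profs$bj_ev$gene_shares[["RNY5"]])
  # fragment (start, stop) pairs lie within their gene
  for (g in names(profs$bj_ev$fragment_models)) {
    fm <- profs$bj_ev$fragment_models[[g]]
    len <- ref$genes$length[ref$genes$gene_id == g]
    expect_true(all(fm$start >= 1 & fm$stop <= len & fm$start <= fm$stop))
  }
  # without decoys there is nothing to calibrate against
  p0 <- default_library_profiles(test_ref_nodecoys())$bj_ev
  expect_equal(p0$truth_fractions[["RNY5"]], p0$gene_shares[["RNY5"]])
})

test_that("simulated libraries hit their truth fractions and are reproducible", {
  ref <- test_ref()
  prof <- default_library_profiles(ref, read_count = 5e4)$bj_ev
  sim1 <- simulate_library(prof, ref, seed = 31L)
  sim2 <- simulate_library(prof, ref, seed = 31L)
  expect_identical(sim1, sim2)
  sim3 <- simulate_library(prof, ref, seed = 32L)
  expect_false(identical(sim1$seq, sim3$seq))
  # multinomial 3-sigma check of the calibrated RNY5 truth fraction
  f <- prof$truth_fractions[["RNY5"]]
  obs <- mean(sim1$gene_id == "RNY5")
  expect_lt(abs(obs - f), 3 * sqrt(f * (1 - f) / nrow(sim1)))
  # the calibrated fraction stays in the neighbourhood of the printed
  # EV abundance anchor
  expect_lt(abs(f - prof$gene_shares[["RNY5"]]), 0.05)
  # FASTQ emission is byte-identical for the same seed
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(sim1$read_id, sim1$seq, f1)
  write_fastq(sim2$read_id, sim2$seq, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("error-free reads are exact substrings of their source locus", {
  run <- clean_run()
  sim <- run$sim
  expect_true(all(sim$n_errors == 0L))
  chrom_seq <- as.character(run$ref$chromosomes)
  idx <- sample(nrow(sim), 500)
  ok <- vapply(idx, function(i) {
    substr(chrom_seq[[sim$chrom[i]]], sim$gstart[i], sim$gend[i]) == sim$seq[i]
  }, logical(1))
  expect_true(all(ok))
})

test_that("fragment-model sampling matches configured probabilities (chi-square GOF)", {
  ref <- test_ref()
  prof <- default_library_profiles(ref, read_count = 1e5)$bj_ev
  sim <- simulate_library(prof, ref, seed = 77L)
  rny5 <- sim[sim$gene_id == "RNY5", ]
  fm <- prof$fragment_models$RNY5
  key <- paste(rny5$tstart, rny5$tstop)
  obs <- as.vector(table(factor(key, levels = paste(fm$start, fm$stop))))
  gof <- stats::chisq.test(obs, p = fm$weight)
  expect_gt(gof$p.value, 0.01)
})

test_that("processing rules reproduce the in vitro assay outcomes", {
  ol <- rny5_oligos()
  # whole-cell extract: no detectable processing of the full-length RNA
  expect_equal(nrow(simulate_processing(ol$RNY5_83mer, "whole_cell")), 0L)
  # EV extract: all processed forms plus remaining substrate
  p <- simulate_processing(ol$RNY5_83mer, "ev")
  expect_setequal(p$length[p$abundance == "full"], c(23L, 29L, 31L))
  expect_true(83L %in% p$length[p$abundance == "remaining"])
  # the 31-mer still yields the 23-nt product
  p31 <- simulate_processing(ol$RNY5_31mer, "ev")
  expect_true(23L %in% p31$length[p31$abundance == "full"])
  # motif scrambled: residual 23-nt product only
  pm <- simulate_processing(ol$RNY5_motif_scrambled, "ev")
  expect_equal(pm$length[pm$abundance == "residual"], 23L)
  expect_equal(sum(pm$abundance == "full"), 0L)
  # completely scrambled or double-stranded: nothing
  expect_equal(nrow(simulate_processing(ol$RNY5_31mer_scrambled, "ev")), 0L)
  expect_equal(nrow(simulate_processing(ol$RNY5_ds_sense_32mer, "ev",
                                        double_stranded = TRUE)), 0L)
  # every printed substrate is covered by some rule
  panel <- processing_panel()
  expect_equal(nrow(panel), 16L)
  expect_false(anyNA(panel$n_products))
})

test_that("cytometry generator hits configured dead fractions and is seeded", {
  cond <- cyto_condition("half", 0.5, n_events = 1e4, seed = 9L)
  ev1 <- simulate_cytometry(cond)
  ev2 <- simulate_cytometry(cond)
  expect_identical(ev1, ev2)
  realized <- mean(ev1$true_class[ev1$true_class != "debris"] == "dead")
  expect_lt(abs(realized - 0.5), 3 * sqrt(0.25 / 1e4))
  # dead population is shifted upward in the viability channel
  expect_gt(mean(ev1$yopro[ev1$true_class == "dead"]),
            mean(ev1$yopro[ev1$true_class == "live"]))
  expect_error(cyto_condition("bad", 1.5), "dead_fraction")
  expect_error(cyto_condition("bad", 0.2, yopro_pos = c(1, 1),
                              yopro_neg = c(2, 1)), "shifted upward")
})

test_that("mixed-species preset spikes RNY5 into an RNY5-free background", {
  ref <- test_ref()
  prof <- mixed_species_profile(ref, rny5_share = 0.05, read_count = 3e4)
  expect_equal(sum(prof$gene_shares), 1, tolerance = 1e-12)
  sim <- simulate_library(prof, ref, seed = 91L)
  aln <- align_reads(sim, ref)
  ct <- count_genes(aln, ref, "mixed")
  share <- ct$rpm[ct$gene_id == "RNY5"] / sum(ct$rpm)
  expect_lt(abs(share - 0.05), 3 * sqrt(0.05 * 0.95 / attr(ct, "n_counted")))
  # only RNY5 carries the EV fragment signature
  rny5 <- sim[sim$gene_id == "RNY5", ]
  expect_setequal(unique(rny5$tstop[rny5$tstart == 1L]), c(23L, 29L, 31L, 83L))
})
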