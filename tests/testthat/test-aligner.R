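test_that("aligner agrees with the brute-force oracle on random reads", {
  ref <- test_ref()  # ~4.7 kb over three chromosomes
  chrom_seq <- as.character(ref$chromosomes)
  set.seed(101)
  reads <- character(1000)
  for (i in seq_along(reads)) {
    kind <- sample(c("exact", "mutated", "random"), 1,
                   prob = c(0.4, 0.4, 0.2))
    if (kind == "random") {
      reads[i] <- random_dna_str(sample(15:40, 1))
    } else {
      chrom <- sample(names(chrom_seq), 1)
      w <- sample(15:40, 1)
      p <- sample(nchar(chrom_seq[[chrom]]) - w, 1)
      s <- substr(chrom_seq[[chrom]], p, p + w - 1L)
      if (kind == "mutated") {
        sv <- strsplit(s, "", fixed = TRUE)[[1L]]
        for (q in sample(w, sample(1:6, 1)))
          sv[q] <- sample(setdiff(c("A", "C", "G", "T"), sv[q]), 1)
        s <- paste(sv, collapse = "")
      }
      if (stats::runif(1) < 0.3) s <- oracle_revcomp(s)
      reads[i] <- s
    }
  }
  aln <- align_reads(stats::setNames(reads, sprintf("r%04d", seq_along(reads))),
                     ref)
  by_read <- split(aln, aln$read_id)
  for (i in seq_along(reads)) {
    id <- sprintf("r%04d", i)
    expected <- oracle_align(reads[i], ref)
    got <- by_read[[id]]
    if (is.null(expected)) {
      expect_true(is.null(got) || nrow(got) == 0L, label = id)
    } else {
      expect_false(is.null(got), label = id)
      expect_equal(nrow(got), nrow(expected), label = id)
      expect_equal(got$chrom, expected$chrom, label = id)
      expect_equal(got$pos, expected$pos, label = id)
      expect_equal(got$strand, expected$strand, label = id)
      expect_equal(got$nm, expected$nm, label = id)
      expect_equal(got$nh, rep(expected$nh[1], nrow(expected)), label = id)
    }
  }
})

test_that("only the minimal-mismatch stratum is reported", {
  ref <- test_ref()
  set.seed(55)
  chrom1 <- as.character(ref$chromosomes[["chr1"]])
  for (i in 1:50) {
    w <- sample(18:35, 1)
    p <- sample(nchar(chrom1) - w, 1)
    sv <- strsplit(substr(chrom1, p, p + w - 1L), "", fixed = TRUE)[[1L]]
    for (q in sample(w, sample(0:4, 1)))
      sv[q] <- sample(setdiff(c("A", "C", "G", "T"), sv[q]), 1)
    aln <- align_reads(paste(sv, collapse = ""), ref)
    if (nrow(aln) > 0L) {
      expect_equal(length(unique(aln$nm)), 1L)
      expect_equal(aln$nh[1], nrow(aln))
    }
  }
})

test_that("strand symmetry: the reverse complement maps to the same loci, flipped", {
  ref <- test_ref()
  rny5_31 <- substr(evrny5:::gene_sequence(ref, "RNY5"), 1, 31)
  fwd <- align_reads(rny5_31, ref)
  rev <- align_reads(oracle_revcomp(rny5_31), ref)
  expect_equal(fwd$chrom, rev$chrom)
  expect_equal(fwd$pos, rev$pos)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
})

test_that("RNY5 fragment reads respect the multimapping contract", {
  ref <- test_ref()
  gene <- evrny5:::gene_sequence(ref, "RNY5")
  # >29 nt 5' reads map uniquely to the RNY5 locus
  a31 <- align_reads(substr(gene, 1, 31), ref)
  expect_equal(nrow(a31), 1L)
  expect_true(a31$is_unique)
  # <=29 nt 5' reads hit the perfect decoys too
  a23 <- align_reads(substr(gene, 1, 23), ref)
  expect_gte(a23$nh[1], 3L)
  expect_false(any(a23$is_unique))
  # a read exceeding max_loci placements is suppressed entirely
  ref12 <- build_reference(reference_config(n_perfect_decoys = 11L,
                                            n_near_decoys = 0L))
  gene12 <- evrny5:::gene_sequence(ref12, "RNY5")
  expect_equal(nrow(align_reads(substr(gene12, 1, 23), ref12)), 0L)
  expect_equal(align_reads(substr(gene12, 1, 23), ref12, max_loci = 12L)$nh[1],
               12L)
  # unmappable random read (oracle-confirmed absent) yields no records
  set.seed(3)
  repeat {
    rnd <- random_dna_str(31)
    if (is.null(oracle_align(rnd, ref))) break
  }
  expect_equal(nrow(align_reads(rnd, ref)), 0L)
  # degenerate inputs
  expect_error(align_reads("", ref), "empty read")
  expect_equal(nrow(align_reads("ACGTACGTACGT", ref)), 0L)  # <15 nt dropped
})

test_that("aligning an error-free decoy-free library reproduces the truth exactly", {
  run <- clean_run()
  aln <- run$aln
  sim <- run$sim
  expect_true(all(aln$nh == 1L))
  m <- merge(as.data.frame(sim)[, c("read_id", "chrom", "gstart")],
             as.data.frame(aln)[, c("read_id", "chrom", "pos", "nm", "strand")],
             by = "read_id")
  expect_equal(nrow(m), nrow(sim))
  expect_true(all(m$chrom.x == m$chrom.y))
  expect_true(all(m$gstart == m$pos))
  expect_true(all(m$nm == 0L))
  expect_true(all(m$strand == "+"))
})

test_that("align_library round-trips through FASTQ and SAM files", {
  run <- clean_run()
  sim <- run$sim[1:200, ]
  fq <- tempfile(fileext = ".fastq")
  sam <- tempfile(fileext = ".sam")
  write_fastq(sim$read_id, sim$seq, fq)
  align_library(fq, run$ref, out = sam)
  back <- read_sam(sam)
  direct <- align_reads(sim, run$ref)
  expect_equal(back$read_id, direct$read_id)
  expect_equal(back$pos, direct$pos)
  expect_equal(back$chrom, direct$chrom)
  expect_equal(back$nh, direct$nh)
  expect_equal(back$seq, direct$seq)
  # empty library -> header-only SAM
  fq0 <- tempfile(fileext = ".fastq")
  writeLines(character(0), fq0)
  sam0 <- tempfile(fileext = ".sam")
  align_library(fq0, run$ref, out = sam0)
  lines <- readLines(sam0)
  expect_true(all(startsWith(lines, "@")))
  expect_equal(nrow(read_sam(sam0)), 0L)
  unlink(c(fq, sam, fq0, sam0))
})
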