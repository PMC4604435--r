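test_that("sequence container validates alphabet and length", {
  s <- rna_seq("x", "gucga")
  expect_equal(s$residues, "GUCGA")
  expect_equal(seq_length(s), 5L)
  expect_error(rna_seq("x", ""), "non-empty")
  expect_error(rna_seq("x", "ACGT"), "RNA alphabet")      # T in RNA
  expect_error(rna_seq("x", "ACGU", is_dna = TRUE), "DNA alphabet")
  expect_error(rna_seq("x", "ACGUN"), "RNA alphabet")     # mixed/invalid
})

test_that("packaged oligo set matches its printed geometry", {
  ol <- rny5_oligos()
  expect_equal(seq_length(ol$RNY5_83mer), 83L)
  expect_equal(seq_length(ol$RNY5_31mer), 31L)
  expect_equal(seq_length(ol$RNY5_23mer), 23L)
  expect_equal(seq_length(ol$RNY5_motif_deleted), 23L)
  expect_equal(seq_length(ol$RNY5_3p_32mer), 32L)
  # 5' products are prefixes of the full-length transcript
  expect_true(startsWith(ol$RNY5_83mer$residues, ol$RNY5_31mer$residues))
  expect_true(startsWith(ol$RNY5_83mer$residues, ol$RNY5_23mer$residues))
})

test_that("motif search finds the 8-mer at position 14 and handles controls", {
  ol <- rny5_oligos()
  motif <- rny5_motif()
  expect_equal(motif$end_1based - motif$start_1based + 1L,
               nchar(motif$sequence))
  expect_equal(find_motif(ol$RNY5_83mer, motif$sequence), 14L)
  expect_equal(find_motif(ol$RNY5_31mer, motif$sequence), 14L)
  expect_equal(find_motif(ol$RNY5_motif_scrambled, motif$sequence), integer(0))
  expect_equal(find_motif(ol$RNY5_31mer_scrambled, motif$sequence), integer(0))
  # identity case
  s <- rna_seq("s", "GUUGUGGG")
  expect_equal(find_motif(s, s$residues), 1L)
  expect_error(find_motif(ol$RNY5_83mer, "GTTGTGGG"), "alphabet")
  expect_error(find_motif(ol$RNY5_83mer, ""), "non-empty")
})

test_that("fragment location places the printed products on the transcript", {
  ol <- rny5_oligos()
  expect_equal(locate_fragment(ol$RNY5_31mer, ol$RNY5_83mer), 1L)
  expect_equal(locate_fragment(ol$RNY5_23mer, ol$RNY5_83mer), 1L)
  expect_equal(locate_fragment(ol$RNY5_3p_32mer, ol$RNY5_83mer), 52L)
  expect_error(locate_fragment(ol$RNY5_31mer_scrambled, ol$RNY5_83mer),
               "lookup error")
  expect_error(locate_fragment(ol$RNY5_83mer, ol$RNY5_31mer), "longer")
})

test_that("locating then slicing reproduces every printed fragment oligo", {
  ol <- rny5_oligos()
  full <- ol$RNY5_83mer
  for (nm in c("RNY5_31mer", "RNY5_23mer", "RNY5_3p_32mer",
               "RNY5_ds_sense_32mer")) {
    frag <- ol[[nm]]
    p <- locate_fragment(frag, full)
    expect_identical(substr(full$residues, p, p + seq_length(frag) - 1L),
                     frag$residues, label = nm)
  }
})

test_that("search operations agree with a brute-force all-offsets scan", {
  set.seed(11)
  for (i in 1:30) {
    text <- rna_seq("t", random_rna(sample(20:200, 1)))
    w <- sample(2:8, 1)
    p0 <- sample(seq_len(seq_length(text) - w + 1L), 1)
    pat <- substr(text$residues, p0, p0 + w - 1L)
    expect_equal(find_motif(text, pat),
                 oracle_substring_starts(text$residues, pat))
    expect_equal(locate_fragment(rna_seq("f", pat), text),
                 oracle_substring_starts(text$residues, pat)[1L])
  }
})

test_that("perturbations reproduce the printed control oligos", {
  ol <- rny5_oligos()
  deleted <- perturb(ol$RNY5_31mer, "delete_range", start = 14, end = 21)
  expect_identical(deleted$residues, ol$RNY5_motif_deleted$residues)
  scrambled <- perturb(ol$RNY5_31mer, "replace_range", start = 14, end = 21,
                       replacement = "ACGUACAG")
  expect_identical(scrambled$residues, ol$RNY5_motif_scrambled$residues)
  expect_error(perturb(ol$RNY5_31mer, "delete_range", start = 14, end = 40),
               "out of bounds")
  expect_error(perturb(ol$RNY5_31mer, "replace_range", start = 14, end = 21,
                       replacement = "ACGU"), "length")
})

test_that("deletion length arithmetic and shuffle composition invariants hold", {
  set.seed(5)
  for (i in 1:20) {
    s <- rna_seq("s", random_rna(sample(10:100, 1)))
    n <- seq_length(s)
    a <- sort(sample(n, 2))
    del <- perturb(s, "delete_range", start = a[1], end = a[2])
    expect_equal(seq_length(del), n - (a[2] - a[1] + 1L))
    shuf <- perturb(s, "shuffle_all", seed = i)
    expect_equal(seq_composition(shuf), seq_composition(s))
  }
})

test_that("composition tallies residues exactly", {
  expect_equal(seq_composition(rna_seq("a", "AAAA")),
               c(A = 4L, C = 0L, G = 0L, U = 0L))
  ol <- rny5_oligos()
  expect_equal(sum(seq_composition(ol$RNY5_83mer)), 83L)
  # the completely scrambled 31-mer is a true permutation of the wild type
  expect_equal(seq_composition(ol$RNY5_31mer_scrambled),
               seq_composition(ol$RNY5_31mer))
  # the motif replacement ACGUACAG is NOT composition-preserving
  expect_false(identical(seq_composition(ol$RNY5_motif_scrambled),
                         seq_composition(ol$RNY5_31mer)))
})

test_that("the Northern probe hybridises to the transcript 5' end only", {
  probe <- northern_probe()
  ol <- rny5_oligos()
  expect_true(probe$is_dna)
  expect_equal(probe_complementarity(probe, ol$RNY5_83mer),
               c(start = 1L, end = 32L))
  expect_null(probe_complementarity(probe, ol$RNY5_31mer_scrambled))
  # a probe built as the reverse complement of its target covers it fully
  target <- rna_seq("t", random_rna(25))
  rc_dna <- rna_seq("p", chartr("U", "T", reverse_complement(target)$residues),
                    is_dna = TRUE)
  expect_equal(probe_complementarity(rc_dna, target),
               c(start = 1L, end = 25L))
  expect_error(probe_complementarity(ol$RNY5_31mer, ol$RNY5_83mer), "DNA")
})
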