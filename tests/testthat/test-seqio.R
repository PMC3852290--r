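test_that("reverse complement follows the complement table and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAAC"), "GTTT")
  expect_equal(revcomp("ANNGT"), "ACNNT")
  expect_error(revcomp("ACGU"), "non-nucleotide")
  withr::with_seed(11, {
    for (i in 1:100) {
      x <- rnd_nt(sample(5:80, 1))
      expect_identical(revcomp(revcomp(x)), x)
    }
  })
})

test_that("six-frame translation matches an independent translator", {
  tr <- translate_six_frames(seq_tbl("x", "ATGAAATAA"))
  expect_equal(tr$peptide[tr$frame == 1L], "MK*")
  # floor arithmetic on a length-7 input
  tr7 <- translate_six_frames(seq_tbl("x", "ATGAAAT"))
  expect_equal(nchar(tr7$peptide[match(c(1L, 2L, 3L), tr7$frame)]),
               c(2L, 2L, 1L))
  # frame -1 equals +1 of the reverse complement; all frames agree with
  # Biostrings' translator on random inputs
  gc11 <- Biostrings::getGeneticCode("11")
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- rnd_nt(60)
      tr <- translate_six_frames(seq_tbl("r", s))
      trc <- translate_six_frames(seq_tbl("r", revcomp(s)))
      expect_identical(tr$peptide[tr$frame == -1L],
                       trc$peptide[trc$frame == 1L])
      for (f in 1:3) {
        sub <- substring(s, f)
        sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
        ref <- as.character(Biostrings::translate(
          Biostrings::DNAString(sub), genetic.code = gc11,
          no.init.codon = TRUE))
        expect_identical(tr$peptide[tr$frame == f], ref)
      }
    }
  })
  # N codons become X
  trn <- translate_six_frames(seq_tbl("n", "ATGNNNAAA"))
  expect_equal(trn$peptide[trn$frame == 1L], "MXK")
})

test_that("genome segmentation covers the sequence with the stated starts", {
  g <- seq_tbl("g", rnd_nt(12000))
  s0 <- segment_genome(g, window = 5000L, overlap = 0L)
  expect_equal(nchar(s0$seq), c(5000L, 5000L, 2000L))
  expect_equal(segment_genome(seq_tbl("g", rnd_nt(4000)), 5000L, 0L)$start, 0L)
  s3 <- segment_genome(g, window = 5000L, overlap = 300L)
  expect_equal(s3$start, c(0L, 4700L, 9400L))
  # non-overlapping parts reconstruct the genome exactly
  parts <- substring(s3$seq, c(1L, rep(301L, nrow(s3) - 1L)))
  expect_identical(paste0(parts, collapse = ""), g$seq[1])
  expect_error(segment_genome(g, window = 100L, overlap = 100L), "overlap")
  expect_error(segment_genome(g, window = 0L))
})

test_that("FASTA and MSA readers round-trip and normalise gaps", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  seqs <- seq_tbl(c("a", "b"), c(rnd_nt(150), rnd_nt(37)))
  write_fasta(seqs, tf, width = 60L)
  back <- read_fasta(tf)
  expect_equal(back$id, seqs$id)
  expect_equal(back$seq, seqs$seq)
  expect_error(read_fasta("no/such/file.fa"), "not found")

  ta <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AC-GT", ">s2", "AC.GT"), ta)
  msa <- read_msa(ta)
  expect_equal(msa$seq, c("AC-GT", "AC-GT"))

  ts <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1  ACD-E", "s2  ACDKE", "//"), ts)
  sto <- read_msa(ts)
  expect_equal(sto$id, c("s1", "s2"))
  expect_equal(sto$seq, c("ACD-E", "ACDKE"))

  tr <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACG"), tr)
  expect_error(read_msa(tr), "ragged")
})
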