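test_that("implanted copies match their declared structure in the genome", {
  msa <- tpase_msa(seed = 3L, len = 150L)
  sim <- simulate_genome(list(
    implant_spec("fam1", 4L, 900L, ir_len = 17L, dr_len = 5L,
                 transposase = msa$seq[1])), 40000L, seed = 21L)
  tr <- sim$truth
  expect_equal(nrow(tr), 4L)
  g <- sim$genome$seq[1]
  for (r in seq_len(nrow(tr))) {
    el <- substr(g, tr$start[r] + 1L, tr$end[r])
    expect_equal(nchar(el), 900L)
    # terminal 17 nt are reverse-complement pairs
    expect_identical(substr(el, 1L, 17L),
                     revcomp(substr(el, 900L - 16L, 900L)))
    # 5 nt direct repeats flank the insertion
    expect_identical(substr(g, tr$start[r] - 4L, tr$start[r]),
                     substr(g, tr$end[r] + 1L, tr$end[r] + 5L))
    # the transposase ORF is readable in one of the six frames
    fr <- translate_six_frames(seq_tbl("el", el))
    hit <- vapply(fr$peptide, function(p) grepl(msa$seq[1], p, fixed = TRUE),
                  logical(1))
    expect_true(any(hit))
  }
  # empty spec list gives a pure random genome
  sim0 <- simulate_genome(list(), 5000L, seed = 3L)
  expect_equal(nrow(sim0$truth), 0L)
  expect_equal(nchar(sim0$genome$seq[1]), 5000L)
  # determinism
  sim2 <- simulate_genome(list(
    implant_spec("fam1", 4L, 900L, ir_len = 17L, dr_len = 5L,
                 transposase = msa$seq[1])), 40000L, seed = 21L)
  expect_identical(sim, sim2)
})

test_that("MITEs are internal deletions sharing their partner's termini", {
  sim <- simulate_genome(list(
    implant_spec("IS1", 3L, 1000L, ir_len = 15L, dr_len = 4L),
    implant_spec("M1", 5L, 200L, dr_len = 4L, partner_of = "IS1")),
    40000L, seed = 5L)
  g <- sim$genome$seq[1]
  oriented <- function(row) {
    s <- substr(g, row$start + 1L, row$end)
    if (row$strand == "-") revcomp(s) else s
  }
  is1 <- subset(sim$truth, family_id == "IS1")[1, ]
  m1 <- subset(sim$truth, family_id == "M1")[1, ]
  is_el <- oriented(is1)
  m_el <- oriented(m1)
  expect_identical(substr(m_el, 1L, 100L), substr(is_el, 1L, 100L))
  expect_identical(substr(m_el, 101L, 200L),
                   substr(is_el, 1000L - 99L, 1000L))
  expect_true(all(subset(sim$truth, family_id == "M1")$partner == "IS1"))
})

test_that("nested implants sit inside a host copy and are recorded", {
  sim <- simulate_genome(list(
    implant_spec("host", 2L, 1200L, ir_len = 12L),
    implant_spec("guest", 2L, 400L, ir_len = 10L, nested_in = "host")),
    30000L, seed = 13L)
  guest <- subset(sim$truth, family_id == "guest" & !is.na(nested_in))
  host <- subset(sim$truth, family_id == "host")
  expect_equal(nrow(guest), 1L)
  inside <- any(guest$start > host$start & guest$end < host$end)
  expect_true(inside)
})

test_that("fragmentation arithmetic and determinism", {
  g <- seq_tbl("g", paste0(rep("ACGT", 2500), collapse = ""))
  expect_equal(nrow(fragment_genome(g, 1000L)), 10L)
  expect_equal(nrow(fragment_genome(g, 250L)), 40L)
  r1 <- fragment_genome(g, 100L, seed = 4L, mode = "uniform", n_reads = 30L)
  r2 <- fragment_genome(g, 100L, seed = 4L, mode = "uniform", n_reads = 30L)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1$seq) == 100L))
  # ids encode source coordinates
  m <- stringr::str_match(r1$id, "^g:(\\d+)-(\\d+)$")
  expect_true(all(!is.na(m[, 1])))
  expect_error(fragment_genome(g, 0L), "positive")
})

test_that("mutation rates behave as declared", {
  s <- paste0(rep("ACGT", 2500), collapse = "")
  expect_identical(mutate_seq(s, 0, 0), s)
  m <- mutate_seq(s, sub_rate = 0.05, seed = 9L)
  nmut <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  # observed substitution fraction within the binomial 99% CI of 0.05
  ci <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(nmut, ci[1]); expect_lte(nmut, ci[2])
  expect_identical(mutate_seq(s, 0.05, 0.01, seed = 2L),
                   mutate_seq(s, 0.05, 0.01, seed = 2L))
  ind <- mutate_seq(s, 0, 0.02, seed = 6L)
  expect_false(nchar(ind) == nchar(s) && ind == s)
})

test_that("simulated transposase alignments have the declared divergence", {
  msa <- simulate_transposase_msa(n_seqs = 30L, length = 200L,
                                  divergence = 0.25, seed = 8L)
  expect_equal(nrow(msa), 30L)
  expect_true(all(nchar(msa$seq) == 200L))
  anc <- strsplit(attr(msa, "ancestor"), "")[[1]]
  div <- vapply(msa$seq, function(s) {
    mean(strsplit(s, "")[[1]] != anc)
  }, numeric(1))
  expect_equal(mean(div), 0.25, tolerance = 0.03)
})
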