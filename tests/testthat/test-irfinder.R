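test_that("no IR pairs in homopolymer or below the minimum arm", {
  expect_equal(nrow(find_inverted_repeats(seq_tbl("a", strrep("A", 3000)))), 0L)
  # perfect 9 nt arm is below the default minimum of 10 (non-pairing A|A
  # boundaries block extension; exact matching isolates the length rule)
  arm <- "ACCGGTACC"
  s <- paste0("AA", arm, strrep("T", 40), revcomp(arm), "AA")
  expect_equal(nrow(find_inverted_repeats(seq_tbl("s", s),
                                          ir_params(max_mismatch = 0L))), 0L)
  # a 10 nt arm at the same spot is reported
  arm10 <- "ACCGGTACCG"
  s10 <- paste0("AA", arm10, strrep("T", 40), revcomp(arm10), "AA")
  p <- find_inverted_repeats(seq_tbl("s", s10), ir_params(max_mismatch = 0L))
  expect_true(any(p$arm_len >= 10L & p$mismatches == 0L))
})

test_that("arm pairs beyond the mismatch budget are not reported", {
  arm <- "ACCGGTACCGTT"
  arm_mut <- arm
  substr(arm_mut, 2, 2) <- "T"; substr(arm_mut, 5, 5) <- "A"
  substr(arm_mut, 8, 8) <- "G"  # 3 mismatches vs arm
  s <- paste0("CC", arm, strrep("T", 60), revcomp(arm_mut), "GG")
  p <- find_inverted_repeats(seq_tbl("s", s),
                             ir_params(min_arm = 12L, max_mismatch = 2L))
  expect_false(any(p$arm_len >= 12L & p$left_start == 2L))
})

test_that("implanted exact inverted repeat is recovered as one maximal pair", {
  withr::with_seed(21, {
    arm <- "ACGTACCGGTAC"
    # force non-pairing bases (A opposite A) at all four extension boundaries
    s <- paste0(rnd_nt(100), "A", arm, "A", rnd_nt(498), "A", revcomp(arm),
                "A", rnd_nt(86))
    p <- find_inverted_repeats(seq_tbl("s", s),
                               ir_params(max_mismatch = 0L))
    hit <- p[p$arm_len == 12L & p$mismatches == 0L, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$left_start, 101L)
    expect_equal(hit$right_end, 101L + 12L + 500L + 12L)
  })
})

test_that("scan equals brute-force maximal-pair enumeration on random sequences", {
  settings <- list(
    list(min_arm = 10L, max_arm = 50L, max_gap = 2000L, max_mismatch = 2L),
    list(min_arm = 4L, max_arm = 12L, max_gap = 100L, max_mismatch = 0L),
    list(min_arm = 6L, max_arm = 20L, max_gap = 300L, max_mismatch = 1L))
  withr::with_seed(99, {
    for (i in 1:12) {
      n <- sample(150:400, 1)
      s <- rnd_nt(n)
      if (i %% 3 == 0) { # implant a structured pair and some N's
        arm <- rnd_nt(9)
        s <- paste0(s, arm, rnd_nt(30), "N", rnd_nt(10), revcomp(arm), rnd_nt(50))
      }
      for (st in settings) {
        got <- find_inverted_repeats(
          seq_tbl("s", s),
          ir_params(st$min_arm, st$max_arm, st$max_gap, st$max_mismatch))
        exp <- oracle_ir_pairs(s, st$min_arm, st$max_arm, st$max_gap,
                               st$max_mismatch)
        expect_identical(as.data.frame(got[, -1]),
                         `rownames<-`(as.data.frame(exp), NULL))
      }
    }
  })
})

test_that("IR pair set is mirrored under reverse complement and re-verifies", {
  withr::with_seed(7, {
    for (i in 1:5) {
      s <- paste0(rnd_nt(300), "GGCCATAGCC", rnd_nt(40),
                  revcomp("GGCCATAGCC"), rnd_nt(200))
      n <- nchar(s)
      prm <- ir_params(min_arm = 8L, max_gap = 500L, max_mismatch = 1L)
      p <- find_inverted_repeats(seq_tbl("s", s), prm)
      prc <- find_inverted_repeats(seq_tbl("s", revcomp(s)), prm)
      mirrored <- data.frame(
        left_start = n - p$right_end, left_end = n - p$right_start,
        right_start = n - p$left_end, right_end = n - p$left_start,
        arm_len = p$arm_len, mismatches = p$mismatches)
      mirrored <- mirrored[order(mirrored$left_start,
                                 mirrored$right_end - mirrored$left_start,
                                 mirrored$arm_len, mirrored$right_start), ]
      expect_identical(`rownames<-`(as.data.frame(prc[, -1]), NULL),
                       `rownames<-`(mirrored, NULL))
      # every reported pair re-verifies its mismatch count
      v <- strsplit(s, "")[[1]]
      for (r in seq_len(nrow(p))) {
        left <- paste0(v[(p$left_start[r] + 1):p$left_end[r]], collapse = "")
        right <- paste0(v[(p$right_start[r] + 1):p$right_end[r]], collapse = "")
        hd <- sum(strsplit(right, "")[[1]] != strsplit(revcomp(left), "")[[1]])
        expect_equal(hd, p$mismatches[r])
      }
    }
  })
})

test_that("candidate extraction spans both arms and deduplicates", {
  s <- seq_tbl("g", rnd_nt(800))
  pairs <- tibble::tibble(seq_id = "g", left_start = c(100L, 100L),
                          left_end = c(112L, 112L),
                          right_start = c(688L, 688L),
                          right_end = c(700L, 700L),
                          arm_len = 12L, mismatches = 0L)
  cands <- extract_ir_candidates(s, pairs)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$end - cands$start, 600L)
  expect_equal(nchar(cands$seq), 600L)
  expect_equal(nrow(extract_ir_candidates(s, pairs[0, ])), 0L)
  bad <- dplyr::mutate(pairs, right_end = 9000L)
  expect_error(extract_ir_candidates(s, bad), "outside")
})

test_that("singleton filtering keeps candidates with enough genomic copies", {
  withr::with_seed(31, {
    el <- rnd_nt(300)
    single <- rnd_nt(280)
    g <- seq_tbl("g", paste0(rnd_nt(2000), el, rnd_nt(1500), el,
                             rnd_nt(1200), single, rnd_nt(900)))
    cands <- tibble::tibble(
      cand_id = c("dup", "once"), seq_id = "g",
      start = c(2000L, 5300L), end = c(2300L, 5580L),
      seq = c(el, single))
    kept <- filter_singletons(cands, g, min_copies = 2L)
    expect_equal(kept$cand_id, "dup")
    expect_equal(kept$n_copies, 2L)
    all_kept <- filter_singletons(cands, g, min_copies = 1L)
    expect_equal(nrow(all_kept), 2L)
    # the k-mer counter agrees with the alignment-based counter here
    expect_equal(count_occurrences(cands, g, method = "kmer"),
                 count_occurrences(cands, g, method = "align"))
  })
})
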