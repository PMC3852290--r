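test_that("profile building follows the match-column rule and normalises", {
  # gap-free alignment of identical sequences: K match states, modal residue
  msa <- tibble::tibble(id = paste0("s", 1:10), seq = rep("ACDEFG", 10))
  hmm <- build_profile(msa)
  expect_equal(hmm$K, 6L)
  modal <- colnames(hmm$match_emissions)[apply(hmm$match_emissions, 1, which.max)]
  expect_equal(modal, strsplit("ACDEFG", "")[[1]])
  # a column with exactly 50% gaps is an insert column, under 50% is match
  msa2 <- tibble::tibble(id = paste0("s", 1:4),
                         seq = c("A-CD", "A-CD", "AKCD", "AKC-"))
  expect_equal(build_profile(msa2)$K, 3L)   # col2: 50% gaps -> insert
  # all stored emission and transition rows sum to 1
  hmm3 <- toy_profile(K = 4L, n_seqs = 8L, seed = 2L)
  expect_true(all(abs(rowSums(hmm3$match_emissions) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm3$insert_emissions) - 1) < 1e-9))
  expect_true(all(abs(hmm3$tmm + hmm3$tmi + hmm3$tmd + hmm3$tme - 1) < 1e-9))
  expect_true(all(abs(hmm3$tim + hmm3$tii - 1) < 1e-9))
  if (hmm3$K >= 3L) {
    d <- 2:(hmm3$K - 1L)
    expect_true(all(abs(hmm3$tdm[d] + hmm3$tdd[d] - 1) < 1e-9))
  }
  expect_error(build_profile(msa[1, ]), "at least 2")
  expect_error(build_profile(tibble::tibble(id = c("a", "b"),
                                            seq = c("ACD", "AC"))), "ragged")
})

test_that("Viterbi and forward equal exhaustive path enumeration on toy models", {
  withr::with_seed(8, {
    for (trial in 1:12) {
      K <- sample(2:4, 1)
      hmm <- toy_profile(K = K, n_seqs = 6L, seed = 100L + trial)
      for (L in c(2L, 4L, 6L)) {
        pep <- rnd_aa(L)
        ora <- oracle_phmm_scores(hmm, pep)
        vit <- viterbi_score(hmm, pep)
        fwd <- forward_score(hmm, pep)
        expect_equal(vit$bits, ora$viterbi, tolerance = 1e-9)
        expect_equal(fwd, ora$forward, tolerance = 1e-9)
        expect_gte(fwd, vit$bits - 1e-12)
      }
    }
  })
})

test_that("modal-residue peptide of a tight model scores the closed form", {
  msa <- tibble::tibble(id = paste0("s", 1:50), seq = rep("MKWVLR", 50))
  hmm <- build_profile(msa, pseudocount = 1e-4)
  pep <- "MKWVLR"
  vit <- viterbi_score(hmm, pep)
  # closed form: entry + per-state modal log-odds + M->M transitions + exit
  lo <- sum(log2(diag(hmm$match_emissions[, strsplit(pep, "")[[1]]]) / 0.05))
  closed <- log2(1 / hmm$K) + lo + sum(log2(hmm$tmm[1:(hmm$K - 1)])) +
    log2(hmm$tme[hmm$K])
  expect_equal(vit$bits, closed, tolerance = 1e-6)
  expect_equal(vit$env_start, 1L)
  expect_equal(vit$env_end, nchar(pep))
})

test_that("Gumbel calibration recovers known parameters and is deterministic", {
  withr::with_seed(15, {
    x <- r_gumbel(10000, mu = 3, lambda = 0.7)
    fit <- fit_gumbel(x)
    expect_equal(fit$mu, 3, tolerance = 0.05 * 3)
    expect_equal(fit$lambda, 0.7, tolerance = 0.05 * 0.7)
    ora <- oracle_gumbel_fit(x)
    expect_equal(fit$mu, ora$mu, tolerance = 1e-3)
    expect_equal(fit$lambda, ora$lambda, tolerance = 1e-3)
  })
  hmm <- toy_profile(K = 4L, n_seqs = 8L, seed = 5L)
  c1 <- calibrate_profile(hmm, n_random = 200L, seed = 42L)
  c2 <- calibrate_profile(hmm, n_random = 200L, seed = 42L)
  expect_identical(c1$calib, c2$calib)
  # E(score) is monotone decreasing in score
  sc <- seq(-5, 50, by = 5)
  ev <- profile_evalue(c1, sc, 1000)
  expect_true(all(diff(ev) < 0))
  expect_error(calibrate_profile(hmm, n_random = 10L), "n_random")
})

test_that("profile search hits planted transposases and ignores reversed peptides", {
  msa <- tpase_msa(seed = 3L, len = 120L)
  hmm <- calibrate_profile(build_profile(msa, name = "famA"),
                           n_random = 1000L, seed = 7L)
  withr::with_seed(19, {
    orf <- teminer:::back_translate(msa$seq[1])
    g <- seq_tbl("g", paste0(rnd_nt(900), "ATG", orf, rnd_nt(700)))
    tr <- translate_six_frames(g)
    hits <- search_profiles(list(hmm), tr, evalue_max = 1e-5)
    expect_gte(nrow(hits), 1L)
    # reversed (not reverse-complemented) random peptides: no significant hits
    n_hit <- 0L
    for (r in 1:20) {
      revpep <- stringi::stri_reverse(rnd_aa(300))
      fake <- tibble::tibble(parent_id = "x", frame = 1L, nt_offset = 0L,
                             peptide = revpep)
      n_hit <- n_hit + nrow(search_profiles(list(hmm), fake, evalue_max = 1e-5))
    }
    expect_lte(n_hit, 1L)
    # profile order does not change the hit set
    hmm2 <- calibrate_profile(build_profile(tpase_msa(seed = 9L, len = 100L),
                                            name = "famB"),
                              n_random = 1000L, seed = 8L)
    h12 <- search_profiles(list(hmm, hmm2), tr, evalue_max = 1e-5)
    h21 <- search_profiles(list(hmm2, hmm), tr, evalue_max = 1e-5)
    expect_identical(h12, h21)
    # an uncalibrated profile is an error
    expect_error(search_profiles(list(build_profile(msa)), tr), "calibrated")
  })
})

test_that("profile serialization round-trips to 12 significant digits", {
  hmm <- calibrate_profile(toy_profile(K = 4L, n_seqs = 10L, seed = 77L),
                           n_random = 150L, seed = 3L)
  tf <- withr::local_tempfile(fileext = ".phmm")
  write_profile(hmm, tf)
  back <- read_profile(tf)
  expect_equal(back$K, hmm$K)
  expect_lt(max(abs(back$match_emissions - hmm$match_emissions)), 1e-12)
  expect_lt(max(abs(back$insert_emissions - hmm$insert_emissions)), 1e-12)
  for (f in c("tmm", "tmi", "tmd", "tme", "tim", "tii", "tdm", "tdd")) {
    expect_lt(max(abs(back[[f]] - hmm[[f]])), 1e-12)
  }
  expect_equal(back$calib$mu, hmm$calib$mu, tolerance = 1e-12)
  pep <- "ACDEFMKW"
  expect_equal(viterbi_score(back, pep)$bits, viterbi_score(hmm, pep)$bits,
               tolerance = 1e-9)
})

test_that("tidy, glance and autoplot summarise a profile", {
  hmm <- calibrate_profile(toy_profile(K = 3L, seed = 4L), n_random = 150L,
                           seed = 2L)
  td <- tidy(hmm)
  expect_equal(nrow(td), 3L * 20L)
  expect_true(all(c("state", "residue", "match_emission") %in% names(td)))
  gl <- glance(hmm)
  expect_equal(gl$n_states, 3L)
  expect_true(gl$calibrated)
  expect_s3_class(autoplot(hmm), "ggplot")
})
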