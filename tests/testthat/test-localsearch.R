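test_that("Karlin-Altschul E-value closed form and lambda root", {
  sch <- structure(list(K = 0.1, lambda = 0.3, lambda_gapped = 0.3,
                        mode = "nt"), class = "scoring_scheme")
  expect_equal(karlin_evalue(0, 1000, 1000, sch), 1e5)
  # raising the score by 10 shrinks E by exp(10 * lambda)
  expect_equal(karlin_evalue(10, 1000, 1000, sch) * exp(10 * 0.3),
               karlin_evalue(0, 1000, 1000, sch), tolerance = 1e-9)
  # +1/-2 at uniform base frequencies: lambda ~ 1.33 from the Karlin sum
  sch_nt <- scoring_scheme("nt")
  f <- function(l) 0.25 * exp(l * 1) + 0.75 * exp(l * -2) - 1
  lam_oracle <- uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  expect_equal(sch_nt$lambda, lam_oracle, tolerance = 1e-8)
  expect_equal(sch_nt$lambda, 1.33, tolerance = 0.01)
  expect_error(karlin_lambda(matrix(1, 2, 2), c(0.5, 0.5)), "negative")
})

test_that("exact substring queries give one full-coverage perfect hit", {
  withr::with_seed(41, {
    g <- rnd_nt(30000)
    q <- substr(g, 10001, 11000)
    h <- search_nt(seq_tbl("q", q), seq_tbl("g", g))
    expect_gte(nrow(h), 1L)
    expect_equal(h$t_start[1], 10000L)
    expect_equal(h$t_end[1], 11000L)
    expect_equal(h$pct_identity[1], 100)
    expect_lt(h$evalue[1], 1e-5)
    expect_equal(h$strand[1], "+")
  })
})

test_that("hit scores equal the Smith-Waterman oracle on mutated copies", {
  withr::with_seed(17, {
    g0 <- rnd_nt(20000)
    el <- substr(g0, 5001, 5800)
    for (r in 1:5) {
      q <- mutate_seq(el, sub_rate = 0.05, seed = 100 + r)
      h <- search_nt(seq_tbl("q", q), seq_tbl("g", g0))
      expect_gte(nrow(h), 1L)
      best <- h[1, ]
      # reported score is reproduced by an independent full local DP
      expect_equal(best$score, oracle_sw_score(q, g0), tolerance = 1e-9)
      # and by DP restricted to the reported spans
      qs <- substr(q, best$q_start + 1L, best$q_end)
      ts <- substr(g0, best$t_start + 1L, best$t_end)
      expect_equal(best$score, oracle_sw_score(qs, ts), tolerance = 1e-9)
    }
  })
})

test_that("strand symmetry mirrors hits and E-values scale with database size", {
  withr::with_seed(23, {
    g <- rnd_nt(15000)
    q <- substr(g, 3001, 3600)
    hf <- search_nt(seq_tbl("q", q), seq_tbl("g", g))
    hr <- search_nt(seq_tbl("q", revcomp(q)), seq_tbl("g", g))
    expect_equal(nrow(hf), nrow(hr))
    expect_equal(hf$t_start, hr$t_start)
    expect_equal(hf$score, hr$score)
    expect_setequal(paste(hf$strand, hr$strand), "+ -")
    sch <- scoring_scheme("nt")
    expect_equal(karlin_evalue(100, 500, 2e4, sch) * 2,
                 karlin_evalue(100, 500, 4e4, sch))
  })
})

test_that("random queries yield no significant hits against random genomes", {
  withr::with_seed(53, {
    misses <- 0L
    for (r in 1:20) {
      q <- rnd_nt(1000)
      g <- rnd_nt(50000)
      h <- search_nt(seq_tbl("q", q), seq_tbl("g", g), evalue_max = 1e-5)
      if (nrow(h) == 0L) misses <- misses + 1L
    }
    expect_gte(misses, 19L)
  })
})

test_that("translated search finds in-frame encodings in the right frame", {
  withr::with_seed(61, {
    pep <- rnd_aa(220)
    lib <- tibble::tibble(id = "prot1", seq = pep)
    orf <- withr::with_seed(62, teminer:::back_translate(pep))
    q <- paste0(rnd_nt(151), "ATG", orf, rnd_nt(100))
    h <- search_translated(seq_tbl("q", q), lib)
    expect_gte(nrow(h), 1L)
    expect_equal(h$frame[1], ((151 + 3) %% 3) + 1L)
    expect_equal(h$pct_identity[1], 100)
    # reverse-complemented query: same hit, negated frame
    hr <- search_translated(seq_tbl("q", revcomp(q)), lib)
    expect_equal(hr$frame[1], -h$frame[1])
    expect_equal(hr$score[1], h$score[1])
    # 20% substituted library protein still recovered at E <= 1e-5
    for (r in 1:3) {
      mut <- strsplit(pep, "")[[1]]
      swap <- sample(220, 44)
      for (t in swap) mut[t] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], mut[t]), 1)
      libm <- tibble::tibble(id = "mut", seq = paste0(mut, collapse = ""))
      hm <- search_translated(seq_tbl("q", q), libm, evalue_max = 1e-5)
      expect_gte(nrow(hm), 1L)
    }
    expect_error(search_translated(seq_tbl("q", q), lib[0, ]), "empty")
  })
})

test_that("contained hits are dropped and results are sorted by E-value", {
  withr::with_seed(71, {
    el <- rnd_nt(600)
    g <- paste0(rnd_nt(2000), el, rnd_nt(3000), el, rnd_nt(1500))
    h <- search_nt(seq_tbl("q", el), seq_tbl("g", g))
    expect_equal(nrow(h), 2L)
    expect_equal(sort(h$t_start), c(2000L, 5600L))
    expect_true(!is.unsorted(h$evalue))
    # no kept hit is contained in another on the same strand
    for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
      if (i == j || h$strand[i] != h$strand[j]) next
      expect_false(h$t_start[j] <= h$t_start[i] && h$t_end[j] >= h$t_end[i] &&
                     h$score[j] > h$score[i])
    }
  })
})
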