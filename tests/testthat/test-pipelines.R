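# shared small simulated study used by several blocks
pipe_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      msa <- tpase_msa(seed = 3L)
      sim <- simulate_genome(list(
        implant_spec("IS1", 5L, 1400L, ir_len = 17L, dr_len = 5L,
                     transposase = msa$seq[1]),
        implant_spec("IS2", 4L, 1100L, ir_len = 0L,
                     transposase = msa$seq[2]),
        implant_spec("MITE1", 8L, 240L, dr_len = 5L, partner_of = "IS1")),
        120000L, seed = 9L)
      cache <<- list(msa = msa, sim = sim, lib = tpase_lib(msa))
    }
    cache
  }
})

test_that("the 500 bp size split sends the boundary to the MITE branch", {
  ctr <- tibble::tibble(id = c("a", "b", "c"),
                        seq = c(rnd_nt(501), rnd_nt(499), rnd_nt(500)))
  br <- split_by_size(ctr, 500L)
  expect_equal(br$branch, c("IS", "MITE", "MITE"))
})

test_that("IS copy expansion compiles full and truncated copies and merges overlaps", {
  withr::with_seed(57, {
    el <- rnd_nt(1000)
    half <- substr(el, 1L, 500L)
    g <- seq_tbl("g", paste0(rnd_nt(3000), el, rnd_nt(2000), el, rnd_nt(2000),
                             el, rnd_nt(1500), el, rnd_nt(1200), half,
                             rnd_nt(1000)))
    copies <- expand_is_copies(el, g)
    expect_equal(nrow(copies), 5L)
    expect_equal(sum(copies$truncated), 1L)
    tr <- copies[copies$truncated, ]
    expect_lt(tr$end - tr$start, 0.9 * 1000)
  })
})

test_that("nested-element separation excises inner elements recursively", {
  withr::with_seed(63, {
    A <- rnd_nt(900); B <- rnd_nt(400); C <- rnd_nt(150)
    # B contains C; an interrupted copy of A contains (B contains C)
    BC <- paste0(substr(B, 1, 200), C, substr(B, 201, 400))
    ABC <- paste0(substr(A, 1, 350), BC, substr(A, 351, 900))
    g <- seq_tbl("g", paste0(rnd_nt(500), ABC, rnd_nt(800), A, rnd_nt(400)))
    a0 <- 500L
    iv <- tibble::tibble(
      start = c(a0, a0 + 350L, a0 + 350L + 200L),
      end = c(a0 + nchar(ABC), a0 + 350L + nchar(BC), a0 + 350L + 200L + 150L))
    rec <- separate_nested(iv, g)
    expect_equal(nrow(rec), 3L)
    # outer reconstruction excises B (which itself contains C) -> intact A
    expect_identical(rec$seq[rec$start == a0], A)
    expect_identical(rec$seq[rec$start == a0 + 350L], B)
    expect_identical(rec$seq[rec$start == a0 + 550L], C)
    # non-overlapping intervals pass through unchanged
    plain <- tibble::tibble(start = c(10L, 200L), end = c(60L, 280L))
    rp <- separate_nested(plain, g)
    expect_identical(rp$seq,
                     stringi::stri_sub(g$seq[1], plain$start + 1L, plain$end))
    # partial overlap warns and passes both through
    expect_warning(separate_nested(tibble::tibble(start = c(10L, 40L),
                                                  end = c(80L, 120L)), g),
                   "overlap")
  })
})

test_that("decoy screening removes calls matching known non-TE genes", {
  withr::with_seed(69, {
    decoy_pep <- rnd_aa(250)
    orf <- teminer:::back_translate(decoy_pep)
    # c2 carries only a weak, heavily substituted decoy fragment, so its
    # transposase evidence (1e-30) out-competes any decoy hit
    frag <- strsplit(substr(decoy_pep, 1, 60), "")[[1]]
    swap <- sample(60, 30)
    for (t in swap) frag[t] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], frag[t]), 1)
    orf2 <- teminer:::back_translate(paste0(frag, collapse = ""))
    calls <- tibble::tibble(
      call_id = c("c1", "c2"), kind = "IS",
      family = c(NA_character_, "IS3"),
      family_evalue = c(NA_real_, 1e-30),
      consensus = c(paste0(rnd_nt(40), "ATG", orf, rnd_nt(40)),
                    paste0(rnd_nt(30), "ATG", orf2, rnd_nt(30))),
      length = 100L, n_copies = 2L, copies = list(tibble::tibble()),
      ir_len = 0L, ir_mismatches = NA_integer_, dr_len = 0L,
      partner = NA_character_, evidence = "repeats")
    decoys <- tibble::tibble(id = "integrase1", seq = decoy_pep)
    res <- filter_known_non_te(calls, decoys)
    # c1 has no transposase support and hits the decoy -> removed;
    # c2's transposase evidence is stronger than the decoy hit -> kept
    expect_equal(res$removed$call_id, "c1")
    expect_match(res$removed$removed_reason, "integrase1")
    expect_equal(res$kept$call_id, "c2")
    # empty decoy library is a pass-through
    none <- filter_known_non_te(calls, NULL)
    expect_identical(none$kept, calls)
  })
})

test_that("repeats-search pipeline calls implanted families with correct kinds", {
  fx <- pipe_fixture()
  calls <- run_repeats_search(fx$sim$genome, fx$lib)
  expect_true(all(c("IS", "MITE") %in% calls$kind))
  is_calls <- calls[calls$kind == "IS", ]
  expect_equal(sort(is_calls$length), c(1101L, 1400L))
  expect_true(all(is_calls$family == "IS3"))
  mite <- calls[calls$kind == "MITE", ]
  expect_equal(nrow(mite), 1L)
  expect_equal(mite$length, 240L)
  # partner link points at the 1400 nt autonomous element
  expect_equal(calls$length[calls$call_id == mite$partner], 1400L)
  # provenance and bounds invariants
  expect_true(all(calls$evidence == "repeats"))
  glen <- nchar(fx$sim$genome$seq[1])
  for (cp in calls$copies) {
    expect_true(all(cp$start >= 0L & cp$end <= glen & cp$start < cp$end))
  }
  # a MITE call never carries a transposase hit covering most of it
  expect_true(all(is.na(mite$family)))
})

test_that("IR-search pipeline finds IR-bearing families and links MITE partners", {
  fx <- pipe_fixture()
  calls <- run_ir_search(fx$sim$genome, fx$lib)
  # the 17 nt IR element is called with a terminal IR close to its real length
  is1 <- calls[calls$kind == "IS" & abs(calls$length - 1400L) <= 70L, ]
  expect_gte(nrow(is1), 1L)
  expect_true(any(is1$ir_len >= 15L))
  # the MITE is called and linked to an autonomous partner
  mite <- calls[calls$kind == "MITE" & abs(calls$length - 240L) <= 30L, ]
  expect_gte(nrow(mite), 1L)
  expect_false(any(is.na(mite$partner)))
  expect_true(all(calls$evidence == "ir"))
})

test_that("single-copy elements are not called by the de novo paths", {
  withr::with_seed(81, {
    msa <- tpase_msa(seed = 3L)
    orf <- teminer:::back_translate(msa$seq[1])
    el <- paste0("GGCCATAGCCATTTTCC", rnd_nt(40), "ATG", orf, rnd_nt(40),
                 revcomp("GGCCATAGCCATTTTCC"))
    g <- seq_tbl("g", paste0(rnd_nt(20000), el, rnd_nt(20000)))
    lib <- tpase_lib(msa)
    expect_equal(nrow(run_repeats_search(g, lib)), 0L)
    expect_equal(nrow(run_ir_search(g, lib)), 0L)
  })
})

test_that("HMM pipeline hits planted transposase loci and degrades with read length", {
  fx <- pipe_fixture()
  hmm <- calibrate_profile(build_profile(fx$msa, name = "famA"),
                           n_random = 1000L, seed = 7L)
  hits <- run_hmm_pipeline(fx$sim$genome, list(hmm))
  expect_gte(nrow(hits), 1L)
  # hit envelopes fall inside implanted elements (MITEs retain the start of
  # their partner's transposase ORF, so short in-MITE hits are genuine)
  tr_all <- fx$sim$truth
  tr_is <- fx$sim$truth[fx$sim$truth$kind == "IS", ]
  inside <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$g_start[i] >= tr_all$start - 200L &
          hits$g_end[i] <= tr_all$end + 200L)
  }, logical(1))
  expect_true(all(inside))
  # recall per IS copy: 1000 bp reads at least match 250 bp reads
  recall_at <- function(len) {
    reads <- fragment_genome(fx$sim$genome, len)
    h <- run_hmm_pipeline(reads, list(hmm))
    src <- stringr::str_match(h$parent_id, ":(\\d+)-(\\d+)$")
    rs <- as.integer(src[, 2])
    mean(vapply(seq_len(nrow(tr_is)), function(r) {
      any(rs >= tr_is$start[r] - 1000L & rs <= tr_is$end[r])
    }, logical(1)))
  }
  r1000 <- recall_at(1000L)
  r250 <- recall_at(250L)
  expect_gte(r1000, r250)
  expect_gt(r1000, 0.5)
})

test_that("pipelines are byte-identical across repeated runs", {
  fx <- pipe_fixture()
  c1 <- run_repeats_search(fx$sim$genome, fx$lib)
  c2 <- run_repeats_search(fx$sim$genome, fx$lib)
  attr(c1, "removed") <- NULL; attr(c2, "removed") <- NULL
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir()
  f1 <- file.path(d1, "a.gff3"); f2 <- file.path(d1, "b.gff3")
  write_element_gff3(c1, fx$sim$genome, f1)
  write_element_gff3(c2, fx$sim$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})
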