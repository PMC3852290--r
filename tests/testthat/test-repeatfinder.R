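test_that("l-mer seeding counts canonical words like a direct scan", {
  g12 <- seq_tbl("g", strrep("A", 12))
  sl <- seed_lmers(g12, lmer = 9L, min_count = 3L)
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$lmer, strrep("A", 9))
  expect_equal(sl$count, 4L)
  expect_equal(sl$positions[[1]]$pos, 0:3)
  # brute-force canonical substring counting on a random genome
  withr::with_seed(33, {
    g <- rnd_nt(5000)
    sl <- seed_lmers(seq_tbl("g", g), lmer = 9L, min_count = 3L)
    words <- substring(g, 1:(5000 - 8), 9:5000)
    canon <- pmin(words, revcomp(words))
    tab <- table(canon)
    expected <- sort(tab[tab >= 3], decreasing = TRUE)
    expect_setequal(sl$lmer, names(expected))
    expect_equal(sl$count[match(names(expected), sl$lmer)],
                 unname(as.integer(expected)))
    # min_count 1 reports every distinct l-mer
    sl1 <- seed_lmers(seq_tbl("g", g), lmer = 9L, min_count = 1L)
    expect_equal(nrow(sl1), length(tab))
  })
})

test_that("consensus building recovers an implanted element from any shared seed", {
  withr::with_seed(37, {
    el <- rnd_nt(1000)
    g <- seq_tbl("g", paste0(rnd_nt(9000), el, rnd_nt(10000), el,
                             rnd_nt(8000), el, rnd_nt(3000)))
    seedpos <- c(9000L, 20000L, 29000L) + 431L  # same in-element offset
    fam <- build_consensus(g, tibble::tibble(pos = seedpos, strand = "+"),
                           repeat_params())
    expect_false(is.null(fam))
    expect_equal(nrow(fam$copies[[1]]), 3L)
    # consensus matches the implanted element near-perfectly over its length
    expect_gte(pairwise_identity(fam$consensus, el), 0.99)
    expect_gte(fam$length, 0.99 * 1000)
    # a seed with 3 unrelated contexts dies near the seed: below min_len
    rnd_sites <- tibble::tibble(pos = c(1000L, 4000L, 7000L), strand = "+")
    expect_null(build_consensus(g, rnd_sites, repeat_params()))
    # min_copies above the available seeds yields none
    expect_null(build_consensus(g, tibble::tibble(pos = seedpos, strand = "+"),
                                repeat_params(min_copies = 4L)))
  })
})

test_that("family search recovers implants, masks, and is deterministic", {
  withr::with_seed(43, {
    els <- list(a = rnd_nt(800), b = rnd_nt(400), c = rnd_nt(1500))
    chunks <- c(rnd_nt(4000), els$a, rnd_nt(3000), els$b, rnd_nt(3000),
                els$a, rnd_nt(2500), els$c, rnd_nt(3000), els$b,
                rnd_nt(2000), els$a, rnd_nt(2500), els$c, rnd_nt(2200),
                els$b, rnd_nt(2000), els$c, rnd_nt(1500), revcomp(els$a),
                rnd_nt(1800))
    g <- seq_tbl("g", paste0(chunks, collapse = ""))
    fams <- find_repeat_families(g, repeat_params())
    expect_equal(nrow(fams), 3L)
    expect_setequal(fams$n_copies, c(4L, 3L, 3L))
    # each implanted element matches exactly one consensus at >= 99%
    # identity (consensus orientation follows the canonical seed, so compare
    # both strands)
    ident2 <- function(e, cc) max(pairwise_identity(e, cc),
                                  pairwise_identity(revcomp(e), cc))
    best <- vapply(els, function(e) {
      max(vapply(fams$consensus, function(cc) ident2(e, cc), numeric(1)))
    }, numeric(1))
    expect_true(all(best >= 0.99))
    # minus-strand copy is reported with strand '-'
    fa <- fams[vapply(fams$consensus, function(cc)
      ident2(els$a, cc) >= 0.99, logical(1)), ]
    expect_true("-" %in% fa$copies[[1]]$strand)
    # masking invariant: copy intervals non-overlapping across families
    allcp <- dplyr::bind_rows(fams$copies)
    allcp <- allcp[order(allcp$start), ]
    expect_true(all(diff(allcp$start) >= (allcp$end - allcp$start)[-nrow(allcp)]))
    # determinism
    expect_identical(fams, find_repeat_families(g, repeat_params()))
  })
})

test_that("element-free random genomes yield no families", {
  withr::with_seed(47, {
    g <- rnd_nt(50000)
    fams <- find_repeat_families(seq_tbl("g", g), repeat_params())
    expect_equal(nrow(fams), 0L)
    # brute-force support: no 50-mer occurs 3 times
    words <- substring(g, 1:(50000 - 49), 50:50000)
    expect_lt(max(table(words)), 3L)
  })
})
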