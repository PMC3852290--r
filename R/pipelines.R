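#' Element-calling pipelines
#'
#' Wiring of the detection stages into three workflows: the repeats search
#' (repeat-family mining), the IR search (inverted-repeat-delimited candidate
#' extraction) and the profile HMM search over six-frame-translated segments.
#' The two de novo paths share a common tail: clustering, the 500 bp size
#' split into putative ISs and MITE candidates, exhaustive IS copy expansion,
#' terminal-word MITE partner linking with nested-element separation, and
#' validation / annotation against a user-supplied transposase library.
#'
#' @name pipelines
NULL

#' Pipeline configuration
#'
#' All thresholds of the three workflows in one place.
#'
#' @param size_threshold centroids longer than this go to the IS branch;
#'   shorter-or-equal to the MITE branch (500 bp).
#' @param term_len terminal word length used for MITE partner search (23 bp,
#'   roughly the IR length of an element).
#' @param term_max_mismatch ungapped mismatches tolerated when locating
#'   terminal words (surrogate for a very permissive E <= 0.1 on a 23-mer;
#'   gapped statistics are meaningless at that length).
#' @param mite_max_len partner intervals must be shorter than this (3 kb).
#' @param evalue_is_expand E-value for exhaustive IS copy compilation (1e-5).
#' @param evalue_validate E-value for transposase validation / annotation of
#'   partners and consensi (1e-5).
#' @param evalue_hmm E-value for profile HMM hits (1e-5).
#' @param min_copies_repeat minimum copy number in the repeats path (3).
#' @param min_copies_ir minimum copy number for IR candidates (2; candidates
#'   present fewer times are removed).
#' @param min_arm_score minimum arm significance, scored arm_len - 3 *
#'   mismatches, for an IR pair to found a candidate (10 = a perfect 10-mer
#'   equivalent; the scan parameters themselves are deliberately permissive).
#' @param cluster_identity greedy-clustering identity threshold (0.9).
#' @param occurrence_identity identity at which genomic occurrences of a
#'   candidate are counted.
#' @param window,overlap genome segmentation for the HMM pipeline (5 kb
#'   windows, 300 nt overlap).
#' @param ir an [ir_params()] object for the IR search.
#' @param repeat_par a [repeat_params()] object for the repeats search.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(size_threshold = 500L, term_len = 23L,
                            term_max_mismatch = 3L, mite_max_len = 3000L,
                            evalue_is_expand = 1e-5, evalue_validate = 1e-5,
                            evalue_hmm = 1e-5, min_copies_repeat = 3L,
                            min_copies_ir = 2L, min_arm_score = 10L,
                            cluster_identity = 0.9,
                            occurrence_identity = 0.9,
                            window = 5000L, overlap = 300L,
                            ir = ir_params(), repeat_par = NULL) {
  stopifnot(size_threshold > 0L, term_len < mite_max_len)
  repeat_par <- repeat_par %||% repeat_params(min_copies = min_copies_repeat)
  structure(list(
    size_threshold = as.integer(size_threshold),
    term_len = as.integer(term_len),
    term_max_mismatch = as.integer(term_max_mismatch),
    mite_max_len = as.integer(mite_max_len),
    evalue_is_expand = evalue_is_expand, evalue_validate = evalue_validate,
    evalue_hmm = evalue_hmm,
    min_copies_repeat = as.integer(min_copies_repeat),
    min_copies_ir = as.integer(min_copies_ir),
    min_arm_score = as.integer(min_arm_score),
    cluster_identity = cluster_identity,
    occurrence_identity = occurrence_identity,
    window = as.integer(window), overlap = as.integer(overlap),
    ir = ir, repeat_par = repeat_par
  ), class = "pipeline_config")
}

empty_calls <- function() {
  tibble::tibble(call_id = character(), kind = character(),
                 family = character(), family_evalue = numeric(),
                 consensus = character(), length = integer(),
                 n_copies = integer(), copies = list(),
                 ir_len = integer(), ir_mismatches = integer(),
                 dr_len = integer(), partner = character(),
                 evidence = character())
}

#' Split clustered candidates by the 500 bp size rule
#'
#' Centroids longer than the threshold are putative ISs; the rest (including
#' exactly-threshold ones) are MITE candidates.
#'
#' @param centroids tibble with `id`, `seq` (e.g. [cluster_centroids()]).
#' @param threshold size threshold in nt.
#' @return The input with a `branch` column (`"IS"` / `"MITE"`).
#' @export
split_by_size <- function(centroids, threshold = 500L) {
  dplyr::mutate(centroids,
                branch = ifelse(nchar(.data$seq) > threshold, "IS", "MITE"))
}

# best transposase-library hit of a nucleotide consensus; family parsed from
# the library headers ("family=XXX" tag, else second '|' token, else the id)
annotate_consensus <- function(consensus, transposase_lib, evalue_max = 1e-5) {
  if (is.null(transposase_lib) || nrow(transposase_lib) == 0L)
    return(list(family = NA_character_, evalue = NA_real_, hit = NULL))
  hits <- search_translated(seq_tbl("consensus", consensus), transposase_lib,
                            evalue_max = evalue_max)
  if (nrow(hits) == 0L)
    return(list(family = NA_character_, evalue = NA_real_, hit = NULL))
  best <- hits[1, ]
  desc <- transposase_lib$desc %||% transposase_lib$id
  d <- desc[match(best$target_id, transposase_lib$id)]
  fam <- stringr::str_match(d, "family=([^\\s|]+)")[, 2]
  if (is.na(fam)) {
    toks <- strsplit(d, "|", fixed = TRUE)[[1]]
    fam <- if (length(toks) >= 2L) toks[2] else best$target_id
  }
  list(family = fam, evalue = best$evalue, hit = best)
}

#' Compile all genomic copies of an IS consensus
#'
#' Every local hit of the consensus against the genome at the E-value cutoff
#' becomes a copy, including truncated ones; overlapping same-strand copies
#' are merged. Copies covering less than 90% of the consensus are flagged
#' truncated.
#'
#' @param consensus consensus sequence (string).
#' @param genome single-row genome tibble.
#' @param evalue_max local-search E-value cutoff (1e-5).
#' @return A copies tibble: `start`, `end`, `strand`, `identity`, `truncated`.
#' @export
expand_is_copies <- function(consensus, genome, evalue_max = 1e-5) {
  hits <- search_nt(seq_tbl("consensus", consensus), genome,
                    evalue_max = evalue_max)
  if (nrow(hits) == 0L)
    stop("internal error: consensus has no genomic hits")
  iv <- hits %>%
    dplyr::transmute(start = .data$t_start, end = .data$t_end,
                     strand = .data$strand,
                     identity = .data$pct_identity / 100) %>%
    dplyr::arrange(.data$strand, .data$start)
  merged <- iv %>%
    dplyr::group_by(.data$strand) %>%
    dplyr::group_modify(function(df, key) {
      out <- df[0, ]
      for (i in seq_len(nrow(df))) {
        n <- nrow(out)
        if (n > 0L && df$start[i] < out$end[n]) {
          out$end[n] <- max(out$end[n], df$end[i])
          out$identity[n] <- max(out$identity[n], df$identity[i])
        } else out <- dplyr::bind_rows(out, df[i, ])
      }
      out
    }) %>% dplyr::ungroup() %>%
    dplyr::arrange(.data$start)
  dplyr::mutate(merged,
                truncated = (.data$end - .data$start) < 0.9 * nchar(consensus))
}

# terminal IR pair of a consensus: the longest maximal pair whose arms sit
# within `margin` of the two ends
detect_terminal_ir <- function(consensus, params = ir_params(), margin = 30L) {
  n <- nchar(consensus)
  prm <- params
  if (n - 10L < prm$max_gap) {
    prm <- ir_params(prm$min_arm, prm$max_arm, min(prm$max_gap, n),
                     prm$max_mismatch)
  }
  pairs <- find_inverted_repeats(seq_tbl("c", consensus), prm)
  ok <- pairs$left_start <= margin & pairs$right_end >= n - margin
  if (!any(ok)) return(list(ir_len = 0L, ir_mismatches = NA_integer_))
  best <- pairs[ok, ][which.max(pairs$arm_len[ok]), ]
  list(ir_len = best$arm_len, ir_mismatches = best$mismatches)
}

# direct-repeat (target-site duplication) length: the longest flank word
# duplicated identically on both sides of at least two copies
detect_dr <- function(copies, genome, max_dr = 15L) {
  g <- genome$seq[1]
  n <- nchar(g)
  per_copy <- vapply(seq_len(nrow(copies)), function(i) {
    s <- copies$start[i]; e <- copies$end[i]
    best <- 0L
    for (L in seq_len(max_dr)) {
      if (s - L < 0L || e + L > n) break
      left <- stringi::stri_sub(g, s - L + 1L, s)
      right <- stringi::stri_sub(g, e + 1L, e + L)
      if (left == right) best <- L
    }
    best
  }, integer(1))
  if (length(per_copy) < 2L) return(0L)
  sort(per_copy, decreasing = TRUE)[2]
}

#' Separate and reconstruct nested ("Russian doll") elements
#'
#' When a candidate interval strictly contains another, the inner element is
#' excised and the outer element's flanks joined; multiple nesting levels are
#' handled recursively. Partially overlapping intervals are passed through
#' with a warning.
#'
#' @param intervals tibble with `start`, `end` (0-based half-open, one
#'   sequence).
#' @param genome single-row genome tibble.
#' @return A tibble `start`, `end`, `seq` with the reconstructed sequence of
#'   every input interval.
#' @export
separate_nested <- function(intervals, genome) {
  g <- genome$seq[1]
  iv <- dplyr::distinct(intervals[, c("start", "end")])
  n <- nrow(iv)
  if (n == 0L) return(dplyr::mutate(iv, seq = character()))
  # warn on partial (non-nested) overlaps
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- iv[i, ]; b <- iv[j, ]
    if (a$start < b$start && a$end > b$start && a$end < b$end)
      warning("partially overlapping candidate intervals [", a$start, ",",
              a$end, ") and [", b$start, ",", b$end, "): both passed through")
  }
  reconstruct <- function(i) {
    s <- iv$start[i]; e <- iv$end[i]
    inner <- which(iv$start > s & iv$end < e)
    # direct children only: not contained in another inner interval
    if (length(inner) > 1L) {
      keep <- vapply(inner, function(a) {
        !any(vapply(inner, function(b) {
          b != a && iv$start[b] <= iv$start[a] && iv$end[b] >= iv$end[a] &&
            (iv$start[b] < iv$start[a] || iv$end[b] > iv$end[a])
        }, logical(1)))
      }, logical(1))
      inner <- inner[keep]
    }
    if (length(inner) == 0L) return(stringi::stri_sub(g, s + 1L, e))
    spans <- iv[inner, ] %>% dplyr::arrange(.data$start)
    pieces <- character()
    cur <- s
    for (r in seq_len(nrow(spans))) {
      pieces <- c(pieces, stringi::stri_sub(g, cur + 1L, spans$start[r]))
      cur <- spans$end[r]
    }
    pieces <- c(pieces, stringi::stri_sub(g, cur + 1L, e))
    paste0(pieces, collapse = "")
  }
  iv$seq <- vapply(seq_len(n), reconstruct, character(1))
  iv
}

#' Link a MITE candidate to its autonomous IS partner
#'
#' Implements the terminal-word partner search: the terminal `term_len` bases
#' of the MITE centroid are located genome-wide (ungapped, both strands, a few
#' mismatches allowed); co-occurring 5'/3' matches in proper relative
#' orientation spanning less than `mite_max_len` define candidate partner
#' intervals; intervals occurring fewer than 2 times are dropped; nested
#' elements are separated; survivors are validated by translated search
#' against the transposase library. A validated partner longer than the MITE
#' yields an IS call and sets the MITE's `partner`; otherwise the MITE is a
#' `MITE_like_orphan`.
#'
#' @param mite one-row tibble (`id`, `seq`) - the MITE cluster centroid.
#' @param genome single-row genome tibble.
#' @param transposase_lib amino-acid library tibble (ISFinder stand-in).
#' @param cfg a [pipeline_config()].
#' @param evidence provenance tag for the produced calls.
#' @return A calls tibble: the MITE call and, when a new partner is
#'   validated, its IS call.
#' @export
link_mite_partners <- function(mite, genome, transposase_lib,
                               cfg = pipeline_config(), evidence = "ir") {
  mseq <- mite$seq[1]
  mlen <- nchar(mseq)
  mite_call <- function(kind, partner = NA_character_) {
    copies <- tryCatch(
      expand_is_copies(mseq, genome, evalue_max = cfg$evalue_is_expand),
      error = function(e) tibble::tibble(start = integer(), end = integer(),
                                         strand = character(),
                                         identity = numeric(),
                                         truncated = logical()))
    irinfo <- detect_terminal_ir(mseq, cfg$ir)
    drl <- detect_dr(copies, genome)
    tibble::tibble(
      call_id = paste0("mite:", mite$id[1]), kind = kind,
      family = NA_character_, family_evalue = NA_real_,
      consensus = mseq, length = mlen, n_copies = nrow(copies),
      copies = list(copies), ir_len = irinfo$ir_len,
      ir_mismatches = irinfo$ir_mismatches,
      dr_len = drl, partner = partner,
      evidence = evidence)
  }
  if (mlen < 2L * cfg$term_len) {
    out <- mite_call("MITE_like_orphan")
    attr(out, "log") <- paste0(mite$id[1], ": centroid shorter than two ",
                               "terminal words; partner search skipped")
    return(out)
  }
  t5 <- substr(mseq, 1L, cfg$term_len)
  t3 <- substr(mseq, mlen - cfg$term_len + 1L, mlen)
  gcode <- encode_nt(genome$seq[1])
  occ <- function(w) word_occurrences_cpp(gcode, encode_nt(w),
                                          cfg$term_max_mismatch)
  p5 <- occ(t5); p3 <- occ(t3)
  m5 <- occ(revcomp(t5)); m3 <- occ(revcomp(t3))
  # plus orientation: 5' word ... 3' word; minus: rc(3') ... rc(5')
  pair_up <- function(lefts, rights) {
    out <- list()
    for (i in lefts) {
      js <- rights[rights >= i & (rights + cfg$term_len - i) < cfg$mite_max_len]
      for (j in js) out[[length(out) + 1L]] <- c(i, j + cfg$term_len)
    }
    out
  }
  ivs <- c(pair_up(p5, p3), pair_up(m3, m5))
  if (length(ivs) == 0L) return(mite_call("MITE_like_orphan"))
  iv <- dplyr::distinct(tibble::tibble(
    start = vapply(ivs, `[`, 0, 1), end = vapply(ivs, `[`, 0, 2)))
  # doubleton rule: drop partner sequences occurring < 2 times
  iv$seq <- stringi::stri_sub(genome$seq[1], iv$start + 1L, iv$end)
  ncop <- count_occurrences(iv, genome, identity = cfg$occurrence_identity,
                            max_count = 2L)
  iv <- iv[ncop >= 2L, ]
  if (nrow(iv) == 0L) return(mite_call("MITE_like_orphan"))
  rec <- separate_nested(iv, genome)
  rec <- rec[order(-(nchar(rec$seq))), ]
  for (r in seq_len(nrow(rec))) {
    if (nchar(rec$seq[r]) <= mlen) next
    ann <- annotate_consensus(rec$seq[r], transposase_lib,
                              evalue_max = cfg$evalue_validate)
    if (is.null(ann$hit)) next
    # validated partner: emit an IS call and link the MITE to it
    pid <- paste0("is_partner:", mite$id[1])
    copies <- expand_is_copies(rec$seq[r], genome,
                               evalue_max = cfg$evalue_is_expand)
    irinfo <- detect_terminal_ir(rec$seq[r], cfg$ir)
    drl <- detect_dr(copies, genome)
    is_call <- tibble::tibble(
      call_id = pid, kind = "IS", family = ann$family,
      family_evalue = ann$evalue, consensus = rec$seq[r],
      length = nchar(rec$seq[r]), n_copies = nrow(copies),
      copies = list(copies), ir_len = irinfo$ir_len,
      ir_mismatches = irinfo$ir_mismatches,
      dr_len = drl, partner = NA_character_,
      evidence = evidence)
    return(dplyr::bind_rows(mite_call("MITE", partner = pid), is_call))
  }
  mite_call("MITE_like_orphan")
}

#' Screen calls against a decoy library of known non-TE genes
#'
#' A call is removed when its consensus matches the decoy library (group-II
#' intron proteins, phage integrases, rRNA genes, ...) more strongly - lower
#' E-value - than it matches the transposase library.
#'
#' @param calls a calls tibble (with `family_evalue` from annotation).
#' @param decoy_lib decoy sequence tibble (amino-acid or nucleotide); an
#'   empty/NULL library passes everything through.
#' @param evalue_max decoy search E-value cutoff.
#' @return A list with `kept` and `removed` calls tibbles; `removed` gains a
#'   `removed_reason` column.
#' @export
filter_known_non_te <- function(calls, decoy_lib, evalue_max = 1e-5) {
  if (is.null(decoy_lib) || nrow(decoy_lib) == 0L || nrow(calls) == 0L) {
    return(list(kept = calls,
                removed = dplyr::mutate(calls[0, ],
                                        removed_reason = character())))
  }
  decoy_is_aa <- guess_alphabet(decoy_lib) == "aa"
  removed <- logical(nrow(calls))
  reason <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    q <- seq_tbl("call", calls$consensus[i])
    hits <- if (decoy_is_aa) {
      search_translated(q, decoy_lib, evalue_max = evalue_max)
    } else {
      search_nt(q, decoy_lib, evalue_max = evalue_max)
    }
    if (nrow(hits) == 0L) next
    tpase_e <- calls$family_evalue[i]
    if (is.na(tpase_e) || hits$evalue[1] < tpase_e) {
      removed[i] <- TRUE
      reason[i] <- paste0("decoy ", hits$target_id[1], " at E = ",
                          signif(hits$evalue[1], 3))
    }
  }
  list(kept = calls[!removed, ],
       removed = dplyr::mutate(calls[removed, ],
                               removed_reason = reason[removed]))
}

# shared de novo tail: cluster consensi, size-split, expand / link, annotate
denovo_tail <- function(cand_seqs, genome, transposase_lib, cfg, evidence,
                        decoy_lib = NULL) {
  if (nrow(cand_seqs) == 0L) {
    return(list(kept = empty_calls(),
                removed = dplyr::mutate(empty_calls(),
                                        removed_reason = character())))
  }
  clusters <- greedy_cluster(cand_seqs, cfg$cluster_identity, alphabet = "nt")
  centroids <- split_by_size(cluster_centroids(clusters), cfg$size_threshold)
  calls <- empty_calls()
  for (i in which(centroids$branch == "IS")) {
    cons <- centroids$seq[i]
    copies <- expand_is_copies(cons, genome, evalue_max = cfg$evalue_is_expand)
    ann <- annotate_consensus(cons, transposase_lib,
                              evalue_max = cfg$evalue_validate)
    irinfo <- detect_terminal_ir(cons, cfg$ir)
    drl <- detect_dr(copies, genome)
    calls <- dplyr::bind_rows(calls, tibble::tibble(
      call_id = paste0("is:", centroids$id[i]), kind = "IS",
      family = ann$family, family_evalue = ann$evalue, consensus = cons,
      length = nchar(cons), n_copies = nrow(copies), copies = list(copies),
      ir_len = irinfo$ir_len, ir_mismatches = irinfo$ir_mismatches,
      dr_len = drl, partner = NA_character_,
      evidence = evidence))
  }
  for (i in which(centroids$branch == "MITE")) {
    calls <- dplyr::bind_rows(
      calls,
      link_mite_partners(centroids[i, c("id", "seq")], genome, transposase_lib,
                         cfg, evidence = evidence))
  }
  # a MITE partner IS may duplicate an independently called IS: if its copies
  # overlap an existing IS call's copies, re-point the MITE at that call
  if (nrow(calls) > 1L) {
    drop <- logical(nrow(calls))
    partner_rows <- which(grepl("^is_partner:", calls$call_id))
    other_is <- setdiff(which(calls$kind == "IS"), partner_rows)
    for (p in partner_rows) {
      for (j in other_is) {
        if (calls_overlap(calls$copies[[p]], calls$copies[[j]])) {
          calls$partner[!is.na(calls$partner) &
                          calls$partner == calls$call_id[p]] <- calls$call_id[j]
          drop[p] <- TRUE
          break
        }
      }
    }
    calls <- calls[!drop, ]
  }
  filter_known_non_te(calls, decoy_lib, evalue_max = cfg$evalue_validate)
}

calls_overlap <- function(ca, cb, min_frac = 0.5) {
  if (nrow(ca) == 0L || nrow(cb) == 0L) return(FALSE)
  for (i in seq_len(nrow(ca))) {
    ov <- pmin(ca$end[i], cb$end) - pmax(ca$start[i], cb$start)
    if (any(ov > min_frac * (ca$end[i] - ca$start[i]))) return(TRUE)
  }
  FALSE
}

#' Run the repeats-search de novo pipeline
#'
#' Repeat-family mining, clustering of the consensi, 500 bp size split, IS
#' copy expansion / MITE partner linking, transposase annotation and optional
#' decoy screening.
#'
#' @param genome single-row nucleotide genome tibble.
#' @param transposase_lib amino-acid transposase library tibble (headers may
#'   carry `family=...` tags for family annotation).
#' @param cfg a [pipeline_config()].
#' @param decoy_lib optional decoy library for false-positive screening.
#' @return A calls tibble (evidence tag `"repeats"`), with the removed calls
#'   in `attr(, "removed")`.
#' @export
run_repeats_search <- function(genome, transposase_lib,
                               cfg = pipeline_config(), decoy_lib = NULL) {
  fams <- find_repeat_families(genome, cfg$repeat_par)
  cand <- if (nrow(fams) == 0L) tibble::tibble(id = character(),
                                               seq = character())
          else tibble::tibble(id = fams$family_id, seq = fams$consensus)
  res <- denovo_tail(cand, genome, transposase_lib, cfg,
                     evidence = "repeats", decoy_lib = decoy_lib)
  out <- res$kept
  attr(out, "removed") <- res$removed
  out
}

#' Run the IR-search de novo pipeline
#'
#' IR pair detection, candidate extraction, singleton removal, then the shared
#' de novo tail. IS families without terminal IRs are invisible to this path.
#'
#' @inheritParams run_repeats_search
#' @return A calls tibble (evidence tag `"ir"`), with removed calls in
#'   `attr(, "removed")`.
#' @export
run_ir_search <- function(genome, transposase_lib, cfg = pipeline_config(),
                          decoy_lib = NULL) {
  pairs <- find_inverted_repeats(genome, cfg$ir)
  # arm significance and size floors commute with extraction; applying them
  # on the pair list first avoids materialising candidates for the bulk of
  # marginal chance pairs
  pairs <- pairs[pairs$arm_len - 3L * pairs$mismatches >= cfg$min_arm_score &
                   pairs$right_end - pairs$left_start >=
                     cfg$repeat_par$min_len, ]
  cands <- extract_ir_candidates(genome, pairs)
  kept <- filter_singletons(cands, genome, min_copies = cfg$min_copies_ir,
                            identity = cfg$occurrence_identity)
  kept <- sharpen_ir_candidates(kept, genome)
  # one candidate per element locus, preferring the strongest terminal arms
  # (a real IS/MITE IR beats the marginal chance pairs near the same spot),
  # then the longer span
  if (nrow(kept) > 1L) {
    kept <- kept[order(-(kept$arm_len - 3L * kept$mismatches),
                       -(kept$end - kept$start), kept$start), ]
  }
  kept <- dedupe_contained_spans(kept)
  cand <- if (nrow(kept) == 0L) tibble::tibble(id = character(),
                                               seq = character())
          else tibble::tibble(id = kept$cand_id, seq = kept$seq)
  res <- denovo_tail(cand, genome, transposase_lib, cfg, evidence = "ir",
                     decoy_lib = decoy_lib)
  out <- res$kept
  attr(out, "removed") <- res$removed
  out
}

#' Keep IR candidates whose boundaries are real element boundaries
#'
#' A genuine element's repeated unit stops at its termini: extending the
#' candidate span by `flank` bases on each side must give a sequence that no
#' longer occurs multiple times (the flanks of independent copies are
#' unrelated). A candidate lying inside a larger repeated region (e.g. a
#' chance IR pair inside an IS) fails this test and is discarded.
#'
#' @param kept filtered candidates (with `start`, `end`, `seq`).
#' @param genome single-row genome tibble.
#' @param flank_frac flank extension as a fraction of the candidate length
#'   (at least 30 nt). Must be large enough that a repeated candidate's
#'   extended span falls below the occurrence counter's coverage requirement.
#' @return The candidates whose extended span is single-copy.
#' @export
sharpen_ir_candidates <- function(kept, genome, flank_frac = 0.2) {
  if (nrow(kept) == 0L) return(kept)
  n <- nchar(genome$seq[1])
  flank <- pmax(30L, as.integer(ceiling(flank_frac * (kept$end - kept$start))))
  ext <- tibble::tibble(
    seq = stringi::stri_sub(genome$seq[1],
                            pmax(kept$start - flank, 0L) + 1L,
                            pmin(kept$end + flank, n)))
  cnt <- count_occurrences(ext, genome, min_cov = 0.8)
  kept[cnt < 2L, ]
}

# greedy span dedup in the caller's preference order: drop a span when half
# of the shorter of the two overlaps an already-kept span (one candidate per
# element locus)
dedupe_contained_spans <- function(kept) {
  if (nrow(kept) <= 1L) return(kept)
  keep <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    clash <- FALSE
    for (j in which(keep)) {
      if (kept$seq_id[j] != kept$seq_id[i]) next
      ov <- min(kept$end[i], kept$end[j]) - max(kept$start[i], kept$start[j])
      shorter <- min(kept$end[i] - kept$start[i],
                     kept$end[j] - kept$start[j])
      if (ov >= 0.5 * shorter) { clash <- TRUE; break }
    }
    keep[i] <- !clash
  }
  out <- kept[keep, ]
  out[order(out$start), ]
}

#' Run the profile HMM search pipeline
#'
#' Nucleotide input is cut into windows, six-frame translated and searched
#' with every calibrated profile; peptide input is searched directly. Hit
#' envelopes are mapped back to genome coordinates, deduplicated across
#' overlapping windows, and the hit peptides clustered at 0.9 identity.
#'
#' @param input sequence tibble: nucleotide genome/contigs/reads, or peptides.
#' @param profiles list of calibrated `profile_hmm` objects.
#' @param cfg a [pipeline_config()].
#' @return A tibble of hits: `profile`, `parent_id`, `frame`, `g_start`,
#'   `g_end` (0-based half-open on the input sequence; NA for peptide input),
#'   `bits`, `evalue`, `peptide` (envelope) and `cluster_id`.
#' @export
run_hmm_pipeline <- function(input, profiles, cfg = pipeline_config()) {
  alph <- guess_alphabet(input)
  if (alph == "nt") {
    segs <- segment_genome(input, cfg$window, cfg$overlap)
    tr <- translate_six_frames(segs %>% dplyr::select(id = "segment_id",
                                                      "seq"))
    tr <- dplyr::left_join(
      tr, segs %>% dplyr::select(segment_id = "segment_id",
                                 seg_parent = "parent_id",
                                 seg_start = "start", seg_end = "end"),
      by = c(parent_id = "segment_id"))
  } else {
    tr <- tibble::tibble(parent_id = input$id, frame = NA_integer_,
                         nt_offset = 0L, peptide = input$seq,
                         seg_parent = input$id, seg_start = NA_integer_,
                         seg_end = NA_integer_)
  }
  hits <- search_profiles(profiles, tr, evalue_max = cfg$evalue_hmm)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(profile = character(), parent_id = character(),
                          frame = integer(), g_start = integer(),
                          g_end = integer(), bits = numeric(),
                          evalue = numeric(), peptide = character(),
                          cluster_id = character()))
  }
  meta <- tr %>% dplyr::select("parent_id", "frame", "nt_offset",
                               "seg_parent", "seg_start", "seg_end",
                               "peptide") %>%
    dplyr::rename(full_peptide = "peptide")
  hits <- dplyr::left_join(hits, meta,
                           by = c(target_id = "parent_id", frame = "frame"))
  # genome coordinates of the envelope
  if (alph == "nt") {
    seg_len <- hits$seg_end - hits$seg_start
    nt0 <- hits$nt_offset + 3L * (hits$env_start - 1L)
    nt1 <- hits$nt_offset + 3L * hits$env_end
    fwd <- hits$frame > 0
    hits$g_start <- ifelse(fwd, hits$seg_start + nt0,
                           hits$seg_start + seg_len - nt1)
    hits$g_end <- ifelse(fwd, hits$seg_start + nt1,
                         hits$seg_start + seg_len - nt0)
  } else {
    hits$g_start <- NA_integer_; hits$g_end <- NA_integer_
  }
  hits$parent_id <- hits$seg_parent
  hits$peptide <- substr(hits$full_peptide, hits$env_start, hits$env_end)
  # dedupe hits duplicated by window overlap: same profile, parent, frame
  # sign, overlapping genome span -> keep the best-scoring one
  hits <- dplyr::arrange(hits, dplyr::desc(.data$bits))
  keep <- rep(TRUE, nrow(hits))
  if (alph == "nt") {
    for (i in seq_len(nrow(hits))[-1]) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (hits$profile[j] == hits$profile[i] &&
            hits$parent_id[j] == hits$parent_id[i] &&
            sign(hits$frame[j]) == sign(hits$frame[i]) &&
            hits$g_start[i] < hits$g_end[j] && hits$g_start[j] < hits$g_end[i]) {
          keep[i] <- FALSE; break
        }
      }
    }
  }
  hits <- hits[keep, ]
  hitseqs <- tibble::tibble(
    id = sprintf("%s|%s|f%+d|%d-%d", hits$profile, hits$parent_id,
                 dplyr::coalesce(hits$frame, 0L),
                 dplyr::coalesce(hits$g_start, hits$env_start),
                 dplyr::coalesce(hits$g_end, hits$env_end)),
    seq = hits$peptide)
  cl <- greedy_cluster(hitseqs, 0.9, alphabet = "aa")
  hits$hit_id <- hitseqs$id
  hits <- dplyr::left_join(hits,
                           cl %>% dplyr::select(hit_id = "id", "cluster_id"),
                           by = "hit_id")
  hits %>%
    dplyr::select("profile", "parent_id", "frame", "g_start", "g_end",
                  "bits", "evalue", "peptide", "cluster_id") %>%
    dplyr::arrange(.data$evalue, .data$profile)
}
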