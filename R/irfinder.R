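#' Inverted-repeat detection
#'
#' Mismatch-tolerant scan for terminal inverted-repeat (IR) pairs: two arms of
#' equal length whose right arm is the reverse complement of the left arm at
#' all but a bounded number of positions, separated by a bounded spacer. The
#' defaults (arm 10-50 nt, spacer up to 2000 nt, up to 2 mismatches) match the
#' classical palindrome-search settings used for prokaryotic IS ends.
#'
#' A pair is *maximal* when growing either arm by one base - inward (arms
#' toward each other) or outward (arms apart) - violates the arm-length or
#' mismatch limits, runs off the sequence, or hits an N. Arms may not contain
#' N. All maximal pairs are reported, including overlapping and nested ones.
#'
#' @name irfinder
NULL

#' IR search parameters
#'
#' @param min_arm minimum arm length (nt).
#' @param max_arm maximum arm length (nt).
#' @param max_gap maximum spacer between the arms (nt).
#' @param max_mismatch maximum non-complementary positions between the arms.
#' @return A named list of class `ir_params`.
#' @export
ir_params <- function(min_arm = 10L, max_arm = 50L, max_gap = 2000L,
                      max_mismatch = 2L) {
  stopifnot(min_arm > 0L, min_arm <= max_arm, max_gap >= 0L, max_mismatch >= 0L)
  structure(list(min_arm = as.integer(min_arm), max_arm = as.integer(max_arm),
                 max_gap = as.integer(max_gap),
                 max_mismatch = as.integer(max_mismatch)),
            class = "ir_params")
}

#' Find inverted-repeat pairs
#'
#' @param seqs nucleotide sequence tibble.
#' @param params an [ir_params()] object.
#' @return A tibble with one row per maximal IR pair: `seq_id`, `left_start`,
#'   `left_end`, `right_start`, `right_end` (0-based half-open), `arm_len`,
#'   `mismatches`, sorted by `left_start` then span length.
#' @export
find_inverted_repeats <- function(seqs, params = ir_params()) {
  stopifnot(inherits(params, "ir_params"))
  check_alphabet(seqs, "nt")
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    df <- ir_scan_cpp(seqs$seq[i], params$min_arm, params$max_arm,
                      params$max_gap, params$max_mismatch)
    dplyr::bind_cols(tibble::tibble(seq_id = rep(seqs$id[i], nrow(df))),
                     tibble::as_tibble(df))
  })
}

#' Extract IR-delimited candidate elements
#'
#' One candidate per IR pair, spanning both arms inclusive (IS convention: the
#' IRs are the terminal parts of the element). Candidates with identical spans
#' are deduplicated.
#'
#' @param seqs the sequence tibble the pairs came from.
#' @param pairs output of [find_inverted_repeats()].
#' @return A tibble with `cand_id`, `seq_id`, `start`, `end`, `seq`.
#' @export
extract_ir_candidates <- function(seqs, pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(cand_id = character(), seq_id = character(),
                          start = integer(), end = integer(), seq = character()))
  }
  lens <- setNames(nchar(seqs$seq), seqs$id)
  bad <- pairs$left_start < 0L | pairs$right_end > lens[pairs$seq_id]
  if (any(is.na(bad)) || any(bad))
    stop("IR pair coordinates outside the supplied sequences")
  out <- pairs %>%
    dplyr::transmute(seq_id = .data$seq_id, start = .data$left_start,
                     end = .data$right_end, arm_len = .data$arm_len,
                     mismatches = .data$mismatches) %>%
    dplyr::arrange(.data$seq_id, .data$start, .data$end,
                   dplyr::desc(.data$arm_len), .data$mismatches) %>%
    dplyr::distinct(.data$seq_id, .data$start, .data$end,
                    .keep_all = TRUE)
  out$seq <- stringi::stri_sub(setNames(seqs$seq, seqs$id)[out$seq_id],
                               from = out$start + 1L, to = out$end)
  dplyr::bind_cols(
    tibble::tibble(cand_id = sprintf("%s:%d-%d", out$seq_id, out$start, out$end)),
    out)
}

#' Count occurrences of candidate sequences in a genome
#'
#' Two interchangeable counters. `"kmer"` (the genome-scale default) counts
#' colinear clusters of shared canonical 16-mers on both strands: a ~90%+
#' identity copy of a candidate shares an expected 19% of its 16-mers on a
#' near-constant diagonal, while unrelated loci share essentially none, so a
#' cluster holding at least max(3, 5% of the candidate's 16-mers) marks one
#' occurrence. `"align"` runs the local-alignment search and counts hits at or
#' above `identity` covering at least `min_cov` of the candidate - exact but
#' far more expensive; it is the reference the k-mer screen is validated
#' against in the test suite.
#'
#' @param cands tibble with a `seq` column (nucleotide).
#' @param genome single-row genome tibble.
#' @param identity minimum fractional identity of an occurrence (align mode).
#' @param min_cov minimum fraction of the candidate covered (align mode).
#' @param max_count cap on the reported count.
#' @param method `"kmer"` or `"align"`.
#' @return Integer vector of occurrence counts (capped at `max_count`).
#' @export
count_occurrences <- function(cands, genome, identity = 0.9, min_cov = 0.8,
                              max_count = 10L, method = c("kmer", "align")) {
  method <- match.arg(method)
  if (nrow(cands) == 0L) return(integer())
  if (method == "kmer") {
    return(colinear_occurrence_counts_cpp(
      genome$seq[1], cands$seq, 16L, 0.05, min_cov, 0.6, 10L,
      as.integer(max_count), 200L))
  }
  counts <- integer(nrow(cands))
  scheme <- scoring_scheme("nt")
  for (i in seq_len(nrow(cands))) {
    hits <- search_nt(seq_tbl(paste0("cand", i), cands$seq[i]), genome,
                      evalue_max = 1e-3, scheme = scheme)
    qlen <- nchar(cands$seq[i])
    ok <- hits$pct_identity / 100 >= identity &
      (hits$q_end - hits$q_start) >= min_cov * qlen
    counts[i] <- min(sum(ok), max_count)
  }
  counts
}

#' Remove IR candidates without enough genomic copies
#'
#' Candidates bordered by IRs but present fewer than `min_copies` times in the
#' genome (at >= `identity` identity) are removed.
#'
#' @param candidates output of [extract_ir_candidates()].
#' @param genome single-row genome tibble.
#' @param min_copies minimum occurrence count to keep a candidate.
#' @param identity identity threshold defining an occurrence.
#' @param min_cov fraction of the candidate an occurrence must cover; near
#'   full length, since an element's IRs are flush with its termini.
#' @return The kept candidate rows, with an `n_copies` column.
#' @export
filter_singletons <- function(candidates, genome, min_copies = 2L,
                              identity = 0.9, min_cov = 0.95) {
  stopifnot(min_copies >= 1L)
  if (nrow(candidates) == 0L) return(dplyr::mutate(candidates, n_copies = integer()))
  if (min_copies == 1L) return(dplyr::mutate(candidates, n_copies = NA_integer_))
  n <- count_occurrences(candidates, genome, identity = identity,
                         min_cov = min_cov, max_count = min_copies)
  dplyr::filter(dplyr::mutate(candidates, n_copies = n),
                .data$n_copies >= min_copies)
}
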