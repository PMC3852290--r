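#' De novo repeat-family discovery
#'
#' l-mer seeded, greedy-extension repeat consensus mining. Canonical l-mers
#' (forward and reverse-complement occurrences folded together) occurring at
#' least `min_copies` times seed a gapless multi-copy extension: at each flank
#' step the majority base over live copies is appended to the consensus, each
#' copy scores +1 for agreement and -2 for disagreement, and a copy drops out
#' when its cumulative flank score falls `max_score_drop` below its own
#' maximum. A flank stops when fewer than `min_copies` copies remain live and
#' is trimmed back to its aggregate-score peak. Accepted families mask their
#' copy positions so each genome position supports at most one family.
#'
#' @name repeatfinder
NULL

#' Repeat-search parameters
#'
#' @param lmer seed word size (default 9).
#' @param min_copies minimum copies for seeding and for keeping a family
#'   (default 3; raising it to 4-5 trades sensitivity for specificity).
#' @param min_len minimum consensus length (nt).
#' @param max_len maximum consensus length (nt), capping runaway extension.
#' @param match,mismatch_penalty per-position extension scores (+1 / -2).
#' @param max_score_drop a copy drops out when its flank score falls this far
#'   below its running maximum.
#' @param min_entropy skip seeds below this Shannon entropy (bits/base).
#' @return A named list of class `repeat_params`.
#' @export
repeat_params <- function(lmer = 9L, min_copies = 3L, min_len = 50L,
                          max_len = 10000L, match = 1, mismatch_penalty = 2,
                          max_score_drop = 20, min_entropy = 1.0) {
  stopifnot(lmer >= 4L, lmer <= 31L, min_copies >= 2L, min_len > lmer)
  structure(list(lmer = as.integer(lmer), min_copies = as.integer(min_copies),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 match = match, mismatch_penalty = mismatch_penalty,
                 max_score_drop = max_score_drop, min_entropy = min_entropy),
            class = "repeat_params")
}

DECODE_NT <- c("A", "C", "G", "T", "N")

decode_nt <- function(codes) paste0(DECODE_NT[codes + 1L], collapse = "")

#' Enumerate repeated l-mer seeds
#'
#' Canonical l-mers (an occurrence of the reverse complement counts as a
#' minus-strand occurrence of the same seed) occurring at least `min_count`
#' times, with all positions, sorted by descending count then lexicographically.
#'
#' @param genome single-row nucleotide tibble.
#' @param lmer word size.
#' @param min_count minimum occurrence count.
#' @return A tibble: `lmer` (canonical word), `count`, and a nested
#'   `positions` list-column of tibbles (`pos` 0-based, `strand`).
#' @export
seed_lmers <- function(genome, lmer = 9L, min_count = 3L) {
  stopifnot(nrow(genome) == 1L, lmer <= nchar(genome$seq[1]))
  g <- genome$seq[1]
  n <- nchar(g)
  words <- stringi::stri_sub(g, from = seq_len(n - lmer + 1L), length = lmer)
  valid <- !grepl("N", words, fixed = TRUE)
  rc <- revcomp(words[valid])
  fwd <- words[valid]
  canon <- ifelse(fwd <= rc, fwd, rc)
  strand <- ifelse(fwd <= rc, "+", "-")
  pos <- (seq_len(n - lmer + 1L) - 1L)[valid]
  tb <- tibble::tibble(lmer = canon, pos = pos, strand = strand)
  counts <- tb %>% dplyr::count(.data$lmer, name = "count") %>%
    dplyr::filter(.data$count >= min_count)
  if (nrow(counts) == 0L) {
    return(tibble::tibble(lmer = character(), count = integer(),
                          positions = list()))
  }
  tb <- dplyr::semi_join(tb, counts, by = "lmer")
  nested <- tb %>% dplyr::arrange(.data$lmer, .data$pos) %>%
    tidyr::nest(positions = c("pos", "strand"))
  out <- dplyr::left_join(counts, nested, by = "lmer") %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$lmer)
  out
}

#' Build one repeat-family consensus from seed occurrences
#'
#' @param genome single-row nucleotide tibble.
#' @param seed_positions tibble with `pos` (0-based l-mer start) and `strand`
#'   (`"+"`/`"-"`) columns, as produced by [seed_lmers()].
#' @param params a [repeat_params()].
#' @return A one-row family tibble (`consensus`, `length`, nested `copies`
#'   with `start`, `end`, `strand`, `identity`), or `NULL` when fewer than
#'   `min_copies` seeds are given or the trimmed consensus is shorter than
#'   `min_len`.
#' @export
build_consensus <- function(genome, seed_positions, params = repeat_params()) {
  stopifnot(nrow(genome) == 1L)
  if (nrow(seed_positions) < params$min_copies) return(NULL)
  res <- build_consensus_cpp(
    encode_nt(genome$seq[1]),
    as.integer(seed_positions$pos),
    ifelse(seed_positions$strand == "+", 1L, -1L),
    params$lmer, params$min_copies, params$min_len, params$max_len,
    params$match, params$mismatch_penalty, params$max_score_drop)
  if (is.null(res)) return(NULL)
  copies <- tibble::as_tibble(res$copies)
  copies$strand <- ifelse(copies$strand > 0, "+", "-")
  tibble::tibble(
    consensus = decode_nt(res$consensus),
    length = length(res$consensus),
    copies = list(copies)
  )
}

#' Find all repeat families in a genome
#'
#' Iterates seeds by descending occurrence count (ties lexicographic), builds
#' a consensus for each, and masks accepted families' copy intervals so later
#' seeds cannot reuse the same genome positions. Deterministic given params.
#'
#' @param genome single-row nucleotide tibble.
#' @param params a [repeat_params()].
#' @return A tibble with one row per family: `family_id`, `consensus`,
#'   `length`, `n_copies`, and a nested `copies` tibble (`start`, `end`,
#'   `strand`, `identity`; 0-based half-open).
#' @export
find_repeat_families <- function(genome, params = repeat_params()) {
  stopifnot(nrow(genome) == 1L)
  fams <- repeat_families_cpp(
    encode_nt(genome$seq[1]), params$lmer, params$min_copies, params$min_len,
    params$max_len, params$match, params$mismatch_penalty,
    params$max_score_drop, params$min_entropy)
  empty <- tibble::tibble(family_id = character(), consensus = character(),
                          length = integer(), n_copies = integer(),
                          copies = list())
  if (length(fams) == 0L) return(empty)
  consensi <- vapply(fams, function(f) decode_nt(f$consensus), character(1))
  # The greedy extension discovers the consensus; the definitive copy list is
  # re-derived by locating the consensus genome-wide (k-mer colinearity), so
  # copy counts do not depend on which seed anchored the extension.
  # word 13 with a relaxed tiling requirement: family copies can be ~10-15%
  # diverged from the consensus, which thins intact 16-mers sharply
  loc <- colinear_occurrence_locate_cpp(genome$seq[1], consensi, 13L, 0.05,
                                        0.8, 0.5, 10L, 200L)
  claimed <- list()  # copy intervals of already-emitted families
  out <- list()
  gseq <- genome$seq[1]
  for (i in seq_along(consensi)) {
    copies <- tibble::as_tibble(loc[loc$cand == i, c("start", "end", "strand")])
    if (nrow(copies) == 0L) next
    free <- vapply(seq_len(nrow(copies)), function(r) {
      !any(vapply(claimed, function(cl)
        any(pmin(cl$end, copies$end[r]) - pmax(cl$start, copies$start[r]) >
              0.25 * (copies$end[r] - copies$start[r])), logical(1)))
    }, logical(1))
    copies <- copies[free, ]
    if (nrow(copies) < params$min_copies) next
    oriented <- vapply(seq_len(nrow(copies)), function(r) {
      s <- stringi::stri_sub(gseq, copies$start[r] + 1L, copies$end[r])
      if (copies$strand[r] == "-") revcomp(s) else s
    }, character(1))
    # polish the consensus: per-column majority over the full-length oriented
    # copies (ties lexicographic); repairs any phase mixing of the greedy
    # extension's seed anchors
    full <- nchar(oriented) == nchar(consensi[i])
    if (sum(full) >= params$min_copies) {
      mat <- matrix(unlist(strsplit(oriented[full], "")), ncol = sum(full))
      consensi[i] <- paste0(apply(mat, 1, function(col) {
        names(which.max(table(factor(col, levels = c("A", "C", "G", "T", "N")))))
      }), collapse = "")
    }
    copies$identity <- vapply(oriented, function(s) {
      pairwise_identity(s, consensi[i], "nt")
    }, numeric(1), USE.NAMES = FALSE)
    copies <- dplyr::arrange(copies, .data$start)
    claimed[[length(claimed) + 1L]] <- copies
    out[[length(out) + 1L]] <- tibble::tibble(
      family_id = sprintf("repfam_%03d", length(out) + 1L),
      consensus = consensi[i],
      length = nchar(consensi[i]),
      n_copies = nrow(copies),
      copies = list(copies))
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}
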