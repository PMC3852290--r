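#' Seeded local-alignment search with Karlin-Altschul statistics
#'
#' A compact seed-and-extend local aligner: exact word seeds (word 11 for
#' nucleotide, word 4 on a reduced residue alphabet for translated mode),
#' ungapped X-drop extension, then full affine-gap Smith-Waterman over the
#' seeded window. E-values follow the Karlin-Altschul form
#' E = K * m * n * exp(-lambda * S); lambda for ungapped scoring solves the
#' Karlin sum sum_ij p_i p_j exp(lambda * s_ij) = 1 at the scheme's background
#' frequencies, and gapped mode uses the documented empirical correction
#' lambda_gapped = 0.9 * lambda_ungapped with K unchanged.
#'
#' @name localsearch
NULL

encode_nt <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  v[is.na(v)] <- 4L
  v
}

encode_aa <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], AA_CHARS) - 1L
  v[is.na(v)] <- 20L
  v
}

# Murphy 10-letter reduced alphabet for protein seed words
MURPHY10 <- c(
  A = 0L, S = 1L, G = 2L, T = 1L, P = 3L,
  L = 4L, V = 4L, I = 4L, M = 4L, C = 5L,
  F = 6L, Y = 6L, W = 6L,
  E = 7L, D = 7L, N = 7L, Q = 7L,
  K = 8L, R = 8L, H = 9L
)

encode_aa_reduced <- function(x) {
  v <- unname(MURPHY10[strsplit(x, "", fixed = TRUE)[[1]]])
  v[is.na(v)] <- -1L
  v
}

nt_score_matrix <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 5, 5)
  diag(m)[1:4] <- match
  m[5, ] <- mismatch; m[, 5] <- mismatch  # N never matches
  m
}

aa_score_matrix <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  m <- matrix(-1, 21, 21)
  m[1:20, 1:20] <- b62[AA_CHARS, AA_CHARS]
  m[21, ] <- -1; m[, 21] <- -1  # X / unknown
  m
}

#' Scoring scheme for local search
#'
#' @param mode `"nt"` (match +1 / mismatch -2, gap open 5 / extend 2) or
#'   `"tx"` (BLOSUM62, gap open 11 / extend 1). Penalties are positive; a gap
#'   of length g costs `gap_open + g * gap_extend`.
#' @param K Karlin-Altschul K constant.
#' @param word seed word size (11 nt; 4 reduced residues).
#' @param xdrop ungapped extension X-drop threshold.
#' @return A list of class `scoring_scheme` with the score matrix, penalties
#'   and the calibrated `lambda` (ungapped) and `lambda_gapped`.
#' @export
scoring_scheme <- function(mode = c("nt", "tx"), K = 0.1, word = NULL,
                           xdrop = 20) {
  mode <- match.arg(mode)
  if (mode == "nt") {
    smat <- nt_score_matrix()
    bg <- rep(0.25, 4)
    core <- smat[1:4, 1:4]
    gap_open <- 5; gap_ext <- 2
    word <- word %||% 11L
    min_ungapped <- 14
  } else {
    smat <- aa_score_matrix()
    bg <- rep(0.05, 20)
    core <- smat[1:20, 1:20]
    gap_open <- 11; gap_ext <- 1
    word <- word %||% 4L
    min_ungapped <- 15
  }
  lambda <- karlin_lambda(core, bg)
  structure(list(mode = mode, smat = smat, gap_open = gap_open,
                 gap_ext = gap_ext, K = K, lambda = lambda,
                 lambda_gapped = 0.9 * lambda, word = as.integer(word),
                 xdrop = xdrop, min_ungapped = min_ungapped),
            class = "scoring_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the Karlin sum for lambda
#'
#' Finds the positive root of `sum_ij p_i p_j exp(lambda * s_ij) = 1` for an
#' ungapped scoring matrix with negative expected score.
#'
#' @param smat square score matrix over the core alphabet.
#' @param bg background letter frequencies (sums to 1).
#' @return lambda (> 0).
#' @export
karlin_lambda <- function(smat, bg) {
  pp <- outer(bg, bg)
  if (sum(pp * smat) >= 0)
    stop("expected score per aligned pair must be negative")
  f <- function(l) sum(pp * exp(l * smat)) - 1
  uniroot(f, interval = c(1e-8, 20), tol = 1e-12)$root
}

#' Karlin-Altschul E-value
#'
#' @param score raw alignment score.
#' @param m query length.
#' @param n database length.
#' @param scheme a [scoring_scheme()]; its gapped lambda is used.
#' @param gapped use `lambda_gapped` (default) or the ungapped lambda.
#' @return `E = K * m * n * exp(-lambda * score)`.
#' @export
karlin_evalue <- function(score, m, n, scheme, gapped = TRUE) {
  stopifnot(m > 0, n > 0)
  lam <- if (gapped) scheme$lambda_gapped else scheme$lambda
  scheme$K * m * n * exp(-lam * score)
}

# cluster seed matches into candidate windows on (diagonal, target-pos)
cluster_seeds <- function(seeds, diag_band = 16L, pos_gap = 250L) {
  if (nrow(seeds) == 0L) return(list())
  d <- seeds[, 2] - seeds[, 1]
  o <- order(d, seeds[, 2])
  d <- d[o]; qp <- seeds[o, 1]; tp <- seeds[o, 2]
  brk <- c(TRUE, diff(d) > diag_band | diff(tp) > pos_gap)
  grp <- cumsum(brk)
  lapply(split(seq_along(grp), grp), function(ix) {
    cbind(q = qp[ix], t = tp[ix])
  })
}

# one (query, target) strand search over integer codes
search_one <- function(qcode, tcode, scheme, asz, seed_q = NULL, seed_t = NULL) {
  word <- scheme$word
  if (is.null(seed_q)) seed_q <- qcode
  if (is.null(seed_t)) seed_t <- tcode
  seeds <- kmer_match_cpp(seed_q, seed_t, word, asz)
  cl <- cluster_seeds(seeds)
  hits <- list()
  for (grp in cl) {
    s <- grp[1, , drop = TRUE]
    ext <- xdrop_ungapped_cpp(qcode, tcode, s[["q"]], s[["t"]], word,
                              scheme$smat, scheme$xdrop)
    if (ext$score < scheme$min_ungapped) next
    qlen <- length(qcode)
    t_lo <- max(0L, min(grp[, "t"]) - qlen - 30L)
    t_hi <- min(length(tcode), max(grp[, "t"]) + word + qlen + 30L)
    sw <- sw_align_cpp(qcode, tcode[(t_lo + 1L):t_hi], scheme$smat,
                       scheme$gap_open, scheme$gap_ext)
    if (sw$score <= 0) next
    hits[[length(hits) + 1L]] <- tibble::tibble(
      q_start = sw$a_start, q_end = sw$a_end,
      t_start = t_lo + sw$b_start, t_end = t_lo + sw$b_end,
      score = sw$score, matches = sw$matches, aln_len = sw$aln_len)
  }
  if (length(hits) == 0L) return(NULL)
  dplyr::distinct(dplyr::bind_rows(hits))
}

# drop hits whose target span is fully contained in a higher-scoring kept hit
drop_contained <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$t_start)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      same <- hits$strand[j] == hits$strand[i] &&
        hits$target_id[j] == hits$target_id[i] &&
        hits$query_id[j] == hits$query_id[i]
      if (same && hits$t_start[j] <= hits$t_start[i] &&
          hits$t_end[j] >= hits$t_end[i]) { keep[i] <- FALSE; break }
    }
  }
  hits[keep, ]
}

#' Nucleotide local search (both strands)
#'
#' @param query nucleotide sequence tibble (one or more queries).
#' @param genome nucleotide sequence tibble (one or more targets).
#' @param evalue_max report hits with E-value at or below this.
#' @param scheme a `"nt"` [scoring_scheme()].
#' @return A tibble of hits: `query_id`, `target_id`, `pct_identity`,
#'   `aln_len`, `q_start`, `q_end`, `t_start`, `t_end` (0-based half-open,
#'   forward target coordinates), `strand`, `score`, `bitscore`, `evalue`,
#'   sorted by E-value. Hits fully contained in a higher-scoring hit are
#'   dropped.
#' @export
search_nt <- function(query, genome, evalue_max = 1e-5,
                      scheme = scoring_scheme("nt")) {
  stopifnot(scheme$mode == "nt")
  check_alphabet(query, "nt"); check_alphabet(genome, "nt")
  n_db <- 2 * sum(nchar(genome$seq))
  tcodes <- lapply(genome$seq, encode_nt)
  out <- list()
  for (qi in seq_len(nrow(query))) {
    qseq <- query$seq[qi]
    qlen <- nchar(qseq)
    qf <- encode_nt(qseq)
    qr <- encode_nt(revcomp(qseq))
    for (ti in seq_len(nrow(genome))) {
      for (strand in c("+", "-")) {
        qcode <- if (strand == "+") qf else qr
        h <- search_one(qcode, tcodes[[ti]], scheme, 4L)
        if (is.null(h)) next
        if (strand == "-") {
          tmp <- h$q_start
          h$q_start <- qlen - h$q_end
          h$q_end <- qlen - tmp
        }
        h$strand <- strand
        h$query_id <- query$id[qi]
        h$target_id <- genome$id[ti]
        out[[length(out) + 1L]] <- h
      }
    }
  }
  empty <- tibble::tibble(query_id = character(), target_id = character(),
                          pct_identity = numeric(), aln_len = integer(),
                          q_start = integer(), q_end = integer(),
                          t_start = integer(), t_end = integer(),
                          strand = character(), score = numeric(),
                          bitscore = numeric(), evalue = numeric())
  if (length(out) == 0L) return(empty)
  hits <- dplyr::bind_rows(out)
  hits <- drop_contained(hits)
  lam <- scheme$lambda_gapped
  hits$bitscore <- (lam * hits$score - log(scheme$K)) / log(2)
  hits$evalue <- purrr::map_dbl(seq_len(nrow(hits)), function(i) {
    karlin_evalue(hits$score[i], nchar(query$seq[match(hits$query_id[i], query$id)]),
                  n_db, scheme)
  })
  hits <- dplyr::filter(hits, .data$evalue <= evalue_max)
  hits$pct_identity <- 100 * hits$matches / pmax(hits$aln_len, 1L)
  dplyr::arrange(
    dplyr::select(hits, dplyr::all_of(names(empty))),
    .data$evalue, .data$t_start)
}

#' Translated search: nucleotide query against a protein library
#'
#' All six frame translations of the query are searched against each protein
#' with the `"tx"` scheme (BLOSUM62). Coordinates are reported both on the
#' frame peptide (`p_start`, `p_end`) and projected back onto the forward
#' nucleotide query (`q_start`, `q_end`).
#'
#' @param query nucleotide sequence tibble.
#' @param proteins amino-acid sequence tibble.
#' @param evalue_max report hits with E-value at or below this.
#' @param scheme a `"tx"` [scoring_scheme()].
#' @param table genetic code id for the translation.
#' @return A tibble of hits with `frame` in +1..+3 / -1..-3, sorted by E-value.
#' @export
search_translated <- function(query, proteins, evalue_max = 1e-5,
                              scheme = scoring_scheme("tx"), table = "11") {
  stopifnot(scheme$mode == "tx")
  check_alphabet(query, "nt")
  if (nrow(proteins) == 0L) stop("protein library is empty")
  n_db <- sum(nchar(proteins$seq))
  pcodes <- lapply(proteins$seq, encode_aa)
  pred <- lapply(proteins$seq, encode_aa_reduced)
  frames <- translate_six_frames(query, table = table)
  out <- list()
  for (fi in seq_len(nrow(frames))) {
    pep <- frames$peptide[fi]
    if (nchar(pep) < scheme$word) next
    qcode <- encode_aa(pep)
    qred <- encode_aa_reduced(pep)
    qlen_nt <- nchar(query$seq[match(frames$parent_id[fi], query$id)])
    for (ti in seq_len(nrow(proteins))) {
      h <- search_one(qcode, pcodes[[ti]], scheme, 10L,
                      seed_q = qred, seed_t = pred[[ti]])
      if (is.null(h)) next
      h$p_start <- h$q_start; h$p_end <- h$q_end
      fr <- frames$frame[fi]; off <- frames$nt_offset[fi]
      nt0 <- off + 3L * h$p_start
      nt1 <- off + 3L * h$p_end
      if (fr > 0) { h$q_start <- nt0; h$q_end <- nt1 }
      else { h$q_start <- qlen_nt - nt1; h$q_end <- qlen_nt - nt0 }
      h$frame <- fr
      h$strand <- if (fr > 0) "+" else "-"
      h$query_id <- frames$parent_id[fi]
      h$target_id <- proteins$id[ti]
      out[[length(out) + 1L]] <- h
    }
  }
  empty <- tibble::tibble(query_id = character(), target_id = character(),
                          pct_identity = numeric(), aln_len = integer(),
                          q_start = integer(), q_end = integer(),
                          t_start = integer(), t_end = integer(),
                          p_start = integer(), p_end = integer(),
                          frame = integer(), score = numeric(),
                          bitscore = numeric(), evalue = numeric())
  if (length(out) == 0L) return(empty)
  hits <- dplyr::bind_rows(out)
  hits <- drop_contained(hits)
  lam <- scheme$lambda_gapped
  hits$bitscore <- (lam * hits$score - log(scheme$K)) / log(2)
  hits$evalue <- purrr::map_dbl(seq_len(nrow(hits)), function(i) {
    qlen_aa <- nchar(query$seq[match(hits$query_id[i], query$id)]) %/% 3L
    karlin_evalue(hits$score[i], max(qlen_aa, 1L), n_db, scheme)
  })
  hits <- dplyr::filter(hits, .data$evalue <= evalue_max)
  hits$pct_identity <- 100 * hits$matches / pmax(hits$aln_len, 1L)
  dplyr::arrange(dplyr::select(hits, dplyr::all_of(names(empty))),
                 .data$evalue, .data$t_start)
}
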