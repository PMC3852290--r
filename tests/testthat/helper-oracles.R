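# Independent oracles used across the suite. Each is a direct, exhaustive (or
# closed-form) restatement of the contract being tested, sharing no code with
# the implementation path it checks.

rnd_nt <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

rnd_aa <- function(n) {
  paste0(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
         collapse = "")
}

# ---- brute-force maximal IR pair enumerator ---------------------------------
# Enumerates every (left_start, arm, diagonal) window, checks validity and the
# maximality definition (neither inward nor outward extension valid) directly.
oracle_ir_pairs <- function(seq, min_arm, max_arm, max_gap, max_mismatch) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  compv <- c(A = "T", C = "G", G = "C", T = "A")[v]  # NA for N/other
  BIG <- 1e6L
  out <- list()
  mm <- max_mismatch
  for (d in seq_len(2L * n - 3L)) {
    plo <- max(0L, d + 1L - n)
    phi <- (d - 1L) %/% 2L
    if (phi < plo) next
    ps <- plo:phi
    qs <- d - ps
    mloc <- ifelse(is.na(compv[ps + 1]) | is.na(compv[qs + 1]), BIG,
                   ifelse(v[ps + 1] == compv[qs + 1], 0L, 1L))
    len <- length(ps)
    cs <- c(0L, cumsum(mloc))
    for (a in min_arm:max_arm) {
      if (len < a) break
      li <- seq_len(len - a + 1L)
      mism <- cs[li + a] - cs[li]
      gap <- d + 1L - 2L * (ps[li] + a)
      valid <- mism <= mm & gap >= 0L & gap <= max_gap
      iw <- rep(FALSE, length(li))
      can_iw <- li + a <= len
      iw[can_iw] <- (cs[li[can_iw] + a + 1L] - cs[li[can_iw]] <= mm)
      iw <- iw & (a + 1L <= max_arm)
      ow <- rep(FALSE, length(li))
      can_ow <- li - 1L >= 1L
      ow[can_ow] <- (cs[li[can_ow] + a] - cs[li[can_ow] - 1L] <= mm)
      ow <- ow & (a + 1L <= max_arm)
      keep <- which(valid & !iw & !ow)
      if (length(keep) > 0L) {
        l <- ps[li[keep]]
        out[[length(out) + 1L]] <- data.frame(
          left_start = l, left_end = l + a,
          right_start = d - (l + a) + 1L, right_end = d - l + 1L,
          arm_len = a, mismatches = as.integer(mism[keep]))
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_len = integer(), mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$left_start, res$right_end - res$left_start, res$arm_len,
            res$right_start), , drop = FALSE]
}

# ---- exhaustive profile HMM path enumeration --------------------------------
# Enumerates all local paths (entry at any match state, exit from any match
# state) and returns log2 of max and of summed path odds.
oracle_phmm_scores <- function(hmm, peptide) {
  x <- match(strsplit(peptide, "")[[1]], colnames(hmm$match_emissions))
  L <- length(x)
  K <- hmm$K
  bg <- hmm$background
  odds <- c()
  emit_m <- function(k, xi) hmm$match_emissions[k, xi] / bg[xi]
  emit_i <- function(k, xi) hmm$insert_emissions[k, xi] / bg[xi]
  walk <- function(type, k, i, p) {
    # `p` = odds so far; residues consumed up to index i (1-based, i = last
    # consumed). Called after consuming the emission of state (type, k).
    if (type == "M") {
      if (hmm$tme[k] > 0) odds <<- c(odds, p * hmm$tme[k])
      if (k < K && i < L && hmm$tmm[k] > 0)
        walk("M", k + 1L, i + 1L, p * hmm$tmm[k] * emit_m(k + 1L, x[i + 1L]))
      if (k < K && i < L && hmm$tmi[k] > 0)
        walk("I", k, i + 1L, p * hmm$tmi[k] * emit_i(k, x[i + 1L]))
      if (k < K && hmm$tmd[k] > 0)
        walk("D", k + 1L, i, p * hmm$tmd[k])
    } else if (type == "I") {
      if (i < L && hmm$tim[k] > 0)
        walk("M", k + 1L, i + 1L, p * hmm$tim[k] * emit_m(k + 1L, x[i + 1L]))
      if (i < L && hmm$tii[k] > 0)
        walk("I", k, i + 1L, p * hmm$tii[k] * emit_i(k, x[i + 1L]))
    } else { # D
      if (i < L && hmm$tdm[k] > 0)
        walk("M", k + 1L, i + 1L, p * hmm$tdm[k] * emit_m(k + 1L, x[i + 1L]))
      if (k + 1L <= K && hmm$tdd[k] > 0)
        walk("D", k + 1L, i, p * hmm$tdd[k])
    }
  }
  for (start in seq_len(L)) {
    for (k0 in seq_len(K)) {
      walk("M", k0, start, hmm$entry[k0] * emit_m(k0, x[start]))
    }
  }
  list(viterbi = log2(max(odds)), forward = log2(sum(odds)))
}

# a small random profile built from a tiny synthetic alignment
toy_profile <- function(K = 3L, n_seqs = 6L, seed = 1L) {
  withr::with_seed(seed, {
    aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    anc <- sample(aas, K, replace = TRUE)
    rows <- vapply(seq_len(n_seqs), function(i) {
      v <- anc
      j <- sample.int(K, 1L)
      v[j] <- sample(aas, 1L)
      paste0(v, collapse = "")
    }, character(1))
    build_profile(tibble::tibble(id = paste0("s", seq_len(n_seqs)), seq = rows),
                  name = sprintf("toy%d", K))
  })
}

# independent Gumbel ML fit by direct likelihood optimisation
oracle_gumbel_fit <- function(x) {
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (x - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  o <- optim(c(mean(x), log(stats::sd(x))), nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-12))
  list(mu = o$par[1], lambda = 1 / exp(o$par[2]))
}

r_gumbel <- function(n, mu, lambda) mu - log(-log(runif(n))) / lambda

# Smith-Waterman score oracle via Biostrings (affine: open 5 / extend 2 for
# nt with +1/-2); our convention gap cost = open + g * extend matches
# Biostrings' gapOpening/gapExtension convention.
oracle_sw_score <- function(q, t, match = 1, mismatch = -2, open = 5, ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(t), type = "local",
    substitutionMatrix = mat, gapOpening = open, gapExtension = ext,
    scoreOnly = TRUE)
}

oracle_nw_score <- function(a, b, alphabet = "nt") {
  if (alphabet == "nt") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    xa <- Biostrings::DNAString(a); xb <- Biostrings::DNAString(b)
  } else {
    chars <- unique(strsplit(paste0(a, b), "")[[1]])
    mat <- matrix(-1, length(chars), length(chars),
                  dimnames = list(chars, chars))
    diag(mat) <- 1
    xa <- Biostrings::AAString(a); xb <- Biostrings::AAString(b)
  }
  Biostrings::pairwiseAlignment(xa, xb, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 1,
                                scoreOnly = TRUE)
}

# shared fixtures for pipeline tests (built once per test run)
tpase_msa <- function(seed = 3L, len = 300L) {
  simulate_transposase_msa(n_seqs = 60L, length = len, divergence = 0.25,
                           seed = seed)
}

tpase_lib <- function(msa) {
  tibble::tibble(id = c("tpaseA"), desc = c("tpaseA|IS3|family=IS3"),
                 seq = attr(msa, "ancestor"))
}
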