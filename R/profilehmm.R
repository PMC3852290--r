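#' Protein profile hidden Markov models
#'
#' Position-specific models of a transposase (or any protein) family built
#' from a multiple alignment: alignment columns with fewer than 50% gaps
#' become match states; emissions are (counts + pseudocount * background)
#' normalised; transitions are estimated from the observed state paths with
#' Laplace smoothing. Alignment to a peptide is local: paths enter directly at
#' any match state (uniform entry) and leave from any match state (fixed exit
#' mass per node, forced at the last node); deletions are interior only.
#' Scores are log2-odds (bits) of the model against the background.
#' Significance uses an extreme-value (Gumbel) calibration fitted by maximum
#' likelihood to Viterbi scores of random background peptides.
#'
#' @name profilehmm
NULL

#' Build a profile HMM from a multiple sequence alignment
#'
#' @param msa alignment tibble (`id`, `seq` aligned rows with `-` gaps), e.g.
#'   from [read_msa()]. At least 2 rows; 50 or more is recommended for a
#'   well-determined profile.
#' @param pseudocount weight of the background pseudocount added to emission
#'   counts.
#' @param name model name.
#' @param exit_prob per-node match-to-exit probability of the local model.
#' @param background residue background distribution (default uniform 1/20).
#' @return An object of class `profile_hmm`.
#' @export
build_profile <- function(msa, pseudocount = 1.0, name = "profile",
                          exit_prob = 0.05, background = rep(1 / 20, 20)) {
  if (nrow(msa) < 2L) stop("need at least 2 aligned sequences")
  lens <- unique(nchar(msa$seq))
  if (length(lens) != 1L) stop("ragged alignment: rows differ in aligned length")
  stopifnot(abs(sum(background) - 1) < 1e-9)
  rows <- stringr::str_split_fixed(gsub("\\.", "-", toupper(msa$seq)), "", lens)
  ncolA <- ncol(rows)
  gapfrac <- colMeans(rows == "-")
  is_match <- gapfrac < 0.5
  K <- sum(is_match)
  if (K < 1L) stop("alignment has no match columns")
  match_cols <- which(is_match)
  # node index for every alignment column: match col -> its k; insert col ->
  # the preceding match node (0 before the first)
  node_of <- cumsum(is_match)

  # emissions
  me <- matrix(0, K, 20, dimnames = list(NULL, AA_CHARS))
  ie <- matrix(0, K, 20, dimnames = list(NULL, AA_CHARS))
  for (j in seq_len(ncolA)) {
    res <- rows[, j]
    res <- res[res %in% AA_CHARS]
    if (length(res) == 0L) next
    tab <- table(factor(res, levels = AA_CHARS))
    if (is_match[j]) me[node_of[j], ] <- me[node_of[j], ] + tab
    else if (node_of[j] >= 1L && node_of[j] < K)
      ie[node_of[j], ] <- ie[node_of[j], ] + tab
  }
  me <- sweep(me + pseudocount * rep(background, each = K), 1,
              rowSums(me) + pseudocount, "/")
  ie <- sweep(ie + pseudocount * rep(background, each = K), 1,
              rowSums(ie) + pseudocount, "/")

  # transition counts from observed state paths (interior part only)
  cnt <- list(mm = numeric(K), mi = numeric(K), md = numeric(K),
              im = numeric(K), ii = numeric(K),
              dm = numeric(K), dd = numeric(K))
  for (r in seq_len(nrow(rows))) {
    states <- list()
    for (j in seq_len(ncolA)) {
      ch <- rows[r, j]
      if (is_match[j]) {
        states[[length(states) + 1L]] <- c(if (ch == "-") "D" else "M", node_of[j])
      } else if (ch != "-") {
        k <- node_of[j]
        if (k >= 1L && k < K) states[[length(states) + 1L]] <- c("I", k)
      }
    }
    if (length(states) == 0L) next
    typ <- vapply(states, `[`, "", 1L)
    # trim leading/trailing non-match states (local model enters/exits at M)
    mpos <- which(typ == "M")
    if (length(mpos) < 2L) next
    states <- states[mpos[1]:mpos[length(mpos)]]
    typ <- typ[mpos[1]:mpos[length(mpos)]]
    for (t in seq_len(length(states) - 1L)) {
      a <- states[[t]]; b <- states[[t + 1L]]
      k <- as.integer(a[2])
      key <- paste0(tolower(a[1]), tolower(b[1]))
      if (key %in% names(cnt)) cnt[[key]][k] <- cnt[[key]][k] + 1
    }
  }

  # smoothed, normalised transition rows under the interior-deletion
  # architecture: D states exist for k = 2..K-1 only
  tmm <- tmi <- tmd <- tme <- numeric(K)
  tim <- tii <- numeric(max(K - 1L, 0L))
  tdm <- tdd <- numeric(K)
  for (k in seq_len(K)) {
    if (k == K) { tme[k] <- 1; next }
    allow_md <- k <= K - 2L
    raw <- c(mm = cnt$mm[k] + 1, mi = cnt$mi[k] + 1,
             md = if (allow_md) cnt$md[k] + 1 else 0)
    raw <- raw / sum(raw) * (1 - exit_prob)
    tmm[k] <- raw[["mm"]]; tmi[k] <- raw[["mi"]]
    tmd[k] <- if (allow_md) raw[["md"]] else 0
    tme[k] <- exit_prob
  }
  for (k in seq_len(max(K - 1L, 0L))) {
    raw <- c(im = cnt$im[k] + 1, ii = cnt$ii[k] + 1)
    raw <- raw / sum(raw)
    tim[k] <- raw[["im"]]; tii[k] <- raw[["ii"]]
  }
  if (K >= 3L) {
    for (k in 2:(K - 1L)) {
      if (k == K - 1L) { tdm[k] <- 1; tdd[k] <- 0; next }
      raw <- c(dm = cnt$dm[k] + 1, dd = cnt$dd[k] + 1)
      raw <- raw / sum(raw)
      tdm[k] <- raw[["dm"]]; tdd[k] <- raw[["dd"]]
    }
  }

  structure(list(
    name = name, K = K,
    match_emissions = me, insert_emissions = ie,
    entry = rep(1 / K, K),
    tmm = tmm, tmi = tmi, tmd = tmd, tme = tme,
    tim = tim, tii = tii, tdm = tdm, tdd = tdd,
    background = background, calib = NULL
  ), class = "profile_hmm")
}

# log2-odds arrays consumed by the C++ scorers
phmm_model <- function(hmm) {
  lo <- function(p) ifelse(p > 0, log2(p), -Inf)
  K <- hmm$K
  list(
    me_lo = log2(sweep(hmm$match_emissions, 2, hmm$background, "/")),
    ie_lo = log2(sweep(hmm$insert_emissions, 2, hmm$background, "/")),
    tmm = lo(hmm$tmm), tmi = lo(hmm$tmi), tmd = lo(hmm$tmd), tme = lo(hmm$tme),
    tim = lo(hmm$tim), tii = lo(hmm$tii), tdm = lo(hmm$tdm), tdd = lo(hmm$tdd),
    entry = lo(hmm$entry)
  )
}

#' Viterbi score of a peptide against a profile
#'
#' @param hmm a `profile_hmm`.
#' @param peptide amino-acid string.
#' @return A list with `bits` (max log2-odds over local alignments) and the
#'   maximising envelope `env_start`, `env_end` (1-based residue positions).
#' @export
viterbi_score <- function(hmm, peptide) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (nchar(peptide) == 0L) stop("empty peptide")
  viterbi_cpp(phmm_model(hmm), encode_aa(peptide))
}

#' Forward score of a peptide against a profile
#'
#' Log2 of the summed odds over all local alignments; always at least the
#' Viterbi score.
#'
#' @inheritParams viterbi_score
#' @return bits.
#' @export
forward_score <- function(hmm, peptide) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (nchar(peptide) == 0L) stop("empty peptide")
  forward_cpp(phmm_model(hmm), encode_aa(peptide))
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location `mu` and rate `lambda` (scale = 1/lambda) of a Gumbel
#' distribution by maximum likelihood.
#'
#' @param x numeric scores.
#' @return A list with `mu` and `lambda`.
#' @export
fit_gumbel <- function(x) {
  if (length(x) < 10L || stats::sd(x) < 1e-9)
    stop("degenerate score distribution: cannot calibrate")
  xbar <- mean(x)
  h <- function(beta) {
    w <- exp(-(x - max(x)) / beta)
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- stats::sd(x) / 50; hi <- stats::sd(x) * 50
  beta <- uniroot(h, interval = c(lo, hi), tol = 1e-12)$root
  mu <- -beta * (log(mean(exp(-(x - max(x)) / beta))) - max(x) / beta)
  list(mu = mu, lambda = 1 / beta)
}

#' Calibrate a profile against random background peptides
#'
#' Scores `n_random` i.i.d. background-sampled peptides (lengths normal,
#' truncated at 50) with Viterbi and fits a Gumbel to the scores. Deterministic
#' given `seed`.
#'
#' @param hmm a `profile_hmm`.
#' @param n_random number of random peptides (>= 100).
#' @param len_mean,len_sd length distribution of the random peptides.
#' @param seed RNG seed.
#' @return The profile with a `calib` list (`mu`, `lambda`, `n_calib`, `seed`).
#' @export
calibrate_profile <- function(hmm, n_random = 5000L, len_mean = 350,
                              len_sd = 120, seed = 1L) {
  stopifnot(inherits(hmm, "profile_hmm"), n_random >= 100L)
  model <- phmm_model(hmm)
  scores <- withr::with_seed(seed, {
    lens <- pmax(50L, as.integer(round(rnorm(n_random, len_mean, len_sd))))
    peps <- lapply(lens, function(L) {
      sample.int(20L, L, replace = TRUE, prob = hmm$background) - 1L
    })
    viterbi_batch_cpp(model, peps)
  })
  fit <- fit_gumbel(scores)
  hmm$calib <- list(mu = fit$mu, lambda = fit$lambda,
                    n_calib = as.integer(n_random), seed = as.integer(seed))
  hmm
}

#' E-value of a profile hit
#'
#' `E = n_targets * P(S >= score)` under the profile's Gumbel calibration.
#'
#' @param hmm calibrated `profile_hmm`.
#' @param score bits.
#' @param n_targets number of peptides searched.
#' @return E-value.
#' @export
profile_evalue <- function(hmm, score, n_targets) {
  if (is.null(hmm$calib)) stop("profile '", hmm$name, "' is not calibrated")
  p <- 1 - exp(-exp(-hmm$calib$lambda * (score - hmm$calib$mu)))
  n_targets * p
}

#' Search calibrated profiles against frame translations
#'
#' Every (profile, peptide) pair is scored with Viterbi; hits at or below
#' `evalue_max` are reported. The E-value search space per profile is the
#' number of peptides scored. Multi-profile matches to one locus are all
#' reported.
#'
#' @param profiles a list of calibrated `profile_hmm` objects.
#' @param translations tibble with `parent_id`, `frame`, `nt_offset`,
#'   `peptide` (from [translate_six_frames()]).
#' @param evalue_max E-value cutoff.
#' @param min_len skip peptides shorter than this many residues.
#' @return A tibble of hits: `profile`, `target_id`, `frame`, `env_start`,
#'   `env_end` (1-based residue span), `bits`, `evalue`, sorted by E-value.
#' @export
search_profiles <- function(profiles, translations, evalue_max = 1e-5,
                            min_len = 10L) {
  if (inherits(profiles, "profile_hmm")) profiles <- list(profiles)
  for (p in profiles) {
    if (is.null(p$calib)) stop("profile '", p$name, "' is not calibrated")
  }
  keep <- nchar(translations$peptide) >= min_len
  tr <- translations[keep, ]
  n_targets <- nrow(tr)
  if (n_targets == 0L) {
    return(tibble::tibble(profile = character(), target_id = character(),
                          frame = integer(), env_start = integer(),
                          env_end = integer(), bits = numeric(),
                          evalue = numeric()))
  }
  peps <- lapply(tr$peptide, encode_aa)
  # deterministic profile order: by name
  ord <- order(vapply(profiles, function(p) p$name, ""))
  out <- purrr::map_dfr(ord, function(pi) {
    p <- profiles[[pi]]
    model <- phmm_model(p)
    res <- purrr::map_dfr(seq_len(n_targets), function(i) {
      v <- viterbi_cpp(model, peps[[i]])
      tibble::tibble(profile = p$name, target_id = tr$parent_id[i],
                     frame = tr$frame[i], env_start = v$env_start,
                     env_end = v$env_end, bits = v$bits)
    })
    res$evalue <- profile_evalue(p, res$bits, n_targets)
    dplyr::filter(res, .data$evalue <= evalue_max)
  })
  dplyr::arrange(out, .data$evalue, .data$profile, .data$target_id)
}

#' Write a profile HMM to a versioned plain-text file
#'
#' Round-trips losslessly to 12 significant digits via [read_profile()].
#'
#' @param hmm a `profile_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(hmm, path) {
  g <- function(x) sprintf("%.12g", x)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(...), con)
  w("# teminer profile v1")
  w("name", hmm$name)
  w("K", hmm$K)
  w("alphabet", paste0(AA_CHARS, collapse = ""))
  w("background", paste(g(hmm$background), collapse = " "))
  if (!is.null(hmm$calib)) {
    w("calib", g(hmm$calib$mu), g(hmm$calib$lambda), hmm$calib$n_calib,
      hmm$calib$seed)
  }
  for (k in seq_len(hmm$K)) {
    w("match", k, paste(g(hmm$match_emissions[k, ]), collapse = " "))
    w("insert", k, paste(g(hmm$insert_emissions[k, ]), collapse = " "))
    w("trans", k, g(hmm$tmm[k]), g(hmm$tmi[k]), g(hmm$tmd[k]), g(hmm$tme[k]),
      g(if (k < hmm$K) hmm$tim[k] else 0), g(if (k < hmm$K) hmm$tii[k] else 0),
      g(hmm$tdm[k]), g(hmm$tdd[k]))
  }
  invisible(path)
}

#' Read a profile HMM written by [write_profile()]
#'
#' @param path path to a profile text file.
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  if (!startsWith(lines[1], "# teminer profile v1"))
    stop("not a teminer profile file: ", path)
  toks <- strsplit(lines[-1], " +")
  field <- vapply(toks, `[`, "", 1L)
  getl <- function(nm) toks[[which(field == nm)[1]]][-1]
  K <- as.integer(getl("K"))
  hmm <- list(name = getl("name"), K = K,
              match_emissions = matrix(0, K, 20, dimnames = list(NULL, AA_CHARS)),
              insert_emissions = matrix(0, K, 20, dimnames = list(NULL, AA_CHARS)),
              entry = rep(1 / K, K),
              tmm = numeric(K), tmi = numeric(K), tmd = numeric(K),
              tme = numeric(K), tim = numeric(max(K - 1L, 0L)),
              tii = numeric(max(K - 1L, 0L)), tdm = numeric(K),
              tdd = numeric(K),
              background = as.numeric(getl("background")), calib = NULL)
  if (any(field == "calib")) {
    cv <- getl("calib")
    hmm$calib <- list(mu = as.numeric(cv[1]), lambda = as.numeric(cv[2]),
                      n_calib = as.integer(cv[3]), seed = as.integer(cv[4]))
  }
  for (i in which(field == "match")) {
    v <- toks[[i]]; k <- as.integer(v[2])
    hmm$match_emissions[k, ] <- as.numeric(v[-(1:2)])
  }
  for (i in which(field == "insert")) {
    v <- toks[[i]]; k <- as.integer(v[2])
    hmm$insert_emissions[k, ] <- as.numeric(v[-(1:2)])
  }
  for (i in which(field == "trans")) {
    v <- as.numeric(toks[[i]][-1]); k <- as.integer(v[1])
    hmm$tmm[k] <- v[2]; hmm$tmi[k] <- v[3]; hmm$tmd[k] <- v[4]
    hmm$tme[k] <- v[5]
    if (k < K) { hmm$tim[k] <- v[6]; hmm$tii[k] <- v[7] }
    hmm$tdm[k] <- v[8]; hmm$tdd[k] <- v[9]
  }
  structure(hmm, class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm>", x$name, "\n")
  cat("  match states:", x$K, "\n")
  if (!is.null(x$calib)) {
    cat(sprintf("  calibrated: mu = %.3f, lambda = %.3f (n = %d)\n",
                x$calib$mu, x$calib$lambda, x$calib$n_calib))
  } else cat("  not calibrated\n")
  invisible(x)
}

#' Tidy a profile HMM into a long emission table
#'
#' @param x a `profile_hmm`.
#' @param ... unused.
#' @return A tibble with `state`, `residue`, `match_emission`,
#'   `insert_emission`.
#' @export
tidy.profile_hmm <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$K), times = 20),
    residue = rep(AA_CHARS, each = x$K),
    match_emission = as.vector(x$match_emissions),
    insert_emission = as.vector(x$insert_emissions)
  ) %>% dplyr::arrange(.data$state, .data$residue)
}

#' One-row summary of a profile HMM
#'
#' @param x a `profile_hmm`.
#' @param ... unused.
#' @return A one-row tibble: `name`, `n_states`, `calibrated`, `mu`, `lambda`,
#'   `n_calib`.
#' @export
glance.profile_hmm <- function(x, ...) {
  tibble::tibble(
    name = x$name, n_states = x$K, calibrated = !is.null(x$calib),
    mu = if (is.null(x$calib)) NA_real_ else x$calib$mu,
    lambda = if (is.null(x$calib)) NA_real_ else x$calib$lambda,
    n_calib = if (is.null(x$calib)) NA_integer_ else x$calib$n_calib
  )
}

#' Emission-profile heatmap
#'
#' @param object a `profile_hmm`.
#' @param ... unused.
#' @return A ggplot: match-state emission probabilities by state and residue.
#' @export
autoplot.profile_hmm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$residue,
                                   fill = .data$match_emission)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "P(residue)") +
    ggplot2::labs(x = "match state", y = NULL,
                  title = paste0("Profile ", object$name,
                                 " match emissions")) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
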