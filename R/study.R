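#' Built-in simulation study
#'
#' A fixed benchmark design used by the package's validation suite: a 300 kb
#' background carrying four IS families spanning the realistic parameter range
#' (3-8 copies; terminal IRs of 0-20 nt, including one IR-less IS200/605-style
#' family; 0.8-1.3 kb) and two MITE families derived from two of the ISs. The
#' four transposase families are simulated alignments (60 sequences, 25%
#' divergence) with fixed seeds - they are part of the design - while copy
#' placement, orientation and per-copy mutations follow the study seed.
#'
#' @name study
NULL

STUDY_MSA_SEEDS <- c(famA = 11L, famB = 12L, famC = 13L, famD = 14L)
STUDY_MSA_LENS <- c(famA = 300L, famB = 300L, famC = 300L, famD = 200L)
STUDY_FAMILIES <- c(famA = "IS3", famB = "IS5", famC = "IS200/605",
                    famD = "IS630")

#' Transposase family alignments of the built-in study
#'
#' Three 300-residue families and one 200-residue family (the short IS_D
#' element cannot hold a longer ORF).
#'
#' @return Named list of four alignment tibbles (see
#'   [simulate_transposase_msa()]).
#' @export
study_msas <- function() {
  out <- lapply(names(STUDY_MSA_SEEDS), function(f) {
    simulate_transposase_msa(n_seqs = 60L, length = STUDY_MSA_LENS[[f]],
                             divergence = 0.25, seed = STUDY_MSA_SEEDS[[f]])
  })
  names(out) <- names(STUDY_MSA_SEEDS)
  out
}

#' Reference transposase library of the built-in study
#'
#' The four family ancestors, headed with `family=` tags, standing in for a
#' curated reference library.
#'
#' @param msas output of [study_msas()].
#' @return An amino-acid sequence tibble with `desc` family tags.
#' @export
study_library <- function(msas = study_msas()) {
  tibble::tibble(
    id = names(msas),
    desc = sprintf("%s|%s|family=%s", names(msas), STUDY_FAMILIES[names(msas)],
                   STUDY_FAMILIES[names(msas)]),
    seq = vapply(msas, function(m) attr(m, "ancestor"), character(1)))
}

#' Simulate the benchmark genome
#'
#' @param seed study seed (placement, strands, per-copy mutations).
#' @param mutation_rate per-base substitution rate applied to every copy
#'   (0 = exact copies; 0.05 = strongly diverged copies).
#' @param background_len background size in nt.
#' @param msas transposase family alignments (defaults to the study set).
#' @return As [simulate_genome()]: a list with `genome` and `truth`.
#' @export
simulate_is_study <- function(seed = 1L, mutation_rate = 0,
                              background_len = 300000L, msas = study_msas()) {
  specs <- list(
    implant_spec("IS_A", 6L, 1300L, ir_len = 16L, dr_len = 5L,
                 transposase = msas$famA$seq[1], mutation_rate = mutation_rate),
    implant_spec("IS_B", 4L, 1000L, ir_len = 14L, dr_len = 4L,
                 transposase = msas$famB$seq[1], mutation_rate = mutation_rate),
    implant_spec("IS_C", 3L, 1200L, ir_len = 0L, dr_len = 0L,
                 transposase = msas$famC$seq[1], mutation_rate = mutation_rate),
    implant_spec("IS_D", 8L, 800L, ir_len = 20L, dr_len = 0L,
                 transposase = msas$famD$seq[1], mutation_rate = mutation_rate),
    implant_spec("MITE_A", 8L, 220L, dr_len = 5L, partner_of = "IS_A",
                 mutation_rate = mutation_rate),
    implant_spec("MITE_B", 6L, 300L, dr_len = 0L, partner_of = "IS_D",
                 mutation_rate = mutation_rate))
  simulate_genome(specs, background_len, gc = 0.5, seed = seed)
}

# representative (first-copy) sequence of each truth family, oriented
truth_templates <- function(sim) {
  tr <- sim$truth[!duplicated(sim$truth$family_id), ]
  seqs <- vapply(seq_len(nrow(tr)), function(i) {
    s <- stringi::stri_sub(sim$genome$seq[1], tr$start[i] + 1L, tr$end[i])
    if (tr$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(seqs, tr$family_id)
}

#' Match element calls to the simulated truth families
#'
#' A truth family counts as recovered when some call's consensus matches its
#' representative copy at or above `min_identity` (either strand, global
#' alignment) with a compatible length.
#'
#' @param calls calls tibble (possibly a union of several pipelines).
#' @param sim output of [simulate_is_study()] / [simulate_genome()].
#' @param min_identity identity threshold for a match.
#' @return A tibble: `family_id`, `kind`, `recovered`, `call_id` (best match).
#' @export
match_calls_to_truth <- function(calls, sim, min_identity = 0.8) {
  tmpl <- truth_templates(sim)
  kinds <- sim$truth$kind[match(names(tmpl), sim$truth$family_id)]
  purrr::map_dfr(seq_along(tmpl), function(i) {
    best_id <- NA_character_
    best <- 0
    for (r in seq_len(nrow(calls))) {
      lr <- nchar(calls$consensus[r]) / nchar(tmpl[i])
      if (lr < 0.7 || lr > 1.4) next
      idv <- max(pairwise_identity(calls$consensus[r], tmpl[i], "nt"),
                 pairwise_identity(revcomp(calls$consensus[r]), tmpl[i], "nt"))
      if (idv > best) { best <- idv; best_id <- calls$call_id[r] }
    }
    tibble::tibble(family_id = names(tmpl)[i], kind = kinds[i],
                   recovered = best >= min_identity,
                   identity = best, call_id = best_id)
  })
}

#' Check MITE-partner links against the simulated truth
#'
#' @param calls calls tibble.
#' @param sim simulation with MITE families whose `partner` field names the
#'   autonomous truth family.
#' @param min_identity identity threshold used to match calls to families.
#' @return A tibble per truth MITE family: `family_id`, `linked` (a matching
#'   MITE call has a partner call matching the true partner family).
#' @export
check_partner_links <- function(calls, sim, min_identity = 0.8) {
  tmpl <- truth_templates(sim)
  mites <- unique(sim$truth$family_id[sim$truth$kind == "MITE"])
  purrr::map_dfr(mites, function(fid) {
    partner_fid <- sim$truth$partner[sim$truth$family_id == fid][1]
    ok <- FALSE
    for (r in which(calls$kind == "MITE")) {
      idv <- max(pairwise_identity(calls$consensus[r], tmpl[fid], "nt"),
                 pairwise_identity(revcomp(calls$consensus[r]), tmpl[fid], "nt"))
      if (idv < min_identity || is.na(calls$partner[r])) next
      p <- match(calls$partner[r], calls$call_id)
      if (is.na(p)) next
      pid <- max(pairwise_identity(calls$consensus[p], tmpl[partner_fid], "nt"),
                 pairwise_identity(revcomp(calls$consensus[p]),
                                   tmpl[partner_fid], "nt"))
      if (pid >= min_identity) { ok <- TRUE; break }
    }
    tibble::tibble(family_id = fid, partner = partner_fid, linked = ok)
  })
}

#' Shuffle a genome (element-free control)
#'
#' Permutes the genome's bases, preserving composition but destroying all
#' repeat and element structure.
#'
#' @param genome single-row genome tibble.
#' @param seed RNG seed.
#' @return A single-row genome tibble.
#' @export
shuffle_genome <- function(genome, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    v <- strsplit(genome$seq[1], "")[[1]]
    seq_tbl(paste0(genome$id[1], "_shuffled"), paste0(sample(v), collapse = ""))
  })
}

#' Transposase families for the read-length recall experiment
#'
#' Two families simulated at 50% ancestor divergence (real IS families often
#' share under 35% pairwise identity), each with a held-out member: the
#' profile is trained on the first 60 sequences and the genome implants carry
#' the 61st, so detection is neither against a training example nor against
#' an unrelated sequence.
#'
#' @return A named list of two elements, each with `msa` (60 training rows)
#'   and `holdout` (the implanted peptide).
#' @export
study_read_families <- function() {
  out <- lapply(c(famR1 = 21L, famR2 = 22L), function(s) {
    full <- simulate_transposase_msa(n_seqs = 61L, length = 300L,
                                     divergence = 0.5, seed = s)
    list(msa = full[1:60, ], holdout = full$seq[61])
  })
  out
}

#' Per-copy HMM detection recall on fragmented reads
#'
#' Fragments the genome into reads, runs the profile HMM pipeline, and
#' reports the fraction of transposase-bearing truth copies overlapped by at
#' least one read with a significant profile hit.
#'
#' @param sim a simulation (genome + truth).
#' @param profiles calibrated profiles.
#' @param read_len read length (e.g. 1000, 250, 100).
#' @param cfg a [pipeline_config()].
#' @return Recall in `[0, 1]`.
#' @export
hmm_read_recall <- function(sim, profiles, read_len,
                            cfg = pipeline_config()) {
  reads <- fragment_genome(sim$genome, read_len)
  hits <- run_hmm_pipeline(reads, profiles, cfg)
  tr <- sim$truth[sim$truth$kind == "IS", ]
  if (nrow(hits) == 0L) return(0)
  src <- stringr::str_match(hits$parent_id, ":(\\d+)-(\\d+)$")
  rs <- as.integer(src[, 2]); re <- as.integer(src[, 3])
  mean(vapply(seq_len(nrow(tr)), function(i) {
    any(re > tr$start[i] & rs < tr$end[i])
  }, logical(1)))
}
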