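#' Synthetic genomes with implanted mobile elements
#'
#' Fixture generator for the whole toolkit: i.i.d. background sequence at a
#' chosen GC content, with IS and MITE copies implanted at random
#' non-overlapping positions. Elements are built as
#' `[IR arm] internal [revcomp IR arm]`, optionally carrying a transposase ORF
#' back-translated (uniform codon choice) from a supplied peptide; insertions
#' duplicate the target-site word as flanking direct repeats; MITEs are
#' internal deletions of their partner IS retaining both termini; nested
#' copies are inserted inside a host copy. Ground truth is emitted alongside
#' the genome. Deterministic given the seed.
#'
#' @name simdata
NULL

#' Specification of one implanted element family
#'
#' @param family_id family name.
#' @param n_copies number of copies to implant.
#' @param element_len element length (nt); for MITEs this is the retained
#'   terminal length.
#' @param ir_len terminal inverted-repeat arm length (0 for IR-less families
#'   such as the IS200/605 group).
#' @param dr_len target-site duplication length (0-15).
#' @param transposase optional peptide whose back-translated ORF is embedded
#'   (NULL for MITEs and non-coding families).
#' @param mutation_rate per-base substitution probability applied to each
#'   copy.
#' @param partner_of family id of the autonomous partner IS (makes this family
#'   a MITE derived from that element).
#' @param nested_in optional family id: the first copy of this family is
#'   inserted inside a copy of the host family.
#' @return A list of class `implant_spec`.
#' @export
implant_spec <- function(family_id, n_copies, element_len, ir_len = 0L,
                         dr_len = 0L, transposase = NULL, mutation_rate = 0,
                         partner_of = NULL, nested_in = NULL) {
  stopifnot(n_copies >= 1L, element_len >= 2L * ir_len + 50L, dr_len <= 15L,
            mutation_rate >= 0, mutation_rate <= 0.2)
  structure(list(family_id = family_id, n_copies = as.integer(n_copies),
                 element_len = as.integer(element_len),
                 ir_len = as.integer(ir_len), dr_len = as.integer(dr_len),
                 transposase = transposase, mutation_rate = mutation_rate,
                 partner_of = partner_of, nested_in = nested_in),
            class = "implant_spec")
}

random_nt <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# uniform-codon back-translation (genetic code 11); appends a stop codon
back_translate <- function(peptide, table = "11") {
  code <- genetic_code_table(table)
  by_aa <- split(names(code), unname(code))
  aas <- c(strsplit(peptide, "")[[1]], "*")
  codons <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot back-translate residue '", a, "'")
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(codons, collapse = "")
}

substitute_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit) > 0L) {
    for (i in hit) {
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    }
  }
  paste0(v, collapse = "")
}

build_template <- function(spec, templates, table = "11") {
  if (!is.null(spec$partner_of)) {
    host <- templates[[spec$partner_of]]
    if (is.null(host)) stop("partner family '", spec$partner_of,
                            "' must be specified before its MITE")
    L <- spec$element_len
    if (L >= nchar(host)) stop("MITE must be shorter than its partner IS")
    lh <- ceiling(L / 2); rh <- L - lh
    return(paste0(substr(host, 1L, lh),
                  substr(host, nchar(host) - rh + 1L, nchar(host))))
  }
  arm <- if (spec$ir_len > 0L) random_nt(spec$ir_len) else ""
  internal_len <- spec$element_len - 2L * spec$ir_len
  internal <- if (!is.null(spec$transposase)) {
    orf <- paste0("ATG", back_translate(spec$transposase, table))
    pad <- internal_len - nchar(orf)
    if (pad < 20L) stop("element_len too small for the transposase ORF of ",
                        spec$family_id)
    lead <- sample.int(pad - 10L, 1L) + 4L
    paste0(random_nt(lead), orf, random_nt(pad - lead))
  } else random_nt(internal_len)
  paste0(arm, internal, if (spec$ir_len > 0L) revcomp(arm) else "")
}

#' Simulate a genome with implanted elements
#'
#' @param specs list of [implant_spec()] objects (autonomous families before
#'   their MITEs).
#' @param background_len background length in nt.
#' @param gc background GC fraction.
#' @param seed RNG seed (the simulation is deterministic given it).
#' @param table genetic code for transposase ORFs.
#' @return A list: `genome` (single-row sequence tibble) and `truth` (tibble
#'   with `family_id`, `kind`, `copy`, `start`, `end` 0-based half-open,
#'   `strand`, `ir_len`, `dr_len`, `partner`, `nested_in`).
#' @export
simulate_genome <- function(specs, background_len, gc = 0.5, seed = 1L,
                            table = "11") {
  if (inherits(specs, "implant_spec")) specs <- list(specs)
  withr::with_seed(as.integer(seed), {
    bg <- random_nt(background_len, gc)
    templates <- list()
    for (sp in specs) templates[[sp$family_id]] <- build_template(sp, templates,
                                                                  table)
    # per-copy records in insertion planning space
    plan <- list()
    for (sp in specs) {
      kind <- if (!is.null(sp$partner_of)) "MITE" else "IS"
      for (cp in seq_len(sp$n_copies)) {
        seq <- substitute_bases(templates[[sp$family_id]], sp$mutation_rate)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") seq <- revcomp(seq)
        nested <- !is.null(sp$nested_in) && cp == 1L
        plan[[length(plan) + 1L]] <- list(
          family_id = sp$family_id, kind = kind, copy = cp, seq = seq,
          strand = strand, ir_len = sp$ir_len, dr_len = sp$dr_len,
          partner = sp$partner_of %||% NA_character_,
          nested_in = if (nested) sp$nested_in else NA_character_)
      }
    }
    free <- plan[vapply(plan, function(p) is.na(p$nested_in), logical(1))]
    nested <- plan[!vapply(plan, function(p) is.na(p$nested_in), logical(1))]
    # nested copies go inside the first free copy of their host family
    for (nc in nested) {
      hosts <- which(vapply(free, function(p)
        p$family_id == nc$nested_in && p$copy == 1L, logical(1)))
      if (length(hosts) == 0L) stop("nested_in host family '", nc$nested_in,
                                    "' has no free copy")
      h <- hosts[1]
      host <- free[[h]]
      hl <- nchar(host$seq)
      q <- sample.int(hl - 2L * nc$dr_len - 60L, 1L) + 30L
      dr <- nc$dr_len
      host$seq <- paste0(substr(host$seq, 1L, q + dr), nc$seq,
                         substr(host$seq, q + 1L, hl))
      host$nested_child <- list(list(rel_start = q + dr,
                                     rel_end = q + dr + nchar(nc$seq),
                                     rec = nc))
      free[[h]] <- host
    }
    # insertion points in original background coordinates, spacing >= 100
    n_free <- length(free)
    if (background_len < n_free * 120L + 200L)
      stop("background too small for the requested implants")
    repeat {
      pts <- sort(sample.int(background_len - 40L, n_free) + 20L)
      if (n_free <= 1L || min(diff(pts)) >= 100L) break
    }
    # build the final genome left to right, duplicating the target word
    pieces <- character()
    truth <- list()
    prev <- 0L
    offset <- 0L
    for (i in seq_len(n_free)) {
      p <- pts[i]
      el <- free[[i]]
      dr <- el$dr_len
      pieces <- c(pieces, stringi::stri_sub(bg, prev + 1L, p + dr))
      start <- p + dr + offset   # absolute start of the element copy
      el_len <- nchar(el$seq)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        family_id = el$family_id, kind = el$kind, copy = el$copy,
        start = start, end = start + el_len, strand = el$strand,
        ir_len = el$ir_len, dr_len = el$dr_len, partner = el$partner,
        nested_in = NA_character_)
      if (!is.null(el$nested_child)) {
        for (ch in el$nested_child) {
          rec <- ch$rec
          truth[[length(truth) + 1L]] <- tibble::tibble(
            family_id = rec$family_id, kind = rec$kind, copy = rec$copy,
            start = start + ch$rel_start, end = start + ch$rel_end,
            strand = rec$strand, ir_len = rec$ir_len, dr_len = rec$dr_len,
            partner = rec$partner, nested_in = rec$nested_in)
        }
      }
      pieces <- c(pieces, el$seq)
      offset <- offset + el_len + dr
      prev <- p
    }
    pieces <- c(pieces, stringi::stri_sub(bg, prev + 1L, background_len))
    genome <- seq_tbl("simgenome", paste0(pieces, collapse = ""))
    truth <- dplyr::bind_rows(truth)
    list(genome = genome, truth = truth)
  })
}

#' Fragment a genome into read-sized pieces
#'
#' Emulates metagenomic read sets: `tiling` cuts consecutive non-overlapping
#' windows (last one truncated); `uniform` draws `n_reads` reads at uniform
#' random start positions. Read ids encode the source coordinates.
#'
#' @param genome single-row sequence tibble.
#' @param read_len read length (1000 / 250 / 100 bp are the classic Sanger /
#'   early-NGS regimes).
#' @param seed RNG seed (uniform mode).
#' @param mode `"tiling"` or `"uniform"`.
#' @param n_reads number of reads in uniform mode (default: 1x coverage).
#' @return A sequence tibble of reads with ids `parent:start-end`.
#' @export
fragment_genome <- function(genome, read_len, seed = 1L,
                            mode = c("tiling", "uniform"), n_reads = NULL) {
  mode <- match.arg(mode)
  if (read_len <= 0L) stop("read_len must be positive")
  n <- nchar(genome$seq[1])
  if (read_len > n) stop("read_len longer than the genome")
  if (mode == "tiling") {
    starts <- seq.int(0L, n - 1L, by = read_len)
  } else {
    n_reads <- n_reads %||% max(1L, n %/% read_len)
    starts <- withr::with_seed(as.integer(seed),
                               sample.int(n - read_len + 1L, n_reads,
                                          replace = TRUE) - 1L)
  }
  ends <- pmin(starts + read_len, n)
  tibble::tibble(
    id = sprintf("%s:%d-%d", genome$id[1], starts, ends),
    seq = stringi::stri_sub(genome$seq[1], starts + 1L, ends))
}

#' Mutate a sequence with i.i.d. substitutions and indels
#'
#' @param seq nucleotide string.
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel probability (half single-base insertions,
#'   half deletions).
#' @param seed RNG seed.
#' @return The mutated sequence.
#' @export
mutate_seq <- function(seq, sub_rate = 0, indel_rate = 0, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.5, indel_rate >= 0, indel_rate <= 0.5)
  if (sub_rate == 0 && indel_rate == 0) return(seq)
  withr::with_seed(as.integer(seed), {
    v <- strsplit(seq, "")[[1]]
    out <- character(0)
    for (i in seq_along(v)) {
      b <- v[i]
      if (runif(1) < sub_rate) b <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      if (runif(1) < indel_rate) {
        if (runif(1) < 0.5) b <- c(b, sample(c("A", "C", "G", "T"), 1L))
        else b <- character(0)
      }
      out <- c(out, b)
    }
    paste0(out, collapse = "")
  })
}

#' Simulate a transposase family alignment
#'
#' A random ancestral peptide evolved into `n_seqs` descendants by i.i.d.
#' substitutions (no indels, so the set is trivially aligned). Used to train
#' profiles and to source implanted transposase ORFs that are neither
#' identical to the profile consensus nor unrecognisable.
#'
#' @param n_seqs number of sequences (50+ mirrors a well-fed profile).
#' @param length peptide length.
#' @param divergence per-residue substitution probability from the ancestor.
#' @param seed RNG seed.
#' @return An alignment tibble (`id`, `seq`); the ancestor is in
#'   `attr(, "ancestor")`.
#' @export
simulate_transposase_msa <- function(n_seqs = 60L, length = 300L,
                                     divergence = 0.25, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    anc <- sample(AA_CHARS, length, replace = TRUE)
    seqs <- vapply(seq_len(n_seqs), function(i) {
      v <- anc
      hit <- which(runif(length) < divergence)
      for (j in hit) v[j] <- sample(setdiff(AA_CHARS, v[j]), 1L)
      paste0(v, collapse = "")
    }, character(1))
    msa <- tibble::tibble(id = sprintf("tpase_%03d", seq_len(n_seqs)),
                          seq = seqs)
    attr(msa, "ancestor") <- paste0(anc, collapse = "")
    msa
  })
}
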