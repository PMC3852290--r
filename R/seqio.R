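#' Sequence I/O and coordinate plumbing
#'
#' Sequence sets travel through the package as tibbles with columns `id`
#' (unique within a set) and `seq` (upper-case nucleotide or amino-acid
#' string). Coordinates are 0-based half-open everywhere internally; they are
#' converted to 1-based inclusive only when writing GFF3.
#'
#' @name seqio
NULL

NT_CHARS <- c("A", "C", "G", "T", "N")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a sequence tibble
#'
#' @param id character vector of identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @return A tibble with columns `id`, `seq`.
#' @export
seq_tbl <- function(id, seq) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  if (any(id == "" | is.na(id))) stop("sequence ids must be nonempty")
  if (any(seq == "" | is.na(seq))) stop("sequences must be nonempty")
  if (any(grepl("\\s", seq))) stop("sequences must not contain whitespace")
  tibble::tibble(id = as.character(id), seq = seq)
}

#' Guess the alphabet of a sequence set
#'
#' @param seqs sequence tibble.
#' @return `"nt"` if every sequence uses only A/C/G/T/N, else `"aa"`.
#' @export
guess_alphabet <- function(seqs) {
  if (all(grepl("^[ACGTN]+$", seqs$seq))) "nt" else "aa"
}

check_alphabet <- function(seqs, alphabet) {
  pat <- if (alphabet == "nt") "^[ACGTN]+$" else "^[A-Z*]+$"
  bad <- !grepl(pat, seqs$seq)
  if (any(bad)) {
    stop("sequence(s) ", paste(utils::head(seqs$id[bad], 3), collapse = ", "),
         " contain characters outside the ", alphabet, " alphabet")
  }
  invisible(seqs)
}

#' Read a (multi-)FASTA file into a sequence tibble
#'
#' Wrapped or unwrapped lines are accepted; sequences are upper-cased.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (full header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  desc <- names(x)
  tibble::tibble(
    id = sub("\\s.*$", "", desc),
    desc = desc,
    seq = unname(toupper(as.character(x)))
  )
}

#' Write a sequence tibble as FASTA
#'
#' @param seqs sequence tibble (`id`, `seq`; an optional `desc` column is used
#'   as the full header).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  hdr <- if ("desc" %in% names(seqs)) seqs$desc else seqs$id
  x <- Biostrings::BStringSet(seqs$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a multiple sequence alignment (aligned FASTA or Stockholm)
#'
#' Gap characters `-` and `.` are both normalised to `-`. All rows must have
#' equal aligned length.
#'
#' @param path path to the alignment.
#' @param format `"auto"` (sniff the first line), `"fasta"` or `"stockholm"`.
#' @return A tibble with columns `id`, `seq` (aligned rows).
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    msa <- read_fasta(path)[, c("id", "seq")]
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & trimws(lines) != "" & lines != "//"]
    parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2L)
    msa <- tibble::tibble(id = parts[, 1], seq = parts[, 2]) %>%
      dplyr::group_by(.data$id) %>%
      dplyr::summarise(seq = paste0(.data$seq, collapse = ""), .groups = "drop")
    # preserve file order of first appearance
    msa <- msa[match(unique(parts[, 1]), msa$id), ]
  }
  msa$seq <- toupper(gsub("\\.", "-", msa$seq))
  if (length(unique(nchar(msa$seq))) != 1L)
    stop("ragged alignment: rows differ in aligned length")
  msa
}

#' Reverse complement
#'
#' @param x character vector of nucleotide sequences over A/C/G/T/N.
#' @return The Watson-Crick reverse complements.
#' @export
revcomp <- function(x) {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) stop("non-nucleotide character in sequence")
  stringi::stri_reverse(chartr("ACGTacgtn", "TGCAtgcan", x))
}

genetic_code_table <- function(table = "11") {
  gc <- Biostrings::getGeneticCode(as.character(table))
  # index all 64 codons; anything containing N translates to X
  gc
}

translate_one <- function(seq, code) {
  n <- nchar(seq)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- stringi::stri_sub(seq, from = starts, length = 3L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Six-frame translation
#'
#' Frames +1..+3 translate the sequence from offsets 0, 1, 2; frames -1..-3
#' translate the reverse complement from offsets 0, 1, 2. Stop codons are
#' rendered `*`; codons containing N translate to `X`.
#'
#' @param seqs sequence tibble (nucleotide), e.g. from [segment_genome()].
#' @param table NCBI genetic code id (default "11", bacterial/archaeal).
#' @return A tibble with columns `parent_id`, `frame` (+1..+3, -1..-3),
#'   `nt_offset` (offset of codon 1 within the forward / reverse-complemented
#'   sequence) and `peptide`.
#' @export
translate_six_frames <- function(seqs, table = "11") {
  check_alphabet(seqs, "nt")
  code <- genetic_code_table(table)
  res <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    if (nchar(s) < 3L) stop("sequence ", seqs$id[i], " shorter than one codon")
    rc <- revcomp(s)
    tibble::tibble(
      parent_id = seqs$id[i],
      frame = c(1L, 2L, 3L, -1L, -2L, -3L),
      nt_offset = c(0L, 1L, 2L, 0L, 1L, 2L),
      peptide = c(
        translate_one(s, code),
        translate_one(substring(s, 2L), code),
        translate_one(substring(s, 3L), code),
        translate_one(rc, code),
        translate_one(substring(rc, 2L), code),
        translate_one(substring(rc, 3L), code)
      )
    )
  })
  if (all(res$peptide == "")) stop("all six frames empty")
  res
}

#' Cut a genome into fixed windows
#'
#' Segments start at multiples of `window - overlap`; the last segment is
#' truncated at the sequence end. The union of segments covers the sequence.
#'
#' @param seqs sequence tibble (nucleotide).
#' @param window window length in nt (default 5000).
#' @param overlap overlap between consecutive windows in nt (default 300,
#'   about 100 codons, so a transposase straddling a boundary is still seen
#'   complete in one window).
#' @return A tibble with columns `segment_id`, `parent_id`, `start`, `end`
#'   (0-based half-open) and `seq`.
#' @export
segment_genome <- function(seqs, window = 5000L, overlap = 300L) {
  if (window <= 0L) stop("window must be positive")
  if (overlap < 0L || overlap >= window) stop("need window > overlap >= 0")
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    n <- nchar(seqs$seq[i])
    step <- window - overlap
    starts <- seq.int(0L, max(0L, n - 1L), by = step)
    # drop starts that begin a window fully contained in the previous one
    starts <- starts[starts == 0L | starts + overlap < n]
    ends <- pmin(starts + window, n)
    tibble::tibble(
      segment_id = sprintf("%s|%d-%d", seqs$id[i], starts, ends),
      parent_id = seqs$id[i],
      start = as.integer(starts),
      end = as.integer(ends),
      seq = stringi::stri_sub(seqs$seq[i], from = starts + 1L, to = ends)
    )
  })
}
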