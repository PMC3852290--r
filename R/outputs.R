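#' Output writers
#'
#' Element calls are written as GFF3 (one feature per copy, 1-based inclusive
#' coordinates as the format requires), consensus sequences as FASTA, hits and
#' cluster tables as TSV, and every CLI run drops a YAML manifest that makes
#' the run reproducible.
#'
#' @name outputs
NULL

#' Write element calls as GFF3
#'
#' One `mobile_genetic_element` feature per copy, with `call_id`, `kind`,
#' `family`, `partner`, `evidence`, `ir_len` and `dr_len` attributes.
#'
#' @param calls calls tibble (from the de novo pipelines).
#' @param genome the genome tibble the calls refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_element_gff3 <- function(calls, genome, path) {
  if (nrow(calls) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- calls %>%
    dplyr::mutate(copies = purrr::map(.data$copies, ~.x)) %>%
    tidyr::unnest("copies")
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id[1],
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "teminer", type = "mobile_genetic_element",
    ID = sprintf("%s.copy%d", rows$call_id,
                 stats::ave(seq_len(nrow(rows)), rows$call_id, FUN = seq_along)),
    call_id = rows$call_id, kind = rows$kind,
    family = ifelse(is.na(rows$family), "unknown", rows$family),
    partner = ifelse(is.na(rows$partner), ".", rows$partner),
    evidence = rows$evidence,
    ir_len = rows$ir_len, dr_len = rows$dr_len)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write a calls summary TSV
#'
#' @param calls calls tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  flat <- calls %>% dplyr::select(-dplyr::any_of("copies"))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write clustering results as TSV plus one FASTA per cluster
#'
#' @param clusters output of [greedy_cluster()].
#' @param dir output directory (created if needed).
#' @return The TSV path, invisibly.
#' @export
write_clusters <- function(clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "clusters.tsv")
  utils::write.table(
    clusters[, c("cluster_id", "id", "role", "identity", "strand")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  for (cid in unique(clusters$cluster_id)) {
    member <- clusters[clusters$cluster_id == cid, ]
    write_fasta(member[, c("id", "seq")],
                file.path(dir, paste0(cid, ".fasta")))
  }
  invisible(tsv)
}

#' Write call consensus sequences as FASTA
#'
#' @param calls calls tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  write_fasta(tibble::tibble(
    id = sprintf("%s kind=%s family=%s", calls$call_id, calls$kind,
                 ifelse(is.na(calls$family), "unknown", calls$family)),
    seq = calls$consensus), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records tool version, subcommand, resolved configuration, input checksums
#' and seeds; re-running from the same manifest reproduces the primary
#' outputs byte-identically (the manifest itself carries a timestamp and is
#' not a primary output).
#'
#' @param dir output directory.
#' @param subcommand CLI subcommand (or calling function).
#' @param config named list of resolved parameters.
#' @param inputs character vector of input file paths.
#' @param seed seed(s) used.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, subcommand, config, inputs = character(),
                           seed = NULL) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "teminer",
    version = as.character(packageVersion("teminer")),
    subcommand = subcommand,
    config = config,
    inputs = as.list(setNames(
      as.character(tools::md5sum(inputs)), basename(inputs))),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
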