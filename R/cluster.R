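#' Greedy centroid clustering
#'
#' Sequences are processed in descending length order (ties broken
#' lexicographically by id, so the output is invariant to input order); each
#' sequence joins the first existing centroid it matches at or above the
#' identity threshold, otherwise it founds a new cluster. Identity is computed
#' from a global alignment (match +1, mismatch -1, gap -1) as
#' matches / alignment columns, for both alphabets.
#'
#' @name cluster
NULL

#' Pairwise global-alignment identity
#'
#' @param a,b sequences (plain strings) over the same alphabet.
#' @param alphabet `"nt"` or `"aa"`.
#' @return Fraction of matching columns in one optimal global alignment.
#' @export
pairwise_identity <- function(a, b, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  enc <- if (alphabet == "nt") encode_nt else encode_aa
  nw_identity_cpp(enc(a), enc(b), 1, -1, -1)$identity
}

#' Greedy centroid clustering of a sequence set
#'
#' @param seqs sequence tibble.
#' @param identity_threshold member-to-centroid identity in (0, 1];
#'   default 0.9, the historical default of greedy centroid clusterers.
#' @param alphabet `"nt"` or `"aa"`; guessed from content when `NULL`.
#'   Nucleotide clustering is strand-aware: a sequence matches a centroid on
#'   whichever strand aligns better (candidates extracted from a genome come
#'   in either orientation).
#' @return A tibble with one row per sequence: `cluster_id`, `centroid_id`,
#'   `id`, `role` (`"centroid"` or `"member"`), `identity` (to the centroid;
#'   1 for the centroid itself), `strand` (orientation relative to the
#'   centroid; always `"+"` for peptides) and `seq`.
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.9, alphabet = NULL) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(seqs) == 0L) {
    return(tibble::tibble(cluster_id = character(), centroid_id = character(),
                          id = character(), role = character(),
                          identity = numeric(), strand = character(),
                          seq = character()))
  }
  alphabet <- alphabet %||% guess_alphabet(seqs)
  ord <- order(-nchar(seqs$seq), seqs$id, method = "radix")
  seqs <- seqs[ord, ]
  centroids <- integer(0)  # row indices of centroids, in founding order
  assign <- integer(nrow(seqs))
  ident <- numeric(nrow(seqs))
  strand <- rep("+", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    placed <- FALSE
    rc_i <- if (alphabet == "nt") revcomp(seqs$seq[i]) else NULL
    for (ci in seq_along(centroids)) {
      idv <- pairwise_identity(seqs$seq[i], seqs$seq[centroids[ci]], alphabet)
      st <- "+"
      if (alphabet == "nt") {
        idrc <- pairwise_identity(rc_i, seqs$seq[centroids[ci]], alphabet)
        if (idrc > idv) { idv <- idrc; st <- "-" }
      }
      if (idv >= identity_threshold) {
        assign[i] <- ci; ident[i] <- idv; strand[i] <- st
        placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
      ident[i] <- 1.0
    }
  }
  tibble::tibble(
    cluster_id = sprintf("cluster_%03d", assign),
    centroid_id = seqs$id[centroids[assign]],
    id = seqs$id,
    role = ifelse(seq_len(nrow(seqs)) %in% centroids, "centroid", "member"),
    identity = ident,
    strand = strand,
    seq = seqs$seq
  ) %>% dplyr::arrange(.data$cluster_id, dplyr::desc(.data$role == "centroid"),
                       .data$id)
}

#' Cluster centroids as a sequence tibble
#'
#' @param clusters output of [greedy_cluster()].
#' @return One row per cluster: `id` (= centroid id), `seq`, `cluster_id`,
#'   `n_members`.
#' @export
cluster_centroids <- function(clusters) {
  clusters %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(
      id = .data$id[.data$role == "centroid"][1],
      seq = .data$seq[.data$role == "centroid"][1],
      n_members = dplyr::n(), .groups = "drop") %>%
    dplyr::select("id", "seq", "cluster_id", "n_members")
}
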