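#' Pairwise sequence identity under the short-sequence convention
#'
#' Computes the fraction of identical aligned residues between two amino-acid
#' sequences, using a global alignment scored with match = 1, mismatch = 0 and
#' a linear gap penalty of -1, divided by the length of the shorter sequence.
#' This is the identity convention used by incremental clustering tools such
#' as CD-HIT, where a short sequence fully contained in a longer one scores
#' identity 1.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return A single number in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIR") # 8/9
#' @export
pairwise_identity <- function(a, b) {
  align_counts(a, b)$identity
}

#' Identity and aligned coverage of a sequence pair
#'
#' Like [pairwise_identity()] but also reports the aligned fraction of the
#' shorter sequence (non-gap alignment columns / shorter length), the
#' quantity the clustering coverage rule is applied to.
#'
#' @inheritParams pairwise_identity
#' @return A tibble with columns `identity` and `coverage`.
#' @export
alignment_stats <- function(a, b) {
  cnt <- align_counts(a, b)
  tibble::tibble(identity = cnt$identity, coverage = cnt$coverage)
}

# identity plus aligned-fraction-of-shorter, shared by clustering
align_counts <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1)
    abort("`a` and `b` must be single character strings.")
  if (nchar(a) == 0 || nchar(b) == 0)
    abort("Sequences must be non-empty.")
  cnt <- nw_counts(a, b)
  short <- min(nchar(a), nchar(b))
  list(
    identity = cnt[["match"]] / short,
    coverage = cnt[["aligned"]] / short
  )
}

#' Greedy incremental clustering of protein sequences
#'
#' Reduces redundancy in an ORF or protein catalog the way incremental
#' clusterers (CD-HIT, mmseqs2 easy-cluster) do: sequences are sorted by
#' length, longest first (ties broken by id), and each sequence joins the
#' first established representative it matches at or above the identity
#' threshold with sufficient aligned coverage of the shorter sequence;
#' otherwise it founds a new cluster. Identity uses the shorter-sequence
#' denominator (see [pairwise_identity()]). The procedure is deterministic
#' and independent of the input row order.
#'
#' @param records A data frame with columns `id` (unique) and `sequence`.
#' @param identity_threshold Minimum identity to join a cluster, in (0, 1].
#'   Typical settings: 0.90 for search-database reduction, 0.95 for
#'   single-copy core-gene clustering.
#' @param min_short_coverage Minimum fraction of the shorter sequence that
#'   must be aligned (non-gap columns), in (0, 1]. Default 0.80, mirroring
#'   the `-c 0.80` convention of mmseqs2 easy-cluster.
#' @return A tibble with one row per input sequence: `cluster` (integer, in
#'   founding order), `representative`, `member` and `identity` of the member
#'   to its representative (1 for representatives).
#' @examples
#' recs <- tibble::tibble(
#'   id = c("a", "b", "c"),
#'   sequence = c("MKLVVNNALK", "MKLVVNNALK", "WWWWYYYYFF")
#' )
#' greedy_cluster(recs, identity_threshold = 0.9)
#' @export
greedy_cluster <- function(records, identity_threshold = 0.9,
                           min_short_coverage = 0.8) {
  stopifnot(is.data.frame(records))
  if (!all(c("id", "sequence") %in% names(records)))
    abort("`records` needs columns `id` and `sequence`.")
  if (!(identity_threshold > 0 && identity_threshold <= 1))
    abort("`identity_threshold` must be in (0, 1].")
  if (!(min_short_coverage > 0 && min_short_coverage <= 1))
    abort("`min_short_coverage` must be in (0, 1].")
  if (anyDuplicated(records$id))
    abort("Sequence ids must be unique.")
  n <- nrow(records)
  empty <- tibble::tibble(
    cluster = integer(), representative = character(),
    member = character(), identity = double()
  )
  if (n == 0) return(empty)
  if (any(nchar(records$sequence) == 0)) abort("Sequences must be non-empty.")

  # canonical order: length descending, then id
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- toupper(records$sequence[ord])

  rep_idx <- integer(0)        # indices (into ord) of representatives
  assign_cluster <- integer(n)
  assign_ident <- double(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(rep_idx) > 0) {
      cnt <- nw_counts_many(seqs[i], seqs[rep_idx])
      short <- pmin(nchar(seqs[i]), nchar(seqs[rep_idx]))
      ident <- cnt[, "match"] / short
      cov <- cnt[, "aligned"] / short
      ok <- which(ident >= identity_threshold & cov >= min_short_coverage)
      if (length(ok) > 0) {
        k <- ok[1] # first-fit in founding order
        assign_cluster[i] <- k
        assign_ident[i] <- ident[k]
        placed <- TRUE
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign_cluster[i] <- length(rep_idx)
      assign_ident[i] <- 1
    }
  }
  tibble::tibble(
    cluster = assign_cluster,
    representative = ids[rep_idx][assign_cluster],
    member = ids,
    identity = assign_ident
  ) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$identity), .data$member)
}
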