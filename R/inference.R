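# target-decoy q-values shared by the peptide and protein-group tiers:
# at each score threshold t, FDR(t) = D(t) / max(T(t), 1) capped at 1;
# q is the running minimum from the most permissive threshold upward,
# so it is non-increasing in score and tied scores share a q-value.
td_qvalues <- function(score, is_decoy, pi_correction = FALSE) {
  stopifnot(length(score) == length(is_decoy))
  if (!any(!is_decoy)) abort("Need at least one target; all entries are decoys.")
  ord <- order(score, decreasing = TRUE)
  dec <- is_decoy[ord]
  cum_t <- cumsum(!dec)
  cum_d <- cumsum(dec)
  s <- score[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  block <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  t_blk <- cum_t[last_of_tie]
  d_blk <- cum_d[last_of_tie]
  if (pi_correction) d_blk <- d_blk + 1
  fdr_blk <- pmin(d_blk / pmax(t_blk, 1), 1)
  q_blk <- rev(cummin(rev(fdr_blk)))
  out <- tibble::tibble(fdr = fdr_blk[block], qvalue = q_blk[block])
  out[order(ord), ]
}

#' Peptide-level q-values from target-decoy competition
#'
#' Estimates, for every PSM score threshold, the false discovery rate as the
#' ratio of decoy to target PSMs at or above the threshold (capped at 1),
#' and converts it to monotone q-values by taking the running minimum from
#' the bottom of the ranking upward. PSMs tied on score share a q-value.
#'
#' @param psms A data frame with numeric `score` and logical `is_decoy`
#'   columns (e.g. the `psms` tibble of a [simulate_psm_table()] result).
#' @param pi_correction Add 1 to the decoy count (conservative variant);
#'   default `FALSE`, the plain D/T estimator.
#' @return The input with `fdr` and `qvalue` columns appended.
#' @export
peptide_qvalues <- function(psms, pi_correction = FALSE) {
  stopifnot(is.data.frame(psms))
  if (!all(c("score", "is_decoy") %in% names(psms)))
    abort("`psms` needs columns `score` and `is_decoy`.")
  q <- td_qvalues(psms$score, psms$is_decoy, pi_correction)
  psms$fdr <- q$fdr
  psms$qvalue <- q$qvalue
  psms
}

#' Group proteins indistinguishable by their peptide evidence
#'
#' Applies the two parsimony rules used in protein inference: proteins with
#' identical peptide sets are merged into one group, and a protein whose
#' peptide set is a strict subset of another's is absorbed into that
#' protein's group (into the largest containing set; ties broken by the
#' lexicographically smallest founder). A peptide whose protein mappings
#' span more than one group counts as shared — non-unique — for every group
#' it touches.
#'
#' @param peptide_map A data frame with columns `peptide` and `protein`,
#'   one row per mapping.
#' @return A tibble with one row per group: `group`, `members` (list of
#'   protein ids), `n_proteins`, `peptides` (list, the group's peptide set),
#'   `n_unique` (peptides mapping only within the group) and `member_info`
#'   (list of per-member tibbles with `protein`, `n_peptides`,
#'   `n_unique_peptides`).
#' @examples
#' m <- tibble::tibble(
#'   peptide = c("A", "B", "A", "B", "C"),
#'   protein = c("P1", "P1", "P2", "P2", "P3")
#' )
#' group_proteins(m)
#' @export
group_proteins <- function(peptide_map) {
  stopifnot(is.data.frame(peptide_map))
  if (!all(c("peptide", "protein") %in% names(peptide_map)))
    abort("`peptide_map` needs columns `peptide` and `protein`.")
  empty <- tibble::tibble(
    group = character(), members = list(), n_proteins = integer(),
    peptides = list(), n_unique = integer(), member_info = list()
  )
  if (nrow(peptide_map) == 0) return(empty)

  pm <- dplyr::distinct(peptide_map, .data$peptide, .data$protein)
  pep_sets <- split(pm$peptide, pm$protein)
  pep_sets <- lapply(pep_sets, function(x) sort(unique(x)))

  # rule 1: merge proteins with identical peptide sets
  sig <- vapply(pep_sets, paste, character(1), collapse = "\r")
  merged <- split(names(pep_sets), sig)
  merged <- lapply(merged, sort)
  set_peps <- lapply(pep_sets[vapply(merged, `[`, character(1), 1)],
                     identity)
  sizes <- lengths(set_peps)
  founder_id <- vapply(merged, `[`, character(1), 1)

  # rule 2: absorb strict subsets. A set's supersets are exactly the sets
  # indexed by every one of its peptides, found via an inverted index.
  postings <- split(
    rep(seq_along(set_peps), sizes),
    unlist(set_peps, use.names = FALSE)
  )
  owner <- integer(length(set_peps))
  for (i in seq_along(set_peps)) {
    cand <- Reduce(intersect, postings[set_peps[[i]]])
    sup <- cand[sizes[cand] > sizes[i]]
    if (length(sup) == 0) {
      owner[i] <- i
    } else {
      best <- sup[sizes[sup] == max(sizes[sup])]
      owner[i] <- best[order(founder_id[best])][1]
    }
  }
  # chains (A subset B subset C) resolve to the maximal set in one step
  # because the largest superset is always maximal; assert and finish
  stopifnot(all(owner[owner] == owner))

  group_keys <- sort(unique(owner))
  group_of <- match(owner, group_keys)
  members <- lapply(seq_along(group_keys), function(g) {
    sort(unlist(merged[group_of == g], use.names = FALSE))
  })
  peptides <- set_peps[group_keys]

  # shared peptides: map each peptide to the set of groups its proteins span
  prot_group <- setNames(
    rep(seq_along(group_keys), lengths(members)),
    unlist(members, use.names = FALSE)
  )
  pep_groups <- split(prot_group[pm$protein], pm$peptide)
  pep_ngroups <- vapply(pep_groups, function(x) length(unique(x)), integer(1))
  unique_peps <- names(pep_ngroups)[pep_ngroups == 1]

  n_unique <- unname(vapply(peptides, function(p) sum(p %in% unique_peps),
                            integer(1)))
  member_info <- lapply(seq_along(group_keys), function(g) {
    ms <- members[[g]]
    tibble::tibble(
      protein = ms,
      n_peptides = lengths(pep_sets[ms]),
      n_unique_peptides = vapply(pep_sets[ms], function(p)
        sum(p %in% unique_peps), integer(1))
    )
  })

  ord <- order(vapply(members, `[`, character(1), 1))
  tibble::tibble(
    group = sprintf("PG%05d", seq_along(group_keys)),
    members = members[ord],
    n_proteins = lengths(members)[ord],
    peptides = unname(peptides[ord]),
    n_unique = n_unique[ord],
    member_info = member_info[ord]
  )
}

#' Protein-group level q-values
#'
#' Ranks protein groups by their best member-peptide score and applies the
#' same target-decoy step-down q-value construction as the peptide tier.
#'
#' @param groups A data frame with numeric `best_score` and logical
#'   `is_decoy` columns.
#' @param pi_correction See [peptide_qvalues()].
#' @return The input with `fdr` and `qvalue` columns appended.
#' @export
protein_group_fdr <- function(groups, pi_correction = FALSE) {
  stopifnot(is.data.frame(groups))
  if (!all(c("best_score", "is_decoy") %in% names(groups)))
    abort("`groups` needs columns `best_score` and `is_decoy`.")
  q <- td_qvalues(groups$best_score, groups$is_decoy, pi_correction)
  groups$fdr <- q$fdr
  groups$qvalue <- q$qvalue
  groups
}

#' Evidence filters on protein groups
#'
#' Removes groups failing the minimum unique-peptide rule, groups whose
#' entire evidence is modified peptides, and contaminant groups, tallying
#' removals per rule (a group is tallied under the first rule it fails, in
#' the order contaminant, modified-only, unique-peptide minimum).
#'
#' @param groups A data frame with `n_unique` and, if present, logical
#'   `modified_only` and `is_contaminant` columns, plus `members` (list) for
#'   contaminant matching by id.
#' @param min_unique Minimum unique peptides per group (default 2).
#' @param drop_modified_only Drop groups evidenced only by modified peptides.
#' @param contaminant_ids Protein ids treated as contaminants.
#' @return The filtered tibble, with a `filter_audit` attribute tallying
#'   input, removals per rule, and output.
#' @export
apply_evidence_filters <- function(groups, min_unique = 2,
                                   drop_modified_only = TRUE,
                                   contaminant_ids = character()) {
  stopifnot(is.data.frame(groups))
  n_in <- nrow(groups)
  is_cont <- if ("is_contaminant" %in% names(groups)) groups$is_contaminant
             else rep(FALSE, n_in)
  if (length(contaminant_ids) > 0 && "members" %in% names(groups)) {
    is_cont <- is_cont | vapply(groups$members, function(m)
      any(m %in% contaminant_ids), logical(1))
  }
  is_mod <- if (drop_modified_only && "modified_only" %in% names(groups))
    groups$modified_only else rep(FALSE, n_in)
  too_few <- groups$n_unique < min_unique

  fate <- dplyr::case_when(
    is_cont ~ "contaminant",
    is_mod ~ "modified_only",
    too_few ~ "min_unique",
    .default = "retained"
  )
  counts <- c(n_in, sum(fate == "contaminant"), sum(fate == "modified_only"),
              sum(fate == "min_unique"), sum(fate == "retained"))
  audit <- tibble::tibble(
    rule = c("input", "contaminant", "modified_only", "min_unique",
             "retained"),
    n = counts
  )
  out <- groups[fate == "retained", ]
  attr(out, "filter_audit") <- audit
  out
}

#' Pick the representative protein of a group
#'
#' The representative is the member with the most unique peptides; ties are
#' broken by higher aggregate PSM score, then by the lexicographically
#' smallest protein id, so the choice is deterministic.
#'
#' @param member_info A tibble with columns `protein`, `n_unique_peptides`
#'   and optionally `aggregate_score` (one row per group member).
#' @return A single protein id.
#' @export
select_representative <- function(member_info) {
  stopifnot(is.data.frame(member_info), nrow(member_info) > 0)
  score <- if ("aggregate_score" %in% names(member_info))
    member_info$aggregate_score else rep(0, nrow(member_info))
  ord <- order(-member_info$n_unique_peptides, -score, member_info$protein)
  member_info$protein[ord[1]]
}

#' Infer filtered protein groups from a PSM table
#'
#' The full two-tier inference used on metaexoproteomic searches: peptide
#' q-values by target-decoy competition with acceptance at `pep_fdr`;
#' parsimonious protein grouping of the accepted peptides; protein-group
#' q-values at `prot_fdr`; removal of decoy groups, contaminants, groups
#' evidenced only by modified peptides, and groups with fewer than
#' `min_unique` unique peptides; and deterministic representative selection.
#'
#' @param psms A `synthetic_psm_set` or a PSM tibble with columns
#'   `spectrum`, `peptide`, `proteins` (`;`-separated), `score`, `is_decoy`,
#'   `is_modified`, `is_contaminant`, `sample`, `spectral_count`,
#'   `intensity`.
#' @param pep_fdr Peptide-tier q-value threshold (default 0.05).
#' @param prot_fdr Protein-tier q-value threshold (default 0.10).
#' @param min_unique Minimum unique peptides per surviving group (default 2).
#' @param drop_modified_only Drop groups with exclusively modified evidence.
#' @param pi_correction See [peptide_qvalues()].
#' @return A tibble of class `protein_groups`, one row per surviving group,
#'   with `group`, `representative`, `members`, `n_proteins`, `peptides`,
#'   `n_unique`, `best_score`, `qvalue`. The `audit` attribute tallies every
#'   removal stage; retrieve it with `attr(x, "audit")`.
#' @export
infer_protein_groups <- function(psms, pep_fdr = 0.05, prot_fdr = 0.10,
                                 min_unique = 2, drop_modified_only = TRUE,
                                 pi_correction = FALSE) {
  if (inherits(psms, "synthetic_psm_set")) psms <- psms$psms
  stopifnot(is.data.frame(psms))
  need <- c("peptide", "proteins", "score", "is_decoy")
  if (!all(need %in% names(psms)))
    abort(paste("`psms` is missing column(s):",
                paste(setdiff(need, names(psms)), collapse = ", ")))

  scored <- peptide_qvalues(psms, pi_correction)
  accepted <- scored[scored$qvalue <= pep_fdr, ]
  if (nrow(accepted) == 0) abort("No PSMs accepted at the peptide FDR.")

  pairs <- accepted |>
    dplyr::select("peptide", "proteins") |>
    dplyr::distinct() |>
    tidyr::separate_longer_delim("proteins", ";") |>
    dplyr::rename(protein = "proteins")

  decoy_prots <- unique(unlist(
    strsplit(accepted$proteins[accepted$is_decoy], ";", fixed = TRUE)
  ))
  cont_prots <- if ("is_contaminant" %in% names(accepted)) {
    unique(unlist(strsplit(
      accepted$proteins[accepted$is_contaminant], ";", fixed = TRUE)))
  } else character(0)

  groups <- group_proteins(pairs)

  # per-peptide summaries of the accepted PSMs
  pep_best <- accepted |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      best = max(.data$score), total = sum(.data$score),
      all_modified = if ("is_modified" %in% names(accepted))
        all(.data$is_modified) else FALSE,
      .groups = "drop"
    )
  idx <- function(p) match(p, pep_best$peptide)
  groups$best_score <- vapply(groups$peptides, function(p)
    max(pep_best$best[idx(p)]), double(1))
  groups$aggregate_score <- vapply(groups$peptides, function(p)
    sum(pep_best$total[idx(p)]), double(1))
  groups$modified_only <- vapply(groups$peptides, function(p)
    all(pep_best$all_modified[idx(p)]), logical(1))
  n_decoy_members <- vapply(groups$members, function(m)
    sum(m %in% decoy_prots), integer(1))
  if (any(n_decoy_members > 0 & n_decoy_members < lengths(groups$members)))
    abort("A group mixes target and decoy proteins; decoy mapping is corrupt.")
  groups$is_decoy <- n_decoy_members > 0
  groups$is_contaminant <- vapply(groups$members, function(m)
    any(m %in% cont_prots), logical(1))

  groups <- protein_group_fdr(groups, pi_correction)
  n_groups_in <- nrow(groups)
  kept <- groups[groups$qvalue <= prot_fdr, ]
  n_decoy_removed <- sum(kept$is_decoy)
  kept <- kept[!kept$is_decoy, ]

  out <- apply_evidence_filters(
    kept, min_unique = min_unique, drop_modified_only = drop_modified_only
  )
  filter_audit <- attr(out, "filter_audit")

  # member aggregate scores for representative selection
  prot_scores <- pairs |>
    dplyr::left_join(pep_best, by = "peptide") |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(aggregate_score = sum(.data$total), .groups = "drop")
  out$representative <- vapply(out$member_info, function(mi) {
    mi$aggregate_score <- prot_scores$aggregate_score[
      match(mi$protein, prot_scores$protein)]
    select_representative(mi)
  }, character(1))

  out <- dplyr::select(
    out, "group", "representative", "members", "n_proteins", "peptides",
    "n_unique", "best_score", "qvalue"
  )
  attr(out, "audit") <- dplyr::bind_rows(
    tibble::tibble(
      stage = "psm",
      rule = c("input", "peptide_fdr_rejected"),
      n = c(nrow(psms), nrow(psms) - nrow(accepted))
    ),
    tibble::tibble(
      stage = "group",
      rule = c("input", "protein_fdr_rejected", "decoy"),
      n = c(n_groups_in, n_groups_in - nrow(kept) - n_decoy_removed,
            n_decoy_removed)
    ),
    tibble::tibble(stage = "group", rule = filter_audit$rule[-1],
                   n = filter_audit$n[-1])
  )
  class(out) <- c("protein_groups", class(out))
  out
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("<protein_groups> %d groups, %d proteins\n",
              nrow(x), sum(x$n_proteins)))
  NextMethod()
}
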