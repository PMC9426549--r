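#' Classify marker-gene ORFs by family score thresholds
#'
#' Emulates profile-HMM screening of an ORF catalog against marker families
#' (e.g. the alkaline phosphatases PhoX, PhoD, PhoA): an ORF is assigned to
#' the family with the maximal score among families whose threshold it
#' exceeds; if no family qualifies the ORF is unclassified. Exact score ties
#' go to the lexicographically smallest family name.
#'
#' @param score_table A data frame with one row per ORF-family pair:
#'   columns `orf`, `family`, `score`.
#' @param family_thresholds A named numeric vector (or data frame with
#'   `family`, `threshold`) giving the score threshold of every scored
#'   family; a scored family without a threshold is an error.
#' @return A tibble `orf`, `family` (`NA` for unclassified), `score` (the
#'   winning score, `NA` for unclassified).
#' @export
classify_markers <- function(score_table, family_thresholds) {
  stopifnot(is.data.frame(score_table))
  if (!all(c("orf", "family", "score") %in% names(score_table)))
    abort("`score_table` needs columns `orf`, `family`, `score`.")
  if (is.data.frame(family_thresholds)) {
    family_thresholds <- setNames(family_thresholds$threshold,
                                  family_thresholds$family)
  }
  missing <- setdiff(unique(score_table$family), names(family_thresholds))
  if (length(missing) > 0)
    abort(paste("No threshold for scored family(ies):",
                paste(missing, collapse = ", ")))
  d <- score_table
  d$threshold <- family_thresholds[d$family]
  d |>
    dplyr::group_by(.data$orf) |>
    dplyr::summarise(
      family = {
        ok <- .data$score > .data$threshold
        if (!any(ok)) NA_character_ else {
          f <- .data$family[ok]; s <- .data$score[ok]
          f[order(-s, f)][1]
        }
      },
      score = if (any(.data$score > .data$threshold))
        max(.data$score[.data$score > .data$threshold]) else NA_real_,
      .groups = "drop"
    )
}

#' Assign taxonomy to marker ORFs by best reference hit
#'
#' The best (lowest e-value) hit of each ORF assigns its taxonomy, provided
#' the e-value passes the cutoff; ORFs with no qualifying hit are removed
#' from the output and tallied in the `removed` attribute. Ties on e-value
#' are broken by the lexicographically smallest reference id.
#'
#' @param hits A data frame with columns `orf`, `reference`, `taxon`,
#'   `evalue` (>= 0).
#' @param evalue_cutoff Maximum e-value for an assignment (default 1e-20).
#' @return A tibble `orf`, `reference`, `taxon`, `evalue` of assigned ORFs;
#'   `attr(x, "removed")` holds the ORFs without a qualifying hit.
#' @export
assign_marker_taxonomy <- function(hits, evalue_cutoff = 1e-20) {
  stopifnot(is.data.frame(hits))
  if (!all(c("orf", "reference", "taxon", "evalue") %in% names(hits)))
    abort("`hits` needs columns `orf`, `reference`, `taxon`, `evalue`.")
  if (any(hits$evalue < 0)) abort("Negative e-values are invalid.")
  best <- hits |>
    dplyr::group_by(.data$orf) |>
    dplyr::arrange(.data$evalue, .data$reference, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  keep <- best$evalue <= evalue_cutoff
  out <- best[keep, c("orf", "reference", "taxon", "evalue")]
  attr(out, "removed") <- best[!keep, c("orf", "reference", "evalue")]
  out
}

#' SCG-normalized marker-gene abundance
#'
#' Sums the coverage of each marker family's ORFs per taxon and sample and
#' divides by the sample's SCG normalizer (median total single-copy
#' core-gene coverage, from [scg_normalizers()]). The result approximates
#' marker copies per genome equivalent and is invariant to sequencing
#' depth.
#'
#' @param marker_coverage A data frame with columns `orf`, `family`,
#'   `taxon`, `sample`, `coverage`.
#' @param scg_normalizers A data frame with columns `sample`, `normalizer`
#'   (> 0); every sample in `marker_coverage` must have one.
#' @return A tibble `family`, `taxon`, `sample`, `abundance`.
#' @export
marker_relative_abundance <- function(marker_coverage, scg_normalizers) {
  stopifnot(is.data.frame(marker_coverage), is.data.frame(scg_normalizers))
  need <- c("orf", "family", "taxon", "sample", "coverage")
  if (!all(need %in% names(marker_coverage)))
    abort(paste("`marker_coverage` is missing column(s):",
                paste(setdiff(need, names(marker_coverage)), collapse = ", ")))
  if (!all(c("sample", "normalizer") %in% names(scg_normalizers)))
    abort("`scg_normalizers` needs columns `sample` and `normalizer`.")
  missing <- setdiff(unique(marker_coverage$sample),
                     scg_normalizers$sample)
  if (length(missing) > 0)
    abort(paste("No SCG normalizer for sample(s):",
                paste(missing, collapse = ", ")))
  if (any(scg_normalizers$normalizer <= 0))
    abort("Normalizers must be positive.")
  marker_coverage |>
    dplyr::group_by(.data$family, .data$taxon, .data$sample) |>
    dplyr::summarise(coverage = sum(.data$coverage), .groups = "drop") |>
    dplyr::left_join(scg_normalizers, by = "sample") |>
    dplyr::mutate(abundance = .data$coverage / .data$normalizer) |>
    dplyr::select("family", "taxon", "sample", "abundance")
}
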