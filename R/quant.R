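#' Normalized spectral abundance factor (NSAF)
#'
#' For each protein i and sample s, NSAF is the length-normalized spectral
#' count divided by the sample total:
#' `NSAF[i,s] = (SpC[i,s]/L[i]) / sum_j (SpC[j,s]/L[j])`,
#' so every sample column sums to one. Percent abundance is 100 times NSAF.
#'
#' @param data A data frame with one row per protein-sample pair and columns
#'   named by the following arguments.
#' @param protein,sample,count,length Column names (strings) holding the
#'   protein id, sample id, spectral count (>= 0) and protein length (> 0).
#' @return A tibble of class `exo_abundance` (`mode` attribute `"nsaf"`)
#'   with columns `protein`, `sample`, `nsaf`, `percent`. Missing
#'   protein-sample pairs are treated as zero counts.
#' @examples
#' d <- tibble::tibble(
#'   protein = c("a", "b"), sample = "s1",
#'   spectral_count = c(4, 2), length = c(200, 100)
#' )
#' nsaf(d) # both proteins 0.5
#' @export
nsaf <- function(data, protein = "protein", sample = "sample",
                 count = "spectral_count", length = "length") {
  stopifnot(is.data.frame(data))
  need <- c(protein, sample, count, length)
  if (!all(need %in% names(data)))
    abort(paste("`data` is missing column(s):",
                paste(setdiff(need, names(data)), collapse = ", ")))
  d <- tibble::tibble(
    protein = data[[protein]], sample = data[[sample]],
    count = data[[count]], length = data[[length]]
  )
  if (any(d$length <= 0)) abort("Protein lengths must be positive.")
  if (any(d$count < 0)) abort("Spectral counts must be non-negative.")
  d <- d |>
    dplyr::group_by(.data$protein, .data$sample) |>
    dplyr::summarise(count = sum(.data$count),
                     length = dplyr::first(.data$length), .groups = "drop")
  totals <- d |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total = sum(.data$count / .data$length),
                     .groups = "drop")
  bad <- totals$sample[totals$total == 0]
  if (length(bad) > 0)
    abort(paste("Sample(s) with all-zero spectral counts:",
                paste(bad, collapse = ", ")))
  out <- d |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::mutate(nsaf = (.data$count / .data$length) / .data$total,
                  percent = 100 * .data$nsaf) |>
    dplyr::select("protein", "sample", "nsaf", "percent") |>
    dplyr::arrange(.data$protein, .data$sample)
  attr(out, "mode") <- "nsaf"
  class(out) <- c("exo_abundance", class(out))
  out
}

#' Median-centred label-free quantification
#'
#' A transparent stand-in for search-engine LFQ values: non-zero intensities
#' are log2-transformed and every sample is shifted so its median equals the
#' global median of all observed values, removing constant loading or
#' injection differences between runs. Zero intensities denote missing
#' observations and stay missing (`NA`); no imputation is performed.
#'
#' @param data A data frame with one row per protein-sample pair.
#' @param protein,sample,intensity Column names holding the protein id,
#'   sample id and raw intensity (>= 0; 0 = missing).
#' @return A tibble of class `exo_abundance` (`mode` attribute `"lfq"`)
#'   with columns `protein`, `sample`, `log2_lfq` (NA where missing).
#' @export
lfq_normalize <- function(data, protein = "protein", sample = "sample",
                          intensity = "intensity") {
  stopifnot(is.data.frame(data))
  need <- c(protein, sample, intensity)
  if (!all(need %in% names(data)))
    abort(paste("`data` is missing column(s):",
                paste(setdiff(need, names(data)), collapse = ", ")))
  d <- tibble::tibble(
    protein = data[[protein]], sample = data[[sample]],
    intensity = data[[intensity]]
  )
  if (any(d$intensity < 0)) abort("Intensities must be non-negative.")
  d <- d |>
    dplyr::group_by(.data$protein, .data$sample) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  d$log2 <- ifelse(d$intensity > 0, log2(d$intensity), NA_real_)
  obs <- d |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(med = median(.data$log2, na.rm = TRUE),
                     n_obs = sum(!is.na(.data$log2)), .groups = "drop")
  bad <- obs$sample[obs$n_obs == 0]
  if (length(bad) > 0)
    abort(paste("Sample(s) with no observed intensities:",
                paste(bad, collapse = ", ")))
  global <- median(d$log2, na.rm = TRUE)
  out <- d |>
    dplyr::left_join(obs, by = "sample") |>
    dplyr::mutate(log2_lfq = .data$log2 - .data$med + global) |>
    dplyr::select("protein", "sample", "log2_lfq") |>
    dplyr::arrange(.data$protein, .data$sample)
  attr(out, "mode") <- "lfq"
  class(out) <- c("exo_abundance", class(out))
  out
}

#' Per-protein Z-score profiles across conditions
#'
#' Averages replicate values per condition, then standardizes each protein's
#' vector of condition means to mean 0 and standard deviation 1 — the
#' profile used for abundance heat maps across growth conditions. Proteins
#' with zero variance across conditions get an all-zero row.
#'
#' @param data A data frame with columns `protein`, `sample` and a value
#'   column (default `percent`).
#' @param conditions A data frame mapping `sample` to `condition`.
#' @param value Name of the value column.
#' @return A tibble `protein`, `condition`, `mean_value`, `z`.
#' @export
zscore_profiles <- function(data, conditions, value = "percent") {
  stopifnot(is.data.frame(data), is.data.frame(conditions))
  if (!all(c("sample", "condition") %in% names(conditions)))
    abort("`conditions` needs columns `sample` and `condition`.")
  if (!value %in% names(data))
    abort(paste0("`data` has no column `", value, "`."))
  d <- data |>
    dplyr::left_join(conditions, by = "sample") |>
    dplyr::group_by(.data$protein, .data$condition) |>
    dplyr::summarise(mean_value = mean(.data[[value]], na.rm = TRUE),
                     .groups = "drop_last") |>
    dplyr::mutate(
      z = if (dplyr::n() < 2 || sd(.data$mean_value) == 0)
        0 else (.data$mean_value - mean(.data$mean_value)) /
          sd(.data$mean_value)
    ) |>
    dplyr::ungroup()
  d
}

#' Roll protein evidence up to taxonomic or functional categories
#'
#' Two complementary summaries of annotated protein abundance: `count` mode
#' reports the number of distinct detected proteins per category (a
#' diversity-style measure, independent of quantitative values), and
#' `abundance` mode sums values per category and sample, conserving each
#' sample's total. Proteins lacking an annotation are routed to an
#' `"unannotated"` category with a warning.
#'
#' @param data A data frame with columns `protein`, `sample` and a value
#'   column.
#' @param annotations A data frame mapping `protein` to the chosen key
#'   column.
#' @param by Name of the annotation column to roll up by (e.g. `"taxon"`,
#'   `"cog_category"`).
#' @param mode `"count"` or `"abundance"`.
#' @param value Name of the value column used in abundance mode.
#' @return A tibble `category`, `sample` (abundance mode), and `n_proteins`
#'   or `total`.
#' @export
rollup <- function(data, annotations, by, mode = c("abundance", "count"),
                   value = "nsaf") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), is.data.frame(annotations))
  if (!by %in% names(annotations))
    abort(paste0("`annotations` has no column `", by, "`."))
  ann <- tibble::tibble(
    protein = annotations$protein, category = annotations[[by]]
  )
  d <- dplyr::left_join(data, ann, by = "protein")
  if (anyNA(d$category)) {
    warn(sprintf("%d protein(s) without a `%s` annotation; using 'unannotated'.",
                 dplyr::n_distinct(d$protein[is.na(d$category)]), by))
    d$category[is.na(d$category)] <- "unannotated"
  }
  if (mode == "count") {
    d |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n_proteins = dplyr::n_distinct(.data$protein),
                       .groups = "drop")
  } else {
    if (!value %in% names(d))
      abort(paste0("`data` has no column `", value, "`."))
    d |>
      dplyr::group_by(.data$category, .data$sample) |>
      dplyr::summarise(total = sum(.data[[value]], na.rm = TRUE),
                       .groups = "drop")
  }
}

#' @export
print.exo_abundance <- function(x, ...) {
  cat(sprintf("<exo_abundance> mode = %s\n", attr(x, "mode")))
  NextMethod()
}
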