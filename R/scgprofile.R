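# length-normalized k-mer frequency vector of an amino-acid sequence
kmer_profile <- function(seq, k = 4) {
  n <- nchar(seq)
  if (n < k) abort("Sequence shorter than k.")
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  tab <- table(kmers)
  v <- as.numeric(tab) / sum(tab)
  names(v) <- names(tab)
  v
}

kmer_cosine_distance <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) == 0) return(1)
  dot <- sum(a[common] * b[common])
  1 - dot / sqrt(sum(a^2) * sum(b^2))
}

#' Assign cluster representatives to their nearest reference
#'
#' Stands in for per-family phylogenetic placement: each representative
#' sequence is compared to every reference by cosine distance between
#' length-normalized k-mer frequency vectors, and assigned to the reference
#' at minimal distance (exact ties go to the lexicographically smallest
#' reference id). The assigned reference's lineage annotations are carried
#' through. The distance is pluggable via `distance_fun(seq_a, seq_b)`.
#'
#' @param representatives A data frame with columns `id` and `sequence`.
#' @param references A data frame with columns `reference` and `sequence`;
#'   any further columns (taxon, lineage) are joined onto the result.
#' @param k k-mer length (default 4).
#' @param distance_fun Optional replacement distance function.
#' @return A tibble: `id`, `reference`, `distance`, plus the reference
#'   annotation columns.
#' @export
assign_nearest_reference <- function(representatives, references, k = 4,
                                     distance_fun = NULL) {
  stopifnot(is.data.frame(representatives), is.data.frame(references))
  if (nrow(references) == 0) abort("Reference set is empty.")
  if (!all(c("id", "sequence") %in% names(representatives)))
    abort("`representatives` needs columns `id` and `sequence`.")
  if (!all(c("reference", "sequence") %in% names(references)))
    abort("`references` needs columns `reference` and `sequence`.")

  refs <- dplyr::arrange(references, .data$reference)
  if (is.null(distance_fun)) {
    ref_prof <- lapply(refs$sequence, kmer_profile, k = k)
    dists <- vapply(representatives$sequence, function(s) {
      p <- kmer_profile(s, k = k)
      vapply(ref_prof, function(q) kmer_cosine_distance(p, q), double(1))
    }, double(nrow(refs)))
  } else {
    dists <- vapply(representatives$sequence, function(s) {
      vapply(refs$sequence, function(q) distance_fun(s, q), double(1))
    }, double(nrow(refs)))
  }
  dists <- matrix(dists, nrow = nrow(refs))
  best <- apply(dists, 2, which.min) # refs sorted, so ties go to smallest id
  out <- tibble::tibble(
    id = representatives$id,
    reference = refs$reference[best],
    distance = dists[cbind(best, seq_len(ncol(dists)))]
  )
  dplyr::left_join(out, dplyr::select(refs, -"sequence"), by = "reference")
}

#' Build an SCG catalog from a synthetic metagenome
#'
#' Pipeline glue reproducing the profiling contract: single-copy core-gene
#' ORFs are clustered per family with [greedy_cluster()] (default identity
#' 0.95), each cluster representative is assigned to its nearest reference
#' with [assign_nearest_reference()], and every member inherits its
#' representative's lineage.
#'
#' @param metagenome A `synthetic_metagenome`.
#' @param identity_threshold Clustering identity (default 0.95).
#' @param min_short_coverage Aligned-coverage rule (default 0.8).
#' @param k k-mer length for reference assignment.
#' @return A catalog tibble: `orf`, `family`, `cluster`, `taxon` (assigned),
#'   `lineage`.
#' @export
build_scg_catalog <- function(metagenome, identity_threshold = 0.95,
                              min_short_coverage = 0.8, k = 4) {
  stopifnot(inherits(metagenome, "synthetic_metagenome"))
  fams <- scg_family_names()
  orfs <- metagenome$orfs[metagenome$orfs$family %in% fams, ]
  refs <- metagenome$references
  purrr::map_dfr(fams, function(f) {
    fo <- orfs[orfs$family == f, ]
    fr <- refs[refs$family == f, ]
    cl <- greedy_cluster(
      dplyr::select(fo, id = "orf", "sequence"),
      identity_threshold = identity_threshold,
      min_short_coverage = min_short_coverage
    )
    reps <- tibble::tibble(
      id = unique(cl$representative),
      sequence = fo$sequence[match(unique(cl$representative), fo$orf)]
    )
    asg <- assign_nearest_reference(
      reps, dplyr::select(fr, "reference", "sequence", "taxon", "lineage"),
      k = k
    )
    tibble::tibble(
      orf = cl$member,
      family = f,
      cluster = paste0(f, "_c", cl$cluster),
      taxon = asg$taxon[match(cl$representative, asg$id)],
      lineage = asg$lineage[match(cl$representative, asg$id)]
    )
  })
}

#' Taxonomic profile from single-copy core-gene coverage
#'
#' Sums ORF coverage within each (taxon, SCG family, sample) cell at the
#' chosen rank, then aggregates the per-family sums for a taxon by taking
#' their median — the median makes the estimate robust to a single family
#' inflated by repeats or mis-mapping. By default the median runs over the
#' families actually detected for the taxon (coverage > 0); set
#' `include_zero_families = TRUE` to take it over all families, counting
#' undetected ones as zero. Taxa with no covered SCG are omitted.
#'
#' @param coverage An ORF-by-sample matrix or long data frame with columns
#'   `orf`, `sample`, `coverage`; must cover every catalog ORF.
#' @param catalog A data frame with columns `orf`, `family`, `lineage`
#'   (7-rank, `;`-separated), e.g. from [build_scg_catalog()].
#' @param rank One of domain, phylum, class, order, family, genus, species.
#' @param include_zero_families Include undetected families in the median.
#' @return A tibble of class `taxon_profile` (`taxon`, `sample`,
#'   `abundance`), carrying per-family sums and per-sample family totals as
#'   attributes for [normalize_profile()].
#' @export
scg_taxon_profile <- function(coverage, catalog, rank = "order",
                              include_zero_families = FALSE) {
  if (!rank %in% LINEAGE_RANKS)
    abort(paste0("Unknown rank `", rank, "`; use one of: ",
                 paste(LINEAGE_RANKS, collapse = ", "), "."))
  if (is.matrix(coverage)) {
    coverage <- tibble::tibble(
      orf = rep(rownames(coverage), ncol(coverage)),
      sample = rep(colnames(coverage), each = nrow(coverage)),
      coverage = as.vector(coverage)
    )
  }
  stopifnot(is.data.frame(coverage), is.data.frame(catalog))
  if (!all(c("orf", "sample", "coverage") %in% names(coverage)))
    abort("`coverage` needs columns `orf`, `sample`, `coverage`.")
  if (!all(c("orf", "family", "lineage") %in% names(catalog)))
    abort("`catalog` needs columns `orf`, `family`, `lineage`.")
  missing_orfs <- setdiff(catalog$orf, coverage$orf)
  if (length(missing_orfs) > 0)
    abort(paste("Coverage is missing", length(missing_orfs),
                "catalog ORF(s)."))
  if (any(coverage$coverage < 0)) abort("Coverage must be non-negative.")

  depth_i <- match(rank, LINEAGE_RANKS)
  cat2 <- catalog
  cat2$taxon_at_rank <- vapply(
    strsplit(cat2$lineage, ";", fixed = TRUE),
    function(x) paste(x[seq_len(depth_i)], collapse = ";"), character(1)
  )
  d <- dplyr::inner_join(coverage, cat2, by = "orf")

  family_sums <- d |>
    dplyr::group_by(taxon = .data$taxon_at_rank, .data$family,
                    .data$sample) |>
    dplyr::summarise(coverage = sum(.data$coverage), .groups = "drop")

  n_families <- dplyr::n_distinct(catalog$family)
  agg <- family_sums |>
    dplyr::group_by(.data$taxon, .data$sample) |>
    dplyr::summarise(
      abundance = {
        v <- .data$coverage[.data$coverage > 0]
        if (include_zero_families)
          v <- c(v, rep(0, n_families - length(v)))
        if (length(v) == 0) NA_real_ else median(v)
      },
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$abundance), .data$abundance > 0)

  # per-sample totals of each family across all taxa (for normalization)
  family_totals <- d |>
    dplyr::group_by(.data$family, .data$sample) |>
    dplyr::summarise(total = sum(.data$coverage), .groups = "drop") |>
    tidyr::complete(family = unique(catalog$family),
                    sample = unique(coverage$sample),
                    fill = list(total = 0))

  structure(
    agg,
    rank = rank, normalized = FALSE,
    family_sums = family_sums, family_totals = family_totals,
    class = c("taxon_profile", class(agg))
  )
}

#' Normalize an SCG profile by the median total family coverage
#'
#' The per-sample normalizer `N_s` is the median, over the SCG families, of
#' each family's total coverage in the sample (all taxa summed). Dividing
#' the per-taxon medians by `N_s` yields relative abundances that are
#' invariant to sequencing depth and to genome size. Samples with `N_s = 0`
#' are flagged with a warning and excluded from the relative output.
#'
#' @param profile An unnormalized `taxon_profile`.
#' @return A `taxon_profile` with relative `abundance`; the per-sample
#'   normalizers are available via [scg_normalizers()].
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  if (isTRUE(attr(profile, "normalized")))
    abort("Profile is already normalized.")
  ft <- attr(profile, "family_totals")
  normalizers <- ft |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(normalizer = median(.data$total), .groups = "drop")
  bad <- normalizers$sample[normalizers$normalizer == 0]
  if (length(bad) > 0)
    warn(paste("Excluding sample(s) with zero SCG coverage:",
               paste(bad, collapse = ", ")))
  out <- profile |>
    dplyr::left_join(normalizers, by = "sample") |>
    dplyr::filter(.data$normalizer > 0) |>
    dplyr::mutate(abundance = .data$abundance / .data$normalizer) |>
    dplyr::select("taxon", "sample", "abundance")
  structure(
    out,
    rank = attr(profile, "rank"), normalized = TRUE,
    family_sums = attr(profile, "family_sums"),
    family_totals = ft, normalizers = normalizers,
    class = c("taxon_profile", class(out))
  )
}

#' Per-sample SCG normalizers of a normalized profile
#'
#' @param profile A normalized `taxon_profile`.
#' @return A tibble `sample`, `normalizer` (median total SCG coverage).
#' @export
scg_normalizers <- function(profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  n <- attr(profile, "normalizers")
  if (is.null(n)) {
    ft <- attr(profile, "family_totals")
    n <- ft |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(normalizer = median(.data$total), .groups = "drop")
  }
  n
}

#' Stacked-bar plot of a taxon profile
#'
#' @param object A `taxon_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.taxon_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$taxon_label <- vapply(strsplit(d$taxon, ";", fixed = TRUE),
                          function(x) x[length(x)], character(1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$abundance,
                                  fill = .data$taxon_label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, fill = attr(object, "rank"),
                  y = if (isTRUE(attr(object, "normalized")))
                    "relative abundance" else "median SCG coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
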