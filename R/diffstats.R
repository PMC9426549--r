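#' Per-protein compartment enrichment
#'
#' Welch two-sample tests on log2-scale protein abundances between
#' rhizosphere and bulk samples, Benjamini-Hochberg correction across tested
#' proteins, and enrichment calls under asymmetric fold-change rules: a
#' protein is called rhizosphere-enriched when q < `alpha` and its linear
#' fold change (rhizosphere/bulk) exceeds `fc_rhizo` (default 2), and
#' bulk-enriched when q < `alpha` and the inverse fold change exceeds
#' `fc_bulk` (default 1.5). Proteins observed fewer than `min_obs` times in
#' either compartment are excluded from testing and reported as
#' `not_tested`; missing values are never imputed.
#'
#' @param abundance An `exo_abundance` tibble (LFQ mode preferred) or any
#'   data frame with `protein`, `sample` and a value column.
#' @param metadata A data frame mapping `sample` to `compartment`
#'   (`"bulk"` / `"rhizosphere"`); both compartments must have >= 2 samples.
#' @param value Value column; defaults to `log2_lfq` when present, else
#'   `nsaf`.
#' @param log_scale Is the value column already on log2 scale? Defaults to
#'   `TRUE` for `log2_lfq`, otherwise `FALSE` (values are log2-transformed,
#'   zeros treated as missing).
#' @param fc_rhizo,fc_bulk Linear fold-change thresholds for the two calls.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_obs Minimum observed values per compartment (default 2).
#' @return A tibble of class `exo_enrichment`: `protein`, `n_bulk`,
#'   `n_rhizo`, `log2_fc`, `fold_change`, `statistic`, `df`, `p.value`,
#'   `q.value`, `enriched_in`.
#' @export
differential_enrichment <- function(abundance, metadata, value = NULL,
                                    log_scale = NULL, fc_rhizo = 2,
                                    fc_bulk = 1.5, alpha = 0.05,
                                    min_obs = 2) {
  stopifnot(is.data.frame(abundance), is.data.frame(metadata))
  if (!all(c("sample", "compartment") %in% names(metadata)))
    abort("`metadata` needs columns `sample` and `compartment`.")
  value <- value %||%
    (if ("log2_lfq" %in% names(abundance)) "log2_lfq" else "nsaf")
  if (!value %in% names(abundance))
    abort(paste0("`abundance` has no column `", value, "`."))
  log_scale <- log_scale %||% (value == "log2_lfq")

  comps <- unique(metadata$compartment)
  if (!all(c("bulk", "rhizosphere") %in% comps))
    abort("`metadata` must contain both 'bulk' and 'rhizosphere' samples.")

  x <- abundance |>
    dplyr::select("protein", "sample", value = dplyr::all_of(value)) |>
    dplyr::left_join(metadata, by = "sample")
  if (!log_scale) x$value <- ifelse(x$value > 0, log2(x$value), NA_real_)

  wide <- tidyr::pivot_wider(x, id_cols = "protein",
                             names_from = "sample", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$protein
  bulk_s <- metadata$sample[metadata$compartment == "bulk"]
  rhiz_s <- metadata$sample[metadata$compartment == "rhizosphere"]
  if (length(bulk_s) < 2 || length(rhiz_s) < 2)
    abort("Need at least 2 samples per compartment.")
  mb <- m[, intersect(colnames(m), bulk_s), drop = FALSE]
  mr <- m[, intersect(colnames(m), rhiz_s), drop = FALSE]

  row_stats <- function(mm) {
    n <- rowSums(!is.na(mm))
    mu <- rowMeans(mm, na.rm = TRUE)
    v <- rowSums((mm - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mu = mu, v = v)
  }
  b <- row_stats(mb); r <- row_stats(mr)
  tested <- b$n >= min_obs & r$n >= min_obs

  diff <- r$mu - b$mu
  se2 <- r$v / r$n + b$v / b$n
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((r$v / r$n)^2 / (r$n - 1) + (b$v / b$n)^2 / (b$n - 1))
  p <- 2 * pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  zero_se <- is.finite(diff) & se2 == 0
  p[zero_se & diff == 0] <- 1
  tt[zero_se & diff == 0] <- 0
  p[zero_se & diff != 0] <- 0

  out <- tibble::tibble(
    protein = rownames(m),
    n_bulk = unname(b$n), n_rhizo = unname(r$n),
    log2_fc = unname(diff), fold_change = unname(2^diff),
    statistic = unname(tt), df = unname(df), p.value = unname(p)
  )
  out$q.value <- NA_real_
  out$q.value[tested] <- p.adjust(out$p.value[tested], method = "BH")
  out$enriched_in <- dplyr::case_when(
    !tested ~ "not_tested",
    out$q.value < alpha & out$fold_change > fc_rhizo ~ "rhizosphere",
    out$q.value < alpha & 1 / out$fold_change > fc_bulk ~ "bulk",
    .default = "none"
  )
  out[!tested, c("log2_fc", "fold_change", "statistic", "df", "p.value")] <-
    NA_real_
  attr(out, "params") <- list(fc_rhizo = fc_rhizo, fc_bulk = fc_bulk,
                              alpha = alpha, min_obs = min_obs)
  class(out) <- c("exo_enrichment", class(out))
  out
}

#' @export
tidy.exo_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.exo_enrichment <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_tested = sum(x$enriched_in != "not_tested"),
    n_rhizosphere = sum(x$enriched_in == "rhizosphere"),
    n_bulk = sum(x$enriched_in == "bulk")
  )
}

#' Volcano plot of compartment enrichment
#'
#' @param object An `exo_enrichment` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exo_enrichment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$enriched_in != "not_tested", ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2_fc, y = -log10(pmax(.data$q.value, 1e-300)),
    colour = .data$enriched_in
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      bulk = "#8c6d31", rhizosphere = "#31a354", none = "grey70"
    )) +
    ggplot2::labs(x = "log2 fold change (rhizosphere / bulk)",
                  y = "-log10 q-value", colour = "enriched in") +
    ggplot2::theme_minimal()
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` over shared features,
#' computed with [vegan::vegdist()]. Values lie in \[0, 1\]; identical
#' samples score 0 and samples with disjoint feature support score 1.
#'
#' @param data Either a numeric sample-by-feature matrix (samples as rows)
#'   or a long data frame with columns `sample`, a feature id column and a
#'   value column.
#' @param feature,value Column names used when `data` is a long data frame.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(data, feature = "protein", value = "nsaf") {
  if (is.data.frame(data) && !is.matrix(data)) {
    if (!all(c("sample", feature, value) %in% names(data)))
      abort(paste0("`data` needs columns sample, ", feature, ", ", value, "."))
    wide <- tidyr::pivot_wider(
      data, id_cols = "sample", names_from = dplyr::all_of(feature),
      values_from = dplyr::all_of(value), values_fill = 0,
      values_fn = sum
    )
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$sample
  } else {
    m <- as.matrix(data)
  }
  m[is.na(m)] <- 0
  if (any(m < 0)) abort("Abundances must be non-negative.")
  tot <- rowSums(m)
  if (any(tot == 0))
    abort(paste("All-zero sample(s):",
                paste(rownames(m)[tot == 0], collapse = ", ")))
  vegan::vegdist(m, method = "bray")
}

# all distinct permutations of a label multiset, one per row
multiset_perms <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n <= 1) return(matrix(x, nrow = 1))
  ux <- unique(x)
  do.call(rbind, lapply(ux, function(u) {
    rest <- x[-match(u, x)]
    sub <- multiset_perms(rest)
    cbind(matrix(u, nrow(sub), 1), sub, deparse.level = 0)
  }))
}

check_grouping <- function(d, grouping, min_group = 2) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (length(grouping) != n)
    abort("`grouping` length must match the number of samples.")
  sizes <- table(grouping)
  if (length(sizes) < 2) abort("Need at least 2 groups.")
  if (any(sizes < min_group))
    abort(paste("Every group needs at least", min_group, "samples."))
  list(m = m, n = n, grouping = as.character(grouping))
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based one-way test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All `n(n-1)/2` distances are ranked (ties
#' get average ranks) and `R = (rB - rW) / (n(n-1)/4)`, where `rB` and `rW`
#' are the mean ranks of between- and within-group pairs. R lies in
#' \[-1, 1\]; 1 means every between-group distance exceeds every
#' within-group distance. Significance comes from permuting group labels;
#' the reported p-value includes the observed statistic
#' (`p = (1 + #[R* >= R]) / (1 + n_perm)`), or is exact when
#' `exhaustive = TRUE` (all distinct label permutations are enumerated).
#'
#' @param d A `dist` object or square distance matrix.
#' @param grouping Group label per sample; >= 2 groups of >= 2 samples.
#' @param n_perm Number of sampled permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @param exhaustive Enumerate all distinct label permutations instead of
#'   sampling (feasible for small n).
#' @return An object of class `exo_anosim` with elements `statistic` (R),
#'   `p.value`, `n_perm`, `exhaustive`, `mean_rank_between`,
#'   `mean_rank_within`, `perm_stats`.
#' @export
anosim <- function(d, grouping, n_perm = 999, seed = NULL,
                   exhaustive = FALSE) {
  g <- check_grouping(d, grouping)
  m <- g$m; n <- g$n; grouping <- g$grouping
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(as.dist(m))
  rk <- rk + t(rk)
  denom <- n * (n - 1) / 4

  stat_fun <- function(lab) {
    between <- outer(lab, lab, `!=`)
    lt <- lower.tri(between)
    rB <- mean(rk[lt][between[lt]])
    rW <- mean(rk[lt][!between[lt]])
    (rB - rW) / denom
  }
  obs <- stat_fun(grouping)
  between <- outer(grouping, grouping, `!=`)
  lt <- lower.tri(between)

  if (exhaustive) {
    perms <- multiset_perms(grouping)
    perm_stats <- apply(perms, 1, stat_fun)
    p <- mean(perm_stats >= obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_fun(sample(grouping)),
             double(1))
    })
    p <- (1 + sum(perm_stats >= obs - 1e-12)) / (1 + n_perm)
  }
  structure(
    list(statistic = obs, p.value = p, n_perm = n_perm,
         exhaustive = exhaustive,
         mean_rank_between = mean(rk[lt][between[lt]]),
         mean_rank_within = mean(rk[lt][!between[lt]]),
         perm_stats = perm_stats),
    class = "exo_anosim"
  )
}

#' PERMANOVA (Adonis-style) one-way test on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components:
#' `SS_T = sum_{i<j} d_ij^2 / N`, `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_A = SS_T - SS_W`, with `pseudo-F = (SS_A/(a-1)) / (SS_W/(N-a))` and
#' `R2 = SS_A / SS_T`. Group labels are permuted for the p-value using the
#' same conventions as [anosim()]. When `SS_W = 0` (perfect separation with
#' zero within-group distances) the pseudo-F is reported as `Inf`.
#'
#' @inheritParams anosim
#' @return An object of class `exo_permanova` with `statistic` (pseudo-F),
#'   `R2`, `p.value`, `SS_total`, `SS_among`, `SS_within`, `df` (among,
#'   within), `n_perm`, `exhaustive`, `perm_stats`.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  g <- check_grouping(d, grouping)
  m <- g$m; n <- g$n; grouping <- g$grouping
  a <- length(unique(grouping))
  d2 <- m^2
  lt <- lower.tri(d2)
  ss_t <- sum(d2[lt]) / n

  ss_within <- function(lab) {
    sum(vapply(unique(lab), function(u) {
      idx <- which(lab == u)
      if (length(idx) < 2) return(0)
      sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
    }, double(1)))
  }
  stat_fun <- function(lab) {
    ssw <- ss_within(lab)
    ssa <- ss_t - ssw
    if (ssw <= 1e-12) Inf else (ssa / (a - 1)) / (ssw / (n - a))
  }
  obs <- stat_fun(grouping)
  ssw_obs <- ss_within(grouping)

  if (exhaustive) {
    perms <- multiset_perms(grouping)
    perm_stats <- apply(perms, 1, stat_fun)
    p <- mean(perm_stats >= obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_fun(sample(grouping)),
             double(1))
    })
    p <- (1 + sum(perm_stats >= obs - 1e-12)) / (1 + n_perm)
  }
  structure(
    list(statistic = obs, R2 = (ss_t - ssw_obs) / ss_t, p.value = p,
         SS_total = ss_t, SS_among = ss_t - ssw_obs, SS_within = ssw_obs,
         df = c(among = a - 1, within = n - a),
         n_perm = n_perm, exhaustive = exhaustive, perm_stats = perm_stats),
    class = "exo_permanova"
  )
}

#' @export
print.exo_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, P = %.4g (%s permutations)\n",
              x$statistic, x$p.value,
              if (x$exhaustive) "exhaustive" else x$n_perm))
  invisible(x)
}

#' @export
print.exo_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, P = %.4g (%s permutations)\n",
              x$statistic, x$R2, x$p.value,
              if (x$exhaustive) "exhaustive" else x$n_perm))
  invisible(x)
}

#' @export
glance.exo_anosim <- function(x, ...) {
  tibble::tibble(R = x$statistic, p.value = x$p.value, n_perm = x$n_perm)
}

#' @export
glance.exo_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$statistic, R2 = x$R2, p.value = x$p.value,
                 n_perm = x$n_perm)
}

#' @export
tidy.exo_anosim <- function(x, ...) glance(x)

#' @export
tidy.exo_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("group", "residual", "total"),
    df = c(x$df[["among"]], x$df[["within"]], sum(x$df)),
    SS = c(x$SS_among, x$SS_within, x$SS_total),
    pseudo_F = c(x$statistic, NA, NA),
    R2 = c(x$R2, NA, NA),
    p.value = c(x$p.value, NA, NA)
  )
}
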