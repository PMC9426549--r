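make_dist <- function(m) bray_curtis(m)

test_that("Bray-Curtis matches the formula and its boundary cases", {
  x <- rbind(a = c(2, 1), b = c(1, 1))
  d <- bray_curtis(x)
  expect_equal(as.vector(d), 0.2) # (|1| + |0|) / 5

  same <- rbind(a = c(3, 2, 5), b = c(3, 2, 5))
  expect_equal(as.vector(bray_curtis(same)), 0)

  disjoint <- rbind(a = c(1, 2, 0, 0), b = c(0, 0, 3, 4))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)

  # symmetric, zero diagonal, bounded, invariant to joint rescaling
  set.seed(3)
  m <- matrix(rpois(50, 5), 5, 10,
              dimnames = list(paste0("s", 1:5), NULL))
  dm <- as.matrix(bray_curtis(m))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 5))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(as.matrix(bray_curtis(m * 10)), dm)

  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "All-zero")

  # long-format input agrees with the matrix route
  long <- tibble::tibble(
    sample = rep(rownames(m), 10),
    protein = rep(sprintf("f%02d", 1:10), each = 5),
    nsaf = as.vector(m)
  )
  expect_equal(as.matrix(bray_curtis(long))[rownames(m), rownames(m)], dm)
})

test_that("ANOSIM R hits its extremes and matches vegan", {
  # perfect separation: every between-distance exceeds every within
  m <- rbind(g1a = c(10, 0, 0), g1b = c(11, 1, 0),
             g2a = c(0, 10, 9), g2b = c(0, 11, 10))
  d <- bray_curtis(m)
  g <- c("g1", "g1", "g2", "g2")
  an <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(an$statistic, 1)

  set.seed(14)
  m2 <- matrix(rpois(8 * 15, 8), 8, 15,
               dimnames = list(paste0("s", 1:8), NULL))
  d2 <- bray_curtis(m2)
  g2 <- rep(c("a", "b"), each = 4)
  mine <- anosim(d2, g2, n_perm = 199, seed = 2)
  ref <- vegan::anosim(d2, g2, permutations = 199)
  expect_equal(mine$statistic, unname(ref$statistic))
  # R is rank-based: any strictly monotone transform leaves it unchanged
  mono <- anosim(stats::as.dist(as.matrix(d2)^3), g2, n_perm = 9, seed = 2)
  expect_equal(mono$statistic, mine$statistic)

  expect_error(anosim(d2, rep(c("a", "b", "c"), c(1, 3, 4))), "at least 2")
})

test_that("PERMANOVA sums of squares match the closed form and vegan", {
  # all six pairwise distances equal c: SS_T = 2.5 c^2, SS_W = 2 c^2
  cc <- 0.4
  m <- matrix(cc, 4, 4)
  diag(m) <- 0
  g <- c("a", "a", "b", "b")
  pm <- permanova(m, g, n_perm = 199, seed = 3)
  expect_equal(pm$SS_total, 6 * cc^2 / 4)
  expect_equal(pm$SS_within, 2 * cc^2 / 2)
  expect_equal(pm$R2, 1 - (cc^2) / (6 * cc^2 / 4))
  expect_true(is.finite(pm$statistic))
  expect_gt(pm$p.value, 0.5)

  set.seed(44)
  m2 <- matrix(rpois(10 * 12, 7), 10, 12,
               dimnames = list(paste0("s", 1:10), NULL))
  d2 <- bray_curtis(m2)
  g2 <- rep(c("a", "b"), each = 5)
  mine <- permanova(d2, g2, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(d2 ~ g2, permutations = 199)
  expect_equal(mine$statistic, ref$F[1])
  expect_equal(mine$R2, ref$R2[1])

  # perfect separation with zero within-distance: R2 = 1, F infinite
  sep <- matrix(1, 4, 4)
  sep[1:2, 1:2] <- 0
  sep[3:4, 3:4] <- 0
  ps <- permanova(sep, g, n_perm = 99, seed = 1)
  expect_equal(ps$R2, 1)
  expect_equal(ps$statistic, Inf)
})

test_that("exhaustive permutation p-values agree with dense sampling", {
  set.seed(55)
  m <- matrix(rpois(7 * 10, 6), 7, 10,
              dimnames = list(paste0("s", 1:7), NULL))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), c(4, 3))
  for (fn in list(anosim, permanova)) {
    ex <- fn(d, g, exhaustive = TRUE)
    expect_equal(ex$n_perm, choose(7, 3))
    smp <- fn(d, g, n_perm = 4999, seed = 9)
    # sampled estimate within binomial error of the exact p
    se <- sqrt(ex$p.value * (1 - ex$p.value) / 4999)
    expect_lt(abs(smp$p.value - ex$p.value), 4 * se + 1e-3)
  }
})

test_that("permutation p-values are valid and reproducible under a seed", {
  set.seed(66)
  m <- matrix(rpois(6 * 8, 5), 6, 8,
              dimnames = list(paste0("s", 1:6), NULL))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 3)
  a1 <- anosim(d, g, n_perm = 99, seed = 7)
  a2 <- anosim(d, g, n_perm = 99, seed = 7)
  expect_identical(a1$p.value, a2$p.value)
  expect_gte(a1$p.value, 1 / 100)
  expect_lte(a1$p.value, 1)
})

test_that("differential enrichment labels follow the fold-change rules", {
  set.seed(91)
  meta <- tibble::tibble(
    sample = c(sprintf("b%d", 1:4), sprintf("r%d", 1:4)),
    compartment = rep(c("bulk", "rhizosphere"), each = 4)
  )
  n <- 200
  ab <- tidyr::expand_grid(protein = sprintf("p%03d", 1:n),
                           sample = meta$sample)
  rhizo <- ab$sample %in% meta$sample[meta$compartment == "rhizosphere"]
  base <- rep(rnorm(n, 20, 2), each = 8)
  shift <- ifelse(ab$protein %in% sprintf("p%03d", 1:20) & rhizo, 3,
                  ifelse(ab$protein %in% sprintf("p%03d", 21:30) & !rhizo,
                         2, 0))
  ab$log2_lfq <- base + shift + rnorm(nrow(ab), 0, 0.3)
  res <- differential_enrichment(ab, meta)
  expect_s3_class(res, "exo_enrichment")
  up <- res$protein[res$enriched_in == "rhizosphere"]
  down <- res$protein[res$enriched_in == "bulk"]
  expect_gt(mean(sprintf("p%03d", 1:20) %in% up), 0.9)
  expect_gt(mean(sprintf("p%03d", 21:30) %in% down), 0.9)
  expect_false(any(res$enriched_in[res$q.value > 0.05] %in%
                     c("bulk", "rhizosphere"), na.rm = TRUE))

  # identical values in both groups: FC 1, label none
  flat <- tidyr::expand_grid(protein = "p", sample = meta$sample)
  flat$log2_lfq <- 5
  fr <- differential_enrichment(flat, meta)
  expect_equal(fr$fold_change, 1)
  expect_equal(fr$enriched_in, "none")

  # proteins below min_obs are excluded but reported
  sparse <- tidyr::expand_grid(protein = c("q1", "q2"),
                               sample = meta$sample)
  sparse$log2_lfq <- rnorm(nrow(sparse), 10)
  sparse$log2_lfq[sparse$protein == "q1" &
                    sparse$sample %in% c("b1", "b2", "b3")] <- NA
  sr <- differential_enrichment(sparse, meta)
  expect_equal(sr$enriched_in[sr$protein == "q1"], "not_tested")
  expect_true(is.na(sr$p.value[sr$protein == "q1"]))

  expect_error(
    differential_enrichment(ab, meta[meta$compartment == "bulk", ]),
    "rhizosphere"
  )
})

test_that("BH q-values are a valid step-up output", {
  set.seed(101)
  meta <- tibble::tibble(sample = sprintf("s%d", 1:8),
                         compartment = rep(c("bulk", "rhizosphere"),
                                           each = 4))
  ab <- tidyr::expand_grid(protein = sprintf("p%d", 1:100),
                           sample = meta$sample)
  ab$log2_lfq <- rnorm(nrow(ab), 15, 1)
  res <- differential_enrichment(ab, meta)
  tested <- res[res$enriched_in != "not_tested", ]
  expect_equal(tested$q.value, p.adjust(tested$p.value, "BH"))
  expect_true(all(tested$q.value <= 1))
})

test_that("tidiers and plots return the expected shapes", {
  set.seed(5)
  m <- matrix(rpois(6 * 8, 5), 6, 8,
              dimnames = list(paste0("s", 1:6), NULL))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 3)
  gl <- glance(permanova(d, g, n_perm = 99, seed = 1))
  expect_named(gl, c("pseudo_F", "R2", "p.value", "n_perm"))
  td <- tidy(permanova(d, g, n_perm = 99, seed = 1))
  expect_equal(td$term, c("group", "residual", "total"))
  expect_named(glance(anosim(d, g, n_perm = 99, seed = 1)),
               c("R", "p.value", "n_perm"))

  meta <- tibble::tibble(sample = paste0("s", 1:6),
                         compartment = rep(c("bulk", "rhizosphere"),
                                           each = 3))
  ab <- tidyr::expand_grid(protein = sprintf("p%d", 1:10),
                           sample = meta$sample)
  ab$log2_lfq <- rnorm(nrow(ab))
  e <- differential_enrichment(ab, meta)
  expect_s3_class(autoplot(e), "ggplot")
  expect_named(glance(e), c("n_proteins", "n_tested", "n_rhizosphere",
                            "n_bulk"))
})
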