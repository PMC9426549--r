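test_that("NSAF matches the direct formula and normalizes every column", {
  one <- tibble::tibble(protein = "p", sample = "s",
                        spectral_count = 5, length = 100)
  expect_equal(nsaf(one)$nsaf, 1)

  # SpC/L equal for both proteins: both get 0.5
  two <- tibble::tibble(protein = c("a", "b"), sample = "s1",
                        spectral_count = c(4, 2), length = c(200, 100))
  expect_equal(nsaf(two)$nsaf, c(0.5, 0.5))

  set.seed(8)
  d <- tidyr::expand_grid(protein = sprintf("p%02d", 1:30),
                          sample = sprintf("s%d", 1:4))
  d$spectral_count <- rpois(nrow(d), 6)
  d$length <- rep(sample(100:500, 30), each = 4)
  out <- nsaf(d)
  sums <- tapply(out$nsaf, out$sample, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-9)
  # independent recomputation
  direct <- (d$spectral_count / d$length)
  for (s in unique(d$sample)) {
    i <- d$sample == s
    expect_equal(out$nsaf[match(paste(d$protein[i], s),
                                paste(out$protein, out$sample))],
                 direct[i] / sum(direct[i]))
  }
  expect_equal(out$percent, 100 * out$nsaf)

  # scale invariance per sample
  d2 <- d
  d2$spectral_count[d2$sample == "s1"] <-
    d2$spectral_count[d2$sample == "s1"] * 7
  expect_equal(nsaf(d2)$nsaf, out$nsaf)

  bad <- two
  bad$spectral_count <- 0
  expect_error(nsaf(bad), "s1")
})

test_that("LFQ normalization removes constant log-shifts and keeps NAs", {
  set.seed(12)
  base <- rlnorm(40, 10, 1)
  d <- tibble::tibble(
    protein = rep(sprintf("p%02d", 1:40), 2),
    sample = rep(c("s1", "s2"), each = 40),
    intensity = c(base, base * 8)
  )
  out <- lfq_normalize(d)
  w <- tidyr::pivot_wider(out, names_from = sample,
                          values_from = log2_lfq)
  expect_equal(w$s1, w$s2, tolerance = 1e-12)
  expect_equal(median(out$log2_lfq[out$sample == "s1"]),
               median(out$log2_lfq[out$sample == "s2"]))

  # zeros stay missing
  d$intensity[1] <- 0
  out2 <- lfq_normalize(d)
  expect_true(is.na(out2$log2_lfq[out2$protein == "p01" &
                                    out2$sample == "s1"]))

  expect_error(
    lfq_normalize(tibble::tibble(protein = "p", sample = "s",
                                 intensity = 0)),
    "no observed"
  )
})

test_that("known 4-fold spikes survive LFQ normalization", {
  set.seed(77)
  n <- 300
  spiked <- 1:30
  d <- tidyr::expand_grid(protein = sprintf("p%03d", 1:n),
                          sample = sprintf("s%d", 1:6))
  cond2 <- d$sample %in% c("s4", "s5", "s6")
  base <- rep(rlnorm(n, 12, 1), each = 6)
  fc <- ifelse(d$protein %in% sprintf("p%03d", spiked) & cond2, 4, 1)
  d$intensity <- base * fc * rlnorm(nrow(d), 0, 0.2)
  out <- lfq_normalize(d)
  m <- out |>
    dplyr::mutate(cond = ifelse(sample %in% c("s4", "s5", "s6"),
                                "b", "a")) |>
    dplyr::group_by(protein, cond) |>
    dplyr::summarise(v = mean(log2_lfq), .groups = "drop") |>
    tidyr::pivot_wider(names_from = cond, values_from = v)
  est_fc <- 2^(m$b - m$a)[m$protein %in% sprintf("p%03d", spiked)]
  expect_lt(abs(median(est_fc) - 4) / 4, 0.2)
})

test_that("Z-score profiles standardize condition means", {
  cond <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                         condition = c("c1", "c1", "c2", "c2"))
  flat <- tibble::tibble(protein = "p", sample = cond$sample,
                         percent = c(2, 2, 2, 2))
  expect_equal(zscore_profiles(flat, cond)$z, c(0, 0))

  two <- tibble::tibble(protein = "p", sample = cond$sample,
                        percent = c(1, 1, 3, 3))
  z <- zscore_profiles(two, cond)$z
  expect_equal(z, c(-1, 1) / sqrt(2))

  set.seed(4)
  many <- tidyr::expand_grid(protein = sprintf("p%d", 1:20),
                             sample = cond$sample)
  many$percent <- runif(nrow(many))
  zz <- zscore_profiles(many, cond)
  chk <- zz |>
    dplyr::group_by(protein) |>
    dplyr::summarise(m = mean(z), s = sd(z))
  expect_equal(chk$m, rep(0, 20), tolerance = 1e-12)
  expect_equal(chk$s, rep(1, 20), tolerance = 1e-12)
})

test_that("rollup conserves totals and counts distinct proteins", {
  d <- tidyr::expand_grid(protein = sprintf("p%d", 1:6),
                          sample = c("s1", "s2"))
  set.seed(2)
  d$nsaf <- runif(nrow(d))
  ann <- tibble::tibble(protein = sprintf("p%d", 1:6),
                        taxon = rep(c("A", "B"), each = 3))
  ab <- rollup(d, ann, by = "taxon", mode = "abundance")
  per_sample <- tapply(ab$total, ab$sample, sum)
  expect_equal(unname(per_sample),
               unname(tapply(d$nsaf, d$sample, sum)))
  direct <- sum(d$nsaf[d$protein %in% c("p1", "p2", "p3") &
                         d$sample == "s1"])
  expect_equal(ab$total[ab$category == "A" & ab$sample == "s1"], direct)

  cnt <- rollup(d, ann, by = "taxon", mode = "count")
  expect_equal(sort(cnt$n_proteins), c(3L, 3L))
  # counts ignore the values
  d2 <- d
  d2$nsaf <- d2$nsaf * 100
  expect_identical(rollup(d2, ann, by = "taxon", mode = "count"), cnt)

  # unannotated proteins are routed with a warning
  expect_warning(
    r <- rollup(d, ann[1:5, ], by = "taxon", mode = "count"),
    "unannotated"
  )
  expect_true("unannotated" %in% r$category)
})
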