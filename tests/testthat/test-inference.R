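test_that("the paired t and Cohen's d follow their definitions", {
  r <- paired_t(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2L)
  expect_equal(paired_t(c(-2, -1, 0, 1, 2))$t, 0)
  expect_error(paired_t(rep(5, 10)), "variance")
  expect_error(paired_t(1), "2")
  # identity d = t / sqrt(n) against the direct mean/sd computation
  set.seed(801)
  x <- rnorm(24, 0.3)
  expect_equal(cohens_d_from_t(paired_t(x)$t, 24), mean(x) / sd(x))
  expect_equal(cohens_d_from_t(0, 10), 0)
})

test_that("printed effect sizes are recovered from their t statistics", {
  expect_equal(round(cohens_d_from_t(-0.49, 24), 2), -0.10)
  expect_equal(round(cohens_d_from_t(4.88, 24), 2), 1.00)
  expect_equal(round(cohens_d_from_t(0.15, 24), 2), 0.03)
  expect_equal(round(cohens_d_from_t(-1.01, 32), 2), -0.18)
})

test_that("unit-information Bayes factors obey their analytic identities", {
  for (n in c(5, 8, 24, 92)) {
    for (r in c(0.5, 1, 2)) {
      expect_equal(bf01_unit_information(0, n, r), sqrt(1 + n * r^2))
      # strictly decreasing in |t|
      ts <- seq(0, 6, by = 0.5)
      bf <- vapply(ts, bf01_unit_information, numeric(1), n = n, r = r)
      expect_true(all(diff(bf) < 0))
    }
    # increasing in r at t = 0
    rs <- c(0.25, 0.5, 1, 2)
    bf0 <- vapply(rs, function(r) bf01_unit_information(0, n, r), numeric(1))
    expect_true(all(diff(bf0) > 0))
  }
  expect_error(bf01_unit_information(1, 1), "n >= 2")
})

test_that("noncentral-t power behaves like a power function", {
  expect_equal(power_paired_t(0, 24, alpha = 0.2), 0.2, tolerance = 1e-10)
  expect_equal(power_paired_t(0, 10, alpha = 0.05), 0.05, tolerance = 1e-10)
  ds <- seq(0.1, 1.2, by = 0.1)
  pw <- vapply(ds, power_paired_t, numeric(1), n = 24, alpha = 0.2)
  expect_true(all(diff(pw) > 0))
  ns <- c(8, 16, 24, 48, 92)
  pn <- vapply(ns, function(n) power_paired_t(0.3, n, 0.2), numeric(1))
  expect_true(all(diff(pn) > 0))
  expect_gt(power_paired_t(0.5, 18, 0.2, two_sided = FALSE),
            power_paired_t(0.5, 18, 0.2, two_sided = TRUE))
  expect_equal(f_to_t(23.77, -1), -sqrt(23.77))
})

test_that("contrast tables detect shifts and respect the d identity", {
  set.seed(802)
  null_tab <- simulate_trial_table(24L, c("ANOMALOUS", "COORDINATE"),
                                   interaction_ms = 0)
  ct0 <- contrast_table(null_tab)
  expect_lt(abs(ct0$t), 3)
  expect_gt(ct0$bf01_r1, 0)
  shift_tab <- simulate_trial_table(24L, c("ANOMALOUS", "COORDINATE"),
                                    interaction_ms = 200)
  ct1 <- contrast_table(shift_tab)
  expect_lt(ct1$bf01_r1, 0.05)
  expect_gt(ct1$t, 3)
  for (ct in list(ct0, ct1)) {
    expect_equal(ct$d, ct$t / sqrt(ct$n))
    expect_equal(ct$n, 24L)
    expect_equal(ct$bf01_r1,
                 bf01_unit_information(ct$t, ct$n, 1))
  }
  # per-participant effect input path agrees with the trial-table path
  eff <- do.call(rbind, lapply(c("ANOMALOUS", "COORDINATE"), function(cc) {
    te <- typicality_effect(null_tab, cc)
    data.frame(participant = te$effects$participant, condition = cc,
               effect = te$effects$effect)
  }))
  expect_equal(contrast_table(eff)$t, ct0$t)
  expect_error(contrast_table(null_tab, baseline = "REVERSED"), "baseline")
})

test_that("pooling concatenates per-participant differences across studies", {
  set.seed(803)
  studies <- lapply(c(24, 32, 18, 18), function(n)
    cbind(rnorm(n, 300, 150), rnorm(n, 300, 150)))
  pooled <- pool_combined(studies)
  expect_equal(pooled$n, 92L)
  one <- studies[[1L]]
  double <- pool_combined(list(one, one))
  expect_equal(double$n, 48L)
  expect_equal(double$delta_ms, mean(one[, 2L] - one[, 1L]))
  expect_error(pool_combined(studies[1L]), "2 studies")
  # pooled null t stays small in most replications
  hits <- 0L
  for (rep in seq_len(300L)) {
    st <- lapply(c(24, 32, 18, 18), function(n)
      cbind(rnorm(n, 300, 150), rnorm(n, 300, 150)))
    if (abs(pool_combined(st)$t) < 2) hits <- hits + 1L
  }
  expect_gte(hits / 300, 0.9)
})

test_that("standardization and binning keep counts and pool the far tail", {
  set.seed(804)
  z <- rnorm(1e4)
  b <- standardize_and_bin(z)
  expect_equal(sum(b$counts), 1e4)
  sz <- (z - mean(z)) / sd(z)
  expect_lt(abs(mean(sz)), 0.03)
  expect_equal(sd(sz), 1, tolerance = 0.02)
  # a value past the pooling threshold lands in the top bin
  x <- c(rnorm(50), 100)  # extreme z lands at the pool
  bx <- standardize_and_bin(x)
  expect_equal(unname(bx$counts[length(bx$counts)]), 1L)
  expect_equal(as.numeric(names(bx$counts)[length(bx$counts)]), 2.25)
  # hand-binned fixture: effects chosen to give round z-scores
  h <- c(-2, -1, -1, 0, 0, 0, 0, 1, 1, 2)
  bh <- standardize_and_bin(h)
  z_h <- (h - mean(h)) / sd(h)
  expect_equal(sum(b$counts > 0) > 3, TRUE)
  expect_equal(sum(bh$counts), 10L)
  expect_equal(max(bh$counts), 4L)  # the four zeros share one bin
  expect_error(standardize_and_bin(rep(1, 5)), "zero")
})

test_that("binned distributions compare by the standard chi-square", {
  a <- structure(list(counts = c(`0` = 10L, `0.25` = 20L), width = 0.25,
                      pool_at = 2.25, n = 30L),
                 class = "binned_distribution")
  b <- structure(list(counts = c(`0` = 20L, `0.25` = 10L), width = 0.25,
                      pool_at = 2.25, n = 30L),
                 class = "binned_distribution")
  r <- chi_square_binned(a, b)
  expect_equal(r$statistic, 100 / 15, tolerance = 1e-6)
  expect_equal(r$df, 1L)
  same <- chi_square_binned(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # zero-combined bins are dropped before computing df
  a2 <- a; a2$counts <- c(a2$counts, `0.5` = 0L)
  b2 <- b; b2$counts <- c(b2$counts, `0.5` = 0L)
  expect_equal(chi_square_binned(a2, b2)$df, 1L)
  set.seed(805)
  d1 <- standardize_and_bin(rnorm(92))
  d2 <- standardize_and_bin(rnorm(92))
  r2 <- chi_square_binned(d1, d2)
  expect_true(r2$p.value > 0 && r2$p.value <= 1)
  expect_lte(r2$df,
             length(union(names(d1$counts), names(d2$counts))) - 1L)
})
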