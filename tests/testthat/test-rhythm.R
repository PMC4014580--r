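test_that("Buys-Ballot folding assigns slots by index mod period, NA-aware", {
  bb <- fold(c(1, 2, 3, 4, 5, 6), 2)
  expect_equal(bb$column_means, c(3, 4))
  v <- c(NA, 2, 3, 4, 5, 6)
  expect_equal(fold(v, 2)$column_means, c(mean(c(3, 5)), 4))
  expect_equal(fold(rep(7, 10), 5)$column_means, rep(7, 5))
  expect_error(fold(1:6, 4), "period")  # > n/2
  expect_error(fold(1:6, 1), "period")
})

test_that("WR amplitude is the sd of the defined column means", {
  expect_equal(wr_statistic(fold(c(1, 2, 3, 4, 5, 6), 2)), sd(c(3, 4)))
  expect_equal(round(wr_statistic(fold(c(1, 2, 3, 4, 5, 6), 2)), 4), 0.7071)
  expect_equal(wr_statistic(fold(rep(2, 12), 3)), 0)
  expect_equal(wr_statistic(fold(c(1, 2, 3, 4, 5, 6), 2), sd_type = "population"),
               sd(c(3, 4)) * sqrt(1 / 2))
  # all-missing column excluded: only 1 defined mean left -> error
  expect_error(wr_statistic(fold(c(1, NA, 2, NA), 2)), "defined")
})

test_that("a noiseless sinusoid peaks at its own period over non-multiples", {
  tt <- 0:111
  v <- sin(2 * pi * tt / 7 + 0.3)
  amps <- vapply(2:56, function(T) oracle_wr_amplitude(v, T), numeric(1))
  names(amps) <- 2:56
  a7 <- amps["7"]
  non_mult <- setdiff(2:56, seq(7, 56, by = 7))
  expect_true(all(a7 > amps[as.character(non_mult)]))
  # and the package statistic agrees with the direct-fold oracle everywhere
  pkg <- vapply(2:56, function(T) wr_statistic(fold(v, T)), numeric(1))
  expect_equal(pkg, unname(amps))
})

test_that("periodogram scans 2..floor(n/2) and matches fold/wr_statistic per period", {
  s <- generate_series(series_spec(n_slots = 100, n_missing = 7,
                                   periods = list(c(12, 1.5)), noise_sd = 1,
                                   seed = 31))
  pg <- wr_periodogram(s, n_perm = 99, seed = 1)
  expect_equal(pg$period, 2:50)
  byhand <- vapply(pg$period, function(T) wr_statistic(fold(s, T)), numeric(1))
  expect_equal(pg$amplitude, byhand)
  s559 <- generate_series(series_spec(seed = 32))
  pg559 <- wr_periodogram(s559, n_perm = 99, seed = 1)
  expect_equal(max(pg559$period), 279)
  expect_error(wr_periodogram(1:3), "short")
})

test_that("permutation p-values match exhaustive enumeration (complete and gapped)", {
  v <- c(2.1, -0.5, 0.8, 1.9, -1.2, 0.3, 1.1, -0.7)       # n = 8, complete
  pm <- all_perms(8)
  pg <- wr_periodogram(v, n_perm = nrow(pm), permutations = pm)
  for (T in 2:4)
    expect_equal(pg$p_value[pg$period == T], oracle_wr_exact_p(v, T))
  vna <- c(1.4, NA, -0.9, 2.2, 0.5, -1.8, 0.7)            # n = 7, one gap
  pm6 <- all_perms(6)
  pgna <- wr_periodogram(vna, n_perm = nrow(pm6), permutations = pm6)
  for (T in 2:3)
    expect_equal(pgna$p_value[pgna$period == T], oracle_wr_exact_p(vna, T))
})

test_that("amplitude is shift-invariant and scales linearly", {
  s <- generate_series(series_spec(n_slots = 96, n_missing = 5,
                                   periods = list(c(8, 1)), noise_sd = 0.5,
                                   seed = 33))
  a <- wr_periodogram(s, n_perm = 99, seed = 2)$amplitude
  s2 <- hourly_series(s$time, 3 * s$values + 5)
  a2 <- wr_periodogram(s2, n_perm = 99, seed = 2)$amplitude
  expect_equal(a2, 3 * a, tolerance = 1e-12)
})

test_that("per-period type-I error under an IID null is close to alpha", {
  n_seeds <- 100L
  rej <- 0L; tot <- 0L
  for (i in seq_len(n_seeds)) {
    set.seed(40000 + i)
    pg <- wr_periodogram(rnorm(48), n_perm = 99, seed = i)
    rej <- rej + sum(pg$significant)
    tot <- tot + nrow(pg)
  }
  rate <- rej / tot
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
})

test_that("permutations fix the missing pattern and seeds reproduce results", {
  s <- generate_series(series_spec(n_slots = 80, n_missing = 8,
                                   periods = list(c(10, 2)), noise_sd = 1,
                                   seed = 35))
  pg1 <- wr_periodogram(s, n_perm = 199, seed = 7)
  pg2 <- wr_periodogram(s, n_perm = 199, seed = 7)
  expect_identical(pg1, pg2)
  expect_equal(attr(pg1, "n_missing"), 8)
})

test_that("auto detrending triggers on a drifting series and is recorded", {
  sp <- series_spec(n_slots = 120, n_missing = 0, trend_slope = 0.2,
                    periods = list(c(12, 2)), noise_sd = 1, seed = 36)
  pg <- wr_periodogram(generate_series(sp), n_perm = 99, seed = 1,
                       detrend = "auto")
  expect_true(attr(pg, "detrended"))
  pg2 <- wr_periodogram(generate_series(sp), n_perm = 99, seed = 1,
                        detrend = "never")
  expect_false(attr(pg2, "detrended"))
})

test_that("harmonics enumerate integer multiples up to the maximum", {
  expect_equal(harmonics(12, 50), c(12, 24, 36, 48))
  expect_equal(harmonics(279, 279), 279)
  expect_equal(harmonics(7, 30), c(7, 14, 21, 28))
  expect_error(harmonics(1, 10), "t_base")
})

test_that("peak_period picks the strongest significant period inside a band", {
  s <- generate_series(series_spec(n_slots = 240, n_missing = 10,
                                   periods = list(c(12, 3)), noise_sd = 1,
                                   seed = 37))
  pg <- wr_periodogram(s, n_perm = 199, seed = 3)
  expect_equal(peak_period(pg, 2, 20), 12L)
  expect_true(is.na(peak_period(pg, 119, 120)) ||
                pg$significant[pg$period %in% 119:120][1])
})
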