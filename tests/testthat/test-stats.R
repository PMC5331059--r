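test_that("outcome rates follow the chosen denominator convention", {
  outcomes <- c(rep("HIT", 6), rep("MISS", 52), rep("EARLY", 2),
                rep("CORRECT_REJECTION", 30))
  is_catch <- c(rep(FALSE, 60), rep(TRUE, 30))
  tr <- make_trials(outcomes, is_catch)
  r <- compute_rates(tr, "per_type")
  expect_equal(r$hit_rate, 0.10)
  expect_equal(r$fa_rate, 0)
  expect_equal(r$early_rate, 2 / 90)
  expect_identical(r$flags, character(0))

  rt <- compute_rates(tr, "per_total")
  expect_equal(rt$hit_rate, 6 / 90)
  expect_equal(rt$early_rate, 2 / 90)
  expect_identical(rt$denominator_convention, "per_total")

  quiet <- make_trials(c(rep("MISS", 10), rep("CORRECT_REJECTION", 5)),
                       c(rep(FALSE, 10), rep(TRUE, 5)))
  rq <- compute_rates(quiet)
  expect_equal(rq$hit_rate, 0)
  expect_equal(rq$fa_rate, 0)
  expect_equal(rq$early_rate, 0)

  # zero-denominator rates are undefined and flagged
  no_catch <- make_trials(rep("MISS", 5), rep(FALSE, 5))
  rn <- compute_rates(no_catch)
  expect_true(is.na(rn$fa_rate))
  expect_identical(rn$flags, "fa_rate")
  expect_error(compute_rates(no_catch[0, ]), "empty")
})

test_that("the reference four-cage table gives hit/early ratio ~3 and mean d' ~1", {
  ref <- reference_final_sessions()
  expect_identical(nrow(ref), 4L)
  s <- summarize_final_sessions(ref)
  expect_equal(s$hit_early_ratio, mean(c(4.1, 6.4, 5.0, 5.2)) /
                 mean(c(1.8, 3.0, 1.1, 0.9)))
  expect_equal(s$hit_early_ratio, 3.0441, tolerance = 1e-4)
  expect_equal(s$mean_dprime, 1.0425)
})

test_that("d-prime matches the bisection inverse-CDF oracle", {
  expect_equal(compute_dprime(0.5, 0.5), 0)
  # Z(pnorm(1)) - Z(pnorm(-1)) = 2, via the 6-decimal rounded rates
  expect_equal(compute_dprime(0.841345, 0.158655), 2.0, tolerance = 1e-4)
  # the low-rate regime typical of ad libitum training
  expect_equal(compute_dprime(0.041, 0.005), dprime_oracle(0.041, 0.005),
               tolerance = 1e-9)
  expect_equal(compute_dprime(0.041, 0.005), 0.8366, tolerance = 1e-4)

  h <- runif(50, 0.001, 0.999)
  f <- runif(50, 0.001, 0.999)
  expect_equal(compute_dprime(h, f), dprime_oracle(h, f), tolerance = 1e-7)
  # antisymmetry and monotonicity in the hit rate
  expect_equal(compute_dprime(h, f), -compute_dprime(f, h))
  hh <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(compute_dprime(hh, rep(0.1, length(hh)))) > 0))
})

test_that("d-prime applies the 1/(2n) correction at rates of exactly 0 or 1", {
  expect_equal(compute_dprime(0.5, 0, n_catch = 100),
               stats::qnorm(0.5) - stats::qnorm(1 / 200))
  expect_equal(compute_dprime(1, 0.1, n_tone = 50),
               stats::qnorm(1 - 1 / 100) - stats::qnorm(0.1))
  expect_error(compute_dprime(0, 0.1), "count")
  expect_error(compute_dprime(1.2, 0.1), "outside")
})

test_that("first-lick statistics: median, histogram-mode peak, degenerate cases", {
  expect_equal(first_lick_stats(c(1.0, 2.0, 3.0))$median, 2.0)
  one <- first_lick_stats(1.7)
  expect_equal(one$median, 1.7)
  expect_equal(one$peak, 1.7)

  # 40 of 100 latencies in [1.6, 1.7): modal bin midpoint 1.65 at 0.1 s bins
  set.seed(4)
  lat <- c(runif(40, 1.6, 1.7 - 1e-9), runif(30, 0, 1.5), runif(30, 1.8, 4))
  expect_equal(first_lick_stats(lat, 0.1)$peak, 1.65)

  none <- first_lick_stats(make_trials("MISS", FALSE))
  expect_true(is.na(none$median) && is.na(none$peak))
  expect_identical(none$flags, "no_licks")
  expect_error(first_lick_stats(lat, histogram_bin = 0), "histogram_bin")
})

test_that("lick-rate traces average binary per-bin indicators across trials", {
  no_licks <- make_trials(rep("MISS", 3), rep(FALSE, 3))
  tr0 <- lick_rate_trace(no_licks, 0.1)
  expect_true(all(tr0$p_lick == 0))
  expect_equal(length(tr0$p_lick), length(tr0$bin_edges) - 1L)

  both <- make_trials(rep("HIT", 2), rep(FALSE, 2),
                      licks = list(c(1.02, 1.08), 1.05))
  t2 <- lick_rate_trace(both, 0.1)
  bin <- findInterval(1.0, t2$bin_edges)
  expect_equal(t2$p_lick[bin], 1.0)   # both trials lick in [1.0, 1.1)
  expect_true(all(t2$p_lick[-bin] == 0))

  four <- make_trials(rep("MISS", 4), rep(FALSE, 4),
                      licks = list(numeric(0), numeric(0), numeric(0), 2.51))
  t4 <- lick_rate_trace(four, 0.1)
  expect_equal(t4$p_lick[findInterval(2.5, t4$bin_edges)], 0.25)

  # invariant to trial order
  shuffled <- four[c(4, 2, 1, 3), ]
  expect_equal(lick_rate_trace(shuffled, 0.1)$p_lick, t4$p_lick)
  expect_error(lick_rate_trace(four, bin_width = -1), "bin_width")
})

test_that("learning-curve correlations match the Pearson oracle", {
  curve <- data.frame(day_index = 1:4,
                      delay = c(0, 0.25, 0.5, 0.75),
                      peak_latency = c(0, 0.25, 0.5, 0.75) + 0.5,
                      hit_rate = c(0.3, 0.6, 0.5, 0.9))
  expect_equal(correlate_curve(curve, "delay", "peak_latency")$r, 1.0)
  curve$neg <- -curve$delay
  expect_equal(correlate_curve(curve, "delay", "neg")$r, -1.0)
  ct <- correlate_curve(curve, "delay", "hit_rate")
  expect_equal(ct$r, cor(curve$delay, curve$hit_rate))
  expect_equal(ct$r, 0.87788, tolerance = 1e-5)
  expect_equal(ct$p, cor.test(curve$delay, curve$hit_rate)$p.value)

  curve$const <- 1
  cc <- correlate_curve(curve, "delay", "const")
  expect_true(is.na(cc$r))
  expect_identical(cc$flags, "constant_series")
  expect_identical(correlate_curve(curve[1:2, ], "delay", "hit_rate")$flags,
                   "too_few_days")
})

test_that("learning_curve aggregates per day across cages", {
  t1 <- make_trials(c("HIT", "MISS", "EARLY", "CORRECT_REJECTION"),
                    c(FALSE, FALSE, FALSE, TRUE),
                    latencies = c(1.5, NA, 0.4, NA),
                    day_index = 1L, cage_id = 0L, delay = 0)
  t2 <- make_trials(c("HIT", "HIT", "MISS", "FALSE_ALARM"),
                    c(FALSE, FALSE, FALSE, TRUE),
                    latencies = c(1.5, 1.6, NA, 2.0),
                    day_index = 1L, cage_id = 1L, delay = 0)
  t3 <- make_trials(c("MISS", "MISS"), c(FALSE, FALSE),
                    day_index = 2L, cage_id = 0L, delay = 0.25)
  cv <- learning_curve(rbind(t1, t2, t3))
  expect_identical(nrow(cv), 2L)
  expect_equal(cv$delay, c(0, 0.25))
  expect_equal(cv$n_cages, c(2, 1))
  # day-1 hit rate: mean of per-cage rates (1/3 and 2/3)
  expect_equal(cv$hit_rate[1], mean(c(1 / 3, 2 / 3)))
  expect_equal(cv$fa_rate[1], mean(c(0, 1)))
  expect_true(is.na(cv$fa_rate[2]))
})

test_that("session_summary composes rates, d-prime and latencies", {
  outcomes <- c(rep("HIT", 20), rep("MISS", 70), rep("EARLY", 10),
                rep("FALSE_ALARM", 2), rep("CORRECT_REJECTION", 48))
  is_catch <- c(rep(FALSE, 100), rep(TRUE, 50))
  lat <- rep(NA_real_, 150)
  lat[1:20] <- seq(1.3, 2.3, length.out = 20)
  tr <- make_trials(outcomes, is_catch, latencies = lat)
  s <- session_summary(tr)
  expect_equal(s$hit_rate, 0.2)
  expect_equal(s$fa_rate, 0.04)
  expect_equal(s$dprime, stats::qnorm(0.2) - stats::qnorm(0.04))
  expect_equal(s$median_first_lick_latency, median(lat[1:20]))
})
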