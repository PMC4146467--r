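test_that("periodogram: degenerate and exactly periodic cases", {
  # constant series: no power anywhere
  ps0 <- power_spectrum(rep(1.3, 200), n_steps = 200)
  expect_true(all(ps0$power < 1e-24))

  # pure period-4 alternation: a single line exactly at 1/4
  v4 <- rep(c(0, 1, 0, -1), 50)
  ps4 <- power_spectrum(v4, n_steps = 200)
  hot <- ps4$power > 1e-12
  expect_equal(ps4$frequency[hot], 1 / 4)

  # frequencies live in (0, 1/2]; the zero-frequency term is excluded
  expect_true(all(ps4$frequency > 0 & ps4$frequency <= 0.5))
})

test_that("total spectral power equals the variance of the analyzed window", {
  set.seed(42)
  for (rep_ in 1:3) {
    v <- stats::rnorm(256)
    ps <- power_spectrum(v, n_steps = 256, trim_to_module = FALSE)
    n <- attr(ps, "n_used")
    expect_equal(sum(ps$power), mean((v[1:n] - mean(v[1:n]))^2), tolerance = 1e-10)
  }
})

test_that("an exactly p-periodic series only has lines at multiples of 1/p", {
  for (p in c(3, 5, 8)) {
    set.seed(p)
    motif <- stats::runif(p)
    v <- rep(motif, 40)
    ps <- power_spectrum(v, n_steps = 10 * p)
    hot <- ps$frequency[ps$power > 1e-16 * max(ps$power)]
    k <- hot * p
    expect_true(all(abs(k - round(k)) < 1e-9))
  }
})

test_that("dominant periods and harmonics are identified", {
  v <- rep(c(0, 1, 0, -1), 50)
  dp <- dominant_periods(power_spectrum(v, 200), threshold_frac = 0.05)
  expect_equal(dp$period, 4L)
  expect_true(is.na(dp$harmonic_of))
  expect_equal(mode_diversity(power_spectrum(v, 200)), 1)

  # sawtooth of period 5: fundamental 1/5 plus harmonics at 2/5
  v5 <- rep(c(0, 1, 2, 3, 4), 60)
  dp5 <- dominant_periods(power_spectrum(v5, 300), threshold_frac = 0.01)
  expect_equal(dp5$period[1], 5L)          # strongest line is the fundamental
  expect_true(all(is.na(dp5$harmonic_of[dp5$frequency == 0.2])))
  expect_true(all(dp5$harmonic_of[abs(dp5$frequency - 0.4) < 1e-9] == 5L))

  expect_error(dominant_periods(power_spectrum(v, 200)[0, ]), "empty")
})

test_that("running averages flatten their own period and keep envelopes", {
  v <- as.numeric(rep(c(0, 2, 1, 1), 25))

  # w = 1 is the identity
  expect_equal(running_average(v, 1), v)

  # window = period: complete flattening to the series mean
  ra <- running_average(v, 4)
  expect_true(all(abs(ra - 1) < 1e-12))
  expect_equal(length(ra), length(v) - 3)

  # superposition of period 8 and period 9: 4-step averaging leaves a
  # 72-step module (the lcm), 8- and 9-step averaging remove one component
  set.seed(17)
  s8 <- rep(stats::runif(8, 0, 1), 90)[1:720]
  s9 <- rep(stats::runif(9, 0, 1), 80)[1:720]
  mix <- (s8 + s9) / 2
  expect_equal(recurrent_module_length(mix), 72L)
  expect_equal(recurrent_module_length(running_average(mix, 4)), 72L)
  after8 <- running_average(mix, 8)          # the 8-component is wiped out
  expect_equal(recurrent_module_length(after8), 9L)
  after9 <- running_average(mix, 9)
  expect_equal(recurrent_module_length(after9), 8L)

  expect_error(running_average(v, 200), "exceeds")
})

test_that("recurrence-module detection returns the smallest valid lag", {
  expect_equal(recurrent_module_length(rep(c(0, 1, 0, 1), 30)), 2L)
  expect_equal(recurrent_module_length(rep(c(0, 1, 2, 1), 30)), 4L)
  expect_equal(recurrent_module_length(rep(3.3, 40)), 1L)
  # aperiodic at scale: strictly increasing sequence
  expect_true(is.na(recurrent_module_length(seq(0, 1, length.out = 50))))
})

test_that("ring fixtures give closed-form spectra through the full pipeline", {
  for (p in c(4, 7)) {
    rf <- ring_fixture(p)
    ser <- ensemble_average(rf$network, node = sprintf("R%02d", p), n_ic = 64,
                            seed = 2, t_max = 20 * p, transient = p,
                            ic_policy = NULL)
    # ICs are uniform so the average is p-periodic (not necessarily constant)
    m <- recurrent_module_length(ser$value)
    expect_true(p %% m == 0)
    ps <- power_spectrum(ser, n_steps = 10 * p)
    hot <- ps$frequency[ps$power > 1e-12]
    expect_true(all(abs(hot * m - round(hot * m)) < 1e-9))
  }
})
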