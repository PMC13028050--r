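# Synthetic voltage-clamp generator: construction oracles, determinism,
# noise behaviour and the CSV round trip.

params <- squid_params()
gates <- canonical_gates()

test_that("noiseless potassium traces equal the closed-form gate power exactly", {
  ds <- synthesize_clamp(params, "K", steps = 0, hold = -65, duration = 20,
                         dt = 0.05, exponents = c(4, 0), noise_sd = 0, seed = 3)
  tr <- ds$traces
  n0 <- steady_state(gates$n, -65)
  expect_equal(tr$g_mS_cm2,
               params$gK_max * gate_relaxation(gates$n, 0, tr$t_ms, n0)^4)
})

test_that("sodium onset from a fully deactivated hold rises as t^3", {
  # hold at -120 mV so m0 ~ 0; series expansion gives g ~ t^p at small t,
  # measured as the log-log slope on t in [0.01, 0.05] ms
  ds <- synthesize_clamp(params, "Na", steps = 0, hold = -120, duration = 20,
                         dt = 0.005, exponents = c(3, 1), noise_sd = 0, seed = 0)
  tr <- ds$traces[ds$traces$t_ms >= 0.01 & ds$traces$t_ms <= 0.05, ]
  slope <- unname(stats::coef(stats::lm(log(tr$g_mS_cm2) ~ log(tr$t_ms)))[2])
  expect_equal(slope, 3, tolerance = 0.1)
})

test_that("the generator is deterministic and seed-faithful", {
  mk <- function(seed) synthesize_clamp(params, "K", steps = c(-20, 0),
                                        hold = -65, duration = 15, dt = 0.05,
                                        exponents = c(4, 0), noise_sd = 0.3,
                                        seed = seed)
  expect_identical(mk(7), mk(7))
  expect_false(identical(mk(7)$traces$g_mS_cm2, mk(8)$traces$g_mS_cm2))
  # noiseless datasets are reproducible to full precision
  nl <- function() synthesize_clamp(params, "K", steps = 0, hold = -65,
                                    duration = 10, dt = 0.05,
                                    exponents = c(4, 0), noise_sd = 0, seed = 0)
  expect_identical(nl(), nl())
  # and the generator leaves the global RNG stream untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(mk(7)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("ensemble means of noisy traces converge to the noiseless trace at 1/sqrt(N)", {
  noiseless <- synthesize_clamp(params, "K", steps = 0, hold = -65,
                                duration = 10, dt = 0.2, exponents = c(4, 0),
                                noise_sd = 0, seed = 0)$traces$g_mS_cm2
  rms_at <- function(N) {
    acc <- 0
    for (s in seq_len(N))
      acc <- acc + synthesize_clamp(params, "K", steps = 0, hold = -65,
                                    duration = 10, dt = 0.2,
                                    exponents = c(4, 0), noise_sd = 1,
                                    seed = 1000 + s)$traces$g_mS_cm2
    sqrt(mean((acc / N - noiseless)^2))
  }
  r <- vapply(c(10, 100, 1000), rms_at, numeric(1))
  expect_true(all(diff(r) < 0))
  # two decades of N should buy roughly a factor 10 in RMS
  expect_gt(r[1] / r[3], 4)
  expect_lt(r[1] / r[3], 40)
})

test_that("invalid clamp requests are rejected; hypothetical channels recorded", {
  expect_error(synthesize_clamp(params, "K", steps = 80, hold = -65,
                                duration = 10, dt = 0.05, exponents = c(4, 0)),
               "\\[-120, 60\\]")
  expect_error(synthesize_clamp(params, "K", steps = 0, hold = -65,
                                duration = 10, dt = 0.05, exponents = c(0, 0)),
               "p >= 1")
  expect_warning(synthesize_clamp(params, "K", steps = 0, hold = -65,
                                  duration = 1, dt = 0.05,
                                  exponents = c(4, 0)),
                 "time constants")
  ds <- synthesize_clamp(params, "K", steps = 0, hold = -65, duration = 30,
                         dt = 0.05, exponents = c(4, 1), noise_sd = 0, seed = 0)
  expect_true(ds$hypothetical_inactivation)
})

test_that("clamp datasets round-trip through CSV + JSON metadata", {
  ds <- synthesize_clamp(params, "Na", steps = c(-20, 0), hold = -65,
                         duration = 10, dt = 0.05, exponents = c(3, 1),
                         noise_sd = 0.2, seed = 11)
  stem <- file.path(withr::local_tempdir(), "clamp")
  write_clamp_csv(ds, stem)
  back <- read_clamp_csv(stem)
  expect_equal(back$traces$g_mS_cm2, ds$traces$g_mS_cm2, tolerance = 1e-12)
  expect_equal(back$seed, 11L)
  expect_equal(unname(back$true_exponents), c(3, 1))
  expect_equal(back$g_max, params$gNa_max)
})
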