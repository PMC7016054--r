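test_that("temporal example kernels have the printed structure", {
  m <- example_temporal_model()
  expect_equal(m$space_in$S, 0.2)
  expect_equal(m$space_in$dim, 21L)
  # t^3 prefactor: the analytic kernel vanishes at zero
  h11 <- function(t) 2.472e10 * t^3 * exp(-100 * pi * t) * cos(36 * pi * t)
  expect_equal(h11(0), 0)
  # each second-order kernel is a sum of two separable terms: rank <= 2
  for (k in list(m$T1$h2, m$T2$h2, m$T3$h2)) {
    expect_lte(k2_rank(k, tol = 1e-8), 2L)
    expect_true(k2_is_real(k))
    Cn <- k2_nat(k)
    expect_lt(max(Mod(Cn - t(Cn))), 1e-10 * max(Mod(Cn)))
  }
  expect_equal(m$T2$b + m$T3$b, 1)
})

test_that("spatial example has the centred profile and tied symmetric pairs", {
  m <- example_spatial_model()
  expect_equal(m$space_in$dim, 17L)
  expect_equal(m$space_in$S, 0.4)
  amps <- sapply(m$mvp$h1_list, function(k) max(abs(eval_signal(k, canonical_grid(m$space_out, 64)))))
  expect_equal(which.max(amps), 2L)   # e^{-(i-2)^2/4} peaks at channel 2
  expect_equal(amps[1], amps[3], tolerance = 1e-10)
  for (i in 1:4) for (j in 1:4) {
    kij <- m$mvp$h2_grid[[i]][[j]]
    expect_equal(k2_rank(kij), 1L)
    expect_equal(kij$coeffs, m$mvp$h2_grid[[j]][[i]]$coeffs)
  }
  expect_equal(m$T2$b + m$T3$b + m$mvp$b4, 1)
})

test_that("random stimuli are real, reproducible, and correctly scaled", {
  sp <- trig_space(5, 50 * pi)
  s1 <- random_stimuli(sp, 3, sigma = 0.7, seed = 42)
  s2 <- random_stimuli(sp, 3, sigma = 0.7, seed = 42)
  for (i in 1:3) {
    expect_true(is_conj_symmetric(s1[[i]]$coeffs))
    expect_identical(s1[[i]]$coeffs, s2[[i]]$coeffs)
    tg <- runif(10, 0, sp$S)
    expect_lt(max(abs(Im(eval_signal(s1[[i]], tg, complex_value = TRUE)))), 1e-12)
  }
  # per-coefficient second moment within 3 standard errors of sigma^2
  big <- random_stimuli(sp, 1000, sigma = 0.7, seed = 7)
  A <- sapply(big, function(u) u$coeffs)
  for (l in c(0, 2, 5)) {
    v <- mean(Mod(A[sp$L + 1 + l, ])^2)
    se <- stats::sd(Mod(A[sp$L + 1 + l, ])^2) / sqrt(1000)
    expect_lt(abs(v - 0.49), 3 * se)
  }
})

test_that("scenarios round-trip through YAML bit-identically", {
  scn <- scenario_example3()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, p)
  scn2 <- read_scenario(p)
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn2, p2)
  expect_identical(readLines(p), readLines(p2))
  expect_equal(unclass(scn2)[!vapply(scn2, is.null, TRUE)],
               unclass(scn)[!vapply(scn, is.null, TRUE)])
})

test_that("the end-to-end scenario driver runs and reports", {
  scn <- dnp_scenario("mini", "example_temporal", L = 2, Omega = 20 * pi,
                      M = 30L, sigma = 0.05, seed = 11L, T_samples = 8L,
                      max_iter = 600L, min_snr_db = 40)
  outdir <- withr::local_tempdir()
  rep <- suppressWarnings(run_scenario(scn, outdir = outdir))
  expect_true(file.exists(file.path(outdir, "model.json")))
  expect_true(file.exists(file.path(outdir, "snr.csv")))
  expect_true(is.finite(rep$min_snr_db))
  expect_equal(rep$n_meas, 240L)
})

test_that("degenerate scenarios abort with a denominator diagnostic", {
  expect_error(run_scenario(scenario_degenerate()), "denominator degeneracy")
})

test_that("gain-control demo shifts response curves with background", {
  curves <- demo_gain_control(backgrounds = c(0.5, 2),
                              flashes = c(0, 1, 2, 4))
  expect_true(all(is.finite(curves$response)))
  # response grows with flash amplitude at fixed background
  for (B in unique(curves$background)) {
    r <- curves$response[curves$background == B]
    expect_true(all(diff(r[order(curves$flash[curves$background == B])]) > 0))
  }
  # gain control: the same flash increment produces a smaller response
  # increment on the brighter background
  lo <- curves[curves$background == 0.5, ]
  hi <- curves[curves$background == 2, ]
  gain_lo <- diff(lo$response[order(lo$flash)])[1]
  gain_hi <- diff(hi$response[order(hi$flash)])[1]
  expect_lt(gain_hi, gain_lo)
})
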