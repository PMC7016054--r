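test_that("feedback-free circuits reduce to pointwise division", {
  sp <- trig_space(4, 40 * pi)
  set.seed(14)
  u <- rand_real_signal(sp, 0.3)

  # constant numerator, unit denominator
  d1 <- dnp_temporal(volterra(0.8, space = sp), volterra(1, space = sp),
                     volterra(0, space = sp))
  r1 <- simulate_temporal(d1, u)
  expect_equal(r1$v, rep(0.8, length(r1$grid)))

  # T3 = 0: v = T1 u / T2 u pointwise
  T1 <- volterra(0.1, kernel1(sp, rand_real_signal(sp, 0.4)$coeffs),
                 rand_lowrank_k2(sp, 0.6))
  T2 <- volterra(1, kernel1(sp, rand_real_signal(sp, 0.1)$coeffs),
                 rand_lowrank_k2(sp, 0.2))
  d2 <- dnp_temporal(T1, T2, volterra(0, space = sp))
  r2 <- simulate_temporal(d2, u)
  expect_lt(max(abs(r2$v - vp_apply(T1, u, r2$grid) / vp_apply(T2, u, r2$grid))),
            1e-10)
})

test_that("output is invariant under joint kernel scaling", {
  m <- small_temporal_model(seed = 3)
  set.seed(41)
  u <- rand_real_signal(m$space_in, 0.3)
  base <- simulate_temporal(m, u)

  scale_vp <- function(v, a) {
    volterra(a * v$b,
             if (is.null(v$h1)) NULL else kernel1(v$space, a * v$h1$coeffs),
             if (is.null(v$h2)) NULL else kernel2(v$space, a * v$h2$coeffs,
                                                  symmetric = v$h2$symmetric),
             v$space)
  }
  m2 <- dnp_temporal(scale_vp(m$T1, 2), scale_vp(m$T2, 2), scale_vp(m$T3, 2),
                     normalize_check = FALSE)
  r2 <- simulate_temporal(m2, u)
  expect_lt(max(abs(r2$v - base$v)), 1e-9)
})

test_that("converged runs satisfy the fixed-point residual bound and are deterministic", {
  m <- small_temporal_model(seed = 6)
  set.seed(55)
  tol <- 1e-12
  for (i in 1:3) {
    u <- rand_real_signal(m$space_in, 0.3)
    r <- simulate_temporal(m, u, tol = tol)
    expect_true(r$converged)
    expect_lte(r$residual, 10 * tol)
    expect_gt(r$min_denominator, 0)
    r2 <- simulate_temporal(m, u, tol = tol)
    expect_identical(r$v, r2$v)
    # halving the tolerance moves the solution by at most the previous one
    r3 <- simulate_temporal(m, u, tol = tol / 2)
    expect_lte(max(abs(r3$v - r$v)), tol)
  }
})

test_that("spatio-temporal simulation reduces and respects symmetry", {
  L <- 4
  m <- small_spatial_model(N = 3, L = L)
  sp <- m$space_in
  set.seed(61)
  u <- random_stimuli(sp, 3, sigma = 0.5)

  r <- simulate_spatiotemporal(m, u, tol = 1e-12)
  expect_lte(r$residual, 1e-11)
  # fixed-point identity per channel
  tg <- r$grid
  l4 <- mvp_apply(m$mvp, lapply(1:3, function(n)
    trig_signal(m$space_out, r$vproj[, n])), tg)
  for (n in 1:3) {
    num <- vp_apply(m$T1, u[[n]], tg)
    den <- vp_apply(m$T2, u[[n]], tg) +
      vp_apply(m$T3, trig_signal(m$space_out, r$vproj[, n]), tg) + l4
    expect_lt(max(abs(r$v[n, ] * den - num)), 1e-11)
  }

  # zero MVP: channels equal the temporal simulation
  m0 <- dnp_spatiotemporal(3, m$T1, m$T2, m$T3, mvp(3, 0, space = m$space_out))
  r0 <- simulate_spatiotemporal(m0, u)
  mt <- dnp_temporal(m$T1, m$T2, m$T3)
  for (n in 1:3) {
    rt <- simulate_temporal(mt, u[[n]], n_grid = length(r0$grid))
    expect_lt(max(abs(r0$v[n, ] - rt$v)), 1e-9)
  }

  # identical inputs + symmetric spatial profile: channels 1 and 3 agree
  # (the profile is centred on channel 2)
  rs <- simulate_spatiotemporal(m, list(u[[1]], u[[1]], u[[1]]))
  expect_lt(max(abs(rs$v[1, ] - rs$v[3, ])), 1e-9)
})

test_that("degenerate denominators abort loudly", {
  sp <- trig_space(3, 30 * pi)
  h <- kernel1(sp, rand_real_signal(sp, 0.3)$coeffs)
  bad <- dnp_temporal(volterra(0.5, h, NULL), volterra(0, space = sp),
                      volterra(0, space = sp), normalize_check = FALSE)
  set.seed(71)
  expect_error(simulate_temporal(bad, rand_real_signal(sp, 0.3)),
               "denominator degeneracy")
})

test_that("trigonometric interpolation reproduces smooth periodic samples", {
  S <- 0.4
  G <- 128
  tg <- (0:(G - 1)) * S / G
  y <- 1 + sin(2 * pi * tg / S) - 0.3 * cos(6 * pi * tg / S)
  tq <- runif(20, 0, S)
  ref <- 1 + sin(2 * pi * tq / S) - 0.3 * cos(6 * pi * tq / S)
  expect_lt(max(abs(trig_interp(y, S, tq) - ref)), 1e-10)
})
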