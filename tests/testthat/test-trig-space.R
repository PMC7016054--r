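test_that("space arithmetic matches the printed example spaces", {
  H1 <- trig_space(10, 100 * pi)
  expect_equal(H1$S, 0.2)
  expect_equal(H1$dim, 21L)

  H3 <- trig_space(8, 40 * pi)
  expect_equal(H3$S, 0.4)
  expect_equal(H3$dim, 17L)

  H0 <- trig_space(0, 1, S_override = 1)
  expect_equal(H0$dim, 1L)
  expect_equal(eval_signal(trig_signal(H0, sqrt(H0$S)), c(0, 0.3, 0.9)),
               rep(1, 3))

  expect_error(trig_space(-1, 10), "nonnegative")
  expect_error(trig_space(3, -1), "positive")
  expect_error(trig_space(3, 10, S_override = 2), "L = 0")
})

test_that("signal evaluation matches term-by-term summation and is periodic", {
  set.seed(11)
  sp <- trig_space(6, 60 * pi)
  u <- rand_real_signal(sp)
  expect_true(is_conj_symmetric(u$coeffs))

  t0 <- runif(7, -0.4, 0.6)
  direct <- sapply(t0, function(t)
    sum(u$coeffs * exp(1i * sp$l * sp$omega1 * t) / sqrt(sp$S)))
  expect_lt(max(Mod(eval_signal(u, t0, complex_value = TRUE) - direct)), 1e-12)
  expect_lt(max(abs(eval_signal(u, t0) - eval_signal(u, t0 + sp$S))), 1e-10)

  z <- trig_signal(sp)
  expect_equal(eval_signal(z, t0), rep(0, 7))
})

test_that("projection is idempotent and matches an independent quadrature oracle", {
  sp <- trig_space(10, 100 * pi)
  # printed first-order gamma-tone of the temporal example
  f <- function(t) 2.472e10 * t^3 * exp(-100 * pi * t) * cos(36 * pi * t)
  k <- project1(f, sp)
  # independent oracle: explicit trapezoid quadrature of f * conj(e_l) on a
  # very fine grid
  G <- 65536
  tg <- (0:(G - 1)) * sp$S / G
  fv <- f(tg)
  oracle <- sapply(sp$l, function(l)
    (sp$S / G) * sum(fv * exp(-1i * l * sp$omega1 * tg)) / sqrt(sp$S))
  expect_lt(max(Mod(k$coeffs - oracle)) / max(Mod(oracle)), 1e-6)

  # idempotence on members and on generic smooth functions
  set.seed(4)
  for (i in 1:20) {
    sp2 <- trig_space(4, 40 * pi)
    g0 <- rand_real_signal(sp2, 0.7)
    p1 <- project1(function(t) eval_signal(g0, t), sp2)
    expect_lt(max(Mod(p1$coeffs - g0$coeffs)), 1e-10)
    h <- function(t) exp(-50 * (t - 0.05 - 0.002 * i)^2) + 0.1 * sin(2 * pi * t / sp2$S)
    p2 <- project1(h, sp2)
    p3 <- project1(function(t) eval_signal(p2, t), sp2)
    expect_lt(max(Mod(p3$coeffs - p2$coeffs)), 1e-10)
  }

  expect_error(project1(function(t) t, trig_space(10, 100 * pi), n_quad = 50),
               "too coarse")
})

test_that("reproducing property and Parseval hold", {
  set.seed(21)
  sp <- trig_space(5, 50 * pi)
  for (i in 1:5) {
    f <- rand_real_signal(sp)
    t0 <- runif(1, 0, sp$S)
    # K(.; t0) expanded in the basis: kappa_l = conj(e_l(t0))
    kappa <- Conj(as.vector(basis_eval(sp, t0)))
    rk <- trig_signal(sp, kappa)
    expect_lt(Mod(inner1(f, rk) - eval_signal(f, t0, complex_value = TRUE)), 1e-9)
    # Parseval against fine-grid L2 norm
    G <- 4096
    tg <- canonical_grid(sp, G)
    l2 <- (sp$S / G) * sum(eval_signal(f, tg)^2)
    expect_lt(abs(l2 - sum(Mod(f$coeffs)^2)), 1e-9)
  }
})

test_that("reversed-shift coefficients represent u(t_k - t) exactly", {
  set.seed(31)
  sp <- trig_space(6, 60 * pi)

  const <- trig_signal(sp, c(rep(0, 6), sqrt(sp$S) * 2, rep(0, 6)))
  expect_equal(reversed_shift_coeffs(const, 0.123), const$coeffs)

  # pure basis signal e_l at t_k = 0 moves to index -l
  el <- trig_signal(sp, replace(complex(sp$dim), 9, 1))  # l = +2 slot
  out <- reversed_shift_coeffs(el, 0)
  expect_equal(which(Mod(out) > 1e-14), 5L)              # l = -2 slot

  for (i in 1:5) {
    u <- rand_real_signal(sp)
    tk <- runif(1, 0, sp$S)
    w <- trig_signal(sp, reversed_shift_coeffs(u, tk))
    ts <- seq(0, sp$S, length.out = 100)
    expect_lt(max(abs(eval_signal(w, ts) - eval_signal(u, tk - ts))), 1e-10)
  }
})

test_that("basis is orthonormal under the grid inner product", {
  sp <- trig_space(7, 70 * pi)
  G <- 4096
  E <- basis_eval(sp, canonical_grid(sp, G))
  gram <- (sp$S / G) * crossprod(Conj(E), E)
  expect_lt(max(Mod(gram - diag(sp$dim))), 1e-10)
})
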