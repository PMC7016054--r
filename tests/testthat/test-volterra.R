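test_that("constant and separable processors evaluate in closed form", {
  sp <- trig_space(4, 40 * pi)
  set.seed(8)
  u <- rand_real_signal(sp)
  tg <- canonical_grid(sp, 64)

  Tc <- volterra(b = 1.7, space = sp)
  expect_equal(vp_apply(Tc, u, tg), rep(1.7, 64))

  g <- rand_real_signal(sp, 0.5)
  Tsq <- volterra(0, NULL, kernel2_from_factors(sp, 1, list(g)))
  lin <- vp_apply(volterra(0, kernel1(sp, g$coeffs), NULL), u, tg)
  expect_lt(max(abs(vp_apply(Tsq, u, tg) - lin^2)), 1e-9 * max(1, max(lin^2)))
})

test_that("coefficient-domain evaluation matches brute-force quadrature", {
  m <- example_temporal_model()
  sp <- m$space_in
  set.seed(19)
  u <- rand_real_signal(sp, 0.1)
  G <- 2048
  tg <- canonical_grid(sp, G)
  te <- tg[seq(1, G, by = 32)]

  out <- vp_apply(m$T1, u, te)
  uh <- eval_signal(u, tg)
  h1g <- eval_signal(m$T1$h1, tg)
  H2 <- eval_kernel2(m$T1$h2, tg, tg, pairwise = FALSE)
  U <- t(sapply(te, function(t) eval_signal(u, t - tg)))
  brute <- m$T1$b +
    (sp$S / G) * as.vector(U %*% h1g) +
    (sp$S / G)^2 * rowSums((U %*% H2) * U)
  expect_lt(max(abs(out - brute)) / max(abs(brute)), 1e-6)
})

test_that("first-order path is linear, second-order exactly quadratic", {
  sp <- trig_space(5, 50 * pi)
  set.seed(23)
  h <- kernel1(sp, rand_real_signal(sp)$coeffs)
  T1 <- volterra(0, h, NULL)
  tg <- canonical_grid(sp, 80)
  for (i in 1:5) {
    u1 <- rand_real_signal(sp); u2 <- rand_real_signal(sp)
    a <- rnorm(1)
    lhs <- vp_apply(T1, trig_signal(sp, a * u1$coeffs + u2$coeffs), tg)
    rhs <- a * vp_apply(T1, u1, tg) + vp_apply(T1, u2, tg)
    expect_lt(max(abs(lhs - rhs)), 1e-10 * max(1, max(abs(rhs))))
  }
  T2 <- volterra(0.3, NULL, rand_lowrank_k2(sp, c(0.7, -0.2)))
  u <- rand_real_signal(sp)
  quad <- vp_apply(T2, u, tg) - 0.3
  quad2 <- vp_apply(T2, trig_signal(sp, 2 * u$coeffs), tg) - 0.3
  expect_lt(max(abs(quad2 - 4 * quad)), 1e-9 * max(1, max(abs(quad))))
})

test_that("multi-input processor reduces to the single-channel case", {
  sp <- trig_space(4, 40 * pi)
  set.seed(30)
  h1 <- kernel1(sp, rand_real_signal(sp)$coeffs)
  k2 <- rand_lowrank_k2(sp, 0.5)
  tg <- canonical_grid(sp, 48)
  u <- rand_real_signal(sp)

  M0 <- mvp(2, b4 = 0.4, space = sp)
  expect_equal(mvp_apply(M0, list(u, u), tg), rep(0.4, 48))

  M1 <- mvp(1, b4 = 0.2, h1_list = list(h1),
            h2_grid = list(list(k2)), space = sp)
  T1 <- volterra(0.2, h1, k2)
  expect_lt(max(abs(mvp_apply(M1, list(u), tg) - vp_apply(T1, u, tg))), 1e-10)
})

test_that("spatial-profile MVP with unit inputs matches independent quadrature", {
  m <- example_spatial_model(N = 3, trig_space(6, 30 * pi), trig_space(6, 30 * pi))
  spo <- m$space_out
  ones <- trig_signal(spo, replace(complex(spo$dim), spo$L + 1, sqrt(spo$S)))
  tg <- canonical_grid(spo, 64)
  out <- mvp_apply(m$mvp, list(ones, ones, ones), tg)

  G <- 1024
  tq <- canonical_grid(spo, G)
  int1 <- sapply(m$mvp$h1_list, function(k) (spo$S / G) * sum(eval_signal(k, tq)))
  int2 <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- m$mvp$h2_grid[[i]][[j]]
    int2 <- int2 + (spo$S / G)^2 * sum(eval_kernel2(k, tq, tq, pairwise = FALSE))
  }
  closed <- m$mvp$b4 + sum(int1) + int2
  expect_lt(max(abs(out - closed)) / abs(closed), 1e-6)
})
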