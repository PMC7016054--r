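test_that("sampling vector/matrix dimensions follow the closed-form counts", {
  set.seed(81)
  for (i in 1:10) {
    L <- sample(1:6, 1); Lo <- sample(1:6, 1); N <- sample(1:4, 1)
    dt <- sampling_dims(L, Lo, mode = "temporal")
    expect_equal(dt$phi_len, 4 * L + 2 * Lo + 4)
    expect_equal(dt$xi_dim, c(4 * L + 2 * Lo + 3, 2 * L + 2 * Lo + 2))
    ds <- sampling_dims(L, Lo, N, mode = "spatiotemporal")
    expect_equal(ds$phi_len, 4 * L + 2 * (N + 1) * Lo + N + 4)
    expect_equal(ds$xi_dim[2], 2 * L + 2 * Lo + 2)
  }
  # the worked dimension case: N = 4, L = Lo = 8
  expect_equal(sampling_dims(8, 8, 4, "spatiotemporal")$phi_len, 120)
})

test_that("unknown counts match the printed budgets", {
  expect_equal(count_unknowns(10, 10, mode = "temporal"), 1387L)
  expect_equal(count_unknowns(0, 0, mode = "temporal"), 7L)
  expect_equal(
    count_unknowns(8, 8, N = 4, mode = "spatiotemporal", tie_symmetric = TRUE),
    1L + 2L * 17L + 17L + 4L * 17L + 2L * 289L + 289L + 10L * 289L)
  # block-enumeration cross-check: complex coefficients per layout block
  lay <- dnp_layout(trig_space(8, 40 * pi), trig_space(8, 40 * pi),
                    "spatiotemporal", N = 4, tie_symmetric = TRUE)
  n_complex <- sum(vapply(lay$blocks, function(b) b$n_entries, 1L))
  expect_equal(n_complex,
               count_unknowns(8, 8, 4, "spatiotemporal", tie_symmetric = TRUE))
})

test_that("assembled temporal systems are exactly consistent with the truth", {
  m <- small_temporal_model(seed = 3)
  set.seed(91)
  st <- random_stimuli(m$space_in, 5, sigma = 0.3)
  tr <- suppressWarnings(simulate_trials(m, st, T_samples = 7))
  sys <- suppressWarnings(build_temporal_system(tr))
  th <- encode_model(m, sys$layout)
  expect_lt(max(abs(sys$A %*% th - sys$q)), 1e-6)

  # round trip through the structural parametrization
  dec <- decode_theta(th, sys$layout)
  expect_lt(max(Mod(dec$h2_1 - m$T1$h2$coeffs)), 1e-12)
  expect_lt(max(Mod(dec$h1_3 - m$T3$h1$coeffs)), 1e-12)

  # matrix-form sampling vector: the first slot is the constant 1
  px <- build_phi_xi(sys, 3)
  expect_equal(px$Phi[1], 1 + 0i)
  expect_equal(length(px$Phi), sampling_dims(4, 4, mode = "temporal")$phi_len)
  expect_equal(dim(px$Xi), sampling_dims(4, 4, mode = "temporal")$xi_dim)
})

test_that("spatio-temporal systems (tied and untied) satisfy the identity", {
  m <- small_spatial_model(N = 3)
  set.seed(95)
  st <- lapply(1:4, function(i) random_stimuli(m$space_in, 3, sigma = 0.8))
  tr <- suppressWarnings(simulate_trials(m, st, T_samples = 6))
  for (tie in c(FALSE, TRUE)) {
    sys <- suppressWarnings(build_spatiotemporal_system(tr, tie_symmetric = tie))
    th <- encode_model(m, sys$layout)
    expect_lt(max(abs(sys$A %*% th - sys$q)), 1e-6)
  }

  # matrix-form trace identity Tr(C2^H Xi) on the untied layout
  sys <- suppressWarnings(build_spatiotemporal_system(tr))
  th <- encode_model(m, sys$layout)
  dec <- decode_theta(th, sys$layout)
  c1 <- c(dec$b1, dec$h1_1, dec$h1_2, dec$h1_3,
          dec$h1_4_1, dec$h1_4_2, dec$h1_4_3)
  C2top <- rbind(dec$h2_1, dec$h2_2)
  quad <- names(dec)[grepl("^h2_4", names(dec))]
  C2low <- do.call(rbind, c(list(dec$h2_3), dec[quad]))
  C2 <- rbind(cbind(C2top, matrix(0i, nrow(C2top), ncol(C2low))),
              cbind(matrix(0i, nrow(C2low), ncol(C2top)), C2low))
  for (ix in c(1, 17, 40)) {
    px <- build_phi_xi(sys, ix)
    lhs <- sum(c1 * px$Phi) + sum(diag(Conj(t(C2)) %*% px$Xi))
    expect_lt(Mod(lhs - sys$q[ix]), 1e-9)
  }
})

test_that("N = 1 spatio-temporal layout extends the temporal one by two blocks", {
  sp <- trig_space(3, 30 * pi)
  lt <- dnp_layout(sp, sp, "temporal")
  ls1 <- dnp_layout(sp, sp, "spatiotemporal", N = 1)
  expect_equal(length(ls1$blocks), length(lt$blocks) + 2L)
  expect_true(all(c("h1_4_1", "h2_4_1_1") %in% names(ls1$blocks)))
})

test_that("zero stimuli with b1 = 0 give zero measurements and stimulus blocks", {
  sp <- trig_space(3, 30 * pi)
  m <- dnp_temporal(volterra(0, space = sp), volterra(1, space = sp),
                    volterra(0, space = sp))
  zero <- list(trig_signal(sp))
  tr <- suppressWarnings(simulate_trials(m, zero, T_samples = 5))
  sys <- suppressWarnings(build_temporal_system(tr))
  expect_equal(max(abs(sys$q)), 0)
  expect_equal(max(Mod(sys$U)), 0)
})

test_that("t_k outside the period and few trials are flagged", {
  m <- small_temporal_model(seed = 3)
  set.seed(99)
  st <- random_stimuli(m$space_in, 2, sigma = 0.2)
  tr <- suppressWarnings(simulate_trials(m, st, T_samples = 4))
  expect_error(dnp_trials(tr$inputs, tr$responses, m$space_in, m$space_out,
                          t_k = c(0, m$space_in$S * 1.1)),
               "within one period")
  expect_warning(build_temporal_system(tr), "dense generalized-sampling bound")
})

test_that("extra consistent measurements leave the dense solution unchanged", {
  m <- small_temporal_model(L = 2, seed = 13, w1 = c(0.5, 0.2, 0.1, 0.05, 0.02),
                            w2 = c(0.3, 0.1), w3 = c(0.2, 0.1))
  set.seed(103)
  st <- random_stimuli(m$space_in, 30, sigma = 0.3)
  tr1 <- simulate_trials(m, st, T_samples = 6)
  tr2 <- simulate_trials(m, st, T_samples = 12)
  s1 <- build_temporal_system(tr1)
  s2 <- build_temporal_system(tr2)
  x1 <- qr.solve(s1$A, s1$q)
  x2 <- qr.solve(s2$A, s2$q)
  expect_lt(max(abs(x1 - x2)), 1e-8)
})
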