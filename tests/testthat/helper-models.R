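# shared fixtures: random real signals and small random DNP models

rand_real_signal <- function(space, sigma = 1) {
  random_stimuli(space, 1, sigma = sigma)[[1]]
}

rand_lowrank_k2 <- function(space, weights, sigma = 0.4) {
  comps <- lapply(seq_along(weights), function(i) rand_real_signal(space, sigma))
  kernel2_from_factors(space, weights, comps)
}

small_temporal_model <- function(L = 4, Omega = 40 * pi, seed = 3,
                                 w1 = c(0.8, -0.3), w2 = 0.5, w3 = 0.4) {
  set.seed(seed)
  sp <- trig_space(L, Omega)
  spo <- trig_space(L, Omega)
  dnp_temporal(
    T1 = volterra(0.1, kernel1(sp, rand_real_signal(sp, 0.5)$coeffs),
                  rand_lowrank_k2(sp, w1)),
    T2 = volterra(0.6, kernel1(sp, rand_real_signal(sp, 0.2)$coeffs),
                  rand_lowrank_k2(sp, w2)),
    T3 = volterra(0.4, kernel1(spo, rand_real_signal(spo, 0.2)$coeffs),
                  rand_lowrank_k2(spo, w3))
  )
}

small_spatial_model <- function(N = 3, L = 4, Omega = 20 * pi) {
  example_spatial_model(N, trig_space(L, Omega), trig_space(L, Omega))
}

example3_include <- function(N = 4) {
  c("b1", "h1_1", "h1_2", sprintf("h1_4_%d", seq_len(N)),
    unlist(lapply(seq_len(N), function(i) sapply(i:N, function(j)
      sprintf("h2_4_%d_%d", i, j)))))
}
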