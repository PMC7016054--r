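#' Random bandlimited stimuli with i.i.d. Gaussian coefficients
#'
#' Draws `M` real-valued signals from a trigonometric-polynomial space:
#' independent Gaussian coefficients for `l >= 0` (per-coefficient variance
#' `sigma^2`, split evenly over real and imaginary parts for `l > 0`), with
#' conjugate-symmetric completion for `l < 0`.
#'
#' @param space a [trig_space()].
#' @param M number of stimuli.
#' @param sigma per-coefficient standard deviation.
#' @param seed optional integer seed (local to this call).
#' @return list of `M` real-valued [trig_signal()]s.
#' @export
random_stimuli <- function(space, M, sigma = 1, seed = NULL) {
  if (M < 1) stop("M must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  L <- space$L
  lapply(seq_len(M), function(m) {
    a0 <- stats::rnorm(1, 0, sigma)
    if (L > 0) {
      ap <- complex(real = stats::rnorm(L, 0, sigma / sqrt(2)),
                    imaginary = stats::rnorm(L, 0, sigma / sqrt(2)))
      coeffs <- c(Conj(rev(ap)), a0, ap)
    } else {
      coeffs <- as.complex(a0)
    }
    trig_signal(space, coeffs, label = sprintf("stim%03d", m))
  })
}

# gamma-tone shape t^3 e^{-100 pi t} cos(w t): the building block of all
# printed temporal-example kernels
gtone <- function(amp, wcos) {
  force(amp); force(wcos)
  function(t) amp * t^3 * exp(-100 * pi * t) * cos(wcos * t)
}

#' Temporal example model (printed kernel set)
#'
#' The temporal DNP fixture with the six printed analytic kernels: three
#' first-order gamma-tone filters and three second-order kernels, each the
#' sum of two separable gamma-tone products (hence numerical rank at most 2
#' after projection). Kernels are projected into the model spaces; second-
#' order kernels use the exactness of projection on separable products
#' (\eqn{P_2(f \otimes g) = P_1 f \otimes P_1 g}). The printed set specifies
#' no zeroth-order kernels; this fixture uses `b1 = 0`, `b2 = b3 = 0.5`
#' (recorded in the scenario configuration).
#'
#' @param space_in input space, default `trig_space(10, 100*pi)` (S = 0.2 s).
#' @param space_out output space, default equal to the input space.
#' @return a [dnp_temporal()] model.
#' @export
example_temporal_model <- function(space_in = trig_space(10, 100 * pi),
                                   space_out = trig_space(10, 100 * pi)) {
  p1 <- function(f, sp) project1(f, sp)
  h11 <- p1(gtone(2.472e10, 36 * pi), space_in)
  h12 <- p1(gtone(3.117e8, 20 * pi), space_in)
  h13 <- p1(gtone(4.753e8, 52 * pi), space_out)

  f52  <- p1(gtone(1, 52 * pi),  space_in)
  f100 <- p1(gtone(1, 100 * pi), space_in)
  f68  <- p1(gtone(1, 68 * pi),  space_in)
  f84  <- p1(gtone(1, 84 * pi),  space_in)
  h21 <- kernel2_from_factors(space_in, c(9.038e19, 5.3467e14), list(f52, f100))
  h22 <- kernel2_from_factors(space_in, c(1.533e19, 5.970e14), list(f68, f84))
  f100o <- p1(gtone(1, 100 * pi), space_out)
  f84o  <- p1(gtone(1, 84 * pi),  space_out)
  h23 <- kernel2_from_factors(space_out, c(6.771e19, 5.970e16), list(f100o, f84o))

  dnp_temporal(
    T1 = volterra(0, h11, h21, space_in),
    T2 = volterra(0.5, h12, h22, space_in),
    T3 = volterra(0.5, h13, h23, space_out)
  )
}

#' Spatio-temporal example model (printed kernel set)
#'
#' The four-channel amacrine-cell fixture: shared feedforward filters
#' \eqn{h_1^1(t) = h_1^2(t) = 25 t e^{-25 t}}, per-channel feedback filters
#' \eqn{h_1^{i4}(t) = e^{-(i-2)^2/4} (25 - 600 t) e^{-25 t}}, and rank-1
#' pairwise feedback kernels
#' \eqn{h_2^{ij4} = 5000\, e^{-(i-2)^2/4} e^{-(j-2)^2/4}
#' (25 t_1 e^{-25 t_1}) (25 t_2 e^{-25 t_2})}; all other kernels are zero,
#' so the zeroth-order split is `b2 = 1`, `b1 = b3 = b4 = 0`. The pairwise
#' kernels satisfy \eqn{h^{ij4} = h^{ji4}} and the fixture flags them so.
#'
#' @param N channel count (the spatial profile is centred on channel 2).
#' @param space_in,space_out model spaces; defaults L = 8, Omega = 40*pi
#'   (period 0.4 s, 17 coefficients per linear filter).
#' @return a [dnp_spatiotemporal()] model.
#' @export
example_spatial_model <- function(N = 4,
                                  space_in = trig_space(8, 40 * pi),
                                  space_out = trig_space(8, 40 * pi)) {
  halpha <- project1(function(t) 25 * t * exp(-25 * t), space_in)
  halpha_o <- project1(function(t) 25 * t * exp(-25 * t), space_out)
  amp <- function(i) exp(-0.25 * (i - 2)^2)
  h14 <- lapply(seq_len(N), function(i) {
    k <- project1(function(t) amp(i) * (25 - 600 * t) * exp(-25 * t), space_out)
    k$label <- sprintf("h1_%d4", i)
    k
  })
  h24 <- lapply(seq_len(N), function(i) lapply(seq_len(N), function(j) {
    kernel2_from_factors(space_out, 5000 * amp(i) * amp(j), list(halpha_o))
  }))
  dnp_spatiotemporal(
    N = N,
    T1 = volterra(0, halpha, NULL, space_in),
    T2 = volterra(1, kernel1(space_in, halpha$coeffs), NULL, space_in),
    T3 = volterra(0, NULL, NULL, space_out),
    mvp = mvp(N, b4 = 0, h1_list = h14, h2_grid = h24,
              symmetric_pairs = TRUE, space = space_out)
  )
}
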