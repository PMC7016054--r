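#' Default simulation grid size
#'
#' `16 * (2L + 1)` uniform points per period, rounded up to a multiple of
#' `T_samples` when given so measurement sample times fall exactly on stored
#' grid samples.
#' @param space input [trig_space()].
#' @param T_samples optional number of measurement samples per trial.
#' @export
default_grid_size <- function(space, T_samples = NULL) {
  G <- 16L * space$dim
  if (!is.null(T_samples) && T_samples > 0L) {
    G <- as.integer(ceiling(G / T_samples) * T_samples)
  }
  G
}

# --- fixed-point engine -----------------------------------------------------
#
# Solves v .* (den_ff + fb(v)) = num for the whole trajectory at once.
# Stage 1: damped Picard v <- num / (den_ff + fb(v)) — cheap, derivative-free,
#   and reflects the block-diagram feedback semantics; the damping factor is
#   halved when the iteration oscillates.
# Stage 2: damped Newton on F(v) = v .* (den_ff + fb(v)) - num with the
#   analytic Jacobian supplied by the caller and a backtracking line search.
#   The divisive loop gain of the printed example kernels is close to one,
#   where plain Picard stalls; Newton converges quadratically from the
#   Picard iterate.
fp_solve <- function(num, den_ff, fb, jac_fb, v0, tol, max_iter, eps_den,
                     picard_iter = 30L) {
  v <- v0
  theta <- 1
  prev_delta <- Inf
  iterations <- 0L
  for (i in seq_len(picard_iter)) {
    iterations <- iterations + 1L
    den <- den_ff + fb(v)
    if (min(den) <= eps_den) break   # leave the rest to Newton
    step <- num / den - v
    delta <- max(abs(step))
    v_try <- v + theta * step
    v <- v_try
    if (delta <= tol) break
    if (delta > prev_delta) theta <- max(theta / 2, 0.125)
    prev_delta <- delta
  }
  Fres <- function(v) v * (den_ff + fb(v)) - num
  if (!all(is.finite(v))) {
    stop("denominator degeneracy: divisive denominator fell to ",
         format(min(den_ff + fb(0 * num))), " (<= ", eps_den, ")")
  }
  Fv <- Fres(v)
  fnorm <- max(abs(Fv))
  if (!is.finite(fnorm)) {
    stop("denominator degeneracy: non-finite fixed-point residual ",
         "(divisive denominator at or below ", eps_den, ")")
  }
  converged <- FALSE
  while (iterations < max_iter) {
    if (fnorm <= tol) { converged <- TRUE; break }
    iterations <- iterations + 1L
    den <- den_ff + fb(v)
    J <- diag(as.vector(den)) + diag(as.vector(v)) %*% jac_fb(v)
    step <- tryCatch(solve(J, as.vector(Fv)),
                     error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    improved <- FALSE
    for (ls in 1:30) {
      v_new <- v - alpha * array(step, dim = dim(v) %||% length(v))
      F_new <- Fres(v_new)
      if (max(abs(F_new)) < fnorm) {
        v <- v_new; Fv <- F_new; fnorm <- max(abs(F_new)); improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
  }
  if (fnorm <= 10 * tol) converged <- TRUE
  den <- den_ff + fb(v)
  # degeneracy is judged at the solution: transient Newton iterates may
  # cross small denominators harmlessly
  list(v = v, iterations = iterations, converged = converged,
       residual = max(abs(v * den - num)), min_denominator = min(den))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derivative of the Volterra feedback output (on the grid) with respect to
# the projected coefficient vector c: conv term + bilinear term (natural
# order, using d/dc [ S w' Cn w ] with w = c .* e(t))
vp_jac_wrt_coeffs <- function(T_, c, E) {
  sp <- T_$space
  D <- matrix(0i, nrow(E), sp$dim)
  if (!is.null(T_$h1)) {
    D <- D + E * matrix(sqrt(sp$S) * T_$h1$coeffs, nrow(E), sp$dim, byrow = TRUE)
  }
  if (!is.null(T_$h2)) {
    Cn <- k2_nat(T_$h2)
    W <- E * matrix(c, nrow(E), sp$dim, byrow = TRUE)
    D <- D + sp$S * (((W %*% t(Cn)) * E) + ((W %*% Cn) * E))
  }
  D
}

#' Simulate a temporal divisive normalization processor
#'
#' Solves the implicit equation \eqn{v = T^1 u / (T^2 u + T^3 v)} on a
#' uniform grid over one period: damped whole-trajectory Picard iteration
#' \eqn{v^{(i+1)} = T^1 u / (T^2 u + T^3 v^{(i)})} from
#' \eqn{v^{(0)} = T^1 u / (T^2 u + b^3)}, followed by a damped-Newton
#' refinement of the fixed-point residual (the divisive loop gain of
#' realistic kernel sets sits near one, where plain Picard stalls). The
#' feedback processor is applied to the output-space projection of the
#' iterate (the feedback filters are bandlimited to the output space, so
#' this loses nothing), and the same grid projection is reused verbatim by
#' the measurement assembly.
#'
#' @param dnp a [dnp_temporal()] model.
#' @param u input [trig_signal()] in the model's input space.
#' @param n_grid number of grid points per period (default `16 * dim`).
#' @param tol sup-norm tolerance on the fixed-point residual.
#' @param max_iter iteration cap; non-convergence is an error.
#' @param eps_den denominator-positivity guard: the run aborts if the
#'   divisive denominator falls to or below this value at the solution.
#' @return A `dnp_sim` object: `v` (real samples), `grid` (times),
#'   `iterations`, `residual` (max of `|v * denominator - numerator|`),
#'   `converged`, `min_denominator`, and `vproj` (output-space projection
#'   coefficients of `v`).
#' @export
simulate_temporal <- function(dnp, u, n_grid = NULL, tol = 1e-12,
                              max_iter = 500L, eps_den = 1e-9) {
  spo <- dnp$space_out
  G <- if (is.null(n_grid)) default_grid_size(dnp$space_in) else as.integer(n_grid)
  tg <- canonical_grid(dnp$space_in, G)
  num <- vp_apply(dnp$T1, u, tg)
  den_ff <- vp_apply(dnp$T2, u, tg)
  Eo <- basis_eval(spo, tg)
  Pmat <- (spo$S / G) * t(Conj(Eo))        # grid samples -> coefficients
  fb <- function(v) {
    vproj <- trig_signal(spo, as.vector(Pmat %*% v))
    vp_apply(dnp$T3, vproj, tg)
  }
  jac_fb <- function(v) {
    c <- as.vector(Pmat %*% v)
    Re(vp_jac_wrt_coeffs(dnp$T3, c, Eo) %*% Pmat)
  }
  v0 <- num / (den_ff + dnp$T3$b)
  res <- fp_solve(num, den_ff, fb, jac_fb, v0, tol, max_iter, eps_den)
  if (res$min_denominator <= eps_den) {
    stop("denominator degeneracy: divisive denominator fell to ",
         format(res$min_denominator), " (<= ", eps_den, ")")
  }
  if (!res$converged) {
    stop("no stable fixed point found within ", max_iter, " iterations ",
         "(last residual ", format(res$residual), ")")
  }
  structure(list(v = res$v, grid = tg, iterations = res$iterations,
                 residual = res$residual, converged = res$converged,
                 min_denominator = res$min_denominator,
                 vproj = as.vector(Pmat %*% res$v), space_out = spo),
            class = "dnp_sim")
}

#' Simulate a spatio-temporal divisive normalization processor
#'
#' As [simulate_temporal()], with the amacrine-cell feedback \eqn{L^4 v} in
#' every channel's denominator; all channels are updated jointly.
#'
#' @param dnp a [dnp_spatiotemporal()] model.
#' @param u_list list of `N` input [trig_signal()]s.
#' @inheritParams simulate_temporal
#' @return A `dnp_sim` object; `v` is an `N x n_grid` matrix and `vproj` a
#'   `dim_out x N` coefficient matrix.
#' @export
simulate_spatiotemporal <- function(dnp, u_list, n_grid = NULL, tol = 1e-12,
                                    max_iter = 500L, eps_den = 1e-9) {
  N <- dnp$N
  if (length(u_list) != N) stop("expected ", N, " input signals")
  spo <- dnp$space_out
  G <- if (is.null(n_grid)) default_grid_size(dnp$space_in) else as.integer(n_grid)
  tg <- canonical_grid(dnp$space_in, G)
  num <- t(vapply(u_list, function(u) vp_apply(dnp$T1, u, tg), numeric(G)))
  den_ff <- t(vapply(u_list, function(u) vp_apply(dnp$T2, u, tg), numeric(G)))
  Eo <- basis_eval(spo, tg)
  Pmat <- (spo$S / G) * t(Conj(Eo))
  proj_all <- function(v) Pmat %*% t(v)      # dim_o x N
  fb <- function(v) {
    C <- proj_all(v)
    vsig <- lapply(seq_len(N), function(n) trig_signal(spo, C[, n]))
    l4 <- mvp_apply(dnp$mvp, vsig, tg)
    t3 <- t(vapply(vsig, function(vs) vp_apply(dnp$T3, vs, tg), numeric(G)))
    sweep(t3, 2, l4, "+")
  }
  # Jacobian of the stacked residual; unknown ordering: channel-major rows
  # of v flattened as c(t(v))? We flatten v (N x G) column-major as R does:
  # index = n + (g-1)*N.
  jac_fb_full <- function(v) {
    C <- proj_all(v)
    # d fb_n / d v_m = [delta_nm * D_T3(c_n) + D_L4,m(C)] %*% Pmat
    D_T3 <- lapply(seq_len(N), function(n)
      Re(vp_jac_wrt_coeffs(dnp$T3, C[, n], Eo) %*% Pmat))
    D_L4 <- lapply(seq_len(N), function(m) {
      D <- matrix(0i, G, spo$dim)
      h <- dnp$mvp$h1_list[[m]]
      if (!is.null(h)) {
        D <- D + Eo * matrix(sqrt(spo$S) * h$coeffs, G, spo$dim, byrow = TRUE)
      }
      for (i in seq_len(N)) for (j in seq_len(N)) {
        k <- dnp$mvp$h2_grid[[i]][[j]]
        if (is.null(k)) next
        Cn <- k2_nat(k)
        if (i == m) {
          Wj <- Eo * matrix(C[, j], G, spo$dim, byrow = TRUE)
          D <- D + spo$S * ((Wj %*% t(Cn)) * Eo)
        }
        if (j == m) {
          Wi <- Eo * matrix(C[, i], G, spo$dim, byrow = TRUE)
          D <- D + spo$S * ((Wi %*% Cn) * Eo)
        }
      }
      Re(D %*% Pmat)
    })
    J <- matrix(0, N * G, N * G)
    idx <- function(n) seq.int(n, N * G, by = N)
    for (n in seq_len(N)) for (m in seq_len(N)) {
      Jnm <- D_L4[[m]]
      if (n == m) Jnm <- Jnm + D_T3[[n]]
      J[idx(n), idx(m)] <- Jnm
    }
    J
  }
  fb_flat <- function(vflat) {
    as.vector(fb(matrix(vflat, N, G)))
  }
  jac_flat <- function(vflat) jac_fb_full(matrix(vflat, N, G))
  v0 <- num / (den_ff + dnp$T3$b + dnp$mvp$b4)
  res <- fp_solve(as.vector(num), as.vector(den_ff), fb_flat, jac_flat,
                  as.vector(v0), tol, max_iter, eps_den)
  if (res$min_denominator <= eps_den) {
    stop("denominator degeneracy: divisive denominator fell to ",
         format(res$min_denominator), " (<= ", eps_den, ")")
  }
  if (!res$converged) {
    stop("no stable fixed point found within ", max_iter, " iterations ",
         "(last residual ", format(res$residual), ")")
  }
  v <- matrix(res$v, N, G)
  structure(list(v = v, grid = tg, iterations = res$iterations,
                 residual = res$residual, converged = res$converged,
                 min_denominator = res$min_denominator,
                 vproj = proj_all(v), space_out = spo),
            class = "dnp_sim")
}

#' @export
print.dnp_sim <- function(x, ...) {
  nch <- if (is.matrix(x$v)) nrow(x$v) else 1L
  cat(sprintf(
    "DNP simulation: %d channel(s), %d grid points, %d iterations\n",
    nch, length(x$grid), x$iterations))
  cat(sprintf("  fixed-point residual %.3e, min denominator %.4g\n",
              x$residual, x$min_denominator))
  invisible(x)
}

#' Trigonometric (spectral) interpolation from uniform-grid samples
#'
#' Interpolates a smooth periodic function known on the canonical uniform
#' grid to arbitrary times via its discrete Fourier series. Used to read
#' responses at sample times that do not fall on the simulation grid.
#'
#' @param y real samples on the canonical grid over `[0, S)`.
#' @param S period (seconds).
#' @param t_out times at which to interpolate.
#' @export
trig_interp <- function(y, S, t_out) {
  G <- length(y)
  a <- stats::fft(y) / G
  half <- floor((G - 1) / 2)
  if (G %% 2 == 0) {
    ks <- c(0:(G / 2 - 1), c(G / 2, -G / 2), -((G / 2 - 1):1))
    a <- c(a[1:(G / 2)], 0.5 * a[G / 2 + 1], 0.5 * a[G / 2 + 1],
           a[(G / 2 + 2):G])
  } else {
    ks <- c(0:half, -(half:1))
  }
  ph <- outer(t_out, 2 * pi * ks / S)
  as.vector(Re(exp(1i * ph) %*% a))
}
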