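#' Trigonometric-polynomial Hilbert space
#'
#' Constructs the space of trigonometric polynomials of order `L` and
#' bandwidth `Omega` (rad/s): the span of the orthonormal basis
#' \deqn{e_l(t) = \exp(j l \Omega t / L) / \sqrt{S}, \qquad l = -L, \dots, L,}
#' over one period \eqn{S = 2\pi L / \Omega}. Signals in the space are
#' extended periodically. The same constructor serves both the input space
#' (order \eqn{L}, bandwidth \eqn{\Omega}) and the output space (order
#' \eqn{L^o}, bandwidth \eqn{\Omega^o}).
#'
#' @param L nonnegative integer, order of the space; the dimension is `2L+1`.
#' @param Omega positive bandwidth in rad/s.
#' @param S_override period in seconds; only allowed for `L = 0`, where the
#'   period is not determined by `Omega`.
#' @return An object of class `trig_space` with fields `L`, `Omega`, `S`,
#'   `dim`, `omega1` (fundamental frequency `2*pi/S`) and `l` (basis indices).
#' @examples
#' H1 <- trig_space(10, 100 * pi)   # S = 0.2 s, dim = 21
#' @export
trig_space <- function(L, Omega, S_override = NULL) {
  if (length(L) != 1L || L < 0 || L != round(L)) {
    stop("`L` must be a single nonnegative integer")
  }
  if (length(Omega) != 1L || !is.finite(Omega) || Omega <= 0) {
    stop("`Omega` must be a single positive number")
  }
  L <- as.integer(L)
  if (!is.null(S_override)) {
    if (L != 0L) stop("`S_override` is only allowed when L = 0")
    if (S_override <= 0) stop("`S_override` must be positive")
    S <- S_override
  } else {
    if (L == 0L) stop("for L = 0 the period must be supplied via `S_override`")
    S <- 2 * pi * L / Omega
  }
  structure(
    list(L = L, Omega = Omega, S = S, dim = 2L * L + 1L,
         omega1 = 2 * pi / S, l = seq.int(-L, L)),
    class = "trig_space"
  )
}

#' @export
print.trig_space <- function(x, ...) {
  cat(sprintf(
    "Trigonometric polynomial space: L = %d, Omega = %.6g rad/s, S = %.6g s, dim = %d\n",
    x$L, x$Omega, x$S, x$dim))
  invisible(x)
}

#' @export
format.trig_space <- function(x, ...) {
  sprintf("H(L=%d, Omega=%.4g, S=%.4g)", x$L, x$Omega, x$S)
}

same_space <- function(a, b, tol = 1e-9) {
  a$L == b$L && abs(a$S - b$S) <= tol * a$S && abs(a$Omega - b$Omega) <= tol * a$Omega
}

#' Evaluate the orthonormal basis on a time grid
#'
#' Returns the matrix `E` with `E[i, l + L + 1] = e_l(t[i])`.
#'
#' @param space a [trig_space()].
#' @param t numeric vector of times (seconds); periodic extension applies.
#' @return complex matrix, `length(t)` by `dim`.
#' @export
basis_eval <- function(space, t) {
  ph <- outer(t, space$l * space$omega1)
  exp(1i * ph) / sqrt(space$S)
}

#' Signals as basis-coefficient vectors
#'
#' A signal \eqn{u(t) = \sum_l a_l e_l(t)} is stored as its complex
#' coefficient vector indexed \eqn{l = -L, \dots, L}. Real-valued signals
#' satisfy the conjugate symmetry \eqn{a_{-l} = \overline{a_l}}.
#'
#' @param space a [trig_space()].
#' @param coeffs complex vector of length `space$dim` (defaults to zeros).
#' @param label free-text label.
#' @export
trig_signal <- function(space, coeffs = NULL, label = "") {
  if (is.null(coeffs)) coeffs <- complex(space$dim)
  if (length(coeffs) != space$dim) {
    stop("`coeffs` must have length 2L+1 = ", space$dim)
  }
  structure(list(space = space, coeffs = as.complex(coeffs), label = label),
            class = "trig_signal")
}

#' @export
print.trig_signal <- function(x, ...) {
  cat(sprintf("trig_signal%s in %s, ||a|| = %.4g\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              format(x$space), sqrt(sum(Mod(x$coeffs)^2))))
  invisible(x)
}

#' Check conjugate symmetry of a coefficient vector
#'
#' @param coeffs complex coefficient vector indexed `-L..L`.
#' @param tol tolerance on the maximum deviation.
#' @export
is_conj_symmetric <- function(coeffs, tol = 1e-12) {
  max(Mod(coeffs - Conj(rev(coeffs)))) <= tol * max(1, max(Mod(coeffs)))
}

#' Evaluate a signal at arbitrary times
#'
#' Computes \eqn{u(t) = \sum_l a_l e_l(t)} with periodic extension. When the
#' coefficients are conjugate-symmetric the result is real and the (numerically
#' zero) imaginary part is dropped; otherwise the complex value is returned.
#'
#' @param sig a [trig_signal()] (or any object with `space` and `coeffs`).
#' @param t numeric vector of times.
#' @param complex_value return the raw complex sum without dropping the
#'   imaginary part.
#' @export
eval_signal <- function(sig, t, complex_value = FALSE) {
  val <- as.vector(basis_eval(sig$space, t) %*% sig$coeffs)
  if (complex_value) return(val)
  if (is_conj_symmetric(sig$coeffs, tol = 1e-9)) Re(val) else val
}

#' L2 inner product of two signals (conjugate-linear in the second argument)
#' @param f,g signals on the same space.
#' @export
inner1 <- function(f, g) {
  stopifnot(same_space(f$space, g$space))
  sum(f$coeffs * Conj(g$coeffs))
}

#' Project samples on the canonical uniform grid onto a space
#'
#' The canonical grid for `G` samples is `t_g = (g-1) * S / G`, `g = 1..G`.
#' The projection coefficients are computed by the periodic trapezoid
#' (rectangle) rule, `a_l = (S/G) * sum_g y_g * Conj(e_l(t_g))`, which is the
#' discrete realization of the projection operator used throughout the
#' package: the simulator and the measurement assembly share it verbatim so
#' that feedback projections are bit-identical on both paths.
#'
#' @param space target [trig_space()].
#' @param y real (or complex) samples on the canonical grid of length `G`.
#' @return complex coefficient vector of length `space$dim`.
#' @export
project_grid <- function(space, y) {
  G <- length(y)
  if (G < 2L * space$dim) {
    stop("grid too coarse for projection: need at least ", 2L * space$dim,
         " samples, got ", G)
  }
  tg <- (seq_len(G) - 1) * space$S / G
  as.vector((space$S / G) * crossprod(Conj(basis_eval(space, tg)), y))
}

canonical_grid <- function(space, G) (seq_len(G) - 1) * space$S / G

#' Project an integrable function onto a trigonometric-polynomial space
#'
#' Orthogonal (reproducing-kernel) projection of `f` onto the span of the
#' basis, computed by uniform-grid quadrature over one period. Because the
#' integrands are smooth and periodic, the periodic trapezoid rule converges
#' spectrally; the default grid holds 32 points per basis function. The
#' projection is idempotent: members of the space are reproduced exactly (to
#' quadrature accuracy).
#'
#' @param f either a function of `t` or a list `list(t = , y = )` of samples
#'   on a uniform grid over `[0, S)`.
#' @param space target [trig_space()].
#' @param n_quad number of quadrature points for a callable `f`.
#' @return a [kernel1()] (a `trig_signal` subclass) holding the coefficients.
#' @export
project1 <- function(f, space, n_quad = NULL) {
  if (is.function(f)) {
    G <- if (is.null(n_quad)) max(32L * space$dim, 1024L) else as.integer(n_quad)
    if (G < 8L * space$dim) {
      stop("quadrature grid too coarse: need at least 8*(2L+1) = ",
           8L * space$dim, " points")
    }
    y <- f(canonical_grid(space, G))
  } else if (is.list(f) && !is.null(f$y)) {
    y <- f$y
    if (length(y) < 8L * space$dim) {
      stop("sample grid too coarse: need at least 8*(2L+1) = ",
           8L * space$dim, " points (aliasing guard)")
    }
    if (!is.null(f$t)) {
      dt <- diff(f$t)
      if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("sample grid must be uniform")
    }
  } else {
    stop("`f` must be a function or a list with components t, y")
  }
  kernel1(space, project_grid(space, y))
}

#' Coefficients of the time-reversed, shifted signal
#'
#' Returns the coefficient vector of \eqn{t \mapsto u(t_k - t)} as an element
#' of the same space: \eqn{b_l = a_{-l} \exp(-j l \omega_1 t_k)}. This is the
#' representation of the first-order sampling functions
#' \eqn{\phi(t) = u(t_k - t)} used by the measurement assembly.
#'
#' @param sig a [trig_signal()].
#' @param t_k shift in seconds.
#' @return complex coefficient vector of length `dim`.
#' @export
reversed_shift_coeffs <- function(sig, t_k) {
  sp <- sig$space
  rev(sig$coeffs) * exp(-1i * sp$l * sp$omega1 * t_k)
}

#' Parseval norm of a signal
#' @param sig a [trig_signal()].
#' @export
signal_norm <- function(sig) sqrt(sum(Mod(sig$coeffs)^2))
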