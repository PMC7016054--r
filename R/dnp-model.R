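#' Temporal divisive normalization processor
#'
#' The single-photoreceptor circuit: output \eqn{v} solves the implicit
#' divisive-feedback equation
#' \deqn{v = \frac{T^1 u}{T^2 u + T^3 v},}
#' where \eqn{T^1, T^2} are feedforward Volterra processors on the input
#' space and \eqn{T^3} a feedback processor on the output space. The output
#' is invariant under joint scaling of numerator and denominator, so the
#' zeroth-order kernels are normalized to \eqn{b^2 + b^3 = 1}.
#'
#' @param T1,T2 feedforward [volterra()] processors on the input space.
#' @param T3 feedback [volterra()] processor on the output space.
#' @param space_in,space_out input/output [trig_space()]s; inferred from the
#'   processors when omitted. Both must share the same period.
#' @param normalize_check enforce the `b2 + b3 = 1` convention. Disable only
#'   for diagnostics that exercise the joint numerator/denominator scale
#'   invariance.
#' @export
dnp_temporal <- function(T1, T2, T3, space_in = NULL, space_out = NULL,
                         normalize_check = TRUE) {
  if (is.null(space_in)) space_in <- T1$space
  if (is.null(space_out)) space_out <- T3$space
  if (normalize_check && abs(T2$b + T3$b - 1) > 1e-12) {
    stop("normalization requires b2 + b3 = 1 (got ", T2$b + T3$b, ")")
  }
  if (abs(space_in$S - space_out$S) > 1e-12 * space_in$S) {
    stop("input and output spaces must share the same period")
  }
  structure(list(T1 = T1, T2 = T2, T3 = T3,
                 space_in = space_in, space_out = space_out),
            class = "dnp_temporal")
}

#' @export
print.dnp_temporal <- function(x, ...) {
  cat("Temporal divisive normalization processor\n")
  cat("  input  space:", format(x$space_in), "\n")
  cat("  output space:", format(x$space_out), "\n")
  cat(sprintf("  b1 = %.4g, b2 = %.4g, b3 = %.4g\n", x$T1$b, x$T2$b, x$T3$b))
  invisible(x)
}

#' Spatio-temporal divisive normalization processor
#'
#' `N` photoreceptor channels, each a copy of the temporal circuit with
#' shared \eqn{T^1, T^2, T^3}, coupled through the amacrine-cell [mvp()]
#' feedback block:
#' \deqn{v^n = \frac{T^1 u^n}{T^2 u^n + T^3 v^n + L^4 \mathbf v}.}
#' Normalization: \eqn{b^2 + b^3 + b^4 = 1}.
#'
#' @param N channel count.
#' @param T1,T2,T3 shared per-channel [volterra()] processors.
#' @param mvp the cross-channel feedback [mvp()] block.
#' @inheritParams dnp_temporal
#' @export
dnp_spatiotemporal <- function(N, T1, T2, T3, mvp,
                               space_in = NULL, space_out = NULL,
                               normalize_check = TRUE) {
  if (is.null(space_in)) space_in <- T1$space
  if (is.null(space_out)) space_out <- mvp$space
  if (mvp$N != N) stop("MVP channel count must equal N")
  if (normalize_check && abs(T2$b + T3$b + mvp$b4 - 1) > 1e-12) {
    stop("normalization requires b2 + b3 + b4 = 1 (got ",
         T2$b + T3$b + mvp$b4, ")")
  }
  if (abs(space_in$S - space_out$S) > 1e-12 * space_in$S) {
    stop("input and output spaces must share the same period")
  }
  structure(list(N = as.integer(N), T1 = T1, T2 = T2, T3 = T3, mvp = mvp,
                 space_in = space_in, space_out = space_out),
            class = "dnp_spatiotemporal")
}

#' @export
print.dnp_spatiotemporal <- function(x, ...) {
  cat(sprintf("Spatio-temporal divisive normalization processor, N = %d\n", x$N))
  cat("  input  space:", format(x$space_in), "\n")
  cat("  output space:", format(x$space_out), "\n")
  cat(sprintf("  b1 = %.4g, b2 = %.4g, b3 = %.4g, b4 = %.4g\n",
              x$T1$b, x$T2$b, x$T3$b, x$mvp$b4))
  invisible(x)
}
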