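#' Volterra processor (order <= 2)
#'
#' The building block of the divisive-normalization circuit: a functional
#' \deqn{(T u)(t) = b + \int_D h_1(s) u(t-s)\,ds +
#'       \int_{D^2} h_2(s_1,s_2) u(t-s_1) u(t-s_2)\,ds_1 ds_2,}
#' with all integrals over one period \eqn{D = [0, S]} and periodic
#' (circular) convolution semantics. Absent kernels act as exact zeros.
#'
#' @param b real constant (zeroth-order kernel).
#' @param h1 a [kernel1()] or `NULL`.
#' @param h2 a [kernel2()] or `NULL`.
#' @param space the input [trig_space()]; inferred from the kernels when
#'   omitted.
#' @export
volterra <- function(b = 0, h1 = NULL, h2 = NULL, space = NULL) {
  if (is.null(space)) {
    space <- if (!is.null(h1)) h1$space else if (!is.null(h2)) h2$space else
      stop("supply `space` when both kernels are absent")
  }
  if (!is.null(h1) && !same_space(h1$space, space)) stop("h1 space mismatch")
  if (!is.null(h2) && !same_space(h2$space, space)) stop("h2 space mismatch")
  structure(list(b = b, h1 = h1, h2 = h2, space = space), class = "volterra")
}

#' @export
print.volterra <- function(x, ...) {
  cat(sprintf("Volterra processor on %s: b = %.4g, h1 %s, h2 %s\n",
              format(x$space), x$b,
              if (is.null(x$h1)) "absent" else "present",
              if (is.null(x$h2)) "absent" else "present"))
  invisible(x)
}

# first-order circular convolution in the coefficient domain:
# (h * u)(t) = sqrt(S) * sum_l h_l a_l e_l(t)
conv_coeffs <- function(space, h_coeffs, a_coeffs) {
  sqrt(space$S) * h_coeffs * a_coeffs
}

# second-order bilinear term on a time grid, natural-order kernel matrix:
# out(t) = S * sum_{l1 l2} Cn[l1, l2] a_{l1} a_{l2} e_{l1}(t) e_{l2}(t)
bilinear_on_grid <- function(space, Cn, a1, a2, t) {
  E <- basis_eval(space, t)
  W1 <- E * matrix(a1, nrow(E), length(a1), byrow = TRUE)
  W2 <- E * matrix(a2, nrow(E), length(a2), byrow = TRUE)
  space$S * rowSums((W1 %*% Cn) * W2)
}

#' Apply a Volterra processor to a signal on a time grid
#'
#' Evaluation is exact in the coefficient domain: the first-order path is a
#' circular convolution (diagonal in the basis), the second-order path the
#' bilinear form of the kernel coefficients over coefficient pairs. Note the
#' second-order output contains frequencies up to twice the space bandwidth,
#' so samples (not a `trig_signal`) are returned.
#'
#' @param T_ a [volterra()] processor.
#' @param u a [trig_signal()] in the processor's input space.
#' @param t numeric vector of evaluation times.
#' @param complex_value keep complex values (diagnostics).
#' @return real (default) samples of `(T u)(t)`.
#' @export
vp_apply <- function(T_, u, t, complex_value = FALSE) {
  if (!same_space(u$space, T_$space)) {
    stop("signal space does not match the processor's input space")
  }
  sp <- T_$space
  val <- rep(T_$b + 0i, length(t))
  if (!is.null(T_$h1)) {
    val <- val + as.vector(basis_eval(sp, t) %*%
                             conv_coeffs(sp, T_$h1$coeffs, u$coeffs))
  }
  if (!is.null(T_$h2)) {
    val <- val + bilinear_on_grid(sp, k2_nat(T_$h2), u$coeffs, u$coeffs, t)
  }
  if (complex_value) val else Re(val)
}

#' Multi-input Volterra processor (amacrine-cell feedback block)
#'
#' Per-channel linear filters plus second-order filters on all ordered pairs
#' of channel outputs:
#' \deqn{(L^4 v)(t) = b^4 + \sum_i \int h_1^{i4}(s) v^i(t-s) ds +
#'   \sum_{i,j} \int\int h_2^{ij4}(s_1,s_2) v^i(t-s_1) v^j(t-s_2) ds_1 ds_2.}
#'
#' @param N number of input channels.
#' @param b4 real constant.
#' @param h1_list list of `N` [kernel1()] entries (or `NULL`s).
#' @param h2_grid `N x N` list-matrix (list of rows, each a list of `N`) of
#'   [kernel2()] entries (or `NULL`s).
#' @param symmetric_pairs assert `h2[[i]][[j]]` identical to `h2[[j]][[i]]`.
#' @param space the shared (output) space of the feedback filters.
#' @export
mvp <- function(N, b4 = 0, h1_list = NULL, h2_grid = NULL,
                symmetric_pairs = FALSE, space = NULL) {
  if (is.null(h1_list)) h1_list <- vector("list", N)
  if (is.null(h2_grid)) h2_grid <- lapply(seq_len(N), function(i) vector("list", N))
  stopifnot(length(h1_list) == N, length(h2_grid) == N)
  if (is.null(space)) {
    for (k in h1_list) if (!is.null(k)) { space <- k$space; break }
    if (is.null(space)) for (row in h2_grid) for (k in row) {
      if (!is.null(k)) { space <- k$space; break }
    }
    if (is.null(space)) stop("supply `space` when all kernels are absent")
  }
  if (symmetric_pairs) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      a <- h2_grid[[i]][[j]]; b <- h2_grid[[j]][[i]]
      ok <- (is.null(a) && is.null(b)) ||
        (!is.null(a) && !is.null(b) && max(Mod(a$coeffs - b$coeffs)) <=
           1e-12 * max(1, max(Mod(a$coeffs))))
      if (!ok) stop("symmetric_pairs set but h2[[", i, "]][[", j,
                    "]] differs from its transpose partner")
    }
  }
  structure(list(N = as.integer(N), b4 = b4, h1_list = h1_list,
                 h2_grid = h2_grid, symmetric_pairs = symmetric_pairs,
                 space = space),
            class = "mvp")
}

#' Apply a multi-input Volterra processor
#'
#' @param M an [mvp()].
#' @param v_list list of `N` [trig_signal()]s in the MVP's space.
#' @param t numeric vector of evaluation times.
#' @param complex_value keep complex values.
#' @export
mvp_apply <- function(M, v_list, t, complex_value = FALSE) {
  if (length(v_list) != M$N) stop("expected ", M$N, " channel signals")
  sp <- M$space
  for (v in v_list) {
    if (!same_space(v$space, sp)) stop("channel signal space mismatch")
  }
  E <- basis_eval(sp, t)
  val <- rep(M$b4 + 0i, length(t))
  for (i in seq_len(M$N)) {
    h <- M$h1_list[[i]]
    if (!is.null(h)) {
      val <- val + as.vector(E %*% conv_coeffs(sp, h$coeffs, v_list[[i]]$coeffs))
    }
  }
  for (i in seq_len(M$N)) for (j in seq_len(M$N)) {
    k <- M$h2_grid[[i]][[j]]
    if (!is.null(k)) {
      val <- val + bilinear_on_grid(sp, k2_nat(k),
                                    v_list[[i]]$coeffs, v_list[[j]]$coeffs, t)
    }
  }
  if (complex_value) val else Re(val)
}
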