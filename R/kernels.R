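#' First-order Volterra kernel
#'
#' A first-order kernel is an element of a trigonometric-polynomial space,
#' stored exactly like a signal (coefficient vector indexed `-L..L`).
#'
#' @inheritParams trig_signal
#' @export
kernel1 <- function(space, coeffs = NULL, label = "") {
  out <- trig_signal(space, coeffs, label)
  class(out) <- c("kernel1", class(out))
  out
}

#' Second-order Volterra kernel
#'
#' A bivariate kernel \eqn{h_2(t_1, t_2) = \sum_{l_1 l_2} c_{l_1 l_2}
#' e_{l_1}(t_1) e_{l_2}(t_2)} on the tensor square of a
#' trigonometric-polynomial space. The coefficient matrix is stored in the
#' reconstruction index convention: the coefficient of
#' \eqn{e_{l_1}(t_1) e_{l_2}(t_2)} sits at row `l1 + L + 1`, column
#' `L + 1 - l2` (note the reversed column index). Use [k2_nat()] /
#' [k2_store()] to convert to/from the natural `(l1 + L + 1, l2 + L + 1)`
#' ordering.
#'
#' @param space marginal [trig_space()].
#' @param coeffs complex `dim x dim` matrix in the stored convention
#'   (defaults to zeros).
#' @param symmetric flag the kernel as symmetric under `(t1, t2)` swap.
#' @export
kernel2 <- function(space, coeffs = NULL, symmetric = FALSE, label = "") {
  d <- space$dim
  if (is.null(coeffs)) coeffs <- matrix(complex(1), d, d)
  coeffs <- matrix(as.complex(coeffs), d, d)
  structure(list(space = space, coeffs = coeffs, symmetric = symmetric,
                 label = label),
            class = "kernel2")
}

#' @export
print.kernel2 <- function(x, ...) {
  sv <- svd(x$coeffs, nu = 0, nv = 0)$d
  r <- sum(sv > 1e-10 * max(sv, 1e-300))
  cat(sprintf("kernel2%s on %s^2, ||C||_F = %.4g, numerical rank %d%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              format(x$space), sqrt(sum(Mod(x$coeffs)^2)), r,
              if (x$symmetric) ", symmetric" else ""))
  invisible(x)
}

# stored (reversed-column) <-> natural column ordering; the map is an
# involution (a plain column flip), so one helper serves both directions.
flip_cols <- function(C) C[, ncol(C):1, drop = FALSE]

#' Natural-order coefficient matrix of a second-order kernel
#'
#' Returns the matrix `Cn` with `Cn[l1 + L + 1, l2 + L + 1]` multiplying
#' `e_{l1}(t1) e_{l2}(t2)`.
#' @param k a [kernel2()].
#' @export
k2_nat <- function(k) flip_cols(k$coeffs)

#' Build a kernel2 from a natural-order coefficient matrix
#' @param space marginal space.
#' @param Cn natural-order coefficient matrix.
#' @inheritParams kernel2
#' @export
k2_store <- function(space, Cn, symmetric = FALSE, label = "") {
  kernel2(space, flip_cols(Cn), symmetric = symmetric, label = label)
}

#' Evaluate a second-order kernel
#'
#' @param k a [kernel2()].
#' @param t1,t2 numeric vectors. With `pairwise = TRUE` (default when the
#'   lengths match) the value at each pair `(t1[i], t2[i])` is returned;
#'   otherwise the full outer grid `length(t1) x length(t2)` matrix.
#' @param complex_value keep the complex value instead of dropping the
#'   numerically zero imaginary part of real kernels.
#' @export
eval_kernel2 <- function(k, t1, t2, pairwise = length(t1) == length(t2),
                         complex_value = FALSE) {
  Cn <- k2_nat(k)
  E1 <- basis_eval(k$space, t1)
  E2 <- basis_eval(k$space, t2)
  val <- if (pairwise) rowSums((E1 %*% Cn) * E2) else (E1 %*% Cn) %*% t(E2)
  if (complex_value) val else Re(val)
}

#' Is a second-order kernel real-valued?
#'
#' A kernel is real iff its natural-order coefficients satisfy
#' `C[-l1, -l2] = Conj(C[l1, l2])`, i.e. the stored matrix equals its
#' reversed conjugate.
#' @param k a [kernel2()].
#' @param tol relative tolerance.
#' @export
k2_is_real <- function(k, tol = 1e-10) {
  C <- k$coeffs
  ref <- Conj(C[nrow(C):1, ncol(C):1])
  max(Mod(C - ref)) <= tol * max(1, max(Mod(C)))
}

#' Bivariate projection onto the tensor-product space
#'
#' Orthogonal projection of a bivariate function onto
#' \eqn{H_2 = H_1 \otimes H_1}, by tensor-grid quadrature:
#' `C[l1, l2] = (S/G)^2 sum f(t_i, t_j) Conj(e_{l1}(t_i) e_{l2}(t_j))`.
#'
#' @param f function of `(t1, t2)` (vectorized), or a list `list(y = )` with a
#'   `G x G` sample matrix on the canonical grid.
#' @param space marginal [trig_space()].
#' @param n_quad quadrature points per axis for a callable `f`.
#' @param symmetric flag passed to the resulting [kernel2()].
#' @export
project2 <- function(f, space, n_quad = NULL, symmetric = FALSE) {
  if (is.function(f)) {
    G <- if (is.null(n_quad)) max(16L * space$dim, 256L) else as.integer(n_quad)
    if (G < 8L * space$dim) {
      stop("quadrature grid too coarse: need at least 8*(2L+1) = ",
           8L * space$dim, " points per axis")
    }
    tg <- canonical_grid(space, G)
    Y <- outer(tg, tg, f)
  } else if (is.list(f) && !is.null(f$y)) {
    Y <- f$y
    G <- nrow(Y)
    if (G != ncol(Y)) stop("sample matrix must be square (tensor grid)")
    if (G < 8L * space$dim) {
      stop("sample grid too coarse: need at least 8*(2L+1) = ",
           8L * space$dim, " points per axis (aliasing guard)")
    }
    tg <- canonical_grid(space, G)
  } else {
    stop("`f` must be a function or a list with component y")
  }
  E <- basis_eval(space, tg)
  Cn <- (space$S / G)^2 * crossprod(Conj(E), Y %*% Conj(E))
  k2_store(space, Cn, symmetric = symmetric)
}

#' Low-rank second-order kernel from orthonormal components
#'
#' Builds \eqn{h_2(t_1, t_2) = \sum_k \lambda_k g_k(t_1) g_k(t_2)} from
#' unit-norm, mutually orthogonal components, the canonical symmetric
#' expansion of a sparse (low-rank) kernel. The coefficient matrix is the
#' weighted sum of outer products \eqn{g_k g_k^{\mathsf T}} (plain transpose:
#' the expansion has no conjugation), so its rank equals the number of
#' nonzero weights.
#'
#' @param weights numeric vector of weights \eqn{\lambda_k} (may be empty,
#'   giving the zero kernel).
#' @param components list of [kernel1()]/[trig_signal()] objects, unit norm
#'   and mutually orthogonal.
#' @param tol orthonormality tolerance.
#' @param space marginal space; required only when `components` is empty.
#' @export
make_lowrank_kernel2 <- function(weights, components, tol = 1e-8,
                                 space = NULL) {
  if (length(weights) != length(components)) {
    stop("`weights` and `components` must have equal length")
  }
  if (length(components) == 0L) {
    if (is.null(space)) stop("supply `space` for an empty component list")
    return(k2_store(space, matrix(0i, space$dim, space$dim), symmetric = TRUE))
  }
  sp <- components[[1]]$space
  d <- sp$dim
  Cn <- matrix(complex(1), d, d)
  if (length(weights)) {
    Gm <- vapply(components, function(g) g$coeffs, complex(d))
    Gm <- matrix(Gm, nrow = d)
    gram <- Conj(t(Gm)) %*% Gm
    if (max(Mod(gram - diag(ncol(Gm)))) > tol) {
      stop("components must be unit-norm and mutually orthogonal")
    }
    for (kk in seq_along(weights)) {
      g <- components[[kk]]$coeffs
      Cn <- Cn + weights[kk] * (g %o% g)
    }
  }
  k2_store(sp, Cn, symmetric = TRUE)
}

# outer-product kernel from (possibly different) factor signals, without the
# orthonormality requirement: h2 = sum_k w_k f_k(t1) g_k(t2)
kernel2_from_factors <- function(space, weights, f_list, g_list = f_list,
                                 symmetric = identical(f_list, g_list)) {
  d <- space$dim
  Cn <- matrix(complex(1), d, d)
  for (kk in seq_along(weights)) {
    Cn <- Cn + weights[kk] * (f_list[[kk]]$coeffs %o% g_list[[kk]]$coeffs)
  }
  k2_store(space, Cn, symmetric = symmetric)
}

#' Numerical rank of a second-order kernel
#' @param k a [kernel2()].
#' @param tol singular values below `tol * sigma_max` count as zero.
#' @export
k2_rank <- function(k, tol = 1e-6) {
  sv <- svd(k$coeffs, nu = 0, nv = 0)$d
  if (max(sv) == 0) return(0L)
  sum(sv > tol * max(sv))
}
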