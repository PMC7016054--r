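# Measurement-system assembly: turns a trial set into the linear
# generalized-sampling system  lhs(theta) = q  whose rows realize
#   b1 + <h1^1, phi11> + <h1^2, phi12> + <h1^3, phi13> [+ <h1^i4, phi14^i>]
#     + <h2^1, phi21> + <h2^2, phi22> + <h2^3, phi23> [+ <h2^ij4, phi24^ij>]
# In the coefficient domain every inner product collapses to a plain dot
# product with the "sampled-stimulus" vectors
#   U_l = a_l exp( i l w1 t_k)          (stimulus coefficients a)
#   V_l = c_l exp( i l w1 t_k)          (projected-response coefficients c)
# so a first-order block with sampling rule "qu" contributes -q * U . h, a
# second-order block with rule "quu" contributes -q * sum C[l1,l2] U_l1 U_l2,
# etc. Realness of the parametrized kernels makes every row real.

sampled_vec <- function(space, coeffs, t_k) {
  # T x dim matrix with row k: coeffs_l * exp(i l w1 t_k)
  ph <- outer(t_k, space$l * space$omega1)
  exp(1i * ph) * matrix(coeffs, length(t_k), space$dim, byrow = TRUE)
}

flip_vec_outer <- function(x, y) {
  # vec (column-major) of the stored-convention weight matrix for natural
  # outer(x, y): natural columns l2 reversed
  as.vector(flip_cols(outer(x, y)))
}

#' Assemble the generalized-sampling measurement system
#'
#' Builds, for every measurement `(n, m, k)`, the sampling weights of each
#' unknown block and stacks them into the real design matrix `A` acting on
#' the structural parameter vector, so that consistent data satisfy
#' `A %*% theta = q` exactly. Measurement ordering is `k` fastest, then `m`,
#' then channel `n`.
#'
#' @param trials a [dnp_trials()] set.
#' @param layout a [dnp_layout()]; defaults to the full layout of the
#'   trial set's mode.
#' @param tie_symmetric,include forwarded to [dnp_layout()] when `layout` is
#'   not supplied.
#' @return a `dnp_system` object: `A` (real, measurements x parameters),
#'   `q`, `W` (per-block complex weight matrices), `layout`, and the raw
#'   per-measurement `U`/`V` vectors used to assemble matrix-form sampling
#'   vectors via [build_phi_xi()].
#' @export
build_system <- function(trials, layout = NULL, tie_symmetric = FALSE,
                         include = NULL) {
  N <- trials$N; M <- trials$M; Tk <- trials$T
  sp_in <- trials$space_in; sp_out <- trials$space_out
  if (is.null(layout)) {
    layout <- dnp_layout(sp_in, sp_out,
                         mode = if (N == 1L) "temporal" else "spatiotemporal",
                         N = N, tie_symmetric = tie_symmetric,
                         include = include)
  }
  if (layout$mode == "temporal" && N != 1L) {
    stop("temporal layout requires single-channel trials")
  }
  n_meas <- N * M * Tk
  # necessary condition of the dense formulation (informative only: the
  # sparse solver succeeds below it)
  if (M < 3 + 2 * sp_in$dim) {
    warning("only ", M, " trials; the dense generalized-sampling bound asks for ",
            3 + 2 * sp_in$dim, " (the sparse solver may still succeed)",
            call. = FALSE)
  }

  d_in <- sp_in$dim; d_out <- sp_out$dim
  # per-trial sampled vectors
  Ukm <- lapply(seq_len(M), function(m) lapply(seq_len(N), function(n)
    sampled_vec(sp_in, trials$inputs[[m]][[n]]$coeffs, trials$t_k)))
  Vkm <- lapply(seq_len(M), function(m) lapply(seq_len(N), function(n)
    sampled_vec(sp_out, project_grid(sp_out, trials$responses[[m]][n, ]),
                trials$t_k)))

  qv <- numeric(n_meas)
  Umat <- matrix(0i, n_meas, d_in)
  Vall <- lapply(seq_len(N), function(i) matrix(0i, n_meas, d_out))
  row <- 0L
  meas_index <- matrix(0L, n_meas, 3, dimnames = list(NULL, c("n", "m", "k")))
  for (n in seq_len(N)) for (m in seq_len(M)) for (k in seq_len(Tk)) {
    row <- row + 1L
    qv[row] <- trials$q[n, m, k]
    Umat[row, ] <- Ukm[[m]][[n]][k, ]
    for (i in seq_len(N)) Vall[[i]][row, ] <- Vkm[[m]][[i]][k, ]
    meas_index[row, ] <- c(n, m, k)
  }
  Vn <- matrix(0i, n_meas, d_out)   # own-channel response vector
  for (row in seq_len(n_meas)) Vn[row, ] <- Vall[[meas_index[row, 1]]][row, ]

  W <- vector("list", length(layout$blocks))
  names(W) <- names(layout$blocks)
  for (b in layout$blocks) {
    W[[b$name]] <- switch(b$rule,
      one = matrix(1 + 0i, n_meas, 1),
      u = Umat,
      qu = -qv * Umat,
      qv = -qv * Vn,
      qv_i = -qv * Vall[[b$chan]],
      uu = , quu = {
        Wb <- matrix(0i, n_meas, d_in^2)
        for (r in seq_len(n_meas)) {
          Wb[r, ] <- flip_vec_outer(Umat[r, ], Umat[r, ])
        }
        if (b$rule == "quu") -qv * Wb else Wb
      },
      qvv = {
        Wb <- matrix(0i, n_meas, d_out^2)
        for (r in seq_len(n_meas)) {
          Wb[r, ] <- flip_vec_outer(Vn[r, ], Vn[r, ])
        }
        -qv * Wb
      },
      qvv_ij = {
        i <- b$chan[1]; j <- b$chan[2]
        Wb <- matrix(0i, n_meas, d_out^2)
        for (r in seq_len(n_meas)) {
          w <- flip_vec_outer(Vall[[i]][r, ], Vall[[j]][r, ])
          if (isTRUE(b$tie)) {
            w <- w + flip_vec_outer(Vall[[j]][r, ], Vall[[i]][r, ])
          }
          Wb[r, ] <- w
        }
        -qv * Wb
      },
      stop("unknown sampling rule ", b$rule))
  }
  A <- matrix(0, n_meas, layout$n_par)
  for (b in layout$blocks) {
    A[, b$cols] <- Re(W[[b$name]] %*% b$M)
  }
  structure(list(A = A, q = qv, W = W, layout = layout,
                 U = Umat, V = Vall, Vn = Vn, meas_index = meas_index,
                 n_meas = n_meas, trials_meta = list(N = N, M = M, T = Tk)),
            class = "dnp_system")
}

#' @export
print.dnp_system <- function(x, ...) {
  cat(sprintf("DNP measurement system: %d measurements x %d real parameters (%s)\n",
              x$n_meas, x$layout$n_par, x$layout$mode))
  invisible(x)
}

#' @rdname build_system
#' @export
build_temporal_system <- function(trials, include = NULL) {
  build_system(trials, tie_symmetric = FALSE, include = include)
}

#' @rdname build_system
#' @param trials a [dnp_trials()] set.
#' @export
build_spatiotemporal_system <- function(trials, tie_symmetric = FALSE,
                                        include = NULL) {
  if (trials$N < 1L) stop("need at least one channel")
  layout <- dnp_layout(trials$space_in, trials$space_out,
                       mode = "spatiotemporal", N = trials$N,
                       tie_symmetric = tie_symmetric, include = include)
  build_system(trials, layout = layout)
}

#' Matrix-form sampling vector and matrix of one measurement
#'
#' Assembles the literal per-measurement sampling vector `Phi` (starting
#' with the constant slot 1, then the stimulus block, the `-q`-scaled
#' stimulus block and the `-q`-scaled response block(s)) and block sampling
#' matrix `Xi` whose dimensions are given by [sampling_dims()].
#'
#' @param system a `dnp_system` from [build_system()].
#' @param idx measurement row index.
#' @return list with `Phi` (complex vector) and `Xi` (complex matrix).
#' @export
build_phi_xi <- function(system, idx) {
  lay <- system$layout
  d_in <- lay$space_in$dim; d_out <- lay$space_out$dim
  q <- system$q[idx]
  U <- system$U[idx, ]
  n <- system$meas_index[idx, 1]
  Vn <- system$Vn[idx, ]
  # Xi enters through Tr(C2^H Xi) = sum Conj(C2) * Xi, so its blocks carry
  # the conjugates of the linear-form weights (for real stimuli/responses
  # this is the sampled vector of the un-reversed shift)
  o2 <- function(x, y) Conj(flip_cols(outer(x, y)))
  if (lay$mode == "temporal") {
    Phi <- c(1, U, -q * U, -q * Vn)
    U2 <- o2(U, U)
    V2 <- o2(Vn, Vn)
    Z <- matrix(0i, d_in, d_out)
    Xi <- rbind(cbind(U2, Z), cbind(-q * U2, Z),
                cbind(matrix(0i, d_out, d_in), -q * V2))
  } else {
    N <- lay$N
    Vi <- lapply(seq_len(N), function(i) system$V[[i]][idx, ])
    Phi <- c(1, U, -q * U, -q * Vn, unlist(lapply(Vi, function(v) -q * v)))
    U2 <- o2(U, U)
    Z <- matrix(0i, d_in, d_out)
    top <- rbind(cbind(U2, Z), cbind(-q * U2, Z))
    Zl <- matrix(0i, d_out, d_in)
    low <- list(cbind(Zl, -q * o2(Vn, Vn)))
    for (i in seq_len(N)) for (j in seq_len(N)) {
      low[[length(low) + 1L]] <- cbind(Zl, -q * o2(Vi[[i]], Vi[[j]]))
    }
    Xi <- do.call(rbind, c(list(top), low))
  }
  list(Phi = Phi, Xi = Xi)
}
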