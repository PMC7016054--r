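# Unknown-block layout for the generalized-sampling system.
#
# Every identification unknown (the constant, each first-order kernel, each
# second-order kernel block) is a "block" with
#   * a sampling rule saying which stimulus/response vectors weight it in a
#     measurement row,
#   * a structural parametrization: real kernels are conjugate-symmetric in
#     the basis, and the within-channel second-order blocks are additionally
#     Hermitian (<=> symmetric kernels). These constraints are imposed by
#     construction: each block carries a complex embedding matrix M mapping
#     free real parameters to its complex coefficients, built from the
#     orbits of the index maps (l1,l2) -> (-l1,-l2) (conjugation) and
#     (l1,l2) -> (l2,l1) (Hermitian).
# The layout drives system assembly, the convex solver, the polish stage and
# kernel reconstruction, so index conventions live in exactly one place.

# orbit decomposition of an index set under value-preserving /
# value-conjugating involutions; returns the real-parameter embedding
param_orbits <- function(n_entries, neg_map, swap_map = NULL) {
  visited <- integer(0)
  orbits <- list()
  state <- rep(NA_integer_, n_entries)   # parity relative to orbit root
  for (e0 in seq_len(n_entries)) {
    if (!is.na(state[e0])) next
    members <- e0
    state[e0] <- 0L
    real_orbit <- FALSE
    queue <- e0
    while (length(queue)) {
      e <- queue[[1]]; queue <- queue[-1]
      nbrs <- list(c(neg_map[e], 1L))
      if (!is.null(swap_map)) nbrs <- c(nbrs, list(c(swap_map[e], 0L)))
      for (nb in nbrs) {
        tgt <- nb[1]; par <- (state[e] + nb[2]) %% 2L
        if (is.na(state[tgt])) {
          state[tgt] <- par
          members <- c(members, tgt)
          queue <- c(queue, tgt)
        } else if (state[tgt] != par) {
          real_orbit <- TRUE   # cycle forces value = Conj(value)
        }
      }
    }
    orbits[[length(orbits) + 1L]] <- list(members = members,
                                          parity = state[members],
                                          real = real_orbit)
  }
  npar <- sum(vapply(orbits, function(o) if (o$real) 1L else 2L, 1L))
  M <- matrix(0i, n_entries, npar)
  col <- 0L
  rep_entry <- integer(length(orbits))
  for (oi in seq_along(orbits)) {
    o <- orbits[[oi]]
    rep_entry[oi] <- o$members[1]
    col <- col + 1L
    M[o$members, col] <- 1 + 0i
    if (!o$real) {
      col <- col + 1L
      M[o$members, col] <- 1i * ifelse(o$parity == 0L, 1, -1)
    }
  }
  list(M = M, npar = npar, orbits = orbits)
}

# embedding for a real-valued first-order kernel (conjugate-symmetric vector)
k1_embedding <- function(d) {
  L <- (d - 1L) / 2L
  idx <- seq_len(d)             # l = idx - L - 1
  neg <- d + 1L - idx           # l -> -l
  param_orbits(d, neg)
}

# embedding for a real-valued second-order kernel block in the stored
# (reversed-column) convention; hermitian adds the (l1,l2)->(l2,l1) tie
k2_embedding <- function(d, hermitian) {
  L <- (d - 1L) / 2L
  grid <- expand.grid(r = seq_len(d), c = seq_len(d))
  l1 <- grid$r - L - 1L
  l2 <- L + 1L - grid$c
  lin <- function(l1, l2) (l1 + L + 1L) + (L + 1L - l2 - 1L) * d
  neg <- lin(-l1, -l2)
  swap <- if (hermitian) lin(l2, l1) else NULL
  param_orbits(d * d, neg, swap)
}

dnp_layout_block <- function(name, kind, space, rule, chan = NULL,
                             group = NA_character_, hermitian = FALSE,
                             tie = NULL) {
  list(name = name, kind = kind, space = space, rule = rule, chan = chan,
       group = group, hermitian = hermitian, tie = tie)
}

#' Unknown-block layout of the identification problem
#'
#' Describes which kernels are identified, their structural constraints and
#' their order in the coefficient vector/matrix pair `(c1, C2)`: `c1` holds
#' the constant and the first-order kernels, `C2` the second-order blocks;
#' the nuclear-norm groups are the two stacked block columns of `C2` (the
#' feedforward pair `[H2^1; H2^2]` and the feedback stack
#' `[H2^3; H2^{ij4} ...]`).
#'
#' @param space_in,space_out model spaces.
#' @param mode `"temporal"` or `"spatiotemporal"`.
#' @param N channel count (spatio-temporal mode).
#' @param tie_symmetric tie the `(i,j)` and `(j,i)` feedback kernels into a
#'   single unknown (assumes `h2^{ij4} = h2^{ji4}`).
#' @param include optional character vector of block names to keep (e.g. to
#'   drop blocks known to be zero); defaults to all blocks of the mode.
#' @return a `dnp_layout` object.
#' @export
dnp_layout <- function(space_in, space_out, mode = c("temporal", "spatiotemporal"),
                       N = 1L, tie_symmetric = FALSE, include = NULL) {
  mode <- match.arg(mode)
  blocks <- list(
    dnp_layout_block("b1", "scalar", "in", "one"),
    dnp_layout_block("h1_1", "k1", "in", "u"),
    dnp_layout_block("h1_2", "k1", "in", "qu"),
    dnp_layout_block("h1_3", "k1", "out", "qv"),
    dnp_layout_block("h2_1", "k2", "in", "uu", group = "g1", hermitian = TRUE),
    dnp_layout_block("h2_2", "k2", "in", "quu", group = "g1", hermitian = TRUE),
    dnp_layout_block("h2_3", "k2", "out", "qvv", group = "g2", hermitian = TRUE)
  )
  if (mode == "spatiotemporal") {
    for (i in seq_len(N)) {
      blocks[[length(blocks) + 1L]] <-
        dnp_layout_block(sprintf("h1_4_%d", i), "k1", "out", "qv_i", chan = i)
    }
    if (tie_symmetric) {
      # tying h2^{ij4} = h2^{ji4} makes the anti-symmetric coefficient part
      # unobservable (measurements see c + t(c) only), so the symmetric
      # representative is identified: the blocks carry the Hermitian tie
      for (i in seq_len(N)) for (j in i:N) {
        blocks[[length(blocks) + 1L]] <-
          dnp_layout_block(sprintf("h2_4_%d_%d", i, j), "k2", "out", "qvv_ij",
                           chan = c(i, j), group = "g2", tie = (i != j),
                           hermitian = TRUE)
      }
    } else {
      for (i in seq_len(N)) for (j in seq_len(N)) {
        blocks[[length(blocks) + 1L]] <-
          dnp_layout_block(sprintf("h2_4_%d_%d", i, j), "k2", "out", "qvv_ij",
                           chan = c(i, j), group = "g2", tie = FALSE)
      }
    }
  } else if (N != 1L) stop("temporal mode is single-channel")
  if (!is.null(include)) {
    keep <- vapply(blocks, function(b) b$name %in% include, TRUE)
    if (!any(keep)) stop("`include` matched no blocks")
    blocks <- blocks[keep]
  }
  d_in <- space_in$dim; d_out <- space_out$dim
  emb_k1 <- list("in" = k1_embedding(d_in), "out" = k1_embedding(d_out))
  emb_k2 <- list("in" = list("TRUE" = k2_embedding(d_in, TRUE),
                             "FALSE" = k2_embedding(d_in, FALSE)),
                 "out" = list("TRUE" = k2_embedding(d_out, TRUE),
                              "FALSE" = k2_embedding(d_out, FALSE)))
  offset <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    d <- if (b$space == "in") d_in else d_out
    emb <- switch(b$kind,
                  scalar = list(M = matrix(1 + 0i, 1, 1), npar = 1L),
                  k1 = emb_k1[[b$space]],
                  k2 = emb_k2[[b$space]][[as.character(b$hermitian)]])
    b$dim <- if (b$kind == "k2") c(d, d) else if (b$kind == "k1") d else 1L
    b$n_entries <- nrow(emb$M)
    b$M <- emb$M
    b$npar <- emb$npar
    b$cols <- offset + seq_len(emb$npar)
    offset <- offset + emb$npar
    blocks[[bi]] <- b
  }
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  structure(list(blocks = blocks, n_par = offset, mode = mode, N = as.integer(N),
                 tie_symmetric = tie_symmetric,
                 space_in = space_in, space_out = space_out),
            class = "dnp_layout")
}

#' @export
print.dnp_layout <- function(x, ...) {
  cat(sprintf("DNP unknown layout (%s%s): %d blocks, %d real parameters\n",
              x$mode, if (x$tie_symmetric) ", tied pairs" else "",
              length(x$blocks), x$n_par))
  for (b in x$blocks) {
    cat(sprintf("  %-10s %-6s %-3s npar %4d%s%s\n", b$name, b$kind, b$space,
                b$npar, if (b$hermitian) " hermitian" else "",
                if (!is.na(b$group)) paste0(" [", b$group, "]") else ""))
  }
  invisible(x)
}

# complex coefficients of one block -> structural parameters (inverse of the
# embedding on its range); `coeffs` in the stored convention
block_encode <- function(block, coeffs) {
  v <- as.vector(coeffs)
  if (length(v) != block$n_entries) stop("coefficient size mismatch for ", block$name)
  # M has orthogonal columns with squared norms = orbit sizes
  w <- colSums(Mod(block$M)^2)
  Re(Conj(t(block$M)) %*% v) / w
}

block_decode <- function(block, theta) {
  v <- block$M %*% theta[block$cols]
  if (block$kind == "k2") matrix(v, block$dim[1], block$dim[2]) else as.vector(v)
}

#' Encode a model's kernels as the structural parameter vector
#'
#' Projects each kernel of a model onto the layout's parametrization
#' (exactly, for real kernels satisfying the structural constraints).
#' Used by the measurement-consistency oracle and the round-trip tests.
#'
#' @param model a [dnp_temporal()] or [dnp_spatiotemporal()] model.
#' @param layout a [dnp_layout()].
#' @export
encode_model <- function(model, layout) {
  theta <- numeric(layout$n_par)
  for (b in layout$blocks) {
    co <- model_block_coeffs(model, b)
    theta[b$cols] <- block_encode(b, co)
  }
  theta
}

model_block_coeffs <- function(model, b) {
  zero <- if (b$kind == "k2") matrix(0i, b$dim[1], b$dim[2]) else
    if (b$kind == "k1") complex(b$dim) else 0i
  k1co <- function(k) if (is.null(k)) zero else k$coeffs
  k2co <- function(k) if (is.null(k)) zero else k$coeffs
  switch(b$name,
    b1 = as.complex(model$T1$b),
    h1_1 = k1co(model$T1$h1),
    h1_2 = k1co(model$T2$h1),
    h1_3 = k1co(model$T3$h1),
    h2_1 = k2co(model$T1$h2),
    h2_2 = k2co(model$T2$h2),
    h2_3 = k2co(model$T3$h2),
    {
      if (b$rule == "qv_i") k1co(model$mvp$h1_list[[b$chan]])
      else k2co(model$mvp$h2_grid[[b$chan[1]]][[b$chan[2]]])
    })
}

#' Decode a structural parameter vector into named complex blocks
#' @param theta real parameter vector.
#' @param layout a [dnp_layout()].
#' @return named list of complex coefficient vectors/matrices (stored
#'   convention for second-order blocks).
#' @export
decode_theta <- function(theta, layout) {
  out <- lapply(layout$blocks, block_decode, theta = theta)
  names(out) <- names(layout$blocks)
  out
}

#' Count scalar unknowns of the direct generalized-sampling formulation
#'
#' The dense (non-sparse) identification problem has one unknown per complex
#' coefficient: the constant, two first-order kernels of input-space
#' dimension, one of output-space dimension, two second-order kernels of
#' squared input-space dimension and one of squared output-space dimension
#' (plus `N` first-order and `N^2` — or `N(N+1)/2` when tied — second-order
#' feedback blocks in the spatio-temporal mode).
#'
#' @param L,L_o input/output space orders.
#' @param N channel count.
#' @param mode `"temporal"` or `"spatiotemporal"`.
#' @param tie_symmetric count tied `(i,j)`/`(j,i)` pairs once.
#' @export
count_unknowns <- function(L, L_o = L, N = 1L,
                           mode = c("temporal", "spatiotemporal"),
                           tie_symmetric = FALSE) {
  mode <- match.arg(mode)
  if (L < 0 || L_o < 0) stop("orders must be nonnegative")
  d <- 2 * L + 1; do <- 2 * L_o + 1
  n <- 1 + 2 * d + do + 2 * d^2 + do^2
  if (mode == "spatiotemporal") {
    npairs <- if (tie_symmetric) N * (N + 1) / 2 else N^2
    n <- n + N * do + npairs * do^2
  }
  as.integer(n)
}

#' Dimensions of the matrix-form sampling vector and matrix
#'
#' Lengths/shapes of the per-measurement sampling vector `Phi` and sampling
#' matrix `Xi` of the matrix-form measurement identity, as functions of the
#' space orders and channel count.
#' @inheritParams count_unknowns
#' @export
sampling_dims <- function(L, L_o = L, N = 1L,
                          mode = c("temporal", "spatiotemporal")) {
  mode <- match.arg(mode)
  d <- 2 * L + 1; do <- 2 * L_o + 1
  if (mode == "temporal") {
    list(phi_len = 4 * L + 2 * L_o + 4,
         xi_dim = c(4 * L + 2 * L_o + 3, 2 * L + 2 * L_o + 2))
  } else {
    list(phi_len = 4 * L + 2 * (N + 1) * L_o + N + 4,
         xi_dim = c(4 * L + 2 * (N^2 + 1) * L_o + N^2 + 3,
                    2 * L + 2 * L_o + 2))
  }
}
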