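# JSON serialization of models, trials and fits (plain text, reviewable),
# plus CSV export of kernel coefficient tables.

space_to_list <- function(sp) list(L = sp$L, Omega = sp$Omega, S = sp$S)
space_from_list <- function(x) {
  if (x$L == 0) trig_space(0L, x$Omega, S_override = x$S)
  else trig_space(x$L, x$Omega)
}

cplx_to_list <- function(z) list(re = Re(z), im = Im(z))
cplx_from_list <- function(x, dim2 = NULL) {
  z <- complex(real = unlist(x$re), imaginary = unlist(x$im))
  if (!is.null(dim2)) matrix(z, dim2[1], dim2[2]) else z
}

k1_to_list <- function(k) if (is.null(k)) NULL else cplx_to_list(k$coeffs)
k2_to_list <- function(k) if (is.null(k)) NULL else
  c(cplx_to_list(as.vector(k$coeffs)), list(symmetric = k$symmetric))

vp_to_list <- function(v) list(b = v$b, h1 = k1_to_list(v$h1), h2 = k2_to_list(v$h2))
vp_from_list <- function(x, sp) {
  h1 <- if (!is.null(x$h1)) kernel1(sp, cplx_from_list(x$h1)) else NULL
  h2 <- if (!is.null(x$h2)) kernel2(sp, cplx_from_list(x$h2, c(sp$dim, sp$dim)),
                                    symmetric = isTRUE(x$h2$symmetric)) else NULL
  volterra(x$b, h1, h2, sp)
}

#' Serialize a DNP model to JSON
#'
#' Writes spaces, constants and kernel coefficient arrays as plain JSON.
#' The round trip [read_dnp_model()] reproduces the model exactly (binary
#' representation of doubles via full-precision JSON).
#'
#' @param model a [dnp_temporal()] or [dnp_spatiotemporal()].
#' @param path output file.
#' @export
write_dnp_model <- function(model, path) {
  spatial <- inherits(model, "dnp_spatiotemporal")
  x <- list(
    type = if (spatial) "spatiotemporal" else "temporal",
    space_in = space_to_list(model$space_in),
    space_out = space_to_list(model$space_out),
    T1 = vp_to_list(model$T1), T2 = vp_to_list(model$T2), T3 = vp_to_list(model$T3))
  if (spatial) {
    x$N <- model$N
    x$b4 <- model$mvp$b4
    x$symmetric_pairs <- model$mvp$symmetric_pairs
    x$h1_4 <- lapply(model$mvp$h1_list, k1_to_list)
    x$h2_4 <- lapply(model$mvp$h2_grid, function(row) lapply(row, k2_to_list))
  }
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_dnp_model
#' @export
read_dnp_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp_in <- space_from_list(x$space_in)
  sp_out <- space_from_list(x$space_out)
  T1 <- vp_from_list(x$T1, sp_in)
  T2 <- vp_from_list(x$T2, sp_in)
  T3 <- vp_from_list(x$T3, sp_out)
  if (identical(x$type, "temporal")) {
    return(dnp_temporal(T1, T2, T3, sp_in, sp_out))
  }
  N <- x$N
  h14 <- lapply(x$h1_4, function(k) if (is.null(k)) NULL else kernel1(sp_out, cplx_from_list(k)))
  h24 <- lapply(x$h2_4, function(row) lapply(row, function(k) {
    if (is.null(k)) NULL else kernel2(sp_out, cplx_from_list(k, c(sp_out$dim, sp_out$dim)),
                                      symmetric = isTRUE(k$symmetric))
  }))
  dnp_spatiotemporal(N, T1, T2, T3,
                     mvp(N, x$b4, h14, h24,
                         symmetric_pairs = isTRUE(x$symmetric_pairs),
                         space = sp_out),
                     sp_in, sp_out)
}

#' Serialize a trial set to JSON
#' @param trials a [dnp_trials()] set.
#' @param path output file.
#' @export
write_trials <- function(trials, path) {
  x <- list(
    space_in = space_to_list(trials$space_in),
    space_out = space_to_list(trials$space_out),
    t_k = trials$t_k,
    inputs = lapply(trials$inputs, function(tr) lapply(tr, function(u) cplx_to_list(u$coeffs))),
    responses = lapply(trials$responses, function(v) apply(v, 1, identity, simplify = FALSE)))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp_in <- space_from_list(x$space_in)
  sp_out <- space_from_list(x$space_out)
  inputs <- lapply(x$inputs, function(tr) lapply(tr, function(u) trig_signal(sp_in, cplx_from_list(u))))
  responses <- lapply(x$responses, function(v) do.call(rbind, lapply(v, unlist)))
  dnp_trials(inputs, responses, sp_in, sp_out, t_k = unlist(x$t_k))
}

#' Export kernel coefficients as a CSV table
#'
#' First-order kernels get columns `l, real, imag`; second-order kernels
#' `l1, l2, real, imag` (natural index order).
#'
#' @param k a [kernel1()] or [kernel2()].
#' @param path output file.
#' @export
write_kernel_csv <- function(k, path) {
  sp <- k$space
  if (inherits(k, "kernel2")) {
    Cn <- k2_nat(k)
    df <- expand.grid(l1 = sp$l, l2 = sp$l)
    df$real <- Re(as.vector(Cn))
    df$imag <- Im(as.vector(Cn))
  } else {
    df <- data.frame(l = sp$l, real = Re(k$coeffs), imag = Im(k$coeffs))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an identification result (coefficients and diagnostics) to JSON
#' @param ident a `dnp_ident`.
#' @param path output file.
#' @export
write_ident <- function(ident, path) {
  x <- list(
    mode = ident$layout$mode,
    blocks = lapply(ident$blocks, function(b) cplx_to_list(as.vector(b))),
    ranks = as.list(ident$ranks[!is.na(ident$ranks)]),
    mean_slack = ident$mean_slack,
    max_abs_slack = ident$max_abs_slack,
    snr_db = if (!is.null(ident$snr_db)) as.list(ident$snr_db) else NULL)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
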