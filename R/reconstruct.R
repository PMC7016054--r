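#' Reconstruct kernel objects and a runnable model from an identification
#'
#' Slices the recovered coefficient blocks into [kernel1()]/[kernel2()]
#' objects (the stored index convention makes this a pure reshape) and
#' assembles a forward-simulatable DNP. The measurements determine only the
#' sum of the normalization constants (it is fixed to one by the output
#' scale convention), so the reconstructed model carries the whole constant
#' in `b2`.
#'
#' @param ident a `dnp_ident` from [solve_system()].
#' @return a list with `kernels` (named list of kernel objects and `b1`)
#'   and `model` (a [dnp_temporal()] or [dnp_spatiotemporal()]).
#' @export
reconstruct_kernels <- function(ident) {
  layout <- ident$layout
  sp_in <- layout$space_in; sp_out <- layout$space_out
  blocks <- ident$blocks
  gk1 <- function(nm, sp) {
    if (is.null(blocks[[nm]])) return(NULL)
    kernel1(sp, blocks[[nm]], label = nm)
  }
  gk2 <- function(nm, sp, sym) {
    if (is.null(blocks[[nm]])) return(NULL)
    kernel2(sp, blocks[[nm]], symmetric = sym, label = nm)
  }
  b1 <- if (!is.null(blocks$b1)) Re(blocks$b1[1]) else 0
  kernels <- list(b1 = b1,
                  h1_1 = gk1("h1_1", sp_in), h1_2 = gk1("h1_2", sp_in),
                  h1_3 = gk1("h1_3", sp_out),
                  h2_1 = gk2("h2_1", sp_in, TRUE),
                  h2_2 = gk2("h2_2", sp_in, TRUE),
                  h2_3 = gk2("h2_3", sp_out, TRUE))
  T1 <- volterra(b1, kernels$h1_1, kernels$h2_1, sp_in)
  T3 <- volterra(0, kernels$h1_3, kernels$h2_3, sp_out)
  if (layout$mode == "temporal") {
    model <- dnp_temporal(T1, volterra(1, kernels$h1_2, kernels$h2_2, sp_in),
                          T3, sp_in, sp_out)
  } else {
    N <- layout$N
    h14 <- lapply(seq_len(N), function(i) gk1(sprintf("h1_4_%d", i), sp_out))
    h24 <- lapply(seq_len(N), function(i) lapply(seq_len(N), function(j) {
      nm <- sprintf("h2_4_%d_%d", i, j)
      nm2 <- sprintf("h2_4_%d_%d", min(i, j), max(i, j))
      if (!is.null(blocks[[nm]])) gk2(nm, sp_out, FALSE)
      else if (layout$tie_symmetric && !is.null(blocks[[nm2]])) gk2(nm2, sp_out, FALSE)
      else NULL
    }))
    kernels$h1_4 <- h14
    kernels$h2_4 <- h24
    model <- dnp_spatiotemporal(
      N, T1, volterra(1, kernels$h1_2, kernels$h2_2, sp_in), T3,
      mvp(N, 0, h14, h24, symmetric_pairs = isTRUE(layout$tie_symmetric),
          space = sp_out),
      sp_in, sp_out)
  }
  list(kernels = kernels, model = model)
}

#' Fit a divisive normalization processor to stimulus/response trials
#'
#' The front-door identification interface: assembles the
#' generalized-sampling system from a trial set, solves the nuclear-norm
#' sparse identification program (with polish), and reconstructs a runnable
#' model. Returns a `dnp_fit` object with `print`, `summary`, `coef`,
#' `predict`, `residuals` and `plot` methods.
#'
#' @param trials a [dnp_trials()] set (from recordings or
#'   [simulate_trials()]).
#' @param tie_symmetric tie the `(i,j)`/`(j,i)` feedback kernels
#'   (spatio-temporal trials only).
#' @param include optional character vector of unknown blocks to identify
#'   (defaults to all; see [dnp_layout()]).
#' @param config an [ident_config()].
#' @param truth optional ground-truth model; adds per-kernel recovery SNRs.
#' @export
dnp_fit <- function(trials, tie_symmetric = FALSE, include = NULL,
                    config = ident_config(), truth = NULL) {
  system <- if (trials$N == 1L) {
    build_temporal_system(trials, include = include)
  } else {
    build_spatiotemporal_system(trials, tie_symmetric = tie_symmetric,
                                include = include)
  }
  ident <- solve_system(system, config, truth = truth)
  rec <- reconstruct_kernels(ident)
  structure(list(ident = ident, kernels = rec$kernels, model = rec$model,
                 layout = system$layout,
                 n_meas = system$n_meas, q = system$q,
                 trials_meta = system$trials_meta, call = match.call()),
            class = "dnp_fit")
}

#' @export
print.dnp_fit <- function(x, ...) {
  cat(sprintf("Identified divisive normalization processor (%s)\n",
              x$layout$mode))
  cat(sprintf("  %d measurements (%d trials x %d samples%s), %d unknown blocks\n",
              x$n_meas, x$trials_meta$M, x$trials_meta$T,
              if (x$trials_meta$N > 1) sprintf(" x %d cells", x$trials_meta$N) else "",
              length(x$ident$blocks)))
  cat(sprintf("  max |slack| %.3e, mean slack %.3e\n",
              x$ident$max_abs_slack, x$ident$mean_slack))
  if (!is.null(x$ident$snr_db)) {
    s <- x$ident$snr_db[!is.na(x$ident$snr_db)]
    cat(sprintf("  recovery SNR [dB]: min %.1f / mean %.1f / max %.1f\n",
                min(s), mean(s), max(s)))
  }
  invisible(x)
}

#' @export
summary.dnp_fit <- function(object, ...) {
  x <- object
  ranks <- x$ident$ranks[!is.na(x$ident$ranks)]
  out <- list(
    mode = x$layout$mode,
    n_meas = x$n_meas,
    blocks = names(x$ident$blocks),
    ranks = ranks,
    constraint_violation = x$ident$constraint_violation,
    mean_slack = x$ident$mean_slack,
    max_abs_slack = x$ident$max_abs_slack,
    admm = x$ident$admm,
    polish = x$ident$polish,
    snr_db = x$ident$snr_db)
  class(out) <- "summary.dnp_fit"
  out
}

#' @export
print.summary.dnp_fit <- function(x, ...) {
  cat(sprintf("DNP identification summary (%s), %d measurements\n",
              x$mode, x$n_meas))
  cat("  second-order block ranks:\n")
  for (nm in names(x$ranks)) cat(sprintf("    %-10s %d\n", nm, x$ranks[[nm]]))
  cat(sprintf("  constraint violations (pre-projection): hermitian %.2e, realness %.2e\n",
              x$constraint_violation[["hermitian"]],
              x$constraint_violation[["realness"]]))
  cat(sprintf("  slack: mean %.2e, max |.| %.2e\n", x$mean_slack, x$max_abs_slack))
  cat(sprintf("  ADMM: %d iterations (converged: %s)",
              x$admm$iterations, x$admm$converged))
  if (!is.null(x$polish$rel_residual)) {
    cat(sprintf("; polish residual %.2e at ranks [%s]",
                x$polish$rel_residual, paste(x$polish$ranks, collapse = ", ")))
  }
  cat("\n")
  if (!is.null(x$snr_db)) {
    cat("  recovery SNR [dB] per kernel:\n")
    s <- x$snr_db[!is.na(x$snr_db)]
    for (nm in names(s)) cat(sprintf("    %-10s %7.2f\n", nm, s[[nm]]))
  }
  invisible(x)
}

#' @export
coef.dnp_fit <- function(object, complete = FALSE, ...) {
  if (complete) return(object$ident$blocks)
  cc <- unlist(lapply(names(object$ident$blocks), function(nm) {
    b <- object$layout$blocks[[nm]]
    if (b$kind %in% c("scalar", "k1")) {
      stats::setNames(object$ident$blocks[[nm]],
                      paste0(nm, "_", seq_along(object$ident$blocks[[nm]])))
    } else NULL
  }))
  cc
}

#' @export
residuals.dnp_fit <- function(object, ...) object$ident$slack

#' Predict responses of an identified model to new stimuli
#'
#' Runs the reconstructed model forward on held-out stimuli.
#'
#' @param object a `dnp_fit`.
#' @param newdata a [trig_signal()] (or list of channel signals, or a list
#'   of such trials) in the model's input space.
#' @param n_grid,... forwarded to the simulator.
#' @return a `dnp_sim` result, or a list of them for multiple trials.
#' @export
predict.dnp_fit <- function(object, newdata, n_grid = NULL, ...) {
  model <- object$model
  one <- function(u) {
    if (inherits(model, "dnp_temporal")) simulate_temporal(model, u, n_grid = n_grid, ...)
    else simulate_spatiotemporal(model, u, n_grid = n_grid, ...)
  }
  if (inherits(newdata, "trig_signal")) return(one(newdata))
  if (is.list(newdata) && length(newdata) &&
      inherits(newdata[[1]], "trig_signal") &&
      inherits(model, "dnp_spatiotemporal")) {
    return(one(newdata))
  }
  lapply(newdata, one)
}

#' Plot identified first-order kernels (optionally against the truth)
#'
#' @param x a `dnp_fit`.
#' @param truth optional ground-truth model.
#' @param n_grid curve resolution.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dnp_fit <- function(x, truth = NULL, n_grid = 256, ...) {
  k1names <- names(Filter(function(b) b$kind == "k1", x$layout$blocks))
  if (!length(k1names)) return(invisible(x))
  old <- graphics::par(mfrow = c(1, length(k1names)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in k1names) {
    b <- x$layout$blocks[[nm]]
    sp <- if (b$space == "in") x$layout$space_in else x$layout$space_out
    tg <- canonical_grid(sp, n_grid)
    est <- eval_signal(trig_signal(sp, x$ident$blocks[[nm]]), tg)
    if (!is.null(truth)) {
      tv <- model_block_coeffs(truth, b)
      tru <- eval_signal(trig_signal(sp, tv), tg)
      graphics::matplot(tg, cbind(tru, est), type = "l", lty = c(1, 2),
                        col = c("black", "red"), xlab = "t [s]", ylab = nm,
                        main = nm, ...)
    } else {
      graphics::plot(tg, est, type = "l", col = "red", xlab = "t [s]",
                     ylab = nm, main = nm, ...)
    }
  }
  invisible(x)
}
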