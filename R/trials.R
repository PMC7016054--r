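#' Stimulus/response trial set
#'
#' Packages `M` trials of `N`-channel inputs with their recorded responses
#' on a dense uniform grid, together with the measurement sample times
#' `t_k`. This is the identification input: measurements are
#' `q^{nmk} = v^{nm}(t_k)`, read off the stored responses (exactly when
#' `t_k` falls on the grid, by trigonometric interpolation otherwise).
#'
#' @param inputs list of `M` trials; each trial is a list of `N`
#'   [trig_signal()]s (a single signal is promoted to a one-channel list).
#' @param responses list of `M` response sample matrices (`N x G`; a vector
#'   is promoted to one channel), on the canonical grid.
#' @param space_in,space_out the model spaces.
#' @param t_k measurement sample times within one period; default `T_samples`
#'   uniform times over `[0, S)`.
#' @param T_samples number of sample times per trial when `t_k` is omitted.
#' @export
dnp_trials <- function(inputs, responses, space_in, space_out,
                       t_k = NULL, T_samples = NULL) {
  inputs <- lapply(inputs, function(tr) if (inherits(tr, "trig_signal")) list(tr) else tr)
  responses <- lapply(responses, function(v) if (is.matrix(v)) v else matrix(v, 1))
  M <- length(inputs)
  if (length(responses) != M) stop("inputs and responses must have equal length")
  N <- length(inputs[[1]])
  G <- ncol(responses[[1]])
  S <- space_in$S
  if (is.null(t_k)) {
    if (is.null(T_samples)) stop("supply `t_k` or `T_samples`")
    t_k <- (seq_len(T_samples) - 1) * S / T_samples
  }
  if (any(t_k < 0 | t_k >= S)) stop("t_k must lie within one period [0, S)")
  grid <- canonical_grid(space_in, G)
  # q^{nmk}: exact read-off where t_k hits the grid, spectral interpolation
  # otherwise
  q <- array(NA_real_, c(N, M, length(t_k)))
  gi <- round(t_k / (S / G)) + 1
  on_grid <- abs(t_k - grid[pmin(gi, G)]) < 1e-12 * S & gi <= G
  for (m in seq_len(M)) {
    V <- responses[[m]]
    for (n in seq_len(N)) {
      qk <- numeric(length(t_k))
      if (any(on_grid)) qk[on_grid] <- V[n, gi[on_grid]]
      if (any(!on_grid)) qk[!on_grid] <- trig_interp(V[n, ], S, t_k[!on_grid])
      q[n, m, ] <- qk
    }
  }
  structure(list(inputs = inputs, responses = responses, q = q,
                 t_k = t_k, grid = grid, N = N, M = M, T = length(t_k),
                 space_in = space_in, space_out = space_out),
            class = "dnp_trials")
}

#' @export
print.dnp_trials <- function(x, ...) {
  cat(sprintf(
    "DNP trial set: %d trial(s) x %d channel(s), %d sample time(s)/trial (%d measurements)\n",
    x$M, x$N, x$T, x$N * x$M * x$T))
  cat("  input space:", format(x$space_in), " output space:", format(x$space_out), "\n")
  invisible(x)
}

#' Simulate a trial set from a model and stimuli
#'
#' Runs the forward simulator for each trial and packages inputs, responses
#' and sample times into a [dnp_trials()] set. The simulation grid is sized
#' so every `t_k` falls exactly on a stored sample.
#'
#' @param model a [dnp_temporal()] or [dnp_spatiotemporal()] model.
#' @param stimuli for a temporal model, a list of `M` [trig_signal()]s; for
#'   a spatio-temporal model, a list of `M` trials each a list of `N`
#'   signals.
#' @param T_samples sample times per trial (uniform over the period).
#' @param n_grid simulation grid size; default [default_grid_size()] rounded
#'   to a multiple of `T_samples`.
#' @param ... passed to the simulator (`tol`, `max_iter`, `eps_den`).
#' @export
simulate_trials <- function(model, stimuli, T_samples, n_grid = NULL, ...) {
  spatial <- inherits(model, "dnp_spatiotemporal")
  if (is.null(n_grid)) n_grid <- default_grid_size(model$space_in, T_samples)
  responses <- lapply(stimuli, function(u) {
    if (spatial) simulate_spatiotemporal(model, u, n_grid = n_grid, ...)$v
    else matrix(simulate_temporal(model, u, n_grid = n_grid, ...)$v, 1)
  })
  dnp_trials(stimuli, responses, model$space_in, model$space_out,
             T_samples = T_samples)
}
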