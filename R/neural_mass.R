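## Generative neural-mass model: alpha-kernel synaptic convolution dynamics,
## sigmoid firing-rate coupling, Gaussian-bump exogenous input, LFP-style
## scalar observation of each source's output population.

#' Normalized firing-rate sigmoid
#'
#' `S(V) = 1 / (1 + exp(-r V)) - 1/2`: the odd, bounded transform from a
#' population's composite membrane potential (mV) to its normalized firing
#' rate in (-1/2, 1/2).
#'
#' @param V Membrane potential (mV); vectorized.
#' @param r Curvature parameter (default 0.56).
#' @return Normalized rate, same shape as `V`.
#' @export
sigmoid_rate <- function(V, r = .arch_defaults$sigmoid_r) {
  stopifnot(r > 0)
  1 / (1 + exp(-r * V)) - 0.5
}

#' Synaptic response kernel specification
#'
#' @param H Maximum post-synaptic potential (mV), positive.
#' @param tau Receptor time constant (ms), positive; canonical values are
#'   8 ms (excitatory, AMPA) and 16 ms (inhibitory, GABA-A).
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @return An object of class `synaptic_kernel`.
#' @export
synaptic_kernel <- function(H, tau, polarity = c("excitatory", "inhibitory")) {
  polarity <- match.arg(polarity)
  stopifnot(H > 0, tau > 0)
  structure(list(H = H, tau = tau, polarity = polarity),
            class = "synaptic_kernel")
}

#' Alpha-form post-synaptic kernel
#'
#' Evaluates `p(t) = A (H / tau) t exp(-t / tau)`, the impulse response of
#' one receptor channel. Its maximum is at `t = tau` and its integral over
#' `[0, Inf)` equals `A H tau`.
#'
#' @param t Time since the presynaptic impulse (ms); must be non-negative.
#' @param kernel A [synaptic_kernel()].
#' @param A Connection gain (dimensionless), default 1.
#' @return Kernel value (mV), same shape as `t`.
#' @export
kernel_value <- function(t, kernel, A = 1) {
  if (any(t < 0)) stop("kernel_value is defined for t >= 0 only")
  A * kernel$H / kernel$tau * t * exp(-t / kernel$tau)
}

#' Exogenous input specification
#'
#' The stimulus drive is a sum of Gaussian bumps; the two default components
#' (onsets 10 and 40 ms, dispersions 8 ms) model the two evoked deflections
#' that follow the tone offset. The drive enters the excitatory receptor
#' channel of the excitatory-interneuron population of both sources.
#'
#' @param onsets Bump centres (ms post-stimulus).
#' @param dispersions Bump standard deviations (ms), positive.
#' @param amplitudes Bump amplitudes (dimensionless drive); the default scale
#'   was fixed once so that simulated deflections span a few mV.
#' @return An object of class `input_spec`.
#' @export
input_spec <- function(onsets = c(10, 40), dispersions = c(8, 8),
                       amplitudes = rep(0.25, length(onsets))) {
  stopifnot(length(onsets) == length(dispersions),
            length(onsets) == length(amplitudes),
            all(dispersions > 0))
  structure(list(onsets = onsets, dispersions = dispersions,
                 amplitudes = amplitudes), class = "input_spec")
}

#' Evaluate the exogenous drive
#'
#' @param t Time (ms); vectorized.
#' @param spec An [input_spec()].
#' @return Drive value at `t` (sum of the Gaussian components).
#' @export
exogenous_input <- function(t, spec = input_spec()) {
  out <- numeric(length(t))
  for (k in seq_along(spec$onsets))
    out <- out + spec$amplitudes[k] *
      exp(-(t - spec$onsets[k])^2 / (2 * spec$dispersions[k]^2))
  out
}

#' Simulation grid
#'
#' @param window Modelled time window (ms) relative to the stimulus,
#'   default `c(1, 200)`.
#' @param dt Integration step (ms), default 0.1; must divide the output
#'   sampling interval.
#' @param out_rate Output sampling rate (Hz), default 1000.
#' @return An object of class `simulation_grid` with the output time grid in
#'   `$time_ms`.
#' @export
simulation_grid <- function(window = c(1, 200), dt = 0.1, out_rate = 1000) {
  stopifnot(length(window) == 2, window[2] > window[1], dt > 0, dt <= 1)
  step_ms <- 1000 / out_rate
  out_every <- step_ms / dt
  if (abs(out_every - round(out_every)) > 1e-9)
    stop("dt must divide the output sampling interval")
  out_every <- as.integer(round(out_every))
  n_steps <- as.integer(round(window[2] / dt))
  time_ms <- dt * out_every * seq_len(n_steps %/% out_every)
  keep <- time_ms >= window[1] - 1e-9
  structure(list(window = window, dt = dt, out_rate = out_rate,
                 out_every = out_every, n_steps = n_steps,
                 time_ms = time_ms[keep], keep = keep),
            class = "simulation_grid")
}

#' Construct an ERP pair
#'
#' Container for a pair of per-region evoked responses on a common time grid.
#'
#' @param time_ms Time grid (ms post-stimulus).
#' @param amplitude 2 x length(time_ms) matrix with rownames `MCN`, `vlPAG`.
#' @param n_trials Number of trials averaged (NA for model output).
#' @param meta Optional list of provenance metadata.
#' @return An object of class `erp_pair`.
#' @export
erp_pair <- function(time_ms, amplitude, n_trials = NA_integer_, meta = list()) {
  stopifnot(is.matrix(amplitude), nrow(amplitude) == 2,
            ncol(amplitude) == length(time_ms))
  if (is.null(rownames(amplitude))) rownames(amplitude) <- c("MCN", "vlPAG")
  structure(list(time_ms = time_ms, amplitude = amplitude,
                 n_trials = n_trials, meta = meta), class = "erp_pair")
}

#' @export
print.erp_pair <- function(x, ...) {
  cat(sprintf("<erp_pair> %d samples on (%g, %g) ms; n_trials = %s\n",
              length(x$time_ms), min(x$time_ms), max(x$time_ms),
              format(x$n_trials)))
  invisible(x)
}

## ------------------------------------------------------------------
## Internal: compile a model variant + grid into a fast simulator closure
## ------------------------------------------------------------------

.source_order <- c("MCN", "vlPAG")

#' @keywords internal
.compile_variant <- function(variant, grid, input = input_spec()) {
  archs <- variant$architectures[.source_order]
  pop_index <- list()  # global 0-based population index per source
  offset <- 0L
  for (s in .source_order) {
    labs <- archs[[s]]$populations$label
    pop_index[[s]] <- stats::setNames(seq_along(labs) - 1L + offset, labs)
    offset <- offset + length(labs)
  }
  n_pop <- offset

  ## connection rows: intrinsic then extrinsic; channel 0 = exc, 1 = inh
  conn_from <- integer(0); conn_chan <- integer(0)
  conn_delay <- numeric(0)
  gain_base <- numeric(0)      # fixed part of each connection gain
  gain_param <- character(0)   # latent parameter scaling it ("" = none)
  for (s in .source_order) {
    cc <- archs[[s]]$intrinsic_connections
    for (i in seq_len(nrow(cc))) {
      ch <- if (cc$polarity[i] == "excitatory") 0L else 1L
      conn_from <- c(conn_from, pop_index[[s]][[cc$from[i]]])
      conn_chan <- c(conn_chan, 2L * pop_index[[s]][[cc$to[i]]] + ch)
      conn_delay <- c(conn_delay, cc$delay[i])
      gain_base <- c(gain_base, cc$gain[i])
      gain_param <- c(gain_param, .gain_param_name(s, cc$from[i], cc$to[i]))
    }
  }
  ext <- variant$extrinsic
  for (i in seq_len(nrow(ext))) {
    conn_from <- c(conn_from, pop_index[[ext$from[i]]][["output"]])
    conn_chan <- c(conn_chan, 2L * pop_index[[ext$to[i]]][[ext$target[i]]])
    conn_delay <- c(conn_delay, variant$extrinsic_delay)
    gain_base <- c(gain_base, .arch_defaults$ext_scale * ext$rate[i])
    gain_param <- c(gain_param, paste0("A_", ext$from[i], "_to_", ext$to[i]))
  }

  ## receptor channel constants (channel-major: 2*pop + c)
  H_base <- tau_vec <- numeric(2L * n_pop)
  H_param <- character(2L * n_pop)
  for (s in .source_order) {
    for (p in archs[[s]]$populations$label) {
      gp <- pop_index[[s]][[p]]
      H_base[2 * gp + 1] <- archs[[s]]$H[["e"]]
      H_base[2 * gp + 2] <- archs[[s]]$H[["i"]]
      tau_vec[2 * gp + 1] <- archs[[s]]$tau[["e"]]
      tau_vec[2 * gp + 2] <- archs[[s]]$tau[["i"]]
      H_param[2 * gp + 1] <- paste0("H_e_", s)
      H_param[2 * gp + 2] <- paste0("H_i_", s)
    }
  }

  ## exogenous basis: one Gaussian basis column per component, shared by the
  ## excitatory channel of each source's excitatory-interneuron population
  t_grid <- grid$dt * (0:grid$n_steps)
  basis <- vapply(seq_along(input$onsets), function(k)
    exp(-(t_grid - input$onsets[k])^2 / (2 * input$dispersions[k]^2)),
    numeric(length(t_grid)))
  exo_chan <- vapply(.source_order, function(s)
    2L * pop_index[[s]][["excitatory_interneuron"]], integer(1))

  obs_pop <- vapply(.source_order, function(s) pop_index[[s]][["output"]],
                    integer(1))

  list(n_pop = n_pop, pop_index = pop_index,
       conn_from = conn_from, conn_chan = conn_chan, conn_delay = conn_delay,
       gain_base = gain_base, gain_param = gain_param,
       H_base = H_base, H_param = H_param, tau = tau_vec,
       basis = basis, exo_chan = exo_chan, amp_base = input$amplitudes,
       obs_pop = obs_pop, r = .arch_defaults$sigmoid_r, grid = grid)
}

.gain_param_name <- function(source, from, to) {
  ab <- c(output = "out", excitatory_interneuron = "ei",
          inhibitory_interneuron = "ii")
  paste0("G_", source, "_", ab[[from]], "_to_", ab[[to]])
}

#' @keywords internal
.sim_compiled <- function(cm, theta, return_states = FALSE) {
  scale_by <- function(par_names, base) {
    mult <- rep(1, length(par_names))
    hit <- which(par_names %in% names(theta))
    if (length(hit)) mult[hit] <- exp(theta[par_names[hit]])
    base * mult
  }
  gains <- scale_by(cm$gain_param, cm$gain_base)
  H <- scale_by(cm$H_param, cm$H_base)
  amps <- scale_by(paste0("U_amp", seq_along(cm$amp_base)), cm$amp_base)
  obs_gain <- scale_by(paste0("L_", .source_order), c(1, 1))
  drive <- as.vector(cm$basis %*% amps)
  exo <- matrix(drive, nrow = length(drive), ncol = length(cm$exo_chan))
  res <- .simulate_network_cpp(
    cm$n_pop, H, cm$tau, as.integer(cm$conn_from), as.integer(cm$conn_chan),
    gains, cm$conn_delay, exo, as.integer(cm$exo_chan), cm$r, cm$grid$dt,
    cm$grid$n_steps, cm$grid$out_every, as.integer(cm$obs_pop), obs_gain,
    return_states)
  y <- res$y[, cm$grid$keep, drop = FALSE]
  rownames(y) <- .source_order
  if (return_states) attr(y, "states") <- res$states[cm$grid$keep, , drop = FALSE]
  y
}

#' Simulate the evoked response of a model variant
#'
#' Integrates the coupled neural-mass equations (fixed-step second-order
#' scheme, 0.1 ms default step, delays honoured through interpolated state
#' history) and returns the observed waveform of each source: the lead-field
#' gain times the output population's composite membrane potential, sampled
#' at the output rate on the modelled window.
#'
#' Free parameters are supplied on the latent log-scale: each physical
#' quantity equals its prior mean times `exp(theta)`, so `theta = 0`
#' (or an empty `theta`) simulates at the prior means. Names must be a subset
#' of `pack_parameters(variant)$name`.
#'
#' @param variant A [model_variant()].
#' @param theta Named numeric vector of latent log-scaling parameters.
#' @param grid A [simulation_grid()].
#' @param input An [input_spec()].
#' @param return_states Logical; attach per-population composite potentials.
#' @return A list of class `erp_pair_sim` with `$mcn`, `$vlpag`
#'   ([erp_pair()] is the combined container actually returned).
#' @export
simulate_erp <- function(variant, theta = numeric(0),
                         grid = simulation_grid(), input = input_spec(),
                         return_states = FALSE) {
  stopifnot(inherits(variant, "model_variant"))
  theta <- .check_theta(variant, theta)
  cm <- .compile_variant(variant, grid, input)
  y <- .sim_compiled(cm, theta, return_states)
  out <- erp_pair(grid$time_ms, y, n_trials = NA_integer_,
                  meta = list(variant = variant$id, theta = theta))
  if (return_states) out$states <- attr(y, "states")
  out
}

.check_theta <- function(variant, theta) {
  if (!length(theta)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(theta)) || any(!nzchar(names(theta))))
    stop("theta must be a named vector of latent parameters")
  free <- pack_parameters(variant)$name
  bad <- setdiff(names(theta), free)
  if (length(bad))
    stop("unknown parameter(s) for variant ", variant$id, ": ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(theta))) stop("theta must be finite")
  theta
}
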