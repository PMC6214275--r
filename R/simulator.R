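#' Spiking-network simulation
#'
#' Izhikevich regular-spiking (excitatory) and fast-spiking (inhibitory)
#' neurons coupled by delayed synaptic events, driven by an external
#' Poisson input, integrated by forward Euler.  This stage generates the
#' spike-train data that the rest of the pipeline analyses.
#'
#' @name spiking_simulator
NULL

#' Simulation parameter set
#'
#' @param duration total simulated time (ms); must be a multiple of 1 ms.
#' @param dt Euler step (ms).
#' @param poisson_rate_exc,poisson_rate_inh external Poisson drive rate per
#'   neuron (Hz) for excitatory and inhibitory cells.
#' @param poisson_amp_mean,poisson_amp_sd Gaussian amplitude (mV) of each
#'   external drive event.  The default (mean 8, sd 0.8) models each event
#'   as a compound volley of extrinsic excitatory inputs; together with the
#'   default 80 Hz rate it holds the membrane in a fluctuation-driven
#'   regime where recurrent EPSPs meaningfully modulate spike timing.
#' @param input_mode \code{"voltage"} delivers each synaptic/drive event as
#'   an instantaneous voltage increment equal to its amplitude (the
#'   amplitude then is the maximum voltage increase of the postsynaptic
#'   cell); \code{"current"} sums the exponential synaptic waveform
#'   \code{w * exp(-(t - t_X - t_k)/tau)} into the current term I.
#' @param v_b fast-spiking adaptation threshold (mV).
#' @param tau synaptic decay constant (ms).
#' @param t_delay_exc,t_delay_inh synaptic onset delay t_X (ms) for
#'   excitatory and inhibitory synapses.
#' @return a \code{simulation_params} list.
#' @export
simulation_params <- function(duration = 600000, dt = 0.1,
                              poisson_rate_exc = 80, poisson_rate_inh = 80,
                              poisson_amp_mean = 8, poisson_amp_sd = 0.8,
                              input_mode = c("voltage", "current"),
                              v_b = -55, tau = 3,
                              t_delay_exc = 5, t_delay_inh = 1) {
  stopifnot(dt > 0, duration > 0, abs(duration - round(duration)) < 1e-9,
            tau > 0, t_delay_exc >= 0, t_delay_inh >= 0)
  structure(list(duration = duration, dt = dt,
                 poisson_rate_exc = poisson_rate_exc,
                 poisson_rate_inh = poisson_rate_inh,
                 poisson_amp_mean = poisson_amp_mean,
                 poisson_amp_sd = poisson_amp_sd,
                 input_mode = match.arg(input_mode),
                 v_b = v_b, tau = tau,
                 t_delay_exc = t_delay_exc, t_delay_inh = t_delay_inh),
            class = "simulation_params")
}

#' Single Euler step of the excitatory (regular-spiking) neuron
#'
#' \code{100 dv/dt = 0.7 (v+60)(v+40) - u + I},
#' \code{du/dt = 0.03 (-2 (v+60)) - u}; on reaching 35 mV the neuron
#' spikes, v resets to -50 mV and u jumps by 100.
#'
#' @param v,u membrane potential (mV) and adaptation variable.
#' @param I input (summed synaptic + drive contributions).
#' @param dt step (ms).
#' @return list with updated \code{v}, \code{u} and logical \code{spike}.
#' @export
step_excitatory <- function(v, u, I = 0, dt = 0.1) {
  if (!all(is.finite(c(v, u, I)))) stop("non-finite neuron state or input")
  v1 <- v + dt * (0.7 * (v + 60) * (v + 40) - u + I) / 100
  u1 <- u + dt * (0.03 * (-2 * (v + 60)) - u)
  spike <- v1 >= 35
  if (spike) { v1 <- -50; u1 <- u1 + 100 }
  list(v = v1, u = u1, spike = spike)
}

#' Single Euler step of the inhibitory (fast-spiking) neuron
#'
#' \code{20 dv/dt = (v+55)(v+40) - u + I},
#' \code{du/dt = 0.2 (U(v) - u)} with \code{U(v) = 0.025 (v - v_b)^3} for
#' \code{v >= v_b} and 0 below; on reaching 25 mV, v resets to -45 mV.
#'
#' @inheritParams step_excitatory
#' @param v_b adaptation threshold (mV), default -55.
#' @return list with updated \code{v}, \code{u} and logical \code{spike}.
#' @export
step_inhibitory <- function(v, u, I = 0, dt = 0.1, v_b = -55) {
  if (!all(is.finite(c(v, u, I)))) stop("non-finite neuron state or input")
  U <- fs_adaptation(v, v_b)
  v1 <- v + dt * ((v + 55) * (v + 40) - u + I) / 20
  u1 <- u + dt * 0.2 * (U - u)
  spike <- v1 >= 25
  if (spike) v1 <- -45
  list(v = v1, u = u1, spike = spike)
}

#' Fast-spiking adaptation target U(v)
#'
#' @inheritParams step_inhibitory
#' @return \code{0.025 (v - v_b)^3} for \code{v >= v_b}, else 0.
#' @export
fs_adaptation <- function(v, v_b = -55) {
  ifelse(v >= v_b, 0.025 * (v - v_b)^3, 0)
}

#' Synaptic waveform contribution at time t
#'
#' The contribution of a presynaptic spike at \code{t_spike} through a
#' synapse of amplitude \code{v_x}, onset delay \code{t_x} and decay
#' constant \code{tau}: zero before onset, then
#' \code{v_x * exp(-(t - t_x - t_spike)/tau)}.  Contributions from
#' multiple spikes superpose linearly.
#'
#' @param t evaluation time (ms), may be a vector.
#' @param v_x amplitude (mV).
#' @param t_x onset delay (ms).
#' @param t_spike presynaptic spike time (ms).
#' @param tau decay constant (ms).
#' @export
synaptic_contribution <- function(t, v_x, t_x, t_spike, tau = 3) {
  stopifnot(all(is.finite(t)), tau > 0)
  ifelse(t >= t_spike + t_x,
         v_x * exp(-(t - t_x - t_spike) / tau), 0)
}

#' Simulate a spiking network
#'
#' Integrates the full network and returns the per-neuron spike times and
#' the 1-ms binned binary spike matrix.  Reproducible under
#' \code{set.seed()}.  Aborts with a diagnostic if the integration becomes
#' unstable (|v| > 1000 mV).
#'
#' @param net a finalized \code{structural_network} (types and weights
#'   assigned).
#' @param params a \code{\link{simulation_params}} object.
#' @return a \code{spike_train_set}: list with \code{spike_times} (ms),
#'   \code{binned} (n x T binary matrix, 1-ms bins), \code{duration},
#'   \code{n}, \code{params}.
#' @export
simulate_spiking <- function(net, params = simulation_params()) {
  if (is.null(net$neuron_type) || is.null(net$weights))
    stop("network must have types and weights assigned; see assign_types_and_weights()")
  type <- as.integer(net$neuron_type == "inhibitory")
  res <- simulate_izhikevich_cpp(net$weights, type,
                                 params$duration, params$dt,
                                 params$poisson_rate_exc,
                                 params$poisson_rate_inh,
                                 params$poisson_amp_mean,
                                 params$poisson_amp_sd,
                                 as.integer(params$input_mode == "current"),
                                 params$v_b, params$tau,
                                 params$t_delay_exc, params$t_delay_inh)
  if (isTRUE(res$unstable))
    stop("simulation unstable: |v| exceeded 1000 mV; reduce dt or input amplitudes")
  st <- res$spike_times
  structure(list(spike_times = st,
                 binned = bin_spikes(st, params$duration),
                 duration = params$duration,
                 n = net$n,
                 params = params),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  counts <- lengths(x$spike_times)
  cat("<spike_train_set> ", x$n, " neurons, ", x$duration, " ms, ",
      sum(counts), " spikes (mean rate ",
      round(mean(counts) / (x$duration / 1000), 2), " Hz)\n", sep = "")
  invisible(x)
}

#' Bin spike times into a 1-ms binary matrix
#'
#' Bin b holds spikes with \code{floor(t) == b - 1}; multiple spikes in a
#' bin clip to 1.
#'
#' @param spike_times list of per-neuron spike-time vectors (ms), each in
#'   \code{[0, duration)}.
#' @param duration train length (ms).
#' @return integer matrix, \code{length(spike_times)} x \code{duration}.
#' @export
bin_spikes <- function(spike_times, duration) {
  duration <- as.integer(round(duration))
  n <- length(spike_times)
  M <- matrix(0L, n, duration)
  for (i in seq_len(n)) {
    t <- spike_times[[i]]
    if (!length(t)) next
    if (any(t < 0 | t >= duration))
      stop("spike times must lie in [0, duration)")
    M[i, unique(floor(t)) + 1L] <- 1L
  }
  M
}

#' Write / read spike trains as CSV (neuron_id, spike_time_ms)
#'
#' Neuron ids are 0-based.
#'
#' @param trains a \code{spike_train_set}.
#' @param path output file.
#' @export
write_spikes_csv <- function(trains, path) {
  df <- data.frame(
    neuron_id = rep(seq_along(trains$spike_times) - 1L,
                    lengths(trains$spike_times)),
    spike_time_ms = unlist(trains$spike_times))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param n_neurons,duration shape of the recovered train set.
#' @export
read_spikes_csv <- function(path, n_neurons, duration) {
  df <- utils::read.csv(path)
  st <- lapply(seq_len(n_neurons) - 1L,
               function(i) sort(df$spike_time_ms[df$neuron_id == i]))
  structure(list(spike_times = st,
                 binned = bin_spikes(st, duration),
                 duration = duration, n = n_neurons, params = NULL),
            class = "spike_train_set")
}
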