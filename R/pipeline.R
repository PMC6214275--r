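#' End-to-end experiment orchestration
#'
#' A trial runs build -> simulate -> correlate -> threshold -> multiplex
#' census -> null models -> Z-scores for each correlation method and each
#' kappa; an experiment repeats trials with fresh network/simulation
#' randomizations and aggregates counts and Z-scores across trials.
#'
#' @name pipeline
NULL

#' Experiment configuration
#'
#' The \code{"paper"} profile is the full study design (10 trials of
#' ten-minute trains, 100 null randomizations); the \code{"reduced"}
#' profile (default) keeps the same network and drive but shortens the
#' trains to 60 s, the trials to 3 and the null ensembles to 20 so a full
#' experiment runs on a desktop in minutes.
#'
#' @param profile \code{"reduced"} or \code{"paper"}.
#' @param ... overrides of any configuration field.
#' @return an \code{experiment_config} list.
#' @export
experiment_config <- function(profile = c("reduced", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    rows = 10, cols = 10, radius = sqrt(2),
    p_rw = 0.4, p_r = 0.4, p_d = 0.5,
    inhibitory_fraction = 0.2,
    weight_mean = 3.1, weight_sd = 0.1, v_inh = -1.5,
    duration = if (profile == "paper") 600000 else 60000,
    dt = 0.1,
    poisson_rate_exc = 80, poisson_rate_inh = 80,
    poisson_amp_mean = 8, poisson_amp_sd = 0.8,
    input_mode = "voltage",
    methods = c("te", "cc"),
    te_k = 5, te_l = 5, te_d_max = 30,
    cc_sigma = 0.2, cc_delays = 1:30,
    kappas = c(0.2, 0.5, 0.8),
    trials = if (profile == "paper") 10 else 3,
    n_null = if (profile == "paper") 100 else 20,
    swap_iterations = 100,
    seed = 1,
    profile = profile)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "experiment_config")
}

trial_sim_params <- function(config) {
  simulation_params(duration = config$duration, dt = config$dt,
                    poisson_rate_exc = config$poisson_rate_exc,
                    poisson_rate_inh = config$poisson_rate_inh,
                    poisson_amp_mean = config$poisson_amp_mean,
                    poisson_amp_sd = config$poisson_amp_sd,
                    input_mode = config$input_mode)
}

#' Run one trial
#'
#' Builds a structural network, simulates it, computes the correlation
#' matrix for every configured method, thresholds at every kappa, runs
#' both censuses, both null models, and the Z-scores.  Fully reproducible
#' from \code{trial_seed}.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param trial_seed integer seed for this trial.
#' @return list with the network, per-neuron spike counts, and per
#'   (method, kappa) results: functional network edge counts, censuses,
#'   FP/FN counts, dyadic Z-scores (null model one) and triadic Z-scores
#'   (null model two).
#' @export
run_trial <- function(config, trial_seed) {
  set.seed(trial_seed)
  net <- build_structural_network(
    rows = config$rows, cols = config$cols, radius = config$radius,
    p_rw = config$p_rw, p_r = config$p_r, p_d = config$p_d,
    inhibitory_fraction = config$inhibitory_fraction,
    weight_mean = config$weight_mean, weight_sd = config$weight_sd,
    v_inh = config$v_inh)
  trains <- simulate_spiking(net, trial_sim_params(config))

  cors <- list()
  for (m in config$methods) {
    cors[[m]] <- if (m == "te") {
      correlation_matrix(trains, "te", k = config$te_k, l = config$te_l,
                         d_max = config$te_d_max)
    } else {
      correlation_matrix(trains, "cc", sigma = config$cc_sigma,
                         delays = config$cc_delays)
    }
  }

  results <- list()
  for (m in config$methods) {
    for (kap in config$kappas) {
      fnet <- apply_threshold(cors[[m]], kap)
      M <- build_multiplex(net, fnet)
      dy <- dyadic_census(M)
      tri <- triadic_census(M)
      disc <- edge_discrepancies(M)
      ens1 <- null_ensemble(M, "structure", "dyadic", N = config$n_null,
                            swap_iterations = config$swap_iterations)
      ens2 <- null_ensemble(M, "discrepancy", "triadic", N = config$n_null)
      key <- paste0(m, "_kappa", kap)
      results[[key]] <- list(
        method = m, kappa = kap,
        n_functional_edges = sum(fnet$adjacency),
        dyadic_counts = dy,
        triadic_counts = tri,
        n_fp = nrow(disc$false_positives),
        n_fn = nrow(disc$false_negatives),
        dyadic_z = zscores(dy, ens1),
        triadic_z = zscores(tri, ens2))
    }
  }
  list(seed = trial_seed,
       n_structural_edges = sum(net$adjacency),
       spike_counts = lengths(trains$spike_times),
       network = net,
       results = results)
}

#' Aggregate trials into cross-trial means and standard deviations
#'
#' Element-wise mean and (population) SD across trials for counts and
#' Z-scores; undefined Z cells are excluded from the averages and the
#' number of trials in which each cell was defined is reported.
#'
#' @param trials list of \code{\link{run_trial}} outputs.
#' @return per (method, kappa): mean/sd arrays for dyadic and triadic
#'   counts and Z-scores, plus \code{dyadic_z_n_defined} /
#'   \code{triadic_z_n_defined}.
#' @export
aggregate_trials <- function(trials) {
  if (!length(trials)) stop("at least one completed trial is required")
  keys <- names(trials[[1]]$results)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg_stack <- function(mats) {
    arr <- simplify2array(mats)
    nd <- length(dim(arr))
    list(mean = apply(arr, seq_len(nd - 1), function(x) mean(x[!is.na(x)])),
         sd = apply(arr, seq_len(nd - 1),
                    function(x) if (sum(!is.na(x))) pop_sd(x[!is.na(x)]) else NA_real_),
         n_defined = apply(arr, seq_len(nd - 1), function(x) sum(!is.na(x))))
  }
  out <- lapply(keys, function(key) {
    per <- lapply(trials, function(tr) tr$results[[key]])
    dy <- agg_stack(lapply(per, function(p) as.numeric(p$dyadic_counts)))
    tri <- agg_stack(lapply(per, function(p) p$triadic_counts))
    dz <- agg_stack(lapply(per, function(p) p$dyadic_z$z))
    tz <- agg_stack(lapply(per, function(p) p$triadic_z$z))
    nm <- dyadic_class_names()
    names(dy$mean) <- names(dy$sd) <- nm
    names(dz$mean) <- names(dz$sd) <- nm
    list(method = per[[1]]$method, kappa = per[[1]]$kappa,
         dyadic_counts_mean = dy$mean, dyadic_counts_sd = dy$sd,
         triadic_counts_mean = tri$mean, triadic_counts_sd = tri$sd,
         dyadic_z_mean = dz$mean, dyadic_z_sd = dz$sd,
         dyadic_z_n_defined = dz$n_defined,
         triadic_z_mean = tz$mean, triadic_z_sd = tz$sd,
         triadic_z_n_defined = tz$n_defined,
         n_fp_mean = mean(vapply(per, function(p) p$n_fp, numeric(1))),
         n_fn_mean = mean(vapply(per, function(p) p$n_fn, numeric(1))))
  })
  names(out) <- keys
  out
}

#' Run a full experiment
#'
#' Derives one seed per trial from \code{config$seed}, runs the trials,
#' and aggregates.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param keep_trials keep the per-trial results in the return value.
#' @return list with \code{summary} (see \code{\link{aggregate_trials}}),
#'   \code{trial_seeds}, \code{config}, and optionally \code{trials}.
#' @export
run_experiment <- function(config = experiment_config(), keep_trials = TRUE) {
  set.seed(config$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, config$trials)
  trials <- lapply(trial_seeds, function(s) run_trial(config, s))
  out <- list(summary = aggregate_trials(trials),
              trial_seeds = trial_seeds,
              config = config)
  if (keep_trials) out$trials <- trials
  out
}

#' Write the experiment manifest (config and seeds) as YAML
#'
#' @param experiment output of \code{\link{run_experiment}}.
#' @param path output file.
#' @export
write_manifest_yaml <- function(experiment, path) {
  cfg <- unclass(experiment$config)
  cfg$cc_delays <- range(cfg$cc_delays)
  yaml::write_yaml(list(package = "spikemotif",
                        config = cfg,
                        trial_seeds = experiment$trial_seeds), path)
  invisible(path)
}
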