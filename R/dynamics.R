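#' Run Langevin dynamics for a fixed number of steps
#'
#' Integrates the coupled translational and rotational Langevin equations
#' with a BAOAB splitting: velocity-Verlet kicks and drifts around an
#' exact Ornstein-Uhlenbeck thermostat step whose noise amplitude satisfies
#' the fluctuation-dissipation relation, so the stationary distribution is
#' Boltzmann at `kBT`.  Moment orientations advance by `omega x e` with
#' per-step renormalization.  The run aborts with an error if any particle
#' moves more than a quarter nanoparticle diameter in one step (timestep
#' too large).
#'
#' Randomness is drawn from a counter-based stream: the state's
#' `params$seed` (or `seed`) plus the state's internal segment counter,
#' which increments on every call, so repeated calls continue a
#' deterministic trajectory and identical seeds reproduce it exactly.
#'
#' @param state An `mps_state`.
#' @param n_steps Number of timesteps.
#' @param thermostat Logical; `FALSE` gives pure (NVE-limit) dynamics.
#' @param seed Master seed for the noise stream (default `params$seed`).
#' @param energy_interval Record the energy trace every this many steps
#'   (0 disables).
#' @param sample_interval Store position/orientation frames every this many
#'   steps (0 disables).
#' @return The updated `mps_state`, with attributes `trace` (energy record)
#'   and `frames` (sampled configurations) from this segment.
#' @export
run_dynamics <- function(state, n_steps, thermostat = TRUE,
                         seed = state$params$seed,
                         energy_interval = 100L, sample_interval = 0L) {
  p <- state$params
  dyn <- list(dt = p$dt, kBT = p$kBT, mass = p$mass, mass_mnp = p$mass_mnp,
              inertia = p$inertia,
              zeta_t = p$zeta_t, zeta_r = p$zeta_r,
              thermostat = isTRUE(thermostat),
              energy_interval = as.integer(energy_interval),
              sample_interval = as.integer(sample_interval),
              max_disp = 0.25 * p$dp)
  res <- .cpp_run_langevin(.sim_topology(state), state$positions,
                           state$velocities, state$orientations,
                           state$ang_velocities, dyn, as.integer(n_steps),
                           as.double(seed), as.double(state$rng_counter))
  if (isTRUE(res$aborted)) stop(res$abort_msg, call. = FALSE)
  state$positions <- res$positions
  state$velocities <- res$velocities
  if (state$n_mnp > 0) {
    state$orientations <- res$orientations
    state$ang_velocities <- res$ang_velocities
  }
  state$time <- state$time + n_steps * p$dt
  state$rng_counter <- state$rng_counter + 1L
  state$wca_caps <- state$wca_caps + res$wca_caps
  validate_state(state)
  attr(state, "trace") <- res$trace
  attr(state, "frames") <- res$frames
  state
}

#' Advance the state by a single Langevin timestep
#'
#' @inheritParams run_dynamics
#' @return The updated `mps_state`.
#' @export
langevin_step <- function(state, thermostat = TRUE,
                          seed = state$params$seed) {
  run_dynamics(state, 1L, thermostat = thermostat, seed = seed,
               energy_interval = 0L)
}

#' Run protocol for equilibration and sampling
#'
#' @param equil_window Steps per equilibration window (>= 10 energy
#'   samples each).
#' @param equil_tolerance Relative change of the windowed mean total energy
#'   below which the system counts as equilibrated.
#' @param n_steps_max Hard cap on equilibration steps.
#' @param sample_interval Steps between observable samples in measurement
#'   runs.
#' @param n_measure_steps Length of the post-equilibration measurement run.
#' @return A `run_protocol` list.
#' @export
run_protocol <- function(equil_window = 50000L, equil_tolerance = 1e-3,
                         n_steps_max = 500000L, sample_interval = 1000L,
                         n_measure_steps = 20000L) {
  stopifnot(equil_window >= 10, equil_tolerance > 0,
            n_steps_max >= equil_window, sample_interval >= 1)
  structure(list(equil_window = as.integer(equil_window),
                 equil_tolerance = equil_tolerance,
                 n_steps_max = as.integer(n_steps_max),
                 sample_interval = as.integer(sample_interval),
                 n_measure_steps = as.integer(n_measure_steps)),
            class = "run_protocol")
}

#' Equilibrate a state by windowed energy stabilization
#'
#' Runs dynamics window by window until the relative change of the windowed
#' mean total energy (potential + kinetic) between consecutive windows
#' drops below the tolerance, or the step cap is reached (flagged with a
#' warning; the partial result is returned).
#'
#' @param state An `mps_state`.
#' @param protocol A [run_protocol()].
#' @param seed Master seed for the noise stream.
#' @param min_windows Minimum number of windows to run before testing.
#' @return The equilibrated `mps_state` with attributes `energy_trace`
#'   (matrix over all windows), `converged` (logical), `n_steps_run`.
#' @export
equilibrate <- function(state, protocol = run_protocol(),
                        seed = state$params$seed, min_windows = 2L) {
  win <- protocol$equil_window
  tol <- protocol$equil_tolerance
  e_int <- max(1L, win %/% 25L)
  traces <- list()
  prev_mean <- NULL
  converged <- FALSE
  steps <- 0L
  while (steps < protocol$n_steps_max) {
    state <- run_dynamics(state, win, seed = seed, energy_interval = e_int)
    steps <- steps + win
    tr <- attr(state, "trace")
    traces[[length(traces) + 1L]] <- tr
    mean_e <- mean(tr[, "E_pot"] + tr[, "E_kin_t"] + tr[, "E_kin_r"])
    if (!is.null(prev_mean) && length(traces) >= min_windows) {
      scale <- max(abs(prev_mean), abs(mean_e), state$params$kBT)
      if (abs(mean_e - prev_mean) / scale < tol) {
        converged <- TRUE
        prev_mean <- mean_e
        break
      }
    }
    prev_mean <- mean_e
  }
  if (!converged)
    warning("equilibration did not converge within n_steps_max = ",
            protocol$n_steps_max, " steps", call. = FALSE)
  trace <- do.call(rbind, traces)
  trace[, "step"] <- seq_len(nrow(trace)) * e_int
  attr(state, "energy_trace") <- trace
  attr(state, "converged") <- converged
  attr(state, "n_steps_run") <- steps
  state
}

#' Field-response experiment with replica averaging
#'
#' The full computational protocol for one capsule size: build the
#' membrane, seed the nanoparticles, equilibrate at zero field (basic
#' state), measure, switch the field on instantaneously, re-equilibrate,
#' and measure again.  Replicas share the geometry and nanoparticle
#' positions and differ only in the initial orientational distribution of
#' the magnetic moments (and in their thermostat noise).
#'
#' @param params An [model_params()] object; `params$xi` is the field
#'   applied in the second stage.
#' @param protocol A [run_protocol()] for the field stage.
#' @param seeds Integer vector of replica seeds (default
#'   `seq_len(params$n_replicas)`).
#' @param basic_protocol Optional separate [run_protocol()] for the
#'   zero-field stage (default: same as `protocol`).  The basic state
#'   relaxes much faster than the field-driven shape creep, so desk-scale
#'   runs usually give it a shorter window.
#' @param field_direction Unit vector of the applied field.
#' @param verbose Print per-replica progress.
#' @return A list of class `mps_experiment`: `replicas` (per-replica lists
#'   with `basic` and `field` observable records and final states),
#'   `summary` (data frame of replica means and standard errors of the
#'   elongation, cavity volume, volume defect, magnetization and chain
#'   statistics), `params`, `protocol`.
#' @export
run_field_experiment <- function(params, protocol = run_protocol(),
                                 seeds = seq_len(params$n_replicas),
                                 basic_protocol = protocol,
                                 field_direction = c(0, 0, 1),
                                 verbose = FALSE) {
  p <- validate_params(params)
  membrane <- build_membrane(p)
  replicas <- vector("list", length(seeds))
  for (r in seq_along(seeds)) {
    sd <- as.integer(seeds[r])
    dip <- seed_mnps(membrane, p, orientation_seed = sd)
    st <- system_state(membrane, dip, p, xi = 0,
                       field_direction = field_direction,
                       velocity_seed = sd)
    st <- equilibrate(st, basic_protocol, seed = sd)
    basic <- measure_run(st, basic_protocol, seed = sd)
    st <- basic$state
    st$xi <- p$xi
    st <- equilibrate(st, protocol, seed = sd)
    field <- measure_run(st, protocol, seed = sd)
    replicas[[r]] <- list(seed = sd,
                          basic = basic$record, field = field$record,
                          state = field$state)
    if (verbose)
      message(sprintf("replica %d: eps0 = %+.4f  eps(xi=%g) = %+.4f",
                      sd, basic$record$epsilon, p$xi, field$record$epsilon))
  }
  out <- list(replicas = replicas,
              summary = summarize_replicas(replicas),
              params = p, protocol = protocol)
  class(out) <- "mps_experiment"
  out
}

# measurement run: sample frames, average the observable record over them
measure_run <- function(state, protocol, seed = state$params$seed) {
  state <- run_dynamics(state, protocol$n_measure_steps, seed = seed,
                        energy_interval = 0L,
                        sample_interval = protocol$sample_interval)
  frames <- attr(state, "frames")
  recs <- lapply(frames, function(f) {
    observable_record(state, positions = f$positions,
                      orientations = f$orientations)
  })
  list(state = state, record = average_records(recs))
}

summarize_replicas <- function(replicas) {
  pull <- function(stage, field)
    vapply(replicas, function(r) r[[stage]][[field]], numeric(1))
  fields <- c("epsilon", "cavity_volume", "moment_projection",
              "mean_chain_length", "link_alignment", "polar_occupancy",
              "shell_area")
  rows <- lapply(fields, function(f) {
    b <- pull("basic", f)
    x <- pull("field", f)
    data.frame(observable = f,
               basic_mean = mean(b), basic_se = stats::sd(b) / sqrt(length(b)),
               field_mean = mean(x), field_se = stats::sd(x) / sqrt(length(x)))
  })
  sm <- do.call(rbind, rows)
  # volume defect uses the replica's own basic-state volume as reference
  vd <- vapply(replicas, function(r)
    (r$field$cavity_volume - r$basic$cavity_volume) / r$basic$cavity_volume,
    numeric(1))
  sm <- rbind(sm, data.frame(observable = "volume_defect",
                             basic_mean = 0, basic_se = 0,
                             field_mean = mean(vd),
                             field_se = stats::sd(vd) / sqrt(length(vd))))
  sm
}

#' @export
print.mps_experiment <- function(x, ...) {
  p <- x$params
  cat(sprintf("Field experiment: q = %g, lambda = %g, xi = %g, %d replicas\n",
              p$q, p$lambda, p$xi, length(x$replicas)))
  eps <- x$summary[x$summary$observable == "epsilon", ]
  vd <- x$summary[x$summary$observable == "volume_defect", ]
  cat(sprintf("  elongation eps = %.4f +- %.4f (basic %.4f +- %.4f)\n",
              eps$field_mean, eps$field_se, eps$basic_mean, eps$basic_se))
  cat(sprintf("  volume defect  = %.4f +- %.4f\n",
              vd$field_mean, vd$field_se))
  invisible(x)
}
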