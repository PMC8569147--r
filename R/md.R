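# Minimal classical MD on the package's force fields: velocity-Verlet NVE,
# BAOAB Langevin NVT, and NPT via Langevin dynamics plus an isotropic
# Monte Carlo barostat with molecular center-of-mass scaling. Units:
# positions Angstrom, velocities Angstrom/ps, masses amu, energies
# kcal/mol, time step in fs at the interface.

ACC_CONV <- 418.4  # (kcal/mol/Angstrom)/amu -> Angstrom/ps^2

#' Create an MD state from a cluster
#'
#' @param cl an \code{mbpef_cluster}; its box (if any) becomes the
#'   simulation cell.
#' @param velocities optional 3N x 3 matrix, Angstrom/ps; defaults to zero.
#' @return An object of class \code{mbpef_md_state} with fields \code{pos},
#'   \code{vel}, \code{masses}, \code{L} (NULL for gas phase), \code{step},
#'   \code{time} (ps) and cached \code{epot}/\code{forces}.
#' @export
md_state <- function(cl, velocities = NULL) {
  natom <- nrow(cl$coords)
  masses <- rep(c(mbpef_constants$mass_O, mbpef_constants$mass_H,
                  mbpef_constants$mass_H), cl$n_monomers)
  if (is.null(velocities)) velocities <- matrix(0, natom, 3)
  structure(list(pos = cl$coords, vel = velocities, masses = masses,
                 L = if (is.null(cl$box)) NULL else cl$box$L,
                 n_monomers = cl$n_monomers, step = 0L, time = 0,
                 epot = NULL, forces = NULL,
                 barostat_attempts = 0L, barostat_accepts = 0L,
                 barostat_cutoff_rejects = 0L),
            class = "mbpef_md_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param masses atomic masses, amu.
#' @param temperature K.
#' @param remove_com subtract the center-of-mass velocity.
#' @return natom x 3 matrix, Angstrom/ps.
#' @export
maxwell_velocities <- function(masses, temperature, remove_com = TRUE) {
  n <- length(masses)
  sd <- sqrt(mbpef_constants$kB * temperature * ACC_CONV / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  if (remove_com) {
    vc <- colSums(v * masses) / sum(masses)
    v <- sweep(v, 2, vc, `-`)
  }
  v
}

#' MD configuration
#'
#' @param dt_fs time step, fs (in (0, 2]).
#' @param temperature K (thermostat/barostat target).
#' @param pressure atm (barostat target).
#' @param gamma Langevin friction, 1/ps.
#' @param barostat_every attempt a volume move every this many steps.
#' @param max_lnV_step maximum ln-volume move size.
#' @param cutoff interaction cutoff, Angstrom (NULL: force-field default).
#' @param taper taper width, Angstrom.
#' @param seed RNG seed for the run (NULL: continue the current stream).
#' @param tune_barostat adapt \code{max_lnV_step} toward ~40\% acceptance
#'   (use during equilibration only).
#' @return List of class \code{mbpef_md_config}.
#' @export
md_config <- function(dt_fs = 0.2, temperature = 298, pressure = 1,
                      gamma = 1, barostat_every = 25L, max_lnV_step = 0.02,
                      cutoff = NULL, taper = 1.0, seed = 1L,
                      tune_barostat = FALSE) {
  if (dt_fs <= 0 || dt_fs > 2) stop("dt must be in (0, 2] fs")
  if (gamma < 0) stop("friction gamma must be >= 0")
  structure(list(dt_fs = dt_fs, temperature = temperature,
                 pressure = pressure, gamma = gamma,
                 barostat_every = as.integer(barostat_every),
                 max_lnV_step = max_lnV_step, cutoff = cutoff, taper = taper,
                 seed = seed, tune_barostat = tune_barostat),
            class = "mbpef_md_config")
}

#' Force-field closure for the toy model
#'
#' @param model an \code{mbpef_toy_model}.
#' @param cutoff,taper periodic interaction range (cutoff NULL:
#'   \code{min(9, 0.49 L)}).
#' @return Function \code{(pos, L, forces = TRUE)} returning
#'   \code{list(energy, forces)}.
#' @export
toy_force_field <- function(model = toy_water_model(), cutoff = NULL,
                            taper = 1.0) {
  pars <- unclass(model)
  function(pos, L, forces = TRUE) {
    if (is.null(L)) toy_eval_cpp(pos, pars, -1, -1, taper, forces)
    else {
      rc <- if (is.null(cutoff)) min(9.0, 0.49 * L) else cutoff
      toy_eval_cpp(pos, pars, L, rc, taper, forces)
    }
  }
}

#' Force-field closure for a PEF model
#'
#' @param model an \code{mbpef_model}.
#' @inheritParams toy_force_field
#' @return Function \code{(pos, L, forces = TRUE)}.
#' @export
pef_force_field <- function(model, cutoff = NULL, taper = 1.0) {
  mcpp <- model_for_cpp(model)
  reach0 <- max(c(0, if (!is.null(model$pip2b)) model$pip2b$basis$rout,
                  if (!is.null(model$pip3b)) model$pip3b$basis$rout))
  function(pos, L, forces = TRUE) {
    if (is.null(L)) pef_eval_cpp(pos, mcpp, -1, -1, taper, forces)
    else {
      rc <- if (is.null(cutoff)) min(9.0, 0.49 * L) else cutoff
      if (max(rc, reach0) >= L / 2)
        stop(sprintf("interaction range %.3f A must be < L/2 = %.3f A",
                     max(rc, reach0), L / 2))
      pef_eval_cpp(pos, mcpp, L, rc, taper, forces)
    }
  }
}

ensure_forces <- function(state, ff) {
  if (is.null(state$forces)) {
    r <- ff(state$pos, state$L)
    if (!all(is.finite(r$forces))) {
      bad <- which(!apply(is.finite(r$forces), 1, all))[1]
      stop(sprintf("non-finite force on atom %d", bad))
    }
    state$epot <- r$energy
    state$forces <- r$forces
  }
  state
}

#' One velocity-Verlet (NVE) step
#'
#' Standard kick-drift-kick update; forces are cached in the state so each
#' step costs one force evaluation.
#'
#' @param state an \code{mbpef_md_state}.
#' @param ff a force-field closure.
#' @param dt_fs time step, fs.
#' @return The advanced state.
#' @export
velocity_verlet_step <- function(state, ff, dt_fs) {
  dt <- dt_fs * 1e-3
  state <- ensure_forces(state, ff)
  vhalf <- state$vel + (0.5 * dt * ACC_CONV / state$masses) * state$forces
  pos <- state$pos + dt * vhalf
  r <- ff(pos, state$L)
  if (!all(is.finite(r$forces))) {
    bad <- which(!apply(is.finite(r$forces), 1, all))[1]
    stop(sprintf("non-finite force on atom %d at step %d", bad,
                 state$step + 1L))
  }
  state$vel <- vhalf + (0.5 * dt * ACC_CONV / state$masses) * r$forces
  state$pos <- pos
  state$forces <- r$forces
  state$epot <- r$energy
  state$step <- state$step + 1L
  state$time <- state$time + dt
  state
}

#' One BAOAB Langevin (NVT) step
#'
#' Splitting: half kick, half drift, Ornstein-Uhlenbeck velocity update
#' v <- e^{-gamma dt} v + sqrt((1 - e^{-2 gamma dt}) kB T / m) xi, half
#' drift, half kick. With \code{gamma = 0} the step reduces exactly
#' (bit-identically) to \code{\link{velocity_verlet_step}}.
#'
#' @inheritParams velocity_verlet_step
#' @param temperature target temperature, K.
#' @param gamma friction, 1/ps.
#' @return The advanced state.
#' @export
langevin_step <- function(state, ff, dt_fs, temperature, gamma) {
  if (gamma < 0) stop("friction gamma must be >= 0")
  if (gamma == 0) return(velocity_verlet_step(state, ff, dt_fs))
  dt <- dt_fs * 1e-3
  state <- ensure_forces(state, ff)
  v <- state$vel + (0.5 * dt * ACC_CONV / state$masses) * state$forces
  pos <- state$pos + (0.5 * dt) * v
  c1 <- exp(-gamma * dt)
  c2 <- sqrt((1 - c1^2) * mbpef_constants$kB * temperature * ACC_CONV /
             state$masses)
  v <- c1 * v + c2 * matrix(stats::rnorm(length(v)), nrow(v), 3)
  pos <- pos + (0.5 * dt) * v
  r <- ff(pos, state$L)
  state$vel <- v + (0.5 * dt * ACC_CONV / state$masses) * r$forces
  state$pos <- pos
  state$forces <- r$forces
  state$epot <- r$energy
  state$step <- state$step + 1L
  state$time <- state$time + dt
  state
}

#' One isotropic Monte Carlo barostat move
#'
#' Proposes a uniform ln-volume change, scales molecular centers of mass
#' (internal geometries rigid under the scaling), and accepts with
#' probability min(1, exp(-[dU + P dV - (N_mol + 1) kB T ln(V'/V)] / kB T)).
#' A rejected move restores the state bit-exactly. Moves that would shrink
#' the box below twice the interaction cutoff are rejected and counted in
#' \code{barostat_cutoff_rejects}.
#'
#' @param state an \code{mbpef_md_state} with a box.
#' @param ff force-field closure (used for potential energy only).
#' @param pressure target pressure, atm.
#' @param temperature K.
#' @param max_lnV_step maximum ln-volume move.
#' @param cutoff interaction cutoff used for the shrink guard (Angstrom).
#' @return The (possibly) updated state.
#' @export
mc_barostat_move <- function(state, ff, pressure, temperature,
                             max_lnV_step = 0.02, cutoff = NULL) {
  if (is.null(state$L)) stop("barostat needs a periodic box")
  state <- ensure_forces(state, ff)
  kBT <- mbpef_constants$kB * temperature
  V <- state$L^3
  dln <- stats::runif(1, -max_lnV_step, max_lnV_step)
  u <- stats::runif(1)
  V2 <- exp(log(V) + dln)
  L2 <- V2^(1 / 3)
  state$barostat_attempts <- state$barostat_attempts + 1L
  if (!is.null(cutoff) && L2 < 2 * cutoff) {
    state$barostat_cutoff_rejects <- state$barostat_cutoff_rejects + 1L
    return(state)
  }
  scale <- L2 / state$L
  mol <- rep(seq_len(state$n_monomers), each = 3L)
  mw <- state$masses
  com <- rowsum(state$pos * mw, mol) / rowsum(mw, mol)[, 1]
  disp <- (scale - 1) * com
  pos2 <- state$pos + disp[mol, ]
  e2 <- ff(pos2, L2, forces = FALSE)$energy
  nmol <- state$n_monomers
  arg <- -(e2 - state$epot +
           pressure * (V2 - V) * mbpef_constants$atmA3_to_kcal -
           (nmol + 1) * kBT * log(V2 / V)) / kBT
  if (log(u) < arg) {
    state$pos <- pos2
    state$L <- L2
    state$epot <- e2
    state$forces <- NULL  # stale after the move
    state$barostat_accepts <- state$barostat_accepts + 1L
  }
  state
}

#' Minimize the potential energy by damped steepest descent
#'
#' Simple backtracking gradient descent on atomic positions, used to
#' relieve bad contacts in generated configurations before dynamics.
#'
#' @param state an \code{mbpef_md_state}.
#' @param ff force-field closure.
#' @param n_steps maximum descent steps.
#' @param max_disp initial per-component displacement cap, Angstrom.
#' @param tol stop when the maximum force component drops below this,
#'   kcal/mol/Angstrom.
#' @return The state with relaxed positions (velocities untouched).
#' @export
minimize_energy <- function(state, ff, n_steps = 200L, max_disp = 0.2,
                            tol = 1.0) {
  state <- ensure_forces(state, ff)
  step <- max_disp
  for (it in seq_len(n_steps)) {
    fmax <- max(abs(state$forces))
    if (fmax < tol) break
    trial <- state$pos + state$forces * (step / fmax)
    r <- ff(trial, state$L)
    if (r$energy < state$epot) {
      state$pos <- trial
      state$epot <- r$energy
      state$forces <- r$forces
      step <- min(step * 1.2, max_disp)
    } else {
      step <- step / 2
      if (step < 1e-6) break
    }
  }
  state
}

kinetic_energy <- function(state) {
  0.5 * sum(state$masses * rowSums(state$vel^2)) / ACC_CONV
}

instantaneous_temperature <- function(state) {
  ndof <- 3 * length(state$masses) - 3
  2 * kinetic_energy(state) / (ndof * mbpef_constants$kB)
}

#' Run an MD simulation
#'
#' Drives the component steps for the requested ensemble: \code{"nve"}
#' (velocity Verlet), \code{"nvt"} (BAOAB Langevin) or \code{"npt"}
#' (Langevin plus MC barostat attempts every \code{barostat_every} steps).
#' A single seeded RNG stream drives thermostat and barostat in fixed
#' order, so runs are exactly restartable from a checkpoint.
#'
#' @param state an \code{mbpef_md_state}.
#' @param ff force-field closure (see \code{\link{toy_force_field}},
#'   \code{\link{pef_force_field}}).
#' @param config an \code{mbpef_md_config}.
#' @param ensemble "nve", "nvt" or "npt".
#' @param n_steps number of steps.
#' @param thermo_every record thermodynamic output every this many steps.
#' @param traj_every record trajectory frames every this many steps
#'   (0: none).
#' @return List with \code{state} (final), \code{thermo} (data frame:
#'   step, time_ps, epot, ekin, etot, T_K, V_A3, rho_gcm3) and
#'   \code{trajectory} (an \code{mbpef_trajectory} or NULL).
#' @export
run_simulation <- function(state, ff, config, ensemble = c("nvt", "nve", "npt"),
                           n_steps, thermo_every = 25L, traj_every = 0L) {
  ensemble <- match.arg(ensemble)
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- ensure_forces(state, ff)
  nrec <- floor(n_steps / thermo_every) + 1L
  th <- matrix(NA_real_, nrec, 8)
  frames <- list()
  mass_tot <- sum(state$masses)
  record <- function(state, row) {
    ek <- kinetic_energy(state)
    V <- if (is.null(state$L)) NA_real_ else state$L^3
    th[row, ] <<- c(state$step, state$time, state$epot, ek,
                    state$epot + ek, instantaneous_temperature(state), V,
                    if (is.na(V)) NA_real_ else mass_tot / (0.602214076 * V))
  }
  record(state, 1L)
  row <- 1L
  barostat_window <- c(0L, 0L)  # attempts, accepts (for tuning)
  for (s in seq_len(n_steps)) {
    state <- switch(ensemble,
      nve = velocity_verlet_step(state, ff, config$dt_fs),
      nvt = langevin_step(state, ff, config$dt_fs, config$temperature,
                          config$gamma),
      npt = langevin_step(state, ff, config$dt_fs, config$temperature,
                          config$gamma))
    if (ensemble == "npt" && s %% config$barostat_every == 0L) {
      acc0 <- state$barostat_accepts
      state <- mc_barostat_move(state, ff, config$pressure,
                                config$temperature, config$max_lnV_step,
                                config$cutoff)
      if (config$tune_barostat) {
        barostat_window <- barostat_window +
          c(1L, state$barostat_accepts - acc0)
        if (barostat_window[1] >= 25L) {
          rate <- barostat_window[2] / barostat_window[1]
          if (rate > 0.45) config$max_lnV_step <-
              min(config$max_lnV_step * 1.2, 0.2)
          if (rate < 0.35) config$max_lnV_step <-
              max(config$max_lnV_step / 1.2, 1e-4)
          barostat_window <- c(0L, 0L)
        }
      }
    }
    if (s %% thermo_every == 0L) {
      row <- row + 1L
      record(state, row)
    }
    if (traj_every > 0L && s %% traj_every == 0L) {
      frames[[length(frames) + 1L]] <- list(
        cluster = cluster(state$pos, label = sprintf("step%d", state$step),
                          box = if (is.null(state$L)) NULL else
                            periodic_box(state$L)),
        velocities = state$vel, time = state$time)
    }
  }
  thermo <- as.data.frame(th[seq_len(row), , drop = FALSE])
  names(thermo) <- c("step", "time_ps", "epot", "ekin", "etot", "T_K",
                     "V_A3", "rho_gcm3")
  list(state = state,
       thermo = thermo,
       trajectory = if (length(frames)) trajectory(frames) else NULL,
       final_max_lnV_step = config$max_lnV_step)
}

#' Checkpoint an MD run
#'
#' Captures the state and the RNG stream so that a continued run
#' reproduces an uninterrupted one bit-exactly (continue with
#' \code{seed = NULL} in the config after \code{\link{restore_checkpoint}}).
#'
#' @param state an \code{mbpef_md_state}.
#' @return A checkpoint object.
#' @export
checkpoint_state <- function(state) {
  list(state = state,
       rng = get(".Random.seed", envir = globalenv(), inherits = FALSE))
}

#' Restore a checkpoint's RNG stream and return its state
#'
#' @param ck a checkpoint from \code{\link{checkpoint_state}}.
#' @return The stored \code{mbpef_md_state}.
#' @export
restore_checkpoint <- function(ck) {
  assign(".Random.seed", ck$rng, envir = globalenv())
  ck$state
}
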