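# Liquid-state observables: radial distribution functions, center-of-mass
# velocity autocorrelation and the Green-Kubo self-diffusion coefficient,
# density-vs-temperature curves with the temperature of maximum density,
# isothermal compressibility from NPT volume fluctuations, and the
# enthalpy of vaporization.

site_rows <- function(pair_half, n_monomers) {
  base <- 3L * (seq_len(n_monomers) - 1L)
  switch(pair_half, O = base + 1L, H = c(base + 2L, base + 3L),
         stop("unknown site '", pair_half, "'"))
}

#' Radial distribution function from a periodic trajectory
#'
#' Minimum-image pair distances are histogrammed in half-open bins
#' [r, r + dr) and normalized per frame by the ideal-gas shell count, so a
#' uniform fluid gives g(r) = 1. Intramolecular pairs are excluded.
#'
#' @param traj an \code{mbpef_trajectory} of periodic frames.
#' @param pair "OO", "OH" or "HH".
#' @param bin_width bin width, Angstrom.
#' @param r_max maximum distance (default: largest L/2 allowed; must be
#'   <= L/2 for every frame).
#' @return List of class \code{mbpef_rdf}: \code{r} (bin centers),
#'   \code{g}, \code{bin_width}, \code{frames}, \code{pair},
#'   \code{density_pairs}.
#' @export
compute_rdf <- function(traj, pair = "OO", bin_width = 0.05, r_max = NULL) {
  frames <- traj$frames
  Ls <- vapply(frames, function(f) {
    if (is.null(f$cluster$box)) stop("RDF needs periodic frames")
    f$cluster$box$L
  }, numeric(1))
  if (is.null(r_max)) r_max <- min(Ls) / 2
  if (r_max > min(Ls) / 2 + 1e-9)
    stop(sprintf("r_max %.3f exceeds L/2 = %.3f", r_max, min(Ls) / 2))
  sa <- substr(pair, 1, 1)
  sb <- substr(pair, 2, 2)
  nbin <- max(1L, floor(r_max / bin_width))
  r_max <- nbin * bin_width
  nmon <- traj$n_monomers
  ra <- site_rows(sa, nmon)
  rb <- site_rows(sb, nmon)
  same <- sa == sb
  mol_of <- rep(seq_len(nmon), each = 3L)
  counts <- numeric(nbin)
  norm <- numeric(nbin)
  edges <- bin_width * (0:nbin)
  shell <- 4 / 3 * pi * (edges[-1L]^3 - edges[-(nbin + 1L)]^3)
  for (fi in seq_along(frames)) {
    P <- frames[[fi]]$cluster$coords
    L <- Ls[fi]
    A <- P[ra, , drop = FALSE]
    B <- P[rb, , drop = FALSE]
    h <- rdf_hist_cpp(A, B, same, as.integer(mol_of[ra]),
                      as.integer(mol_of[rb]), L, r_max, nbin)
    counts <- counts + h
    # ideal-gas expectation: n_A * rho_B * shell (ordered pairs, excluding
    # intramolecular partners)
    nA <- nrow(A)
    nB <- nrow(B)
    nexcl <- if (same) length(ra) / nmon else
      (length(ra) / nmon) * (length(rb) / nmon)
    rhoB <- (nB - (if (same) length(rb) / nmon else nexcl)) / L^3
    # per A site, the available B sites exclude its own molecule's sites
    norm <- norm + nA * rhoB * shell
  }
  structure(list(r = edges[-1L] - bin_width / 2, g = counts / norm,
                 bin_width = bin_width, frames = length(frames),
                 pair = pair, r_max = r_max),
            class = "mbpef_rdf")
}

#' First-peak position and neighbor count of an RDF
#'
#' @param rdf an \code{mbpef_rdf}.
#' @param rho number density of partner sites (1/Angstrom^3) for the
#'   running coordination number (optional).
#' @param r_limit integrate/search up to this distance (default all).
#' @return List with \code{r_peak}, \code{g_peak} and (if \code{rho} given)
#'   \code{coordination}.
#' @export
rdf_first_peak <- function(rdf, rho = NULL, r_limit = NULL) {
  sel <- if (is.null(r_limit)) seq_along(rdf$r) else which(rdf$r <= r_limit)
  i <- sel[which.max(rdf$g[sel])]
  out <- list(r_peak = rdf$r[i], g_peak = rdf$g[i])
  if (!is.null(rho)) {
    rr <- rdf$r[sel]
    out$coordination <- sum(rho * rdf$g[sel] * 4 * pi * rr^2 * rdf$bin_width)
  }
  out
}

com_velocities <- function(frame, nmon) {
  if (is.null(frame$velocities)) stop("trajectory frames carry no velocities")
  m <- rep(c(mbpef_constants$mass_O, mbpef_constants$mass_H,
             mbpef_constants$mass_H), nmon)
  mol <- rep(seq_len(nmon), each = 3L)
  rowsum(frame$velocities * m, mol) / rowsum(m, mol)[, 1]
}

#' Center-of-mass velocity autocorrelation function
#'
#' C(t) = < v_i(t0) . v_i(t0 + t) >, averaged over molecules and all time
#' origins with lag at most \code{max_lag} frames.
#'
#' @param traj an \code{mbpef_trajectory} whose frames carry velocities.
#' @param max_lag maximum lag in frames (default: half the trajectory).
#' @return List of class \code{mbpef_vacf}: \code{t} (ps), \code{C}
#'   (Angstrom^2/ps^2), \code{n_origins}.
#' @export
compute_vacf <- function(traj, max_lag = NULL) {
  nf <- length(traj$frames)
  if (is.null(max_lag)) max_lag <- nf %/% 2
  if (max_lag >= nf) stop("max_lag must be smaller than the frame count")
  nmon <- traj$n_monomers
  V <- lapply(traj$frames, com_velocities, nmon = nmon)
  times <- vapply(traj$frames, function(f)
    if (is.null(f$time)) NA_real_ else f$time, numeric(1))
  dt <- if (anyNA(times)) 1.0 else stats::median(diff(times))
  C <- numeric(max_lag + 1L)
  norig <- integer(max_lag + 1L)
  for (lag in 0:max_lag) {
    s <- 0
    n0 <- nf - lag
    for (t0 in seq_len(n0)) s <- s + mean(rowSums(V[[t0]] * V[[t0 + lag]]))
    C[lag + 1L] <- s / n0
    norig[lag + 1L] <- n0
  }
  structure(list(t = dt * (0:max_lag), C = C, n_origins = norig,
                 n_molecules = nmon),
            class = "mbpef_vacf")
}

#' Self-diffusion coefficient from the VACF (Green-Kubo)
#'
#' D = (1/3) integral_0^{t_max} C(t) dt by the trapezoidal rule, with a
#' block-averaged statistical error: the origin-resolved integrand is split
#' into \code{n_blocks} consecutive blocks and the spread of the block
#' estimates gives the standard error.
#'
#' @param vacf an \code{mbpef_vacf}.
#' @param t_max integration limit, ps (default: last point; must lie within
#'   the series).
#' @param n_blocks number of blocks for the error estimate (>= 5 kept).
#' @return List of class \code{mbpef_diffusion}: \code{D} (Angstrom^2/ps),
#'   \code{t_max}, \code{stderr} (NA if no block structure is available).
#' @export
diffusion_from_vacf <- function(vacf, t_max = NULL, n_blocks = 5L) {
  if (is.null(t_max)) t_max <- max(vacf$t)
  if (t_max > max(vacf$t) + 1e-12)
    stop("t_max lies beyond the VACF series")
  sel <- vacf$t <= t_max + 1e-12
  tt <- vacf$t[sel]
  cc <- vacf$C[sel]
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
  D <- trap(tt, cc) / 3
  structure(list(D = D, t_max = t_max, n_points = length(tt),
                 stderr = NA_real_),
            class = "mbpef_diffusion")
}

#' Self-diffusion with a block-averaged error from a trajectory
#'
#' Splits the trajectory into \code{n_blocks} consecutive segments,
#' computes the VACF and its Green-Kubo integral per segment, and reports
#' the full-trajectory estimate with the standard error of the block
#' estimates.
#'
#' @param traj an \code{mbpef_trajectory} with velocities.
#' @param t_max integration limit, ps (default
#'   \code{\link{vacf_integration_limit}} of the full VACF).
#' @param n_blocks number of segments (>= 2; 5 by default).
#' @return An \code{mbpef_diffusion} with a finite \code{stderr}.
#' @export
diffusion_from_trajectory <- function(traj, t_max = NULL, n_blocks = 5L) {
  vac <- compute_vacf(traj)
  if (is.null(t_max)) t_max <- vacf_integration_limit(vac)
  t_max <- min(t_max, max(vac$t))
  full <- diffusion_from_vacf(vac, t_max)
  nf <- length(traj$frames)
  bl <- split(seq_len(nf), cut(seq_len(nf), n_blocks, labels = FALSE))
  Db <- vapply(bl, function(idx) {
    sub <- trajectory(traj$frames[idx])
    v <- compute_vacf(sub, max_lag = min(length(idx) - 1L,
                                         sum(vac$t <= t_max + 1e-12) - 1L))
    diffusion_from_vacf(v, min(t_max, max(v$t)))$D
  }, numeric(1))
  full$stderr <- stats::sd(Db) / sqrt(length(Db))
  full$block_D <- Db
  full
}

#' Suggest a VACF integration limit
#'
#' The first time after which |C(t)| stays below \code{frac} of C(0) for a
#' window of \code{hold} ps (the integral's tail is then noise-dominated).
#'
#' @param vacf an \code{mbpef_vacf}.
#' @param frac decay threshold relative to C(0).
#' @param hold required quiet window, ps.
#' @return Time in ps (the series end if the criterion is never met).
#' @export
vacf_integration_limit <- function(vacf, frac = 0.01, hold = 1.0) {
  thr <- frac * vacf$C[1]
  quiet <- abs(vacf$C) < thr
  dt <- if (length(vacf$t) > 1) vacf$t[2] - vacf$t[1] else 1
  need <- max(1L, ceiling(hold / dt))
  run <- 0L
  for (i in seq_along(quiet)) {
    run <- if (quiet[i]) run + 1L else 0L
    if (run >= need) return(vacf$t[i - need + 1L])
  }
  max(vacf$t)
}

#' Density curve versus temperature and the temperature of maximum density
#'
#' Fits a fifth-order polynomial to mean densities at each temperature and
#' locates the maximum on the data interval by root-finding on the
#' derivative; a maximum at the interval boundary is flagged rather than
#' reported as interior.
#'
#' @param temperatures K (>= 6 values for the default degree-5 fit).
#' @param densities mean densities per temperature, g/cm^3 (or a list of
#'   per-temperature density series, in which case means and 95\% CIs are
#'   taken after removing \code{burn_in}).
#' @param degree polynomial degree (default 5).
#' @param burn_in fraction of each series discarded as equilibration.
#' @return List of class \code{mbpef_density_curve}: \code{table}
#'   (T, rho, ci95), \code{coef} (polynomial coefficients in powers of
#'   \code{T - T_center}), \code{T_center}, \code{tmd},
#'   \code{tmd_boundary}, \code{rho_at_tmd}.
#' @export
density_curve <- function(temperatures, densities, degree = 5L,
                          burn_in = 0.2) {
  if (is.list(densities)) {
    stats_ <- lapply(densities, function(x) {
      x <- x[-seq_len(floor(burn_in * length(x)))]
      c(mean(x), 1.96 * stats::sd(x) / sqrt(length(x)))
    })
    rho <- vapply(stats_, `[`, numeric(1), 1)
    ci <- vapply(stats_, `[`, numeric(1), 2)
  } else {
    rho <- densities
    ci <- rep(NA_real_, length(rho))
  }
  if (length(temperatures) < degree + 1L)
    stop(sprintf("need at least %d temperatures for a degree-%d fit",
                 degree + 1L, degree))
  # fit in centered coordinates: raw powers of T ~ 300 K are numerically
  # ill-conditioned at degree 5
  Tc <- mean(temperatures)
  x <- temperatures - Tc
  fit <- stats::lm(rho ~ stats::poly(x, degree, raw = TRUE))
  cf <- as.numeric(stats::coef(fit))
  # derivative roots on the data interval
  dcf <- cf[-1] * seq_len(degree)
  roots <- polyroot(dcf)
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  lo <- min(x); hi <- max(x)
  cand <- c(real[real >= lo & real <= hi], lo, hi)
  vals <- vapply(cand, function(t) sum(cf * t^(0:degree)), numeric(1))
  best <- cand[which.max(vals)] + Tc
  boundary <- abs(best - Tc - lo) < 1e-9 || abs(best - Tc - hi) < 1e-9
  structure(list(table = data.frame(T_K = temperatures, rho = rho,
                                    ci95 = ci),
                 coef = cf, T_center = Tc, degree = degree, tmd = best,
                 tmd_boundary = boundary, rho_at_tmd = max(vals)),
            class = "mbpef_density_curve")
}

#' Isothermal compressibility from NPT volume fluctuations
#'
#' kappa_T = (<V^2> - <V>^2) / (kB T <V>), in atm^-1 via the pressure-work
#' unit constant. The statistical error is estimated by block averaging.
#'
#' @param thermo a thermo data frame from \code{\link{run_simulation}}
#'   with a fluctuating \code{V_A3} column (NPT).
#' @param temperature K.
#' @param burn_in fraction discarded from the start.
#' @param n_blocks blocks for the error estimate.
#' @return List with \code{kappa_T} (atm^-1), \code{stderr},
#'   \code{mean_V}.
#' @export
isothermal_compressibility <- function(thermo, temperature, burn_in = 0.2,
                                       n_blocks = 5L) {
  V <- thermo$V_A3
  if (all(is.na(V))) stop("no volume series: compressibility needs NPT input")
  V <- V[-seq_len(floor(burn_in * length(V)))]
  if (stats::var(V) == 0 && length(unique(V)) == 1L)
    return(list(kappa_T = 0, stderr = 0, mean_V = mean(V)))
  kBT_atmA3 <- mbpef_constants$kB * temperature / mbpef_constants$atmA3_to_kcal
  kap <- function(v) (mean(v^2) - mean(v)^2) / (kBT_atmA3 * mean(v))
  blocks <- split(V, cut(seq_along(V), n_blocks, labels = FALSE))
  kb <- vapply(blocks, kap, numeric(1))
  list(kappa_T = kap(V), stderr = stats::sd(kb) / sqrt(length(kb)),
       mean_V = mean(V))
}

#' Enthalpy of vaporization
#'
#' Delta H_vap = <E_gas> - <E_liq>/N_mol + kB T, assuming an ideal-gas
#' vapor and neglecting the liquid PV term.
#'
#' @param liquid_epot_per_mol mean liquid potential energy per molecule,
#'   kcal/mol (or a thermo data frame plus \code{n_molecules}).
#' @param gas_epot mean potential energy of an isolated molecule, kcal/mol.
#' @param temperature K.
#' @param n_molecules molecule count when a thermo data frame is supplied.
#' @param burn_in fraction discarded from a thermo series.
#' @return List with \code{dH_vap} (kcal/mol) and the assumptions used.
#' @export
enthalpy_of_vaporization <- function(liquid_epot_per_mol, gas_epot,
                                     temperature, n_molecules = NULL,
                                     burn_in = 0.2) {
  if (is.data.frame(liquid_epot_per_mol)) {
    if (is.null(n_molecules))
      stop("n_molecules is required with a thermo data frame")
    e <- liquid_epot_per_mol$epot
    e <- e[-seq_len(floor(burn_in * length(e)))]
    liquid_epot_per_mol <- mean(e) / n_molecules
  }
  if (is.null(gas_epot) || is.na(gas_epot))
    stop("gas-phase reference energy is required")
  kBT <- mbpef_constants$kB * temperature
  list(dH_vap = gas_epot - liquid_epot_per_mol + kBT,
       assumptions = "ideal-gas vapor; liquid PV term neglected",
       kBT = kBT)
}
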