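# Brownian-dynamics driver: Boltzmann pre-equilibration, the Ito update
#
#   x <- x + sqrt(2 D dt) xi_x
#   y <- y + sqrt(2 D dt) xi_y
#   z <- z - D (dU/dz) dt + (dD/dz) dt + sqrt(2 D dt) xi_z     (kBT = 1)
#
# with D, dU/dz, dD/dz evaluated at the pre-step position (the explicit
# +dD/dz term is exactly the Ito-consistent correction for multiplicative
# noise), and the timestep-validation protocol.

#' Draw initial positions from the Boltzmann distribution
#'
#' z is sampled from the density proportional to exp(-U(z)) over one period
#' [-a/2, a/2) by inverse-transform sampling on a dense grid; x = y = 0.
#'
#' @param U a `meso_profile` potential (bounded).
#' @param n number of particles.
#' @param seed optional integer seed (calls [set.seed()]); the draw is
#'   deterministic given the seed.
#' @param grid_n resolution of the inverse-CDF grid.
#' @return An n x 3 matrix of initial positions (columns x, y, z; nm).
#' @export
sample_boltzmann <- function(U, n, seed = NULL, grid_n = 40001L) {
  stopifnot(inherits(U, "meso_profile"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- U$period
  zg <- seq(-a / 2, a / 2, length.out = grid_n)
  w <- exp(-profile_value(U, zg))
  if (any(!is.finite(w))) stop("exp(-U) is not finite: the potential must be bounded")
  dz <- zg[2] - zg[1]
  cw <- cumsum((w[-1] + w[-grid_n]) / 2) * dz
  cdf <- c(0, cw / cw[grid_n - 1L])
  z <- stats::approx(cdf, zg, xout = stats::runif(n), ties = "ordered")$y
  cbind(x = numeric(n), y = numeric(n), z = z)
}

#' Simulation configuration
#'
#' Times are expressed in the natural unit tau = sigma^2/Dwat of the
#' attached [unit_system()]; the integrator itself works in nm and ns.
#'
#' @param n_particles ensemble size.
#' @param t_total total simulated time (tau).
#' @param seed integer RNG seed (mandatory: every run is reproducible).
#' @param dt timestep (tau); default 3e-4, validated to sample the
#'   equilibrium distribution correctly (see [validate_timestep()]).
#' @param n_frames number of recorded frames.
#' @param frame_spacing `"log"` (default; MSD analyses span decades) or
#'   `"linear"` (density/histogram analyses).
#' @param units a [unit_system()]; defaults to Dwat = 0.7 nm^2/ns.
#' @return A `bd_config` list.
#' @export
bd_config <- function(n_particles, t_total, seed, dt = 3e-4,
                      n_frames = 200L, frame_spacing = c("log", "linear"),
                      units = unit_system(Dwat = 0.7)) {
  frame_spacing <- match.arg(frame_spacing)
  stopifnot(is.numeric(dt), dt > 0, n_particles >= 1, t_total >= dt,
            is.numeric(seed), length(seed) == 1L, is.finite(seed),
            inherits(units, "meso_units"))
  structure(list(n_particles = as.integer(n_particles), t_total = t_total,
                 seed = as.integer(seed), dt = dt,
                 n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, units = units),
            class = "bd_config")
}

frame_steps <- function(n_steps, n_frames, spacing) {
  if (spacing == "log") {
    s <- unique(round(exp(seq(0, log(n_steps), length.out = n_frames))))
  } else {
    s <- unique(round(seq(1, n_steps, length.out = n_frames)))
  }
  as.integer(s[s >= 1 & s <= n_steps])
}

# Dense half-period lookup tables consumed by the C++ core.
profile_tables <- function(U, D, M = 8192L) {
  a <- U$period
  zg <- seq(0, a / 2, length.out = M + 1L)
  list(D = profile_value(D, zg), dD = profile_deriv(D, zg),
       dU = profile_deriv(U, zg))
}

#' Integrate an ensemble of Brownian particles
#'
#' Overdamped Ito dynamics in 3-D with a one-dimensional periodic potential
#' U(z) and position-dependent diffusivity D(z); the same local D drives the
#' noise in all three directions. Trajectories are unwrapped (z is never
#' folded), as required by mean-square-displacement analysis. Each particle
#' has its own RNG substream derived from the seed, so results do not depend
#' on particle ordering.
#'
#' @param U,D `meso_profile` objects sharing the same period.
#' @param config a [bd_config()].
#' @param start optional n x 3 matrix of initial positions; defaults to
#'   Boltzmann pre-equilibration via [sample_boltzmann()] with the config
#'   seed.
#' @param spurious_drift if `FALSE`, drop the +dD/dz correction (negative
#'   control only: without it the stationary density is biased towards
#'   low-D regions).
#' @param noise if `FALSE`, suppress the stochastic terms and integrate the
#'   deterministic drift only (testing aid for the update rule).
#' @param table_n resolution of the internal profile lookup tables.
#' @return A `meso_trajectory`: list with time grid `t` (ns, first entry 0)
#'   and n x frames matrices `x`, `y`, `z` (nm, unwrapped, first column the
#'   initial positions), plus the config.
#' @export
bd_simulate <- function(U, D, config, start = NULL, spurious_drift = TRUE,
                        noise = TRUE, table_n = 8192L) {
  stopifnot(inherits(U, "meso_profile"), inherits(D, "meso_profile"),
            inherits(config, "bd_config"))
  if (abs(U$period - D$period) > 1e-9 * U$period)
    stop("U and D must share the same period")
  tau <- config$units$tau
  dt_ns <- config$dt * tau
  n_steps <- max(1L, as.integer(round(config$t_total / config$dt)))
  rec <- frame_steps(n_steps, config$n_frames, config$frame_spacing)
  if (is.null(start))
    start <- sample_boltzmann(U, config$n_particles, seed = config$seed)
  stopifnot(is.matrix(start), ncol(start) == 3, nrow(start) == config$n_particles)

  tabs <- profile_tables(U, D, M = table_n)
  out <- .bd_core(start[, 1], start[, 2], start[, 3],
                  tabs$D, tabs$dD, tabs$dU,
                  U$period, dt_ns, n_steps, rec,
                  config$seed, spurious_drift, noise)
  structure(list(t = c(0, rec * dt_ns),
                 x = cbind(start[, 1], out$x),
                 y = cbind(start[, 2], out$y),
                 z = cbind(start[, 3], out$z),
                 config = config, period = U$period),
            class = "meso_trajectory")
}

#' @export
print.meso_trajectory <- function(x, ...) {
  cat(sprintf("<meso_trajectory> %d particles, %d frames, t up to %.4g ns\n",
              nrow(x$z), length(x$t), max(x$t)))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Long-format export (particle, frame, t, x, y, z) of the recorded,
#' unwrapped positions.
#'
#' @param traj a `meso_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "meso_trajectory"))
  np <- nrow(traj$z); nf <- length(traj$t)
  df <- data.frame(particle = rep(seq_len(np), nf),
                   frame = rep(seq_len(nf) - 1L, each = np),
                   t = rep(traj$t, each = np),
                   x = as.numeric(traj$x), y = as.numeric(traj$y),
                   z = as.numeric(traj$z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Folded equilibrium histogram of a trajectory
#'
#' Folds recorded z positions onto the half period [0, a/2] (using both the
#' translational and the mirror symmetry), histograms them, and compares
#' -log(density) with the potential: at equilibrium the two agree up to a
#' constant. Frames before `burn_in` (fraction of total time) are discarded;
#' the remaining frames are pooled.
#'
#' @param traj a `meso_trajectory`.
#' @param U the potential the run sampled.
#' @param bins number of bins on the half period.
#' @param burn_in fraction of the run discarded (default 0.25; irrelevant
#'   for pre-equilibrated ensembles but kept as a guard).
#' @param u_max bins with U above this value (kBT) are excluded from the
#'   deviation summary (they are exponentially rarely visited).
#' @return A list with a per-bin data.frame (`z`, `U`, `F_est`, `dev`) and
#'   `max_dev`, the largest |F_est - U| over the retained bins.
#' @export
equilibrium_histogram <- function(traj, U, bins = 60L, burn_in = 0.25,
                                  u_max = 6) {
  stopifnot(inherits(traj, "meso_trajectory"), inherits(U, "meso_profile"))
  a <- U$period
  keep <- traj$t >= burn_in * max(traj$t)
  zs <- as.numeric(traj$z[, keep])
  zf <- fold_half_period(zs, a)$z
  br <- seq(0, a / 2, length.out = bins + 1L)
  ct <- tabulate(pmin(findInterval(zf, br, rightmost.closed = TRUE), bins),
                 nbins = bins)
  zc <- (br[-1] + br[-(bins + 1L)]) / 2
  # expected bin weights from quadrature of exp(-U) (trapezoid on a fine grid)
  expw <- vapply(seq_len(bins), function(i) {
    zq <- seq(br[i], br[i + 1], length.out = 21L)
    w <- exp(-profile_value(U, zq))
    sum((w[-1] + w[-21]) / 2) * (zq[2] - zq[1])
  }, numeric(1))
  p_obs <- ct / sum(ct)
  p_exp <- expw / sum(expw)
  ok <- ct > 0
  dev <- rep(NA_real_, bins)
  dev[ok] <- -log(p_obs[ok] / p_exp[ok])
  Uc <- profile_value(U, zc)
  use <- ok & Uc <= u_max
  # remove the arbitrary free-energy offset (count-weighted mean deviation)
  off <- sum(dev[use] * ct[use]) / sum(ct[use])
  dev <- dev - off
  list(table = data.frame(z = zc, U = Uc, F_est = Uc + dev, dev = dev,
                          count = ct),
       max_dev = max(abs(dev[use])), n_samples = length(zs))
}

#' Validate integration timesteps against equilibrium sampling
#'
#' For each candidate dt, runs an ensemble started at z = 0 (the protocol
#' used to select dt = 3e-4 tau) and reports the maximum deviation between
#' the sampled free energy -log(density) and the implemented U(z). Timesteps
#' that are too large erode barriers systematically and fail the tolerance.
#'
#' @param U,D profiles defining the system.
#' @param dt_candidates timesteps to test (tau).
#' @param n_particles,t_total protocol scale; defaults follow the reference
#'   protocol (1e4 particles, 2e4 tau) and should be reduced for quick
#'   checks.
#' @param seed RNG seed.
#' @param tol tolerance on the maximum deviation (kBT); default 0.15.
#' @param u_max deviation assessed only where U <= u_max (kBT).
#' @param bins histogram bins on the half period.
#' @param units a [unit_system()].
#' @return A data.frame with one row per dt: `dt`, `max_dev`, `pass`.
#' @export
validate_timestep <- function(U, D, dt_candidates, n_particles = 10000L,
                              t_total = 20000, seed = 1L, tol = 0.15,
                              u_max = 6, bins = 60L,
                              units = unit_system(Dwat = 0.7)) {
  stopifnot(all(dt_candidates > 0))
  res <- lapply(dt_candidates, function(dt) {
    cfg <- bd_config(n_particles = n_particles, t_total = t_total,
                     seed = seed, dt = dt, n_frames = 200L,
                     frame_spacing = "linear", units = units)
    start <- cbind(numeric(n_particles), numeric(n_particles),
                   numeric(n_particles))
    traj <- bd_simulate(U, D, cfg, start = start)
    h <- equilibrium_histogram(traj, U, bins = bins, u_max = u_max)
    data.frame(dt = dt, max_dev = h$max_dev, pass = h$max_dev <= tol)
  })
  do.call(rbind, res)
}
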