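# Shared builders and cached simulation runs. Heavy Brownian-dynamics
# ensembles are run once and reused across test blocks; all scales are the
# reduced study sizes discussed in the methods vignette.

toy_U <- function(dU, dUb, ...) {
  build_toy_potential(toy_potential_params(dU = dU, dUb = dUb, ...))
}

toy_D <- function(Dwat = 0.7, Dlip = 0.063, ...) {
  build_toy_diffusion(diffusion_profile_params(Dwat = Dwat, Dlip = Dlip, ...))
}

const_D <- function(D = 0.7, a = 6.65) constant_profile(D, a, "diffusion")
flat_U <- function(a = 6.65) constant_profile(0, a)

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# Perpendicular-coefficient estimate with oracle-budgeted run length:
# simulate until MSD_perp is predicted to reach `msd_target` nm^2 (capped).
bd_dperp <- function(U, D, n_particles, seed, msd_target = 45,
                     cap_tau = 6000, Dwat = 0.7) {
  units <- unit_system(Dwat = Dwat)
  t_tau <- min(cap_tau,
               msd_target / (2 * d_perp_oracle(U, D)) / units$tau)
  cfg <- bd_config(n_particles = n_particles, t_total = max(t_tau, 50),
                   seed = seed, units = units)
  traj <- bd_simulate(U, D, cfg)
  msd <- compute_msd(traj)
  est <- fit_long_time(msd, "perp")
  list(D = est$D, est = est, msd = msd)
}

# Lateral-coefficient estimate (fast: the lateral MSD is diffusive at all
# times for a pre-equilibrated ensemble).
bd_dpar <- function(U, D, n_particles, seed, t_tau = 120, Dwat = 0.7) {
  cfg <- bd_config(n_particles = n_particles, t_total = t_tau, seed = seed,
                   units = unit_system(Dwat = Dwat))
  traj <- bd_simulate(U, D, cfg)
  fit_long_time(compute_msd(traj), "par")
}

# Barrier ladder with per-point oracle cross-values (Dlip = Dwat); used by
# the Arrhenius studies.
arrhenius_study <- function(param, barriers, n_particles, seed0,
                            msd_target = 45) {
  Dc <- const_D()
  vapply(barriers, function(b) {
    U <- if (param == "dUb") toy_U(0, b) else toy_U(b, 0)
    est <- bd_dperp(U, Dc, n_particles, seed = seed0 + b,
                    msd_target = msd_target)
    c(bd = est$D, oracle = d_perp_oracle(U, Dc))
  }, numeric(2))
}

# Simulated and predicted effective coefficients for one toy system with the
# heterogeneous diffusivity profile (Dlip = 0.09 Dwat). D_perp comes from
# direct BD when the oracle-budgeted run fits the cap, otherwise from an
# alpha ladder (largest affordable alpha and three below it, spacing 0.1).
deff_study_system <- function(dU, dUb, seed, n_par = 1200, n_perp = 200,
                              cap_tau = 3500, msd_target = 60) {
  U <- toy_U(dU, dUb)
  D <- toy_D()
  units <- unit_system(Dwat = 0.7)
  t_need <- function(al) {
    msd_target / (2 * d_perp_oracle(scale_potential(U, al), D)) / units$tau
  }
  dpar <- bd_dpar(U, D, n_par, seed)$D
  if (t_need(1) <= cap_tau) {
    dperp <- bd_dperp(U, D, n_perp, seed + 1, msd_target = msd_target,
                      cap_tau = cap_tau)$D
  } else {
    grid <- seq(0.2, 0.95, by = 0.05)
    amax <- max(grid[vapply(grid, t_need, numeric(1)) <= cap_tau])
    alphas <- pmax(amax - c(0.3, 0.2, 0.1, 0), 0.05)
    dps <- vapply(seq_along(alphas), function(i) {
      bd_dperp(scale_potential(U, alphas[i]), D, n_perp, seed + 1 + i,
               msd_target = msd_target, cap_tau = cap_tau)$D
    }, numeric(1))
    ok <- !is.na(dps)   # a refused rung is dropped if >= 3 remain
    dperp <- alpha_extrapolate(alphas[ok], dps[ok])$D_perp1
  }
  Deff_sim <- d_eff(dpar, dperp)
  Deff_pred <- d_eff_large_barrier(log_partition_coefficient(U)$logP,
                                   Dlip = 0.063, Dwat = 0.7)
  list(dpar = dpar, dperp = dperp, Deff_sim = Deff_sim,
       Deff_pred = Deff_pred,
       err_pct = 100 * abs(1 - Deff_pred / Deff_sim))
}
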