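# Configuration-driven entry points (simulate / theory / extrapolate /
# fixtures), run manifests, and the command-line front end.

profile_from_config <- function(pc, base_dir = ".") {
  if (!is.null(pc$pmf_file)) {
    path <- pc$pmf_file
    if (!file.exists(path)) path <- file.path(base_dir, pc$pmf_file)
    return(load_tabulated_pmf(path, period = pc$a))
  }
  if (is.null(pc$dU) || is.null(pc$dUb))
    stop("config error: profile needs either 'pmf_file' or toy parameters 'dU' and 'dUb'")
  args <- list(dU = pc$dU, dUb = pc$dUb)
  for (k in c("a", "l", "h")) if (!is.null(pc[[k]])) args[[k]] <- pc[[k]]
  build_toy_potential(do.call(toy_potential_params, args))
}

diffusion_from_config <- function(dc) {
  if (is.null(dc$Dwat)) stop("config error: diffusion block needs 'Dwat'")
  Dlip <- if (!is.null(dc$Dlip)) dc$Dlip else
    if (!is.null(dc$dlip_ratio)) dc$dlip_ratio * dc$Dwat else dc$Dwat
  args <- list(Dwat = dc$Dwat, Dlip = Dlip)
  for (k in c("a", "l", "w")) if (!is.null(dc[[k]])) args[[k]] <- dc[[k]]
  build_toy_diffusion(do.call(diffusion_profile_params, args))
}

read_config <- function(config) {
  if (is.character(config)) {
    stopifnot(length(config) == 1L, file.exists(config))
    yaml::read_yaml(config)
  } else if (is.list(config)) config else
    stop("config must be a list or a YAML file path")
}

write_manifest <- function(out_dir, config, seed, inputs = character(0),
                           outputs = character(0)) {
  man <- list(package = "mesodiff",
              version = as.character(utils::packageVersion("mesodiff")),
              timestamp = format(Sys.time(), tz = "UTC"),
              seed = seed,
              config = config,
              input_digests = if (length(inputs))
                as.list(tools::md5sum(inputs)) else list(),
              outputs = outputs)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run a simulation study from a configuration
#'
#' Orchestrates the full stochastic pipeline: build U(z) and D(z), Boltzmann
#' pre-equilibration, Brownian-dynamics integration, MSD computation and
#' long-time fits. The configuration is a list (or YAML file) with blocks
#' `profile` (toy `dU`/`dUb`/geometry or `pmf_file`), `diffusion` (`Dwat`,
#' `Dlip` or `dlip_ratio`, geometry) and `dynamics` (`n_particles`,
#' `t_total` in tau, `seed`, optional `dt`, `n_frames`, `frame_spacing`).
#' Units are fixed: nm, ns, kBT.
#'
#' @param config list or YAML path.
#' @param out_dir optional output directory; when given, writes `msd.csv`,
#'   `estimates.json` and `manifest.json`.
#' @return List with `traj`, `msd`, `par`, `perp`, `Deff`, `theory`
#'   (closed-form references for the same system), invisibly when writing.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  base_dir <- if (is.character(config)) dirname(config) else "."
  for (blk in c("profile", "diffusion", "dynamics"))
    if (is.null(cfg[[blk]])) stop(sprintf("config error: missing block '%s'", blk))
  dyn <- cfg$dynamics
  for (k in c("n_particles", "t_total", "seed"))
    if (is.null(dyn[[k]])) stop(sprintf("config error: dynamics block missing key '%s'", k))

  U <- profile_from_config(cfg$profile, base_dir)
  D <- diffusion_from_config(cfg$diffusion)
  units <- unit_system(Dwat = D$params$Dwat)
  bc <- bd_config(n_particles = dyn$n_particles, t_total = dyn$t_total,
                  seed = dyn$seed,
                  dt = if (!is.null(dyn$dt)) dyn$dt else 3e-4,
                  n_frames = if (!is.null(dyn$n_frames)) dyn$n_frames else 200L,
                  frame_spacing = if (!is.null(dyn$frame_spacing))
                    dyn$frame_spacing else "log",
                  units = units)
  traj <- bd_simulate(U, D, bc)
  res <- transport_from_trajectory(traj)
  th <- theory_transport(U, D, l = cfg$profile$l)
  out <- list(traj = traj, msd = res$msd, par = res$par, perp = res$perp,
              Deff = res$Deff, theory = th)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_msd_csv(res$msd, file.path(out_dir, "msd.csv"))
    est <- list(D_parallel = res$par$D, D_perp = res$perp$D, Deff = res$Deff,
                window_par = res$par$window, window_perp = res$perp$window,
                converged_perp = res$perp$converged,
                diagnostic_par = res$par$diagnostic,
                diagnostic_perp = res$perp$diagnostic,
                theory = th)
    jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    inputs <- if (!is.null(cfg$profile$pmf_file)) {
      p <- cfg$profile$pmf_file
      if (file.exists(p)) p else file.path(base_dir, p)
    } else character(0)
    write_manifest(out_dir, cfg, dyn$seed, inputs,
                   c("msd.csv", "estimates.json"))
    return(invisible(out))
  }
  out
}

#' Run the closed-form theory from a configuration
#'
#' Deterministic counterpart of [run_simulate()]: logP, thermally averaged
#' lateral coefficient, exact perpendicular coefficient and Deff for the
#' configured system. If the config has a `drug_table` entry (a CSV path
#' with columns name, logP, Dwat, or the string `"builtin"`), the per-drug
#' closed forms are evaluated instead.
#'
#' @inheritParams run_simulate
#' @return Theory list (or drug data.frame), invisibly when writing.
#' @export
run_theory <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  base_dir <- if (is.character(config)) dirname(config) else "."
  if (!is.null(cfg$drug_table)) {
    drugs <- if (identical(cfg$drug_table, "builtin")) drug_reference_table()
    else {
      path <- cfg$drug_table
      if (!file.exists(path)) path <- file.path(base_dir, cfg$drug_table)
      utils::read.csv(path)
    }
    geo <- cfg$geometry
    args <- list(drugs = drugs)
    for (k in c("a", "l", "w", "dlip_ratio"))
      if (!is.null(geo[[k]])) args[[k]] <- geo[[k]]
    out <- do.call(drug_transport, args)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(out, file.path(out_dir, "drug_transport.csv"),
                       row.names = FALSE)
      write_manifest(out_dir, cfg, seed = NA, outputs = "drug_transport.csv")
      return(invisible(out))
    }
    return(out)
  }
  if (is.null(cfg$profile) || is.null(cfg$diffusion))
    stop("config error: theory mode needs blocks 'profile' and 'diffusion' (or 'drug_table')")
  U <- profile_from_config(cfg$profile, base_dir)
  D <- diffusion_from_config(cfg$diffusion)
  th <- theory_transport(U, D, l = cfg$profile$l)
  # intermediate integrals, for auditability of the closed forms
  th$integrals <- c(log_partition_coefficient(U, l = cfg$profile$l)[
    c("clip", "cwat")],
    d_parallel_theory(U, D, normalized = FALSE)[c("num", "den")])
  th$D_par_from_logP <- d_parallel_from_logP(
    th$logP, a = U$period, l = if (!is.null(cfg$profile$l)) cfg$profile$l else U$params$l,
    w = D$params$w, Dlip = D$params$Dlip, Dwat = D$params$Dwat)
  th$Deff_large_barrier <- 2 / 3 * th$D_par_from_logP
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(th, file.path(out_dir, "theory.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_manifest(out_dir, cfg, seed = NA, outputs = "theory.json")
    return(invisible(th))
  }
  th
}

#' Alpha-rescaling extrapolation of the perpendicular coefficient
#'
#' For systems whose barriers are too high for direct simulation, runs (or
#' evaluates in closed form) the system with U(z) scaled by each
#' `alpha < 1`, fits log D_perp linearly in alpha, and extrapolates to
#' alpha = 1. Config blocks: as [run_simulate()] plus `extrapolate` with
#' `alphas` (>= 3 values) and optional `engine` (`"bd"`, default, or
#' `"oracle"` for the deterministic closed form).
#'
#' @inheritParams run_simulate
#' @return List with `alphas`, `D_perp_alpha`, `D_perp1`, `fit`, invisibly
#'   when writing.
#' @export
run_extrapolate <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  base_dir <- if (is.character(config)) dirname(config) else "."
  ex <- cfg$extrapolate
  if (is.null(ex) || is.null(ex$alphas))
    stop("config error: missing block 'extrapolate' with key 'alphas'")
  alphas <- as.numeric(unlist(ex$alphas))
  if (length(alphas) < 3) stop("need at least 3 alpha values")
  engine <- if (!is.null(ex$engine)) ex$engine else "bd"
  U <- profile_from_config(cfg$profile, base_dir)
  D <- diffusion_from_config(cfg$diffusion)

  Dp <- vapply(alphas, function(al) {
    Ua <- scale_potential(U, al)
    if (engine == "oracle") return(d_perp_oracle(Ua, D))
    dyn <- cfg$dynamics
    units <- unit_system(Dwat = D$params$Dwat)
    bc <- bd_config(n_particles = dyn$n_particles, t_total = dyn$t_total,
                    seed = dyn$seed + round(1000 * al),
                    dt = if (!is.null(dyn$dt)) dyn$dt else 3e-4,
                    units = units)
    traj <- bd_simulate(Ua, D, bc)
    est <- fit_long_time(compute_msd(traj), "perp")
    if (is.na(est$D)) stop(sprintf("alpha = %g run did not converge: %s",
                                   al, est$diagnostic))
    est$D
  }, numeric(1))
  fit <- alpha_extrapolate(alphas, Dp)
  out <- list(alphas = alphas, D_perp_alpha = Dp, D_perp1 = fit$D_perp1,
              slope = fit$slope, intercept = fit$intercept, engine = engine)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(out[names(out) != "fit"],
                         file.path(out_dir, "extrapolation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_manifest(out_dir, cfg,
                   seed = if (!is.null(cfg$dynamics$seed)) cfg$dynamics$seed else NA,
                   outputs = "extrapolation.json")
    return(invisible(out))
  }
  out
}

#' Generate synthetic input fixtures
#'
#' Writes small text fixtures with known ground truth, used for
#' parameter-recovery tests and as stand-ins for externally derived
#' potentials of mean force:
#' \describe{
#'   \item{`toy-sampled-pmf`}{the analytic toy potential sampled on a grid,
#'     for interpolation round-trip tests.}
#'   \item{`amino-acid-like-pmf`}{a synthetic profile with the architecture
#'     of residue PMFs in a phospholipid bilayer: a tail plateau plus a
#'     head-region barrier or well, with mild smooth modulation.}
#'   \item{`drug-table`}{the built-in drug reference table as CSV.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param path output file (TSV for PMFs, CSV for the drug table).
#' @param seed integer seed for the stochastic modulation.
#' @param plateau,head tail-plateau and head-extremum free energies (kBT)
#'   for `amino-acid-like-pmf` (`head < 0` digs an interfacial well).
#' @param dU,dUb toy parameters for `toy-sampled-pmf`.
#' @param a,l,h geometry (nm); defaults: amino-acid geometry uses l = 2.5.
#' @param n_points grid points.
#' @return List with `path` and the ground-truth metadata, invisibly.
#' @export
generate_fixtures <- function(kind = c("toy-sampled-pmf",
                                       "amino-acid-like-pmf", "drug-table"),
                              path, seed = 1L, plateau = 10, head = -5,
                              dU = 3, dUb = 5, a = 6.65, l = NULL, h = 1,
                              n_points = 201L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "drug-table") {
    utils::write.csv(drug_reference_table(), path, row.names = FALSE)
    return(invisible(list(path = path, truth = drug_reference_table())))
  }
  if (kind == "toy-sampled-pmf") {
    l0 <- if (is.null(l)) 2.365 else l
    U <- build_toy_potential(toy_potential_params(dU = dU, dUb = dUb,
                                                  a = a, l = l0, h = h))
    z <- seq(0, a / 2, length.out = n_points)
    cat(sprintf("# period: %.10g\n", a), file = path)
    utils::write.table(data.frame(z = z, U = profile_value(U, z)),
                       path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, append = TRUE)
    return(invisible(list(path = path,
                          truth = list(dU = dU, dUb = dUb, a = a, l = l0,
                                       h = h,
                                       Umax = max(dU, dUb, 0),
                                       Umin = min(0, dU, dUb)))))
  }
  # amino-acid-like: plateau over the tails, parabolic head extremum, zero
  # in water, plus a small smooth random modulation that keeps the extrema.
  l0 <- if (is.null(l)) 2.5 else l
  base <- build_toy_potential(toy_potential_params(dU = plateau, dUb = head,
                                                   a = a, l = l0, h = h))
  z <- seq(0, a / 2, length.out = n_points)
  U <- profile_value(base, z)
  ripple <- 0.1 * min(1, abs(plateau)) *
    sin(2 * pi * 3 * z / a + stats::runif(1, 0, 2 * pi)) *
    exp(-((z - l0 / 2) / l0)^2)
  U <- U + ripple
  U[1] <- plateau; U[n_points] <- 0
  cat(sprintf("# period: %.10g\n", a), file = path)
  utils::write.table(data.frame(z = z, U = U), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(list(path = path,
                 truth = list(plateau = plateau, head = head, a = a, l = l0,
                              h = h, Umax = max(U), Umin = min(U))))
}

#' Command-line front end
#'
#' Thin dispatcher used by the `inst/cli/mesodiff.R` script:
#' `mesodiff.R <simulate|theory|extrapolate|fixtures> --config FILE
#' [--out-dir DIR] [--seed N] [--kind K] [--out FILE]`.
#' Returns a shell exit status (0 on success; 1 on error or when a
#' stochastic run did not converge).
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mesodiff.R <simulate|theory|extrapolate|fixtures>",
    "--config FILE [--out-dir DIR] [--seed N] [--kind K] [--out FILE]")
  if (length(args) < 1) { message(usage); return(1L) }
  cmd <- args[1]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) { message("missing value for --", key); return(1L) }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out_dir <- if (!is.null(opt$`out-dir`)) opt$`out-dir` else "."
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- read_config(opt$config)
        if (!is.null(opt$seed)) cfg$dynamics$seed <- as.integer(opt$seed)
        res <- run_simulate(cfg, out_dir = out_dir)
        if (is.na(res$perp$D) || !res$perp$converged) {
          message("warning: perpendicular estimate not converged (",
                  res$perp$diagnostic, ")")
          2L
        } else 0L
      },
      theory = { run_theory(read_config(opt$config), out_dir = out_dir); 0L },
      extrapolate = {
        cfg <- read_config(opt$config)
        if (!is.null(opt$seed)) cfg$dynamics$seed <- as.integer(opt$seed)
        run_extrapolate(cfg, out_dir = out_dir); 0L
      },
      fixtures = {
        if (is.null(opt$kind) || is.null(opt$out)) {
          message("fixtures needs --kind and --out"); 1L
        } else {
          generate_fixtures(opt$kind, opt$out,
                            seed = if (!is.null(opt$seed))
                              as.integer(opt$seed) else 1L)
          0L
        }
      },
      { message("unknown command: ", cmd); message(usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}
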