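# Mean-square displacements, local log-log exponents, and long-time
# diffusion-coefficient fits.

#' Mean-square displacement of a trajectory ensemble
#'
#' MSD_par(t) = <(x - x0)^2 + (y - y0)^2> and MSD_perp(t) = <(z - z0)^2>,
#' averaged over particles at each recorded time. Displacements are taken
#' from the initial position only (no sliding time origin): the ensemble is
#' Boltzmann pre-equilibrated, hence stationary, and fixed-origin averages
#' are unbiased.
#'
#' @param traj a `meso_trajectory` with unwrapped coordinates.
#' @return A `meso_msd` data.frame with columns `t` (ns), `msd_par`,
#'   `msd_perp` (nm^2) and attribute `n` (ensemble size).
#' @export
compute_msd <- function(traj) {
  stopifnot(inherits(traj, "meso_trajectory"), length(traj$t) >= 2)
  dx <- traj$x - traj$x[, 1]
  dy <- traj$y - traj$y[, 1]
  dz <- traj$z - traj$z[, 1]
  if (max(abs(dz)) < traj$period && max(traj$t) > 100 * traj$period^2)
    warning("no particle displaced by a full period: coordinates may be folded")
  out <- data.frame(t = traj$t,
                    msd_par = colMeans(dx^2 + dy^2),
                    msd_perp = colMeans(dz^2))
  attr(out, "n") <- nrow(traj$z)
  class(out) <- c("meso_msd", class(out))
  out
}

#' Local logarithmic slope of an MSD curve
#'
#' d log MSD / d log t, estimated at each frame by a linear regression of
#' log MSD on log t over a window of `span` decades centred on the frame
#' (plain centred differences are too noisy for stochastic MSD estimates).
#' The exponent segments the dynamics into the short-time free regime
#' (slope 1), the intermediate subdiffusive regime (slope < 1 when barriers
#' are present), and the long-time diffusive regime (slope back to 1).
#'
#' @param msd a `meso_msd`.
#' @param direction `"perp"` or `"par"`.
#' @param span smoothing window in decades of t.
#' @return data.frame with `t` and `exponent` (frames with MSD = 0 or
#'   t = 0 are skipped).
#' @export
local_exponent <- function(msd, direction = c("perp", "par"), span = 0.3) {
  direction <- match.arg(direction)
  stopifnot(inherits(msd, "meso_msd"))
  v <- if (direction == "perp") msd$msd_perp else msd$msd_par
  ok <- msd$t > 0 & v > 0
  lt <- log10(msd$t[ok]); lv <- log10(v[ok])
  if (length(lt) < 5) stop("need at least 5 usable MSD points")
  expo <- vapply(seq_along(lt), function(i) {
    w <- which(abs(lt - lt[i]) <= span / 2)
    if (length(w) < 3) w <- order(abs(lt - lt[i]))[1:3]
    stats::coef(stats::lm.fit(cbind(1, lt[w]), lv[w]))[2]
  }, numeric(1))
  data.frame(t = msd$t[ok], exponent = expo)
}

#' Fit the long-time diffusion coefficient
#'
#' Fits MSD = intercept + slope * t over the final diffusive window;
#' D = slope / (2 * dim) with dim = 1 for the perpendicular and 2 for the
#' parallel direction. The window is the maximal final stretch in which the
#' smoothed local exponent never drops below `1 - band`, where the band
#' widens the nominal tolerance `tol` by the statistical noise floor of an
#' N-particle ensemble MSD (relative standard error `sqrt(2/(dim * N))` per
#' point): a fixed 0.05 band is only attainable for near-noiseless input.
#' Detection is one-sided because the barrier-induced subdiffusive
#' transient approaches slope 1 from below, while upward excursions at
#' finite N are noise; onsets are accepted only during the growth phase
#' (MSD below half its final value) and with an extra 1.6x margin on the
#' band, because a false onset aborts an otherwise valid fit while a
#' genuinely short run is still refused by the window-slope admissibility
#' check. The window must span at least `min_decades` decades
#' and its overall log-log slope must itself lie within the band, otherwise
#' no estimate is returned (run too short). The convergence flag records
#' whether MSD_perp reached `conv_msd` (default 100 nm^2), the run-length
#' rule under which perpendicular fits were found reliable; estimates from
#' unconverged runs are returned but flagged.
#'
#' @param msd a `meso_msd`.
#' @param direction `"perp"` (dim 1) or `"par"` (dim 2).
#' @param tol nominal admissible deviation of the local exponent from 1.
#' @param noise_mult multiplier on the per-point noise floor when widening
#'   `tol`; set to 0 to enforce the nominal tolerance regardless of
#'   ensemble size.
#' @param min_decades minimum width of the fit window, in decades.
#' @param max_decades maximum depth of the fit window below the final time,
#'   in decades; guards against shallow transients that escape onset
#'   detection at noisy ensemble sizes.
#' @param span smoothing span handed to [local_exponent()].
#' @param conv_msd MSD_perp convergence threshold (nm^2).
#' @return A `meso_destimate`: list with `D` (nm^2/ns; `NA` with a
#'   diagnostic if no admissible window exists), `window` (time range),
#'   `band`, `converged`, `n_points`, `diagnostic`.
#' @export
fit_long_time <- function(msd, direction = c("perp", "par"), tol = 0.05,
                          noise_mult = 2.5, min_decades = 0.5,
                          max_decades = 1.5, span = 0.5, conv_msd = 100) {
  direction <- match.arg(direction)
  stopifnot(inherits(msd, "meso_msd"))
  dim_ <- if (direction == "perp") 1 else 2
  v <- if (direction == "perp") msd$msd_perp else msd$msd_par
  converged <- max(msd$msd_perp) >= conv_msd
  n_ens <- attr(msd, "n")
  noise_floor <- if (is.null(n_ens)) 0 else sqrt(2 / (dim_ * n_ens))
  # two bands: onset *detection* is deliberately wide (local-slope noise on
  # correlated ensemble MSDs runs well above the per-point floor, and a
  # false onset aborts the fit), while window *admissibility* stays tight
  # (a too-short run must be refused, not mis-fitted)
  band_detect <- if (noise_mult == 0) tol else
    max(tol, 1.6 * noise_mult * noise_floor)
  band <- if (noise_mult == 0) tol else max(tol, noise_mult * noise_floor)

  ex <- local_exponent(msd, direction, span = span)
  est <- list(D = NA_real_, direction = direction, window = c(NA, NA),
              band = band, converged = converged, n_points = 0L,
              diagnostic = "no diffusive window (simulation too short)")
  class(est) <- "meso_destimate"

  # onset detection is restricted to the growth phase (MSD below half its
  # final value): sub-band excursions later than that are ensemble noise,
  # and a genuinely unconverged run is caught by the window-slope check
  v_ex <- v[match(ex$t, msd$t)]
  low <- which(ex$exponent < 1 - band_detect & v_ex < 0.5 * max(v))
  first <- if (length(low)) max(low) + 1L else 1L
  if (first > nrow(ex)) return(est)
  tw <- ex$t[first:nrow(ex)]
  if (length(tw) < 3 || log10(max(tw) / min(tw)) < min_decades) return(est)
  use <- msd$t >= max(min(tw), max(msd$t) / 10^max_decades) &
    msd$t > 0 & v > 0
  # overall log-log slope of the window must be diffusive
  gslope <- stats::coef(stats::lm.fit(cbind(1, log(msd$t[use])),
                                      log(v[use])))[2]
  if (abs(gslope - 1) > band) {
    est$diagnostic <- sprintf(
      "window log-log slope %.3f outside the diffusive band", gslope)
    return(est)
  }
  fit <- stats::lm(v[use] ~ msd$t[use])
  est$D <- max(0, unname(stats::coef(fit)[2]) / (2 * dim_))
  est$window <- range(msd$t[use])
  est$n_points <- sum(use)
  est$diagnostic <- if (converged || direction == "par") "ok" else
    "ok (MSD_perp below convergence threshold: lower confidence)"
  est
}

#' @export
print.meso_destimate <- function(x, ...) {
  cat(sprintf("<meso_destimate> D_%s = %.4g nm^2/ns [%s], window %.3g..%.3g ns\n",
              x$direction, x$D, x$diagnostic, x$window[1], x$window[2]))
  invisible(x)
}

#' Full transport estimate from a trajectory
#'
#' Convenience wrapper: MSD, long-time fits in both directions, and the
#' orientation-averaged effective coefficient Deff = 2 D_par / 3 + D_perp/3.
#'
#' @param traj a `meso_trajectory`.
#' @param ... passed to [fit_long_time()].
#' @return List with `msd`, `par`, `perp` (the two `meso_destimate`s) and
#'   `Deff` (`NA` if either fit failed).
#' @export
transport_from_trajectory <- function(traj, ...) {
  msd <- compute_msd(traj)
  par_ <- fit_long_time(msd, "par", ...)
  perp <- fit_long_time(msd, "perp", ...)
  Deff <- if (is.na(par_$D) || is.na(perp$D)) NA_real_ else
    d_eff(par_$D, perp$D)
  list(msd = msd, par = par_, perp = perp, Deff = Deff)
}

#' Write an MSD series to CSV
#'
#' @param msd a `meso_msd`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msd_csv <- function(msd, path) {
  df <- as.data.frame(msd)
  df$n <- attr(msd, "n")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
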