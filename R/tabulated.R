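# Tabulated potentials of mean force (e.g. from atomistic simulations),
# interpolated so that both U and dU/dz are continuous and mirror-periodic.

#' Load a tabulated potential of mean force
#'
#' Accepts a two-column table (z in nm, U in kBT) either as a data.frame /
#' matrix or as a whitespace/tab-delimited file with `#` comment lines. The
#' grid must be strictly increasing and cover the half period [0, a/2]
#' (endpoints within one grid spacing of 0 and a/2); a symmetric full-period
#' grid on [-a/2, a/2] is also accepted and is symmetrized onto the half
#' period. The file may carry the period in a directive line
#' `# period: <a>`, otherwise `period` must be supplied.
#'
#' The interpolant is a periodic cubic spline fitted to the mirror-extended
#' data, which makes U C^2 and forces dU/dz = 0 at both symmetry planes, as
#' mirror symmetry requires. Extrema `Umin`/`Umax` are located on a dense
#' grid of at least 1e4 points per half period.
#'
#' @param table data.frame/matrix with columns (z, U), or a file path.
#' @param period lattice parameter a (nm); optional if the file carries a
#'   `# period:` directive.
#' @return A `meso_pmf` (also a `meso_profile`) with fields `z`, `U`,
#'   `Umin`, `Umax`.
#' @export
load_tabulated_pmf <- function(table, period = NULL) {
  if (is.character(table)) {
    stopifnot(length(table) == 1L, file.exists(table))
    lines <- readLines(table)
    dir_line <- grep("^#\\s*period\\s*[:=]", lines, value = TRUE)
    if (length(dir_line) && is.null(period))
      period <- as.numeric(sub("^#\\s*period\\s*[:=]\\s*", "", dir_line[1]))
    body <- lines[!grepl("^\\s*(#|$)", lines)]
    table <- utils::read.table(text = body, col.names = c("z", "U"))
  }
  table <- as.data.frame(table)
  if (ncol(table) < 2) stop("PMF table must have two columns (z, U)")
  z <- as.numeric(table[[1]]); U <- as.numeric(table[[2]])
  if (anyNA(z) || anyNA(U) || any(!is.finite(z)) || any(!is.finite(U)))
    stop("PMF table contains non-finite entries")
  if (is.null(period) || !is.finite(period) || period <= 0)
    stop("a positive period is required (argument or '# period:' directive)")
  if (any(diff(z) <= 0)) stop("PMF grid must be strictly increasing")

  a <- period
  if (min(z) < -a / 4) {
    # full-period symmetric input: average U(z) and U(-z) onto [0, a/2]
    f <- stats::splinefun(z, U, method = "natural")
    zh <- seq(0, a / 2, length.out = max(length(z), 101L))
    zh[1] <- max(zh[1], min(z)); zh[length(zh)] <- min(zh[length(zh)], max(z))
    U <- (f(zh) + f(-zh)) / 2
    z <- zh
  }
  if (length(z) < 8) stop("PMF table needs at least 8 grid points")
  dz <- stats::median(diff(z))
  if (z[1] > dz || z[length(z)] < a / 2 - dz)
    stop("PMF grid must cover the half period [0, a/2] (endpoints within one grid spacing)")

  # clamp the grid to [0, a/2] and pin the endpoints
  z[1] <- 0; z[length(z)] <- a / 2
  # mirror-extend to one full period and fit a periodic cubic spline;
  # for symmetric data the periodic spline is symmetric, hence dU/dz = 0
  # at z = 0 and z = a/2.
  zf <- c(z, a - rev(z[-length(z)]))
  Uf <- c(U, rev(U[-length(U)]))
  sp <- stats::splinefun(zf, Uf, method = "periodic")

  dense <- seq(0, a / 2, length.out = 10001L)
  Ud <- sp(dense)
  opt_refine <- function(z0, maximize) {
    lo <- max(0, z0 - a / 2e4); hi <- min(a / 2, z0 + a / 2e4)
    o <- stats::optimize(sp, c(lo, hi), maximum = maximize)
    if (maximize) o$objective else o$objective
  }
  i_min <- which.min(Ud); i_max <- which.max(Ud)
  Umin <- min(Ud[i_min], opt_refine(dense[i_min], FALSE))
  Umax <- max(Ud[i_max], opt_refine(dense[i_max], TRUE))

  p <- new_profile(function(zz) sp(zz),
                   function(zz) sp(zz, deriv = 1),
                   a, "potential",
                   list(a = a, n_points = length(z)),
                   breaks = numeric(0),
                   label = sprintf("tabulated PMF (%d points)", length(z)))
  p$z <- z; p$U <- U; p$Umin <- Umin; p$Umax <- Umax
  class(p) <- c("meso_pmf", class(p))
  p
}

#' @export
print.meso_pmf <- function(x, ...) {
  cat(sprintf("<meso_pmf> period a = %g nm, %d nodes, Umin = %.3g, Umax = %.3g kBT\n",
              x$period, length(x$z), x$Umin, x$Umax))
  invisible(x)
}

#' Combine charged and neutral PMFs by their pointwise minimum
#'
#' For titratable molecules the effective free-energy profile is taken as
#' `min(Uc(z), U0(z))`, the more stable of the charged and neutral variants
#' at every depth (the two inputs must already be shifted by the
#' neutralization free energy in water). The raw minimum has derivative
#' kinks where the branches cross; nodes within a small window around each
#' crossing are dropped and the interpolating spline bridges the gap, which
#' restores a continuous derivative while shifting barrier heights by well
#' under the smoothing tolerance.
#'
#' @param Uc,U0 `meso_pmf` (or `meso_profile`) objects with equal periods.
#' @param window smoothing window around each crossing (nm); default 0.05.
#' @param n number of nodes of the common dense grid.
#' @return A `meso_pmf` for the combined profile.
#' @export
combine_charged_pmfs <- function(Uc, U0, window = 0.05, n = 2001L) {
  stopifnot(inherits(Uc, "meso_profile"), inherits(U0, "meso_profile"))
  if (abs(Uc$period - U0$period) > 1e-9 * max(Uc$period, U0$period))
    stop("incompatible periods: the two PMFs must share the lattice parameter")
  a <- Uc$period
  z <- seq(0, a / 2, length.out = n)
  d <- profile_value(Uc, z) - profile_value(U0, z)
  m <- pmin(profile_value(Uc, z), profile_value(U0, z))
  s <- sign(d)
  cross <- which(s[-1] * s[-n] < 0)
  keep <- rep(TRUE, n)
  for (i in cross) {
    zc <- z[i] - d[i] * (z[i + 1] - z[i]) / (d[i + 1] - d[i])
    keep <- keep & (abs(z - zc) > window / 2)
  }
  keep[c(1L, n)] <- TRUE
  load_tabulated_pmf(data.frame(z = z[keep], U = m[keep]), period = a)
}

#' Write a PMF to a TSV file
#'
#' Two whitespace-delimited columns (z in nm, U in kBT) preceded by a
#' `# period:` directive, the format read back by [load_tabulated_pmf()].
#'
#' @param pmf a `meso_pmf`, or any `meso_profile` (sampled on `n` points).
#' @param path output file.
#' @param n number of grid points when sampling a non-tabulated profile.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path, n = 201L) {
  stopifnot(inherits(pmf, "meso_profile"))
  if (inherits(pmf, "meso_pmf")) {
    z <- pmf$z; U <- pmf$U
  } else {
    z <- seq(0, pmf$period / 2, length.out = n)
    U <- profile_value(pmf, z)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# potential of mean force: z (nm)\tU (kBT)",
               sprintf("# period: %.10g", pmf$period)), con)
  utils::write.table(data.frame(z = z, U = U), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
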