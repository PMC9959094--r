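# Periodic, mirror-symmetric free-energy and diffusivity profiles.
#
# All profiles are defined by their restriction to the half period [0, a/2]
# (z = 0 at the bilayer midplane, z = a/2 at the centre of the water channel)
# and extended to the whole axis by even reflection at both symmetry planes,
# which yields an a-periodic, mirror-symmetric function. Values are C^1
# everywhere; derivatives are odd under the reflections, so they vanish at
# z = 0 and z = a/2.

# Internal constructor. `value_half`/`deriv_half` operate on folded z in
# [0, a/2]; `breaks` are the interior smooth-segment boundaries used by the
# adaptive quadratures.
new_profile <- function(value_half, deriv_half, period, kind, params,
                        breaks = numeric(0), label = kind) {
  structure(list(value_half = value_half, deriv_half = deriv_half,
                 period = period, kind = kind, params = params,
                 breaks = sort(unique(breaks)), label = label),
            class = "meso_profile")
}

# Fold z onto the fundamental half period [0, a/2]; `sign` is the parity
# factor picked up by derivatives under the mirror reflection.
fold_half_period <- function(z, a) {
  zp <- z - a * floor(z / a)
  s <- ifelse(zp > a / 2, -1, 1)
  zf <- ifelse(zp > a / 2, a - zp, zp)
  list(z = zf, sign = s)
}

#' Evaluate a profile
#'
#' @param profile a `meso_profile` object.
#' @param z positions in nm (any real values; the profile is periodic).
#' @return Profile values (kBT for potentials, nm^2/ns for diffusivities).
#' @export
profile_value <- function(profile, z) {
  stopifnot(inherits(profile, "meso_profile"))
  f <- fold_half_period(z, profile$period)
  profile$value_half(f$z)
}

#' Evaluate the spatial derivative of a profile
#'
#' The derivative is antisymmetric about both symmetry planes (z = 0 and
#' z = a/2), so it vanishes there.
#'
#' @inheritParams profile_value
#' @return d(value)/dz at `z` (kBT/nm or nm/ns).
#' @export
profile_deriv <- function(profile, z) {
  stopifnot(inherits(profile, "meso_profile"))
  f <- fold_half_period(z, profile$period)
  f$sign * profile$deriv_half(f$z)
}

#' @export
print.meso_profile <- function(x, ...) {
  cat(sprintf("<meso_profile: %s> period a = %g nm\n", x$label, x$period))
  invisible(x)
}

#' Parameters of the piecewise-parabolic toy potential
#'
#' Geometry and energetics of the minimal lamellar free-energy model: a flat
#' plateau of height `dU` across the lipid tails, a parabolic barrier (or
#' well) of height `dUb` centred on the lipid heads, and zero free energy in
#' the water channel. `dU > 0` describes a hydrophilic molecule, `dU < 0` a
#' hydrophobic one; `dUb < 0` models amphiphiles that sit at the interface.
#'
#' @param a lattice parameter (nm). Default 6.65 nm (fully hydrated DPPC
#'   lamellar phase at 43 C).
#' @param l lipid length (nm); default 2.365.
#' @param h lipid-head size (nm); default 1.
#' @param dU tail-plateau free energy (kBT).
#' @param dUb head barrier/well (kBT); any sign and ordering relative to
#'   `dU` is accepted.
#' @return A `toy_potential_params` list.
#' @export
toy_potential_params <- function(dU, dUb, a = 6.65, l = 2.365, h = 1) {
  stopifnot(is.finite(a), is.finite(l), is.finite(h),
            is.finite(dU), is.finite(dUb))
  if (!(h > 0)) stop("invalid geometry: head size h must be positive")
  if (!(h < l)) stop("invalid geometry: head size h must be smaller than lipid length l")
  if (!(l < a / 2)) stop("invalid geometry: lipid length l must be smaller than the half period a/2")
  structure(list(a = a, l = l, h = h, dU = dU, dUb = dUb),
            class = "toy_potential_params")
}

#' Parameters of the smooth toy diffusivity profile
#'
#' `D(z)` equals `Dlip` throughout the lipid region (z <= l), rises through
#' two matched parabolic branches across a transition layer of thickness `w`
#' of reduced-mobility water, and equals `Dwat` beyond. The constraint
#' `w <= a/2 - l` guarantees that `Dwat` is attained at or before the channel
#' centre, keeping the derivative continuous at z = a/2.
#'
#' @param Dwat bulk-water diffusivity (nm^2/ns).
#' @param Dlip lipid-phase diffusivity (nm^2/ns), 0 < Dlip <= Dwat.
#' @param a lattice parameter (nm); default 6.65.
#' @param l lipid length (nm); default 2.365.
#' @param w transition-layer thickness (nm); default 0.96, which for the
#'   default geometry makes Dwat be reached exactly at z = a/2.
#' @return A `diffusion_profile_params` list.
#' @export
diffusion_profile_params <- function(Dwat, Dlip, a = 6.65, l = 2.365, w = 0.96) {
  stopifnot(is.finite(a), is.finite(l), is.finite(w),
            is.finite(Dwat), is.finite(Dlip))
  if (!(w > 0)) stop("invalid geometry: transition thickness w must be positive")
  if (w > a / 2 - l + 1e-12)
    stop("invalid geometry: w must not exceed a/2 - l (derivative of D(z) would be discontinuous at a/2)")
  if (!(Dlip > 0)) stop("Dlip must be positive")
  if (Dlip > Dwat + 1e-12) stop("Dlip must not exceed Dwat")
  structure(list(a = a, l = l, w = w, Dwat = Dwat, Dlip = Dlip),
            class = "diffusion_profile_params")
}

#' Build the piecewise-parabolic toy potential U(z)
#'
#' Six smooth branches on the half period: a plateau `dU` for z <= l - h,
#' four parabolic arcs interpolating plateau -> barrier top `dUb`
#' (at z = l - h/2) -> 0 at z = l, and zero across the water channel. Both
#' U and dU/dz are continuous everywhere, which the stochastic integrator
#' requires.
#'
#' @param params a [toy_potential_params()] object.
#' @return A `meso_profile` of kind `"potential"`.
#' @examples
#' U <- build_toy_potential(toy_potential_params(dU = 3, dUb = 5))
#' profile_value(U, c(0, 2.365 - 0.5, 2.365, 6.65 / 2))  # dU, dUb, 0, 0
#' @export
build_toy_potential <- function(params) {
  stopifnot(inherits(params, "toy_potential_params"))
  a <- params$a; l <- params$l; h <- params$h
  dU <- params$dU; dUb <- params$dUb
  c1 <- 8 * (dUb - dU) / h^2
  c2 <- 8 * dUb / h^2

  value_half <- function(z) {
    v <- numeric(length(z))
    i1 <- z <= l - h
    i2 <- z > l - h & z <= l - 0.75 * h
    i3 <- z > l - 0.75 * h & z <= l - 0.5 * h
    i4 <- z > l - 0.5 * h & z <= l - 0.25 * h
    i5 <- z > l - 0.25 * h & z <= l
    v[i1] <- dU
    v[i2] <- dU + c1 * (l - h - z[i2])^2
    v[i3] <- dUb - c1 * (l - 0.5 * h - z[i3])^2
    v[i4] <- dUb - c2 * (l - 0.5 * h - z[i4])^2
    v[i5] <- c2 * (l - z[i5])^2
    v  # zero in the water region (l, a/2]
  }
  deriv_half <- function(z) {
    d <- numeric(length(z))
    i2 <- z > l - h & z <= l - 0.75 * h
    i3 <- z > l - 0.75 * h & z <= l - 0.5 * h
    i4 <- z > l - 0.5 * h & z <= l - 0.25 * h
    i5 <- z > l - 0.25 * h & z <= l
    d[i2] <- 2 * c1 * (z[i2] - (l - h))
    d[i3] <- 2 * c1 * (l - 0.5 * h - z[i3])
    d[i4] <- 2 * c2 * (l - 0.5 * h - z[i4])
    d[i5] <- -2 * c2 * (l - z[i5])
    d
  }
  new_profile(value_half, deriv_half, a, "potential", params,
              breaks = c(l - h, l - 0.75 * h, l - 0.5 * h, l - 0.25 * h, l),
              label = sprintf("toy potential (dU = %g, dUb = %g kBT)", dU, dUb))
}

#' Build the smooth toy diffusivity profile D(z)
#'
#' Four branches on the half period: `Dlip` for z <= l, two matched parabolas
#' over (l, l + w], `Dwat` beyond. C^1 everywhere.
#'
#' @param params a [diffusion_profile_params()] object.
#' @return A `meso_profile` of kind `"diffusion"`.
#' @examples
#' D <- build_toy_diffusion(diffusion_profile_params(Dwat = 0.7, Dlip = 0.063))
#' profile_value(D, c(0, 2.365, 2.365 + 0.48, 6.65 / 2))
#' @export
build_toy_diffusion <- function(params) {
  stopifnot(inherits(params, "diffusion_profile_params"))
  a <- params$a; l <- params$l; w <- params$w
  Dw <- params$Dwat; Dl <- params$Dlip
  c0 <- 2 * (Dw - Dl) / w^2

  value_half <- function(z) {
    v <- rep(Dl, length(z))
    i2 <- z > l & z <= l + 0.5 * w
    i3 <- z > l + 0.5 * w & z <= l + w
    i4 <- z > l + w
    v[i2] <- Dl + c0 * (l - z[i2])^2
    v[i3] <- Dw - c0 * (l + w - z[i3])^2
    v[i4] <- Dw
    v
  }
  deriv_half <- function(z) {
    d <- numeric(length(z))
    i2 <- z > l & z <= l + 0.5 * w
    i3 <- z > l + 0.5 * w & z <= l + w
    d[i2] <- 2 * c0 * (z[i2] - l)
    d[i3] <- 2 * c0 * (l + w - z[i3])
    d
  }
  new_profile(value_half, deriv_half, a, "diffusion", params,
              breaks = c(l, l + 0.5 * w, l + w),
              label = sprintf("toy diffusivity (Dlip = %g, Dwat = %g nm^2/ns)", Dl, Dw))
}

#' Constant profile
#'
#' Convenience constructor for a flat potential (U = 0) or uniform
#' diffusivity, sharing the `meso_profile` interface.
#'
#' @param value constant value (kBT or nm^2/ns).
#' @param a period (nm).
#' @param kind `"potential"` or `"diffusion"`.
#' @return A `meso_profile`.
#' @export
constant_profile <- function(value, a = 6.65, kind = "potential") {
  stopifnot(is.finite(value), is.finite(a), a > 0)
  new_profile(function(z) rep(value, length(z)),
              function(z) numeric(length(z)),
              a, kind, list(value = value, a = a),
              label = sprintf("constant %s (%g)", kind, value))
}

#' Rescale a potential by a factor alpha
#'
#' Used by the alpha-extrapolation protocol for systems whose barriers are
#' too high for direct simulation: the whole free-energy profile is
#' multiplied by `alpha < 1`, lowering every barrier proportionally.
#'
#' @param U a `meso_profile` potential.
#' @param alpha positive scale factor (dimensionless).
#' @return A rescaled `meso_profile`.
#' @export
scale_potential <- function(U, alpha) {
  stopifnot(inherits(U, "meso_profile"), is.finite(alpha), alpha > 0)
  new_profile(function(z) alpha * U$value_half(z),
              function(z) alpha * U$deriv_half(z),
              U$period, U$kind, c(U$params, list(alpha = alpha)), U$breaks,
              label = sprintf("%s x %g", U$label, alpha))
}

#' Sample a profile on a regular grid
#'
#' Dense-grid export used for plotting, validation and file output.
#'
#' @param profile a `meso_profile`.
#' @param n number of points.
#' @param full if `TRUE` sample one full period [0, a); otherwise the half
#'   period [0, a/2].
#' @return A data.frame with columns `z`, `value`, `deriv`.
#' @export
profile_grid <- function(profile, n = 1001, full = FALSE) {
  stopifnot(inherits(profile, "meso_profile"), n >= 2)
  upper <- if (full) profile$period else profile$period / 2
  z <- seq(0, upper, length.out = n)
  data.frame(z = z, value = profile_value(profile, z),
             deriv = profile_deriv(profile, z))
}

#' Write a profile to CSV
#'
#' @inheritParams profile_grid
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, n = 1001) {
  utils::write.csv(profile_grid(profile, n), path, row.names = FALSE)
  invisible(path)
}
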