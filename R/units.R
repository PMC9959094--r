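#' Simulation unit system
#'
#' The package works in reduced units: lengths in nanometres (sigma = 1 nm),
#' energies in units of the thermal energy kBT, and diffusivities in nm^2/ns.
#' The natural timescale is tau = sigma^2 / Dwat, i.e. the time a molecule
#' with bulk-water diffusivity `Dwat` needs to diffuse across one length unit.
#' For Dwat = 0.7 nm^2/ns this gives tau ~ 1.43 ns.
#'
#' @param Dwat bulk-water diffusion coefficient of the guest molecule
#'   (nm^2/ns); must be positive and finite.
#' @param sigma length unit in nm (default 1).
#' @return An object of class `meso_units`: a list with `sigma` (nm),
#'   `Dwat` (nm^2/ns) and `tau` (ns), where `tau = sigma^2 / Dwat` exactly.
#' @examples
#' u <- unit_system(Dwat = 0.7)
#' u$tau  # ~1.43 ns
#' @export
unit_system <- function(Dwat, sigma = 1) {
  stopifnot(is.numeric(Dwat), length(Dwat) == 1L, is.finite(Dwat), Dwat > 0,
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma > 0)
  structure(list(sigma = sigma, Dwat = Dwat, tau = sigma^2 / Dwat),
            class = "meso_units")
}

#' @export
print.meso_units <- function(x, ...) {
  cat(sprintf("<meso_units> sigma = %g nm, Dwat = %g nm^2/ns, tau = %g ns\n",
              x$sigma, x$Dwat, x$tau))
  invisible(x)
}
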