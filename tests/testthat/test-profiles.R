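# Piecewise toy profiles and tabulated PMFs: anchor values, smoothness,
# symmetry, interpolation round trips.

test_that("toy potential hits its anchor values and branch midpoints", {
  U <- toy_U(3, 5, l = 2.365, h = 1)
  l <- 2.365; h <- 1
  expect_equal(profile_value(U, 0), 3)                      # plateau
  expect_equal(profile_value(U, 1.0), 3)                    # z <= l - h
  expect_equal(profile_value(U, l - h / 2), 5)              # barrier top
  expect_equal(profile_value(U, l - 3 * h / 4), (3 + 5) / 2)  # junction
  expect_equal(profile_value(U, l), 0)
  expect_equal(profile_value(U, 6.65 / 2), 0)
  # barrier top and symmetry planes are smooth maxima/minima
  expect_equal(profile_deriv(U, l - h / 2), 0)
  expect_equal(profile_deriv(U, 0), 0)
  expect_equal(profile_deriv(U, 6.65 / 2), 0)
  # plateau and water regions are flat
  expect_equal(profile_deriv(U, 0.7), 0)
  expect_equal(profile_deriv(U, 3.0), 0)
})

test_that("toy diffusivity hits its anchor values and steepest slope", {
  prm <- diffusion_profile_params(Dwat = 0.7, Dlip = 0.063)
  D <- build_toy_diffusion(prm)
  l <- 2.365; w <- 0.96
  expect_equal(profile_value(D, 0), 0.063)
  expect_equal(profile_value(D, l), 0.063)
  expect_equal(profile_value(D, l + w / 2), (0.063 + 0.7) / 2)
  expect_equal(profile_value(D, l + w), 0.7)
  expect_equal(profile_deriv(D, l + w / 2), 2 * (0.7 - 0.063) / w)
  # flat profile identity case
  Dflat <- build_toy_diffusion(diffusion_profile_params(Dwat = 0.7, Dlip = 0.7))
  z <- seq(-5, 5, length.out = 101)
  expect_equal(profile_value(Dflat, z), rep(0.7, 101))
})

test_that("profiles are C1 at every breakpoint and mirror-periodic", {
  eps <- 1e-9
  U <- toy_U(-2.5, 4, l = 2.365, h = 1)
  D <- toy_D()
  for (p in list(U, D)) {
    for (b in c(p$breaks, 0, p$period / 2)) {
      expect_lt(abs(profile_value(p, b + eps) - profile_value(p, b - eps)),
                1e-6)
      expect_lt(abs(profile_deriv(p, b + eps) - profile_deriv(p, b - eps)),
                1e-6)
    }
  }
  set.seed(42)
  z <- stats::runif(1000, -20, 20)
  for (p in list(U, D)) {
    a <- p$period
    expect_equal(profile_value(p, z), profile_value(p, z + a))
    expect_equal(profile_value(p, z), profile_value(p, -z))
    # derivatives are odd under reflection
    expect_equal(profile_deriv(p, z), -profile_deriv(p, -z))
  }
})

test_that("invalid geometries are rejected with informative messages", {
  expect_error(toy_potential_params(1, 1, l = 2, h = 2.5), "head size")
  expect_error(toy_potential_params(1, 1, a = 4, l = 2.1), "lipid length")
  expect_error(diffusion_profile_params(0.7, 0.063, w = 1.5), "a/2 - l")
  expect_error(diffusion_profile_params(0.7, 0.9), "Dlip")
})

test_that("tabulated PMFs round-trip an analytic toy profile", {
  U <- toy_U(3, 5)
  a <- U$period
  z <- seq(0, a / 2, length.out = 200)
  pmf <- load_tabulated_pmf(data.frame(z = z, U = profile_value(U, z)),
                            period = a)
  zz <- seq(0, a / 2, length.out = 4000)
  expect_lt(max(abs(profile_value(pmf, zz) - profile_value(U, zz))), 1e-3)
  # derivative: 1e-2 away from the parabola junctions; the junctions carry
  # a second-derivative jump, so any C^2 interpolant has an O(grid) error
  # there, bounded by the jump magnitude times the spacing
  dz <- z[2] - z[1]
  far <- vapply(zz, function(x) min(abs(x - U$breaks)) > 4 * dz, logical(1))
  derr <- abs(profile_deriv(pmf, zz) - profile_deriv(U, zz))
  expect_lt(max(derr[far]), 1e-2)
  jump <- 16 * abs(5 - 3) / 1^2 + 16 * 5 / 1^2
  expect_lt(max(derr), jump * dz)
  # extrema match the analytic ones
  expect_equal(pmf$Umax - pmf$Umin, 5, tolerance = 1e-3)
  # mirror symmetry of the interpolant: zero slope at both planes
  expect_lt(abs(profile_deriv(pmf, 0)), 1e-8)
  expect_lt(abs(profile_deriv(pmf, a / 2)), 1e-8)
})

test_that("tabulated PMF edge cases and input validation", {
  a <- 6.65
  z <- seq(0, a / 2, length.out = 50)
  expect_error(load_tabulated_pmf(data.frame(z = rev(z), U = z), period = a),
               "increasing")
  expect_error(load_tabulated_pmf(data.frame(z = z, U = c(NA, z[-1])),
                                  period = a), "non-finite")
  expect_error(load_tabulated_pmf(data.frame(z = z[1:5], U = z[1:5]),
                                  period = a))
  expect_error(load_tabulated_pmf(data.frame(z = z, U = z * 0)), "period")
  flat <- load_tabulated_pmf(data.frame(z = z, U = rep(0, 50)), period = a)
  expect_equal(flat$Umin, 0, tolerance = 1e-12)
  expect_equal(flat$Umax, 0, tolerance = 1e-12)
})

test_that("PMF files round-trip through TSV with a period directive", {
  U <- toy_U(2, -3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pmf_tsv(U, f, n = 201)
  pmf <- load_tabulated_pmf(f)  # period from the directive line
  expect_equal(pmf$period, U$period)
  zz <- seq(0, U$period / 2, length.out = 1000)
  expect_lt(max(abs(profile_value(pmf, zz) - profile_value(U, zz))), 2e-3)
})

test_that("charged/neutral combination takes the lower branch and stays smooth", {
  a <- 6.65
  z <- seq(0, a / 2, length.out = 201)
  # Uc below U0 everywhere -> result is Uc
  Uc <- load_tabulated_pmf(data.frame(z = z, U = rep(1, 201)), period = a)
  U0 <- load_tabulated_pmf(data.frame(z = z, U = rep(5, 201)), period = a)
  comb <- combine_charged_pmfs(Uc, U0)
  expect_lt(max(abs(profile_value(comb, z) - 1)), 1e-9)
  # single crossing: lower branch on each side, continuous at the crossing
  Uc2 <- toy_U(8, 0)    # high plateau, zero in water
  U02 <- toy_U(2, 2)    # low plateau
  comb2 <- combine_charged_pmfs(Uc2, U02)
  lower <- pmin(profile_value(Uc2, z), profile_value(U02, z))
  diff2 <- profile_value(Uc2, z) - profile_value(U02, z)
  zc <- z[which(diff2[-1] * diff2[-length(z)] < 0)]
  away <- vapply(z, function(x) all(abs(x - zc) > 0.05), logical(1))
  dev <- abs(profile_value(comb2, z) - lower)
  # away from the rounded kinks the combination equals the lower branch
  expect_lt(max(dev[away]), 0.01)
  # the smoothing must not shift barrier heights by more than 0.05 kBT
  expect_lt(abs(comb2$Umax - max(lower)), 0.05)
  expect_lt(abs(comb2$Umin - min(lower)), 0.05)
  # derivative defined and finite everywhere (C1 after smoothing)
  eps <- 1e-7
  dd <- vapply(z[-c(1, 201)], function(x)
    abs(profile_deriv(comb2, x + eps) - profile_deriv(comb2, x - eps)),
    numeric(1))
  expect_lt(max(dd), 1e-4)
  expect_error(combine_charged_pmfs(Uc, toy_U(1, 1, a = 5)), "period")
})

test_that("profile export writes a dense, consistent grid", {
  U <- toy_U(1, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(U, f, n = 101)
  tab <- utils::read.csv(f)
  expect_equal(nrow(tab), 101)
  expect_equal(tab$value, profile_value(U, tab$z))
  expect_equal(tab$deriv, profile_deriv(U, tab$z))
})
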