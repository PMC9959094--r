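# Closed-form relations: partition coefficient, thermal averages, the logP
# form, the periodic-medium result, Arrhenius and alpha fits, temperature
# rescaling, and the drug table.

test_that("logP vanishes for a flat potential and matches a sharp interface", {
  expect_equal(log_partition_coefficient(flat_U(), l = 2.365)$logP, 0,
               tolerance = 1e-9)
  # sharp two-phase profile: U = 2 kBT in the lipid, 0 in water
  sharp <- mesodiff:::new_profile(
    function(z) ifelse(z <= 2.365, 2, 0), function(z) numeric(length(z)),
    6.65, "potential", list(a = 6.65, l = 2.365), breaks = 2.365)
  expect_equal(log_partition_coefficient(sharp, l = 2.365)$logP,
               -2 * log10(exp(1)), tolerance = 1e-8)
})

test_that("logP quadrature agrees with a brute-force Riemann sum", {
  U <- toy_U(5, 5)
  l <- 2.365; a <- 6.65
  z1 <- seq(0, l, length.out = 5e5); z2 <- seq(l, a / 2, length.out = 5e5)
  clip <- mean(exp(-profile_value(U, z1)))
  cwat <- mean(exp(-profile_value(U, z2)))
  expect_equal(log_partition_coefficient(U)$logP, log10(clip / cwat),
               tolerance = 1e-5)
})

test_that("thermal average of D: trivial cases and exact toy decomposition", {
  D <- toy_D()
  # Eq-12-type arithmetic: flat U, default geometry
  expect_equal(d_parallel_theory(flat_U(), D),
               0.7 - (0.7 - 0.063) * (2 * 2.365 + 0.96) / 6.65,
               tolerance = 1e-8)
  # constant D: thermal average is D regardless of U
  expect_equal(d_parallel_theory(toy_U(4, -3), const_D(0.42)), 0.42,
               tolerance = 1e-9)
  # two-way identity: quadrature vs the Boltzmann-weight decomposition
  # (lipid term Dlip l 10^logP, transition term w (Dwat+Dlip)/2, bulk term),
  # exact for the toy model where U = 0 throughout the water region
  for (prm in list(c(3, 2), c(-2, 5), c(5, -4), c(0, 0))) {
    U <- toy_U(prm[1], prm[2])
    parts <- d_parallel_theory(U, D, normalized = FALSE)
    p <- log_partition_coefficient(U)$ratio
    num_id <- 0.063 * (2.365 * p + 0.96 / 2) + 0.7 * (6.65 / 2 - 2.365 - 0.48)
    den_id <- 2.365 * p + 6.65 / 2 - 2.365
    expect_equal(parts$num, num_id, tolerance = 1e-8)
    expect_equal(parts$den, den_id, tolerance = 1e-8)
    # hence the logP closed form reproduces the full thermal average
    expect_equal(d_parallel_from_logP(log10(p), Dlip = 0.063, Dwat = 0.7),
                 parts$D_par, tolerance = 1e-7)
  }
})

test_that("logP closed form has the right hydropathy limits", {
  # strongly hydrophobic: the molecule lives in the bilayer
  expect_equal(d_parallel_from_logP(8, Dlip = 0.063, Dwat = 0.7), 0.063,
               tolerance = 1e-3)
  # strongly hydrophilic: mean diffusivity of the water region, which for
  # the default geometry (a/2 - l = w) is (Dlip + Dwat)/2, not Dwat
  expect_equal(d_parallel_from_logP(-8, Dlip = 0.063, Dwat = 0.7),
               (0.063 + 0.7) / 2, tolerance = 1e-6)
})

test_that("effective coefficient combines directions with 2/3-1/3 weights", {
  expect_equal(d_eff(0.3, 0.3), 0.3)
  expect_equal(d_eff(0.3, 0), 0.2)
  # large-barrier closed form is 2/3 of the lateral closed form
  expect_equal(d_eff_large_barrier(0.46, Dlip = 0.09 * 1.06, Dwat = 1.06),
               2 / 3 * d_parallel_from_logP(0.46, Dlip = 0.09 * 1.06,
                                            Dwat = 1.06))
  expect_error(d_eff(-0.1, 0.2))
})

test_that("periodic-medium closed form: constant limits and harmonic mean", {
  expect_equal(d_perp_oracle(flat_U(), const_D(0.7)), 0.7, tolerance = 1e-9)
  # flat U: harmonic mean of D over the period
  D <- toy_D()
  z <- seq(0, 6.65 / 2, length.out = 2e5)
  harm <- 1 / mean(1 / profile_value(D, z))
  expect_equal(d_perp_oracle(flat_U(), D), harm, tolerance = 1e-4)
  # approximate power-law behaviour in Dlip/Dwat with exponent ~ 0.92
  expect_equal(harm / 0.7, (0.063 / 0.7)^0.92, tolerance = 0.05)
})

test_that("perpendicular transport is bounded by lateral transport", {
  # two-average (Cauchy-Schwarz) sandwich for any profile pair
  set.seed(7)
  for (i in 1:8) {
    U <- toy_U(stats::runif(1, -5, 5), stats::runif(1, -5, 5))
    D <- toy_D(Dlip = stats::runif(1, 0.05, 0.7))
    expect_lte(d_perp_oracle(U, D), d_parallel_theory(U, D) * (1 + 1e-12))
  }
  # equality iff both profiles are constant
  expect_equal(d_perp_oracle(flat_U(), const_D(0.5)),
               d_parallel_theory(flat_U(), const_D(0.5)), tolerance = 1e-9)
})

test_that("Arrhenius fits recover exact inputs and the high-barrier limit", {
  B <- 5:10
  f <- arrhenius_fit(B, 8.0 * exp(-0.93 * B))
  expect_equal(f$prefactor, 8.0, tolerance = 1e-8)
  expect_equal(f$rate, 0.93, tolerance = 1e-10)
  expect_error(arrhenius_fit(1:2, c(1, 2)), "at least 3")
  expect_error(arrhenius_fit(1:3, c(1, -1, 2)), "positive")
  # oracle-evaluated decay rate tends to 1 per kBT as barriers grow
  Dc <- const_D()
  rate_at <- function(bs) {
    arrhenius_fit(bs, vapply(bs, function(b)
      d_perp_oracle(toy_U(0, b), Dc), numeric(1)))$rate
  }
  r_mid <- rate_at(c(5, 7, 9)); r_high <- rate_at(c(16, 18, 20))
  expect_gt(r_high, r_mid)
  expect_gt(r_high, 0.95)
  expect_lt(r_high, 1.0)
})

test_that("alpha extrapolation is exact for exponential decays", {
  al <- c(0.3, 0.4, 0.5, 0.6)
  ex <- alpha_extrapolate(al, 5 * exp(-4.2 * al))
  expect_equal(ex$D_perp1, 5 * exp(-4.2), tolerance = 1e-10)
  expect_error(alpha_extrapolate(c(0.5, 0.6), c(1, 2)), "at least 3")
  expect_error(alpha_extrapolate(c(0.5, 0.6, 1.2), c(1, 2, 3)), "in \\(0, 1\\]")
})

test_that("Stokes-Einstein rescaling follows the viscosity table", {
  expect_equal(stokes_einstein_rescale(0.7, 25, 25), 0.7)
  # 25 C -> 43 C raises D by ~1.5 (temperature ratio times viscosity ratio)
  ratio <- stokes_einstein_rescale(1, 25, 43)
  expect_equal(ratio, (316.15 / 298.15) * (0.890 / water_viscosity(43)),
               tolerance = 1e-8)
  expect_equal(ratio, 1.5, tolerance = 0.05)
  # typical room-temperature amino-acid diffusivities land in the published
  # 0.9-1.3 nm^2/ns range at 37 C
  r37 <- stokes_einstein_rescale(c(0.7, 0.95), 25, 37)
  expect_true(all(r37 >= 0.9 & r37 <= 1.3))
  expect_error(stokes_einstein_rescale(0.7, 25, 120), "liquid-water")
})

test_that("drug table reports both closed forms and flags the match", {
  out <- drug_transport()
  expect_equal(out$Deff_large_barrier, round(2 / 3 * d_parallel_from_logP(
    out$logP, Dlip = 0.09 * out$Dwat, Dwat = out$Dwat), 2))
  expect_true(all(out$matches == "D_par"))
  # rows with missing inputs are skipped with a warning
  bad <- rbind(drug_reference_table()[1:2, ],
               data.frame(name = "x", logP = NA, Dwat = 1,
                          Deff_printed = NA))
  expect_warning(res <- drug_transport(bad), "skipping")
  expect_equal(nrow(res), 2)
})
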