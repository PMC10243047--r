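test_that("Reynolds number follows N d^2 / nu and is linear in impeller speed", {
  geom <- bench_vessel()
  expect_equal(reynolds_number(geom, water(), agitation_condition(100)),
               (100 / 60) * 0.0325^2 / 1e-6)
  expect_equal(reynolds_number(geom, water(), agitation_condition(100)),
               1763.93, tolerance = 0.005)
  expect_equal(reynolds_number(geom, water(), agitation_condition(0)), 0)
  for (rpm in c(10, 50, 130)) {
    expect_equal(reynolds_number(geom, water(), agitation_condition(2 * rpm)),
                 2 * reynolds_number(geom, water(), agitation_condition(rpm)))
  }
})

test_that("Nagata power number matches an independent transcription and its high-Re limit", {
  cases <- expand.grid(Re = c(50, 867.69, 1763.93, 1e5),
                       dD = c(0.3, 0.5, 0.7), bD = c(0.06, 0.1))
  for (k in seq_len(nrow(cases))) {
    g <- vessel_geometry(0.1, 0.1 * cases$dD[k], 0.1 * cases$bD[k],
                         0.05, pi * 0.05^2 * 0.05)
    expect_equal(nagata_power_number(g, cases$Re[k]),
                 nagata_oracle(cases$Re[k], cases$dD[k], cases$bD[k]))
  }
  # Re -> infinity: A/Re vanishes and the bracket tends to 1.2/3.2
  g <- bench_vessel()
  B <- 10^(1.3 - 4 * (0.06 - 0.5)^2 - 1.14 * 0.5)
  p <- 1.1 + 4 * 0.06 - 2.5 * (0.5 - 0.5)^2 - 7 * 0.06^4
  expect_equal(nagata_power_number(g, 1e10), B * (1.2 / 3.2)^p,
               tolerance = 1e-3)
  expect_error(nagata_power_number(g, 0), "positive")
  expect_error(nagata_power_number(g, -5), "positive")
})

test_that("blade-height default b/D = 0.06 reproduces the expected power-number pair", {
  # brute-force sweep: the default must match (0.78, 0.69) at the two
  # operating Reynolds numbers better than any other b/D in [0.03, 0.15]
  sweep <- seq(0.03, 0.15, by = 0.005)
  err <- vapply(sweep, function(bd) {
    g <- bench_vessel(b_over_D = bd)
    max(abs(nagata_power_number(g, 867.69) - 0.78),
        abs(nagata_power_number(g, 1763.93) - 0.69))
  }, numeric(1))
  expect_equal(sweep[which.min(err)], 0.06)
  expect_lt(min(err), 0.01)
})

test_that("power draw, dissipation, shear stress, ISF and eddy length follow their formulas", {
  geom <- bench_vessel()
  fl <- water()
  # power: hand arithmetic of N_p N^3 d^5 rho
  expect_equal(impeller_power(0.772, agitation_condition(50), geom, fl),
               0.772 * (50 / 60)^3 * 0.0325^5 * 1000)
  expect_equal(impeller_power(0.772, agitation_condition(50), geom, fl),
               1.62e-5, tolerance = 0.002)
  expect_equal(impeller_power(0.5, agitation_condition(0), geom, fl), 0)
  g2 <- vessel_geometry(0.13, 0.065, 0.0078, 0.0598, 8e-4)  # doubled impeller
  expect_equal(impeller_power(0.5, agitation_condition(50), g2, fl),
               32 * impeller_power(0.5, agitation_condition(50), geom, fl))
  # dissipation: P / (V_L rho), inverse in volume
  expect_equal(energy_dissipation(1.62e-5, geom, fl), 1.62e-4)
  expect_equal(energy_dissipation(0, geom, fl), 0)
  half <- vessel_geometry(0.065, 0.0325, 0.0039, 0.01533, 5e-5)
  expect_equal(energy_dissipation(1e-5, half, fl),
               2 * energy_dissipation(1e-5, geom, fl))
  # maximum shear stress against the reported operating points
  expect_equal(max_shear_stress(1.62e-4, fl), 0.068, tolerance = 0.005)
  expect_equal(max_shear_stress(1.32e-3, fl), 0.193, tolerance = 0.005)
  expect_equal(max_shear_stress(0, fl), 0)
  # ISF: 2 pi N d / (D - d); with D = 2d it reduces to 2 pi N
  expect_equal(integrated_shear_factor(geom, agitation_condition(100)),
               10.47, tolerance = 0.002)
  expect_equal(integrated_shear_factor(geom, agitation_condition(50)),
               2 * pi * 50 / 60)
  expect_equal(integrated_shear_factor(geom, agitation_condition(0)), 0)
  # Kolmogorov length at the two operating points plus the unit case
  expect_equal(kolmogorov_length(1.62e-4, fl) * 1e6, 280, tolerance = 0.005)
  expect_equal(kolmogorov_length(1.32e-3, fl) * 1e6, 166, tolerance = 0.005)
  unit_fluid <- fluid_properties(density = 1, kinematic_viscosity = 1)
  expect_equal(kolmogorov_length(1, unit_fluid), 1)
})

test_that("shear threshold comparison is strict with a signed margin", {
  chk <- shear_threshold_check(0.193, 0.092)
  expect_true(chk$exceeds)
  expect_equal(chk$margin, 0.101)
  chk <- shear_threshold_check(0.068, 0.092)
  expect_false(chk$exceeds)
  expect_equal(chk$margin, -0.024)
  chk <- shear_threshold_check(0.092, 0.092)
  expect_false(chk$exceeds)  # boundary: strict inequality
  expect_equal(chk$margin, 0)
})

test_that("hydrodynamic report chains the formulas self-consistently", {
  geom <- bench_vessel()
  rep50 <- hydrodynamic_report(geom, water(), agitation_condition(50),
                               kla = 0.89)
  expect_equal(rep50$tau_max, max_shear_stress(rep50$epsilon, water()))
  expect_equal(rep50$kolmogorov_length,
               kolmogorov_length(rep50$epsilon, water()))
  expect_equal(rep50$power,
               impeller_power(rep50$power_number, agitation_condition(50),
                              geom, water()))
  expect_equal(rep50$kla, 0.89)  # pass-through, never computed
  expect_identical(rep50$shear_exceeds_threshold,
                   rep50$tau_max > rep50$threshold)
  # speed normalised once at construction: formulas see rev/s
  expect_equal(agitation_condition(50)$speed_rps, 50 / 60)
})

test_that("geometry and fluid validation rejects inconsistent inputs", {
  expect_error(vessel_geometry(0.065, 0.07, 0.0039, 0.0299, 1e-4), "smaller")
  expect_error(vessel_geometry(0.065, 0.0325, 0.0039, 0.0299, 2e-4),
               "inconsistent")
  expect_error(vessel_geometry(-0.065, 0.0325, 0.0039, 0.0299, 1e-4),
               "positive")
  expect_error(fluid_properties(density = 0), "positive")
  expect_error(fluid_properties(density = 1000, dynamic_viscosity = 1e-3,
                                kinematic_viscosity = 1e-6), "not both")
  expect_equal(fluid_properties(density = 500,
                                dynamic_viscosity = 1e-3)$kinematic_viscosity,
               2e-6)
  expect_error(agitation_condition(-10), "non-negative")
})
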