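# Closed-form electrochemistry.

test_that("Nernst potentials match hand arithmetic and symmetry", {
  # 58.17 * log10(8/200) at 20 degC
  expect_equal(nernst_potential(1, 8, 200, 20)$value, -81.31, tolerance = 0.01)
  # divalent: 29.09 * log10(46/5)
  expect_equal(nernst_potential(2, 46, 5, 20)$value, 28.04, tolerance = 0.01)
  for (temp in c(4, 20, 37)) {
    expect_equal(nernst_potential(1, 120, 120, temp)$value, 0)
  }
  # anion charge flips the sign
  expect_equal(nernst_potential(-1, 500, 50, 20)$value,
               -nernst_potential(1, 500, 50, 20)$value)
  expect_error(nernst_potential(1, -1, 10), class = "hvchan_domain_error")
  expect_error(nernst_potential(1, 0, 10), class = "hvchan_domain_error")
  expect_error(nernst_potential(0, 10, 10), class = "hvchan_domain_error")
})

test_that("pH equilibrium potential honours the caller's slope choice", {
  expect_equal(ph_equilibrium_potential(8.0, 7.2, slope_mv = 60)$value, -48)
  expect_equal(ph_equilibrium_potential(7.4, 7.4, slope_mv = 58)$value, 0)
  expect_equal(ph_equilibrium_potential(8.0, 7.5, temperature_c = 20)$value,
               -29.09, tolerance = 0.01)
  # slope at 20 degC is 58.17 mV per pH unit
  expect_equal(nernst_slope_mv(20), 58.17, tolerance = 0.01)
  # the slope is never chosen silently
  expect_error(ph_equilibrium_potential(8, 7.2), class = "hvchan_domain_error")
  expect_error(ph_equilibrium_potential(8, 7.2, slope_mv = 58,
                                        temperature_c = 20),
               class = "hvchan_domain_error")
  expect_error(ph_equilibrium_potential(15, 7), class = "hvchan_domain_error")
})

test_that("GHK reversal matches the independent oracle and hand value", {
  sol <- solution_registry()
  # P_H/P_K = 1e6 with the K-glutamate pipette / seawater bath
  expect_equal(ghk_reversal(c(H = 1e6, K = 1), sol$P1a, sol$E1),
               -64.5, tolerance = 0.05)
  expect_equal(ghk_reversal(c(H = 1e6, K = 1), sol$P1a, sol$E1),
               oracle_ghk_mv(1e6, 1, 200, 8, 7.5, 8.0), tolerance = 1e-9)
  # symmetric solutions reverse at 0 regardless of permeabilities
  sym <- solution_composition("sym", c(Na = 100, K = 100, Cl = 200), pH = 7)
  expect_equal(ghk_reversal(c(H = 5, K = 2, Na = 1, Cl = 3), sym, sym), 0)
  expect_error(ghk_reversal(c(H = 0, K = 0), sol$P1a, sol$E1),
               class = "hvchan_domain_error")
  expect_error(ghk_reversal(c(H = 1, Ca = 1), sol$P1a, sol$E1),
               class = "hvchan_unsupported_ion")
})

test_that("single-permeant-ion GHK collapses to the Nernst potential", {
  set.seed(42)
  for (i in 1:25) {
    k_in <- runif(1, 1, 500); k_out <- runif(1, 1, 500)
    ph_in <- runif(1, 6, 8); ph_out <- runif(1, 6, 8)
    tc <- runif(1, 5, 35)
    inside <- solution_composition("in", c(K = k_in), pH = ph_in, tc)
    outside <- solution_composition("out", c(K = k_out), pH = ph_out, tc)
    expect_equal(ghk_reversal(c(K = 1), inside, outside, tc),
                 nernst_potential(1, k_out, k_in, tc)$value,
                 tolerance = 1e-9)
    expect_equal(ghk_reversal(c(H = 1), inside, outside, tc),
                 nernst_potential(1, 10^(-ph_out), 10^(-ph_in), tc)$value,
                 tolerance = 1e-9)
  }
})

test_that("GHK reversal is bounded by the extreme single-ion potentials", {
  set.seed(7)
  for (i in 1:40) {
    inside <- solution_composition("in",
      c(K = runif(1, 1, 400), Na = runif(1, 1, 400),
        Cl = runif(1, 1, 400)), pH = runif(1, 6, 8))
    outside <- solution_composition("out",
      c(K = runif(1, 1, 400), Na = runif(1, 1, 400),
        Cl = runif(1, 1, 400)), pH = runif(1, 6, 8))
    perms <- abs(rnorm(4)) + 1e-3
    names(perms) <- c("H", "K", "Na", "Cl")
    singles <- c(
      nernst_potential(1, 10^(-outside$pH), 10^(-inside$pH), 20)$value,
      nernst_potential(1, ion_concentration(outside, "K"),
                       ion_concentration(inside, "K"), 20)$value,
      nernst_potential(1, ion_concentration(outside, "Na"),
                       ion_concentration(inside, "Na"), 20)$value,
      nernst_potential(-1, ion_concentration(outside, "Cl"),
                       ion_concentration(inside, "Cl"), 20)$value)
    v <- ghk_reversal(perms, inside, outside, 20)
    expect_gte(v, min(singles) - 1e-9)
    expect_lte(v, max(singles) + 1e-9)
  }
})

test_that("minimum selectivity ratio matches the grid-search oracle", {
  sol <- solution_registry()
  r10 <- min_selectivity_ratio(sol$P1a, sol$E1, "K", tolerance_mv = 10)
  expect_equal(log10(r10), log10(oracle_min_ratio(200, 8, 7.5, 8.0, 10)),
               tolerance = 0.01)
  expect_equal(r10, 1e7, tolerance = 0.2)
  r35 <- min_selectivity_ratio(sol$P1a, sol$E1, "K", tolerance_mv = 35.4)
  expect_equal(log10(r35), log10(oracle_min_ratio(200, 8, 7.5, 8.0, 35.4)),
               tolerance = 0.01)
  expect_equal(r35, 1e6, tolerance = 0.2)
  expect_error(min_selectivity_ratio(sol$P1a, sol$E1, "K", 0),
               class = "hvchan_domain_error")
})

test_that("minimum selectivity ratio is monotone non-increasing in tolerance", {
  sol <- solution_registry()
  tols <- c(2, 5, 10, 20, 35)
  ratios <- vapply(tols, function(tol)
    min_selectivity_ratio(sol$P1a, sol$E1, "K", tol), numeric(1))
  expect_true(all(diff(ratios) <= 0))
})

test_that("acid-load arithmetic converts flux and buffering to pH/min", {
  est <- acid_load_rate(2.5e-17, 5e-13, 0.01)
  expect_equal(est$rate_ph_min, 0.30, tolerance = 1e-12)
  expect_equal(acid_load_rate(0, 5e-13, 0.01)$rate_ph_min, 0)
  # doubling the buffer capacity halves the rate
  expect_equal(acid_load_rate(2.5e-17, 5e-13, 0.02)$rate_ph_min,
               est$rate_ph_min / 2)
  expect_error(acid_load_rate(1e-17, 0, 0.01), class = "hvchan_domain_error")
  expect_error(acid_load_rate(1e-17, 1e-13, 0), class = "hvchan_domain_error")
})

test_that("current-to-flux conversion uses the Faraday constant", {
  expect_equal(current_to_proton_flux(96.485), 1e-15, tolerance = 1e-4)
  expect_equal(current_to_proton_flux(0), 0)
  expect_equal(current_to_proton_flux(-10), -1.0364e-16, tolerance = 1e-4)
  expect_equal(current_to_proton_flux(1), 1.0364e-17, tolerance = 1e-4)
})

test_that("solution registry carries the recording solutions", {
  sol <- solution_registry()
  expect_true(all(c("E1", "E3", "E4", "E5", "P1a", "P1b", "P2", "P3",
                    "P4") %in% names(sol)))
  expect_equal(sol$E1$pH, 8.0)
  expect_equal(ion_concentration(sol$E1, "Na"), 452)
  expect_equal(ion_concentration(sol$P1a, "K"), 200)
  # H+ is always derived from pH, never stored
  expect_equal(h_concentration_mM(sol$E1), 1e-8 * 1000)
  expect_error(solution_composition("x", c(Xe = 1), 7),
               class = "hvchan_domain_error")
  expect_error(solution_composition("x", c(K = -5), 7),
               class = "hvchan_domain_error")
})
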