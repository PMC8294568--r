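test_that("published constants pass through as effective rates", {
  expect_equal(effective_rate(0.091), 0.091)
  expect_equal(effective_rate(0.0019), 0.0019)
  expect_equal(effective_rate(0), 0)
  expect_error(effective_rate(-1), "non-negative")
  geo <- colon_geometry(volume_L = 2, surface_cm2 = 2000)
  expect_equal(effective_rate(0.091, "surface_scaled", geo), 0.091 * 1000)
  expect_equal(effective_rate(0.091, "surface_scaled", geo,
                              unit_conversion = 1e-3), 0.091)
})

test_that("the luminal concentration solves the production-absorption ODE", {
  expect_equal(luminal_concentration(7, phi = 1.3, k = 0), 1.3 * 7)
  expect_equal(luminal_concentration(3, phi = 0.5, k = 0, c0 = 2),
               2 + 1.5)
  # steady state phi / k as t grows
  expect_equal(luminal_concentration(1e4, phi = 2, k = 0.5), 4)
  expect_error(luminal_concentration(-1, 1, 1), "negative time")
  # closed form matches RK4 integration, including the small-k branch
  for (k in c(0.091, 0.0019, 1e-10, 2)) {
    ode <- integrate_absorption_ode(function(t) 1, k, tau = 12)
    expect_equal(luminal_concentration(12, 1, k), unname(ode["C"]),
                 tolerance = 1e-8)
  }
})

test_that("the transit mass balance splits production into absorbed and excreted", {
  o0 <- absorption_outcome(phi = 1, k = 0, tau = 12)
  expect_equal(o0$absorbed_mmol, 0)
  expect_equal(o0$excreted_mmol, o0$produced_mmol)

  caco <- absorption_outcome(phi = 1, k = 0.091, tau = 12)
  expect_equal(caco$fraction_absorbed,
               1 - (1 - exp(-0.091 * 12)) / (0.091 * 12), tolerance = 1e-12)
  expect_equal(caco$fraction_absorbed, 0.3915, tolerance = 1e-3)
  dial <- absorption_outcome(phi = 1, k = 0.0019, tau = 12)
  expect_equal(dial$fraction_absorbed, 0.0113, tolerance = 1e-2)
  expect_gt(dial$excreted_mmol / dial$produced_mmol, 0.5)

  # absorbed integral agrees with the RK4 oracle
  for (k in c(0.091, 0.0019, 3)) {
    o <- absorption_outcome(phi = 1.7, k = k, tau = 12, c0 = 0.4,
                            volume_L = 1)
    ode <- integrate_absorption_ode(function(t) 1.7, k, 12, c0 = 0.4)
    expect_equal(o$absorbed_mmol, unname(ode["A"]), tolerance = 1e-8)
    expect_equal(o$excreted_mmol, unname(ode["C"]), tolerance = 1e-8)
  }
  expect_error(absorption_outcome(1, 0.1, tau = 0), "tau")
})

test_that("mass is conserved over random parameter draws", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      phi <- runif(1, 0, 5); k <- runif(1, 0, 2); tau <- runif(1, 0.5, 48)
      c0 <- runif(1, 0, 10); v <- runif(1, 0.5, 3)
      o <- absorption_outcome(phi, k, tau, c0, v)
      lhs <- o$produced_mmol + v * c0
      rhs <- o$absorbed_mmol + o$excreted_mmol
      expect_lt(abs(lhs - rhs), 1e-9 * max(lhs, 1e-12))
    }
  })
})

test_that("the absorbed fraction increases from 0 to 1 with k*tau", {
  ktau <- 10^seq(-6, 3, length.out = 40)
  frac <- vapply(ktau, function(kt)
    absorption_outcome(1, kt / 12, 12)$fraction_absorbed, 0)
  expect_true(all(diff(frac) > 0))
  expect_lt(frac[1L], 1e-5)
  expect_gt(frac[length(frac)], 0.99)
})

test_that("the phase diagram is monotone and exactly linear in phi", {
  k_grid <- c(0.002, 0.02, 0.09, 0.3)
  tau_grid <- c(6, 12, 24, 48)
  pd <- phase_diagram(1.2, k_grid, tau_grid)
  expect_equal(pd[2L, 3L],
               absorption_outcome(1.2, k_grid[2L], tau_grid[3L])$absorbed_mmol)
  expect_equal(dim(phase_diagram(1, 0.1, 12)), c(1L, 1L))
  expect_true(all(apply(pd, 1L, diff) > 0))   # rows increase with tau
  expect_true(all(apply(pd, 2L, diff) > 0))   # columns increase with k
  expect_equal(phase_diagram(2.4, k_grid, tau_grid), 2 * pd,
               tolerance = 1e-12)
  expect_error(phase_diagram(1, numeric(0), tau_grid), "empty grid")
  expect_error(phase_diagram(1, c(0.2, 0.1), tau_grid), "increasing")
  expect_error(phase_diagram(1, c(-0.1, 0.2), tau_grid), "positive")
})

test_that("the two-phase model reduces to single phase and tracks the oracle", {
  single <- absorption_outcome(1, 0.2, tau = 12)
  expect_equal(two_phase_outcome(1, 0.2, t1 = 12, tau = 12), single)
  expect_equal(two_phase_outcome(1, 0.2, t1 = 20, tau = 12), single)

  plateau <- two_phase_outcome(1, k = 0, t1 = 6, tau = 12, volume_L = 1)
  expect_equal(plateau$luminal_mM, 6)   # phi * t1, then nothing happens
  expect_equal(plateau$absorbed_mmol, 0)

  # piecewise oracle: integrate each smooth phase separately
  o <- two_phase_outcome(1, 0.2, t1 = 6, tau = 12, volume_L = 1)
  ph1 <- integrate_absorption_ode(function(t) 1, 0.2, tau = 6)
  ph2 <- integrate_absorption_ode(function(t) 0, 0.2, tau = 6,
                                  c0 = unname(ph1["C"]))
  expect_equal(o$absorbed_mmol, unname(ph1["A"] + ph2["A"]),
               tolerance = 1e-8)
  expect_equal(o$excreted_mmol, unname(ph2["C"]), tolerance = 1e-8)

  # excreted concentration is non-increasing in the decay interval tau - t1
  taus <- seq(6, 30, by = 2)
  ex <- vapply(taus, function(tt)
    two_phase_outcome(1, 0.2, t1 = 6, tau = tt)$luminal_mM, 0)
  expect_true(all(diff(ex) <= 1e-12))
  expect_error(two_phase_outcome(1, 0.2, t1 = 0, tau = 12), "t1")
})

test_that("cohort absorption predictions scale linearly with production", {
  m <- matrix(c(2, 1, 0, 1.4, 0.6, 0.2, 0.8, 0.4, 0.1, 1, 0.5, 0.3,
                0.6, 0.3, 0, 0.2, 0.1, 0.05), nrow = 3,
              dimnames = list(c("Da", "Db", "Dc"),
                              c("inulin:acetate", "inulin:propionate",
                                "inulin:butyrate", "pectin:acetate",
                                "pectin:propionate", "pectin:butyrate")))
  attr(m, "scale") <- "raw"
  pred <- predict_cohort_absorption(m, k = 0.0019, tau = 12)
  ia <- pred[pred$fiber == "inulin" & pred$scfa == "acetate", ]
  expect_equal(ia$absorbed_mmol[ia$donor == "Da"],
               2 * ia$absorbed_mmol[ia$donor == "Db"], tolerance = 1e-12)
  expect_equal(ia$absorbed_mmol[ia$donor == "Dc"], 0)
  # donor ranking is invariant to swapping the absorption constant
  pred_caco <- predict_cohort_absorption(m, k = 0.091, tau = 12)
  expect_equal(order(pred$absorbed_mmol), order(pred_caco$absorbed_mmol))
  expect_error(predict_cohort_absorption(zscore_columns(m), k = 0.1),
               "z-scored")
})
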