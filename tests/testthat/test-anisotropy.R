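resp01 <- response_model(0.1)

test_that("simulated curves are zero without titrant, monotone and bounded", {
  sched <- seq(0, 2e-6, length.out = 20)
  expect_equal(simulate_curve(1e-7, 1e-8, rep(0, 5), resp01),
               rep(0, 5))
  for (k in 10^seq(-9, -6, by = 1)) {
    dr <- simulate_curve(k, 1e-8, sched, resp01)
    expect_true(all(diff(dr) >= -1e-15))
    expect_true(all(dr <= 0.1 + 1e-12))
    expect_true(all(dr >= 0))
  }
})

test_that("analytic and speciation engines agree", {
  sched <- seq(0, 2e-6, length.out = 15)
  for (k in c(1e-8, 9.9e-8, 1e-6)) {
    a <- simulate_curve(k, 1e-8, sched, resp01)
    b <- simulate_curve(k, 1e-8, sched, resp01, engine = "speciation")
    expect_equal(a, b, tolerance = 1e-7)
  }
  # stoichiometric regime too
  sched2 <- seq(0, 30e-6, length.out = 10)
  a <- simulate_curve(1.5e-7, 2.5e-6, sched2, resp01)
  b <- simulate_curve(1.5e-7, 2.5e-6, sched2, resp01,
                      engine = "speciation")
  expect_equal(a, b, tolerance = 1e-7)
})

test_that("half-saturation of the probe gives half the maximal response", {
  # find the monomer total giving 50% site occupancy at trace probe,
  # independently of the response layer, then check the curve there
  k <- 9.9e-8
  probe <- 1e-8
  f <- function(m) {
    sol <- solve_speciation(build_two_tetramer_scheme(k, probe, m),
                            rel_tol = 1e-12)
    occ <- (sol$complexed[["TD"]] + 2 * sol$complexed[["T2D"]]) /
      (2 * probe)
    occ - 0.5
  }
  m_half <- uniroot(f, c(1e-9, 1e-5), tol = 1e-16)$root
  dr <- simulate_curve(k, probe, m_half, resp01)
  expect_equal(dr, 0.5 * 0.1, tolerance = 1e-6)
})

test_that("noise-free K recovery across the affinity grid", {
  sched <- seq(0, 2e-6, length.out = 20)
  for (k in 10^seq(-9, -6, by = 0.5)) {
    dr <- simulate_curve(k, 1e-8, sched, resp01)
    td <- titration_data(1e-8, sched, dr)
    fit <- fit_kdna(td)
    expect_lt(abs(fit$k_dna_hat - k) / k, 1e-4)
    expect_true(fit$converged)
  }
})

test_that("refitting from the fitted optimum is idempotent", {
  sched <- seq(0, 2e-6, length.out = 20)
  td <- gen_titration(9.9e-8, 1e-8, sched, resp01,
                      noise_spec(0.005, 7L, 1))[[1]]
  f1 <- fit_kdna(td)
  cfg <- fit_config(n_starts = 1L,
                    k_bounds = c(f1$k_dna_hat * 0.999,
                                 f1$k_dna_hat * 1.001))
  f2 <- fit_kdna(td, cfg)
  expect_equal(f2$k_dna_hat, f1$k_dna_hat, tolerance = 1e-3)
})

test_that("non-saturating designs are reported as lower bounds", {
  sched <- seq(0, 2e-6, length.out = 20)  # max tetramer 5e-7
  # K far above the accessible tetramer range: only a bound is
  # identifiable (the ">=" convention for Ni(II)/Co(II) entries)
  dr <- simulate_curve(5.9e-6, 1e-8, sched, resp01)
  td <- titration_data(1e-8, sched, dr)
  fit <- fit_kdna(td, fit_config(delta_r_max_fixed = 0.1))
  expect_true(fit$is_lower_bound)
  expect_lt(fit$saturation_at_max, 0.8)

  # saturating design is not flagged
  dr2 <- simulate_curve(9.9e-8, 1e-8, sched, resp01)
  fit2 <- fit_kdna(titration_data(1e-8, sched, dr2))
  expect_false(fit2$is_lower_bound)
})

test_that("flat titrations return the detection limit, not an error", {
  sched <- seq(0, 4e-5, length.out = 20)  # max tetramer 1e-5
  td <- titration_data(1e-8, sched, rep(0, 20))
  fit <- fit_kdna(td, fit_config(delta_r_max_fixed = 0.1))
  expect_true(fit$is_lower_bound)
  # reported as K > 1e-5 M given this titration range
  expect_equal(fit$k_dna_hat, 1e-5)
  expect_identical(fit$saturation_at_max, 0)
})

test_that("replicate lists are summarised as mean +/- SD", {
  sched <- seq(0, 2e-6, length.out = 20)
  reps <- gen_titration(1.5e-7, 1e-8, sched, resp01,
                        noise_spec(0.004, 11L, 3))
  fit <- fit_kdna(reps)
  expect_length(fit$replicates, 3L)
  ks <- vapply(fit$replicates, `[[`, numeric(1), "k_dna_hat")
  expect_equal(fit$k_mean, mean(ks))
  expect_equal(fit$k_sd, sd(ks))
  expect_lt(abs(log10(fit$k_mean / 1.5e-7)), 0.1)
  # joint pooled fit also recovers K
  fitj <- fit_kdna(reps, joint = TRUE)
  expect_lt(abs(log10(fitj$k_dna_hat / 1.5e-7)), 0.1)
})

test_that("fit validates its inputs", {
  expect_error(titration_data(1e-8, seq(0, 1e-6, length.out = 4),
                              rep(0, 4)),
               "at least 5 points")
  expect_error(titration_data(0, seq(0, 1e-6, length.out = 5),
                              rep(0, 5)),
               "probe_total")
  expect_error(titration_data(1e-8, rep(1e-7, 5), rep(0, 5)),
               "strictly")
  expect_error(response_model(0.1, c(TD = 0.5, T2D = 0.7)),
               "weight 1")
  expect_error(fit_config(k_bounds = c(1e-3, 1e-12)), "ordered")
})

test_that("stoichiometric breakpoint reflects two tetramers of four monomers", {
  sched <- seq(0, 30e-6, length.out = 20)
  # effectively infinitely tight binding: ideal piecewise-linear curve
  dr <- simulate_curve(1e-12, 2.5e-6, sched, resp01)
  bp <- stoichiometry_breakpoint(titration_data(2.5e-6, sched, dr))
  expect_equal(bp$equivalents, 8, tolerance = 0.02)

  # apo-RcnR affinity, stoichiometric probe: ~8 monomer eq
  dr2 <- simulate_curve(1.5e-7, 2.5e-6, sched, resp01)
  bp2 <- stoichiometry_breakpoint(titration_data(2.5e-6, sched, dr2))
  expect_equal(bp2$equivalents, 8, tolerance = 0.5 / 8)

  # a single-tetramer (one-site) scheme saturates at 4 eq
  occ1 <- vapply(sched / 4, function(tet)
    closed_form_single_site(1e-12, tet, 2.5e-6) / 2.5e-6, numeric(1))
  bp1 <- stoichiometry_breakpoint(
    titration_data(2.5e-6, sched, 0.1 * occ1))
  expect_equal(bp1$equivalents, 4, tolerance = 0.02)
})

test_that("breakpoint demands a plateau", {
  sched <- seq(0, 10e-6, length.out = 20)  # stops mid-rise
  dr <- simulate_curve(1.5e-7, 2.5e-6, sched, resp01)
  expect_error(
    stoichiometry_breakpoint(titration_data(2.5e-6, sched, dr)),
    "no plateau")
})

test_that("fold change divides constants and propagates bound flags", {
  expect_equal(fold_change(1.5e-7, 1.5e-7)$fold, 1)
  expect_equal(fold_change(1.5e-5, 1.5e-7)$fold, 100)
  expect_equal(fold_change(5.9e-6, 1.5e-7)$fold, 39.33, tolerance = 1e-3)
  expect_false(fold_change(1e-6, 1e-7)$is_lower_bound)
  expect_true(fold_change(1e-6, 1e-7,
                          apparent_is_bound = TRUE)$is_lower_bound)
  expect_error(fold_change(0, 1e-7), "must be > 0")
})
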