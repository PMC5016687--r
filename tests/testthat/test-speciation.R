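test_that("empty system: all-zero totals give zero concentrations", {
  s <- binding_scheme(
    list(component("P", 0), component("D", 0)),
    list(complex_species("PD", c(P = 1, D = 1), 1e-7))
  )
  sol <- solve_speciation(s)
  expect_identical(unname(sol$free), c(0, 0))
  expect_identical(unname(sol$complexed), 0)
  expect_identical(sol$residual, 0)
})

test_that("1:1 binding matches the closed-form quadratic", {
  # frozen single case first (oracle value computed from the quadratic)
  s <- binding_scheme(
    list(component("P", 1e-7), component("D", 1e-8)),
    list(complex_species("PD", c(P = 1, D = 1), 1e-7))
  )
  sol <- solve_speciation(s, rel_tol = 1e-12)
  expect_equal(sol$complexed[["PD"]], 4.8750780275e-09, tolerance = 1e-9)

  # grid over K and totals: solver == quadratic to 1e-9 relative
  for (k in 10^c(-9, -7, -5)) {
    for (p in 10^c(-8, -7, -6)) {
      for (d in 10^c(-9, -8, -7)) {
        s <- binding_scheme(
          list(component("P", p), component("D", d)),
          list(complex_species("PD", c(P = 1, D = 1), k))
        )
        sol <- solve_speciation(s, rel_tol = 1e-12)
        expect_equal(sol$complexed[["PD"]],
                     closed_form_single_site(k, p, d),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("closed-form single site handles its limiting cases", {
  expect_identical(closed_form_single_site(1e-7, 0, 1e-8), 0)
  # at trace ligand and p_tot = K, the bound fraction of D is 1/2
  d <- 1e-15
  expect_equal(closed_form_single_site(1e-7, 1e-7, d) / d, 0.5,
               tolerance = 1e-6)
  expect_equal(closed_form_single_site(1e-7, 1e-7, 1e-8), 4.875078e-9,
               tolerance = 1e-6)
  expect_error(closed_form_single_site(-1, 1e-7, 1e-8), "k must be")
})

test_that("two-site scheme matches the fixed-point oracle", {
  oracle <- two_site_oracle(1e-7, 1e-7, 1e-7, 1e-8)
  s <- binding_scheme(
    list(component("T", 1e-7), component("D", 1e-8)),
    list(complex_species("TD", c(T = 1, D = 1), 1e-7),
         complex_species("T2D", c(T = 2, D = 1), 1e-14))
  )
  sol <- solve_speciation(s, rel_tol = 1e-12)
  expect_equal(sol$free[["T"]], oracle$free_t, tolerance = 1e-6)
  expect_equal(sol$complexed[["TD"]], oracle$TD, tolerance = 1e-6)
  expect_equal(sol$complexed[["T2D"]], oracle$T2D, tolerance = 1e-6)
  # frozen values from the iterated oracle
  expect_equal(sol$free[["T"]], 9.06531490074e-08, tolerance = 1e-9)
  expect_equal(sol$complexed[["TD"]], 3.32265969820e-09,
               tolerance = 1e-9)
  expect_equal(sol$complexed[["T2D"]], 3.01209564722e-09,
               tolerance = 1e-9)
})

test_that("mass conservation and non-negativity hold on random schemes", {
  set.seed(42)
  for (i in 1:60) {
    s <- random_scheme()
    sol <- solve_speciation(s)
    expect_true(all(sol$free >= 0))
    expect_true(all(sol$complexed >= 0))
    expect_lte(mass_balance_residual(s, sol), 1e-9)
  }
})

test_that("bound probe is non-decreasing in titrant total", {
  resp <- response_model(1)
  for (k in c(1e-8, 9.9e-8, 1.5e-6)) {
    mono <- seq(0, 4e-6, length.out = 40)
    bound <- vapply(mono, function(m) {
      sol <- solve_speciation(build_two_tetramer_scheme(k, 1e-8, m))
      sol$complexed[["TD"]] + sol$complexed[["T2D"]]
    }, numeric(1))
    expect_true(all(diff(bound) >= -1e-15))
  }
})

test_that("dilution limit: trace probe reproduces the free-titrant closed form", {
  k <- 1e-7
  mono <- 6e-7  # tetramer 1.5e-7
  tet <- mono / 4
  sol <- solve_speciation(build_two_tetramer_scheme(k, 1e-13, mono),
                          rel_tol = 1e-12)
  frac_unbound <- sol$free[["D"]] / 1e-13
  # with free T ~ total T: [D]/Dtot = 1/(1 + T/K + (T/K)^2)
  expect_equal(frac_unbound, 1 / (1 + tet / k + (tet / k)^2),
               tolerance = 1e-4)
})

test_that("validation errors are explicit", {
  expect_error(component("P", -1), "total must be")
  expect_error(component("P", NaN), "total must be")
  expect_error(complex_species("X", c(P = 1), 1e-7), ">= 2")
  expect_error(complex_species("X", c(P = 1, D = 1), -1), "k_overall")
  expect_error(
    binding_scheme(list(component("P", 1e-7)),
                   list(complex_species("PD", c(P = 1, D = 1), 1e-7))),
    "undeclared"
  )
  expect_error(
    binding_scheme(list(component("P", 1e-7), component("P", 1e-8))),
    "unique"
  )
  s <- binding_scheme(list(component("P", 1e-7)))
  expect_error(solve_speciation(s, rel_tol = 1), "rel_tol")
})

test_that("two-tetramer scheme builder encodes equal stepwise affinity", {
  s <- build_two_tetramer_scheme(9.9e-8, 1e-8, 4e-7)
  tet <- s$components[[which(vapply(s$components, `[[`, character(1),
                                    "name") == "T")]]
  expect_equal(tet$total, 1e-7)
  ks <- vapply(s$complexes, `[[`, numeric(1), "k_overall")
  names(ks) <- vapply(s$complexes, `[[`, character(1), "name")
  expect_equal(ks[["TD"]], 9.9e-8)
  expect_equal(ks[["T2D"]], 9.801e-15)  # k_dna^2
  # zero titrant is a valid scheme
  s0 <- build_two_tetramer_scheme(9.9e-8, 1e-8, 0)
  expect_equal(s0$components[[1]]$total, 0)
  expect_s3_class(solve_speciation(s0), "speciation_result")
  # stoichiometric-regime scheme
  expect_s3_class(build_two_tetramer_scheme(1.5e-7, 2.5e-6, 2e-5),
                  "binding_scheme")
  expect_error(build_two_tetramer_scheme(1.5e-7, -1, 0), "totals")
})

test_that("explicit-assembly mode reproduces the preassembled scheme", {
  mono <- 4e-7
  ref <- solve_speciation(build_two_tetramer_scheme(9.9e-8, 1e-8, mono),
                          rel_tol = 1e-12)
  ex <- solve_speciation(
    build_two_tetramer_scheme(9.9e-8, 1e-8, mono,
                              explicit_assembly = TRUE),
    rel_tol = 1e-12)
  # free monomer negligible; assembled pools agree
  expect_lt(ex$free[["M"]], 1e-3 * mono)
  expect_equal(ex$complexed[["TD"]], ref$complexed[["TD"]],
               tolerance = 1e-5)
  expect_equal(ex$complexed[["T2D"]], ref$complexed[["T2D"]],
               tolerance = 1e-5)
})

test_that("scheme YAML round-trip is lossless", {
  s <- build_two_tetramer_scheme(9.9e-8, 1e-8, 4e-7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(s, path)
  s2 <- read_scheme(path)
  expect_equal(s2, s)
  expect_error(read_scheme(withr::local_tempfile()), "no such file")
})
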