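# Shared helpers: independent oracles and generators for property tests.

# fixed-point oracle for the two-site equal/unequal scheme
# T + D <-> TD (K1), T + TD <-> T2D (K2); iterated to 1e-14 relative
two_site_oracle <- function(K1, K2, Ttot, Dtot, tol = 1e-14) {
  t <- Ttot
  d <- Dtot
  for (i in 1:100000) {
    d_new <- Dtot / (1 + t / K1 + t * t / (K1 * K2))
    t_new <- Ttot / (1 + d_new / K1 + 2 * t * d_new / (K1 * K2))
    if (abs(t_new - t) <= tol * t && abs(d_new - d) <= tol * d) {
      t <- t_new; d <- d_new
      break
    }
    t <- t_new; d <- d_new
  }
  list(free_t = t, free_d = d, TD = t * d / K1,
       T2D = t * t * d / (K1 * K2))
}

# random small scheme: 1-3 components, 1-3 complexes referencing them
random_scheme <- function() {
  n_comp <- sample(1:3, 1)
  cn <- LETTERS[seq_len(n_comp)]
  comps <- lapply(cn, function(nm)
    component(nm, 10^stats::runif(1, -9, -5)))
  n_cx <- sample(1:3, 1)
  cxs <- list()
  for (i in seq_len(n_cx)) {
    k_members <- sample(n_comp, sample(n_comp, 1))
    nu <- sample(1:2, length(k_members), replace = TRUE)
    if (sum(nu) < 2) nu[1] <- 2
    k_overall <- 10^(stats::runif(1, -2, 2) - 7 * (sum(nu) - 1))
    cxs[[i]] <- complex_species(paste0("X", i),
                                stats::setNames(nu, cn[k_members]),
                                k_overall)
  }
  binding_scheme(comps, cxs)
}

mass_balance_residual <- function(scheme, sol) {
  totals <- vapply(scheme$components, `[[`, numeric(1), "total")
  names(totals) <- vapply(scheme$components, `[[`, character(1), "name")
  worst <- 0
  for (nm in names(totals)) {
    bound <- 0
    for (cx in scheme$complexes) {
      nu <- cx$composition[nm]
      if (!is.na(nu)) bound <- bound + nu * sol$complexed[[cx$name]]
    }
    rel <- abs(sol$free[[nm]] + bound - totals[[nm]]) /
      max(totals[[nm]], 1e-30)
    worst <- max(worst, rel)
  }
  worst
}
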