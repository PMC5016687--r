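# Speciation of the two-tetramer scheme along a titration schedule.
# Free tetramer t solves the monomial mass balance
#   t + D * (t/K + 2 t^2/K^2) / (1 + t/K + t^2/K^2) = T_tot ,
# monotone increasing in t, bracketed by [0, T_tot]; solved here by
# vectorised bisection (62 halvings ~ machine precision), which is both
# branch-free over the schedule and immune to the stiffness of the
# Newton path at D >> K.  Agreement with the general scheme solver is
# property-tested.
two_site_probe_species <- function(k_dna, probe_total, tetramer_totals) {
  Ttot <- tetramer_totals
  D <- probe_total
  g <- function(t) {
    a <- t / k_dna
    b <- a * a          # t^2/K^2 under equal stepwise affinity
    t + D * (a + 2 * b) / (1 + a + b) - Ttot
  }
  lo <- numeric(length(Ttot))
  hi <- pmax(Ttot, 0)
  for (i in 1:62) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  t <- (lo + hi) / 2
  a <- t / k_dna
  b <- a * a
  den <- 1 + a + b
  d_free <- D / den
  list(free_t = t, free_d = d_free, TD = d_free * a, T2D = d_free * b)
}

#' Simulate an anisotropy-change titration curve
#'
#' Computes the model anisotropy change at each total titrant monomer
#' concentration under the two-nondissociable-tetramer equal-affinity
#' scheme (see [build_two_tetramer_scheme()]):
#' \deqn{\Delta r_i = \Delta r_{max}\,
#'   (w_{TD}[TD]_i + w_{T_2D}[T_2D]_i)/D_{tot}.}
#' With the default weights the normalised signal equals the probe's
#' site occupancy, so half-saturation gives exactly
#' `0.5 * delta_r_max`.
#'
#' @param k_dna Stepwise tetramer-DNA dissociation constant (M).
#' @param probe_total Probe total (M, > 0).
#' @param titrant_monomer_totals Vector of total monomer concentrations
#'   (M, >= 0).
#' @param response A [response_model()].
#' @param engine `"analytic"` (vectorised reduction of the two-site
#'   balance, the default) or `"speciation"` (general scheme solver at
#'   every point); the two agree to solver tolerance.
#' @return Numeric vector of model anisotropy changes (non-decreasing,
#'   bounded by `delta_r_max`).
#' @examples
#' r <- response_model(0.1)
#' simulate_curve(9.9e-8, 1e-8, seq(0, 2e-6, length.out = 10), r)
#' @export
simulate_curve <- function(k_dna, probe_total, titrant_monomer_totals,
                           response,
                           engine = c("analytic", "speciation")) {
  engine <- match.arg(engine)
  stopifnot(inherits(response, "response_model"))
  if (!is.numeric(k_dna) || k_dna <= 0) {
    stop("k_dna must be > 0", call. = FALSE)
  }
  if (probe_total <= 0) stop("probe_total must be > 0", call. = FALSE)
  mono <- as.numeric(titrant_monomer_totals)
  if (any(mono < 0) || any(!is.finite(mono))) {
    stop("titrant totals must be finite and >= 0", call. = FALSE)
  }
  w <- response$weights
  w_td <- if ("TD" %in% names(w)) w[["TD"]] else 0.5
  w_t2d <- if ("T2D" %in% names(w)) w[["T2D"]] else 1.0
  if (engine == "analytic") {
    sp <- two_site_probe_species(k_dna, probe_total, mono / 4)
    dr <- response$delta_r_max *
      (w_td * sp$TD + w_t2d * sp$T2D) / probe_total
  } else {
    dr <- vapply(seq_along(mono), function(i) {
      sch <- build_two_tetramer_scheme(k_dna, probe_total, mono[i])
      sol <- tryCatch(solve_speciation(sch),
                      error = function(e)
                        stop("speciation failed at point ", i, ": ",
                             conditionMessage(e), call. = FALSE))
      response$delta_r_max *
        (w_td * sol$complexed[["TD"]] + w_t2d * sol$complexed[["T2D"]]) /
        probe_total
    }, numeric(1))
  }
  unname(dr)
}

#' Fit K_DNA to one or more anisotropy titrations
#'
#' Least-squares fit of the two-nondissociable-tetramer equal-affinity
#' model to observed anisotropy changes, minimising
#' `sum((delta_r_obs - delta_r_model)^2)` over `log10 K_DNA` (and
#' `delta_r_max` unless fixed) by Levenberg-Marquardt with log-spaced
#' multistart initialisations; the best local optimum is reported.
#'
#' The fitted K is flagged as a lower bound (the "\eqn{\ge}" reporting
#' convention) when the model saturation fraction at the final titration
#' point falls below `config$saturation_threshold`, or when the
#' estimate presses against the upper K bound.  Titrations showing no
#' detectable signal (all `|delta_r|` below `config$noise_floor`) are
#' not an error: the K is reported at the detection limit of the design
#' - the largest tetramer concentration reached - with the lower-bound
#' flag set.
#'
#' A list of [titration_data()] replicates is fit independently and
#' summarised as mean +/- SD of K (set `joint = TRUE` for a pooled fit
#' with shared parameters).
#'
#' @param data A [titration_data()] or a list of them.
#' @param config A [fit_config()].
#' @param joint Pool replicates into a single fit with shared K and
#'   amplitude (default `FALSE`: independent fits, then summarise).
#' @return Object of class `"fit_result"` with elements `k_dna_hat`,
#'   `delta_r_max_hat`, `sse`, `converged`, `is_lower_bound`,
#'   `saturation_at_max`, and for replicate input also `k_mean`, `k_sd`
#'   and `replicates` (per-replicate fit results).
#' @export
fit_kdna <- function(data, config = fit_config(), joint = FALSE) {
  stopifnot(inherits(config, "fit_config"))
  if (inherits(data, "titration_data")) {
    return(fit_kdna_single(list(data), config))
  }
  if (!is.list(data) || !all(vapply(data, inherits, logical(1),
                                    "titration_data"))) {
    stop("data must be a titration_data or a list of them", call. = FALSE)
  }
  if (length(data) == 1L || joint) {
    return(fit_kdna_single(data, config))
  }
  fits <- lapply(data, function(d) fit_kdna_single(list(d), config))
  ks <- vapply(fits, `[[`, numeric(1), "k_dna_hat")
  any_bound <- any(vapply(fits, `[[`, logical(1), "is_lower_bound"))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  structure(list(k_dna_hat = mean(ks),
                 k_mean = mean(ks),
                 k_sd = stats::sd(ks),
                 delta_r_max_hat = mean(vapply(fits, `[[`, numeric(1),
                                               "delta_r_max_hat")),
                 sse = sum(vapply(fits, `[[`, numeric(1), "sse")),
                 converged = all(vapply(fits, `[[`, logical(1),
                                        "converged")),
                 is_lower_bound = any_bound,
                 saturation_at_max = best$saturation_at_max,
                 replicates = fits),
            class = "fit_result")
}

# one fit over pooled points of >= 1 titrations sharing parameters
fit_kdna_single <- function(datasets, config) {
  n_pts <- sum(vapply(datasets, function(d) length(d$delta_r), integer(1)))
  if (n_pts < 5L) {
    stop("at least 5 titration points are required to fit K_DNA",
         call. = FALSE)
  }
  obs <- unlist(lapply(datasets, `[[`, "delta_r"))
  lb <- config$k_bounds[1]
  ub <- config$k_bounds[2]

  # no-binding call: flat signal over the whole range
  if (max(abs(obs)) < config$noise_floor) {
    det_lim <- max(vapply(datasets, function(d)
      max(d$titrant_monomer_M) / 4, numeric(1)))
    det_lim <- min(max(det_lim, lb), ub)
    drm <- config$delta_r_max_fixed %||% NA_real_
    return(structure(list(k_dna_hat = det_lim,
                          delta_r_max_hat = drm, sse = sum(obs^2),
                          converged = TRUE, is_lower_bound = TRUE,
                          saturation_at_max = 0),
                     class = "fit_result"))
  }

  fit_drm <- "delta_r_max" %in% config$free &&
    is.null(config$delta_r_max_fixed)
  drm_fixed <- config$delta_r_max_fixed %||% NA_real_
  drm_init <- if (fit_drm) max(obs) else drm_fixed

  model_resid <- function(par) {
    k <- 10^par[[1]]
    drm <- if (fit_drm) par[[2]] else drm_fixed
    resp <- response_model(max(drm, 1e-12))
    pred <- unlist(lapply(datasets, function(d)
      simulate_curve(k, d$probe_total, d$titrant_monomer_M, resp)))
    obs - pred
  }

  starts <- 10^seq(log10(lb), log10(ub),
                   length.out = max(config$n_starts, 1L))
  lower <- c(log10(lb), if (fit_drm) 1e-6)
  upper <- c(log10(ub), if (fit_drm) Inf)

  best <- NULL
  for (k0 in starts) {
    par0 <- c(log10(k0), if (fit_drm) drm_init)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = model_resid,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-300 ||
        (sse <= best$sse && fit$par[[1]] < best$par[[1]])) {
      best <- list(par = fit$par, sse = sse,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    stop("all multistart fits failed; check the titration data",
         call. = FALSE)
  }
  k_hat <- 10^best$par[[1]]
  drm_hat <- if (fit_drm) best$par[[2]] else drm_fixed
  resp <- response_model(drm_hat)
  sat <- max(vapply(datasets, function(d) {
    pred <- simulate_curve(k_hat, d$probe_total,
                           max(d$titrant_monomer_M), resp)
    pred / drm_hat
  }, numeric(1)))
  at_ub <- k_hat >= 0.95 * ub
  structure(list(k_dna_hat = k_hat, delta_r_max_hat = drm_hat,
                 sse = best$sse, converged = best$converged,
                 is_lower_bound = sat < config$saturation_threshold ||
                   at_ub,
                 saturation_at_max = sat),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  tag <- if (isTRUE(x$is_lower_bound)) ">= " else ""
  cat(sprintf("K_DNA %s%.4g M (delta_r_max %.4g, sse %.4g)\n",
              tag, x$k_dna_hat, x$delta_r_max_hat, x$sse))
  if (!is.null(x$k_sd)) {
    cat(sprintf("  replicates: n = %d, K = %.4g +/- %.4g M\n",
                length(x$replicates), x$k_mean, x$k_sd))
  }
  cat(sprintf("  saturation at final point: %.1f%%%s\n",
              100 * x$saturation_at_max,
              if (isTRUE(x$is_lower_bound))
                "  [reported as a lower bound]" else ""))
  invisible(x)
}

#' Stoichiometric breakpoint of a saturating titration
#'
#' For a titration performed at probe concentrations far above K
#' (stoichiometric regime) the curve rises almost linearly and then
#' plateaus; the intersection of the least-squares line through the
#' rising phase with the plateau level gives the binding stoichiometry
#' in titrant monomer equivalents per DNA.  Two tetramers of four
#' monomers give 8 equivalents.
#'
#' @param data A [titration_data()], or a list with elements
#'   `titrant_monomer_M`, `delta_r` plus `probe_total` given separately.
#' @param probe_total Probe total (M); taken from `data` when it is a
#'   [titration_data()].
#' @param plateau_frac Fraction of trailing points defining the plateau
#'   (default 0.2).
#' @param rising_max_frac Points at or below this fraction of the
#'   plateau level constitute the rising phase (default 0.5).
#' @param noise_floor Maximum spread tolerated across the plateau
#'   points, as a fraction of the plateau level (default 0.05); a larger
#'   spread means the titration has not saturated.
#' @return List with `equivalents` (monomer eq per DNA),
#'   `breakpoint_monomer_M`, `plateau` and `n_rising`.
#' @export
stoichiometry_breakpoint <- function(data, probe_total = NULL,
                                     plateau_frac = 0.2,
                                     rising_max_frac = 0.5,
                                     noise_floor = 0.05) {
  if (inherits(data, "titration_data")) {
    probe_total <- data$probe_total
  }
  if (is.null(probe_total) || probe_total <= 0) {
    stop("probe_total must be supplied and > 0", call. = FALSE)
  }
  x <- data$titrant_monomer_M
  y <- data$delta_r
  n <- length(x)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)

  i_plat <- seq.int(max(1L, n - ceiling(plateau_frac * n) + 1L), n)
  plateau <- mean(y[i_plat])
  if (plateau <= 0 ||
      (max(y[i_plat]) - min(y[i_plat])) > noise_floor * plateau) {
    stop("no plateau detected in the final ",
         round(100 * plateau_frac),
         "% of points; extend the titration to saturation before ",
         "breakpoint analysis", call. = FALSE)
  }
  rising <- which(y <= rising_max_frac * plateau)
  rising <- rising[rising < min(i_plat)]
  if (length(rising) < 2L) {
    stop("fewer than 2 rising-phase points below ",
         rising_max_frac, " x plateau; use a denser schedule",
         call. = FALSE)
  }
  co <- stats::coef(stats::lm(y[rising] ~ x[rising]))
  if (!is.finite(co[[2]]) || co[[2]] <= 0) {
    stop("rising phase has no positive slope", call. = FALSE)
  }
  x_star <- (plateau - co[[1]]) / co[[2]]
  list(equivalents = x_star / probe_total,
       breakpoint_monomer_M = x_star,
       plateau = plateau,
       n_rising = length(rising))
}

#' Fold change between two dissociation constants
#'
#' `k_apparent / k_reference`, the factor by which an effector weakens
#' (ratio > 1) or tightens (ratio < 1) DNA binding.  When either input
#' is only a lower bound the ratio inherits the "\eqn{\ge}" flag.
#'
#' @param k_apparent,k_reference Dissociation constants (M, > 0).
#' @param apparent_is_bound,reference_is_bound Lower-bound flags for
#'   the inputs.
#' @return List with `fold` and `is_lower_bound`.
#' @examples
#' fold_change(1.5e-5, 1.5e-7)$fold  # 100
#' @export
fold_change <- function(k_apparent, k_reference,
                        apparent_is_bound = FALSE,
                        reference_is_bound = FALSE) {
  if (!is.numeric(k_apparent) || k_apparent <= 0 ||
      !is.numeric(k_reference) || k_reference <= 0) {
    stop("both constants must be > 0", call. = FALSE)
  }
  list(fold = k_apparent / k_reference,
       is_lower_bound = isTRUE(apparent_is_bound) ||
         isTRUE(reference_is_bound))
}
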