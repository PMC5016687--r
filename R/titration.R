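#' Construct a titration data set
#'
#' One anisotropy-change titration: a fixed total concentration of
#' fluorescently labelled DNA probe titrated with protein, entered as
#' total *monomer* concentration (the tetramer bookkeeping is handled by
#' the binding scheme).
#'
#' @param probe_total Probe (DNA) total concentration, M, > 0.
#' @param titrant_monomer_M Strictly increasing vector of total titrant
#'   monomer concentrations (M); the first may be 0.  Length >= 5.
#' @param delta_r Observed anisotropy change at each point
#'   (dimensionless, finite).
#' @param replicate_id Replicate label (default `"r1"`).
#' @param effector Effector label (e.g. `"apo"`, `"Ni(II)"`,
#'   `"formaldehyde"`); metadata only.
#' @param effector_concentration_M Effector concentration (M) or `NA`;
#'   metadata only.
#' @return Object of class `"titration_data"`.
#' @export
titration_data <- function(probe_total, titrant_monomer_M, delta_r,
                           replicate_id = "r1", effector = "apo",
                           effector_concentration_M = NA_real_) {
  if (!is.numeric(probe_total) || length(probe_total) != 1L ||
      !is.finite(probe_total) || probe_total <= 0) {
    stop("probe_total must be a finite concentration > 0 (molar)",
         call. = FALSE)
  }
  x <- as.numeric(titrant_monomer_M)
  y <- as.numeric(delta_r)
  if (length(x) != length(y)) {
    stop("titrant_monomer_M and delta_r must have the same length",
         call. = FALSE)
  }
  if (length(x) < 5L) {
    stop("a titration needs at least 5 points", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(diff(x) <= 0)) {
    stop("titrant_monomer_M must be non-negative, finite and strictly ",
         "increasing", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("delta_r must be finite", call. = FALSE)
  structure(list(probe_total = probe_total,
                 titrant_monomer_M = x,
                 delta_r = y,
                 replicate_id = as.character(replicate_id),
                 effector = as.character(effector),
                 effector_concentration_M =
                   as.numeric(effector_concentration_M)),
            class = "titration_data")
}

#' @export
print.titration_data <- function(x, ...) {
  cat(sprintf(
    "Titration: probe %.3g M, %d points, titrant %.3g-%.3g M monomer\n",
    x$probe_total, length(x$delta_r), min(x$titrant_monomer_M),
    max(x$titrant_monomer_M)))
  cat(sprintf("  replicate %s, effector %s%s\n", x$replicate_id,
              x$effector,
              if (is.finite(x$effector_concentration_M))
                sprintf(" (%.3g M)", x$effector_concentration_M) else ""))
  invisible(x)
}

#' Anisotropy response model
#'
#' Maps the speciation of the probe onto the observable anisotropy
#' change: each DNA-bound state contributes a fraction of `delta_r_max`.
#' The default weights (singly bound 0.5, doubly bound 1.0) make the
#' response linear in the number of bound tetramers, the standard molar
#' response convention of mechanism-fitting software, so the normalised
#' signal equals the site occupancy of the probe.
#'
#' @param delta_r_max Anisotropy change at full saturation (> 0).
#' @param weights Named weights in `[0, 1]` per bound state; the fully
#'   bound state must carry weight 1.
#' @return Object of class `"response_model"`.
#' @export
response_model <- function(delta_r_max,
                           weights = c(TD = 0.5, T2D = 1.0)) {
  if (!is.numeric(delta_r_max) || delta_r_max <= 0 ||
      !is.finite(delta_r_max)) {
    stop("delta_r_max must be finite and > 0", call. = FALSE)
  }
  if (is.null(names(weights)) || any(weights < 0) || any(weights > 1)) {
    stop("weights must be named and lie in [0, 1]", call. = FALSE)
  }
  if (abs(max(weights) - 1) > 1e-12) {
    stop("the fully bound state must carry weight 1", call. = FALSE)
  }
  structure(list(delta_r_max = delta_r_max, weights = weights),
            class = "response_model")
}

#' Fit configuration for K_DNA estimation
#'
#' @param free Character vector of free parameters, subset of
#'   `c("k_dna", "delta_r_max")`.  When `delta_r_max_fixed` is supplied
#'   it overrides membership of `"delta_r_max"` here: non-saturating
#'   titrations are fit with the average saturating-experiment maximum
#'   held fixed.
#' @param k_bounds Lower/upper bounds for K_DNA (M), default
#'   `c(1e-12, 1e-3)`.
#' @param n_starts Number of log-spaced K multistart initialisations
#'   (>= 1, default 7).
#' @param delta_r_max_fixed Optional fixed saturation amplitude.
#' @param saturation_threshold Model saturation fraction at the final
#'   titration point below which the fitted K is reported as a lower
#'   bound (default 0.8).
#' @param noise_floor Anisotropy change below which a titration is
#'   treated as showing no detectable binding (default 0.005).
#' @return Object of class `"fit_config"`.
#' @export
fit_config <- function(free = c("k_dna", "delta_r_max"),
                       k_bounds = c(1e-12, 1e-3),
                       n_starts = 7L,
                       delta_r_max_fixed = NULL,
                       saturation_threshold = 0.8,
                       noise_floor = 0.005) {
  free <- match.arg(free, c("k_dna", "delta_r_max"), several.ok = TRUE)
  if (!"k_dna" %in% free) stop("k_dna must be a free parameter",
                               call. = FALSE)
  if (!is.numeric(k_bounds) || length(k_bounds) != 2L ||
      any(k_bounds <= 0) || k_bounds[1] >= k_bounds[2]) {
    stop("k_bounds must be positive and ordered", call. = FALSE)
  }
  if (n_starts < 1L) stop("n_starts must be >= 1", call. = FALSE)
  if (!is.null(delta_r_max_fixed)) {
    if (delta_r_max_fixed <= 0) {
      stop("delta_r_max_fixed must be > 0", call. = FALSE)
    }
    free <- setdiff(free, "delta_r_max")
  }
  structure(list(free = free, k_bounds = as.numeric(k_bounds),
                 n_starts = as.integer(n_starts),
                 delta_r_max_fixed = delta_r_max_fixed,
                 saturation_threshold = saturation_threshold,
                 noise_floor = noise_floor),
            class = "fit_config")
}
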