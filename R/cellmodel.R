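#' Intracellular formaldehyde-partitioning model parameters
#'
#' Parameters of the fractional-occupancy competition between a trace
#' sensor protein and the bulk glutathione pool for formaldehyde inside
#' the cell.  Covalent sensor modification and spontaneous
#' S-(hydroxymethyl)glutathione (S-HMG) formation are both treated as
#' reversible equilibria with effective dissociation constants.
#' Defaults describe anaerobically grown cells: sensor tetramer
#' 1.61e-8 M (9.7 copies at 1 fl), four formaldehyde sites per
#' tetramer, GSH pool 1.2 mM (assumed fully reduced), GSH/S-HMG Kd
#' 1.77e-3 M; the sensor affinity is 1e-5 M for FrmR and 1e-4 M
#' (a tighter limit) for RcnR.
#'
#' @param sensor `"FrmR"` or `"RcnR"` (sets the default `k_sensor`).
#' @param k_sensor Effective sensor-formaldehyde dissociation constant
#'   (M).
#' @param k_gsh GSH/S-HMG dissociation constant (M).
#' @param sensor_tetramer_total Sensor tetramer concentration (M).
#' @param sites_per_tetramer Formaldehyde sites per tetramer (1 or 4).
#' @param gsh_total Total glutathione (M).
#' @param cell_volume Cell volume (L), default 1 fl.
#' @return Object of class `"cell_model_params"`.
#' @export
cell_model_params <- function(sensor = c("FrmR", "RcnR"),
                              k_sensor = NULL,
                              k_gsh = 1.77e-3,
                              sensor_tetramer_total = 1.61e-8,
                              sites_per_tetramer = 4L,
                              gsh_total = 1.2e-3,
                              cell_volume = 1e-15) {
  sensor <- match.arg(sensor)
  if (is.null(k_sensor)) {
    k_sensor <- if (sensor == "FrmR") 1e-5 else 1e-4
  }
  vals <- c(k_sensor = k_sensor, k_gsh = k_gsh,
            sensor_tetramer_total = sensor_tetramer_total,
            gsh_total = gsh_total, cell_volume = cell_volume)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all cell-model parameters must be finite and > 0",
         call. = FALSE)
  }
  if (!sites_per_tetramer %in% c(1L, 4L)) {
    stop("sites_per_tetramer must be 1 or 4", call. = FALSE)
  }
  structure(list(sensor = sensor, k_sensor = k_sensor, k_gsh = k_gsh,
                 sensor_tetramer_total = sensor_tetramer_total,
                 sites_per_tetramer = as.integer(sites_per_tetramer),
                 gsh_total = gsh_total, cell_volume = cell_volume),
            class = "cell_model_params")
}

# scalar mass balance: F + G*F/(kg+F) + S*F/(ks+F) = Ftot, solved for
# free formaldehyde F by bisection-safeguarded uniroot on [0, Ftot]
free_formaldehyde <- function(params, f_total) {
  S <- params$sites_per_tetramer * params$sensor_tetramer_total
  G <- params$gsh_total
  kg <- params$k_gsh
  ks <- params$k_sensor
  vapply(f_total, function(Ftot) {
    if (Ftot == 0) return(0)
    bal <- function(F) {
      F + G * F / (kg + F) + S * F / (ks + F) - Ftot
    }
    stats::uniroot(bal, c(0, Ftot), tol = Ftot * 1e-13)$root
  }, numeric(1))
}

#' Fractional modification of sensor and glutathione by formaldehyde
#'
#' Solves the formaldehyde mass balance
#' \deqn{F_{free} + [S\text{-}HMG] + [sensor \cdot F] = F_{tot}}
#' at each grid point, with the GSH arm
#' `[S-HMG] = gsh_total * F / (k_gsh + F)` and the sensor arm
#' `sites * tetramer_total * F / (k_sensor + F)`, and returns the
#' fractional modification of each pool.  Because the sensor is at
#' trace concentration its arm barely perturbs the balance, but both
#' pools see the same free formaldehyde, which is what sets their
#' relative occupancy.
#'
#' @param params A [cell_model_params()].
#' @param f_total_grid Non-negative, increasing vector of total
#'   formaldehyde concentrations (M).
#' @return Object of class `"modification_curve"`: data frame with
#'   columns `f_total_M`, `f_free_M`, `frac_sensor`, `frac_gsh`.
#' @examples
#' p <- cell_model_params("FrmR")
#' modification_curve(p, c(0, 1e-5, 1e-4))
#' @export
modification_curve <- function(params, f_total_grid) {
  stopifnot(inherits(params, "cell_model_params"))
  g <- as.numeric(f_total_grid)
  if (any(!is.finite(g)) || any(g < 0) || is.unsorted(g)) {
    stop("f_total_grid must be non-negative, finite and increasing",
         call. = FALSE)
  }
  f_free <- free_formaldehyde(params, g)
  out <- data.frame(
    f_total_M = g,
    f_free_M = f_free,
    frac_sensor = f_free / (params$k_sensor + f_free),
    frac_gsh = f_free / (params$k_gsh + f_free)
  )
  structure(out, class = c("modification_curve", "data.frame"),
            params = params)
}

#' Total formaldehyde at a target S-HMG fraction of the GSH pool
#'
#' Inverts the GSH arm of the competition model: the free formaldehyde
#' giving S-HMG fraction `f` is `f/(1-f) * k_gsh` (so `f = 0.5` at
#' `F_free = k_gsh` exactly); the bound pools are then added back to
#' return the corresponding *total* formaldehyde.
#'
#' @param params A [cell_model_params()].
#' @param target_f_gsh Target S-HMG fraction, in (0, 1).
#' @return Total formaldehyde (M).
#' @examples
#' p <- cell_model_params("FrmR")
#' formaldehyde_at_gsh_fraction(p, 0.04)  # ~1.22e-4 M
#' @export
formaldehyde_at_gsh_fraction <- function(params, target_f_gsh) {
  stopifnot(inherits(params, "cell_model_params"))
  if (!is.numeric(target_f_gsh) || target_f_gsh <= 0 ||
      target_f_gsh >= 1) {
    stop("target_f_gsh must lie in (0, 1)", call. = FALSE)
  }
  f_free <- target_f_gsh / (1 - target_f_gsh) * params$k_gsh
  S <- params$sites_per_tetramer * params$sensor_tetramer_total
  f_free + params$gsh_total * target_f_gsh +
    S * f_free / (params$k_sensor + f_free)
}

#' Convert molar concentration to copies per cell (and back)
#'
#' `copies = concentration * cell_volume * N_A` with the Avogadro
#' constant `N_A = 6.02214e23 / mol`.  At the default 1 fl cell volume,
#' 16.1 nM corresponds to ~9.7 copies per cell.
#'
#' @param concentration Concentration (M, >= 0).
#' @param cell_volume Cell volume (L, > 0), default 1 fl.
#' @param copies Copy number (>= 0) for the inverse conversion.
#' @return Copies per cell, or molar concentration for the inverse.
#' @examples
#' copies_per_cell(16.1e-9)        # ~9.7
#' molar_from_copies(9.7)          # ~1.61e-8
#' @export
copies_per_cell <- function(concentration, cell_volume = 1e-15) {
  if (any(concentration < 0) || cell_volume <= 0) {
    stop("concentration must be >= 0 and cell_volume > 0", call. = FALSE)
  }
  concentration * cell_volume * 6.02214e23
}

#' @rdname copies_per_cell
#' @export
molar_from_copies <- function(copies, cell_volume = 1e-15) {
  if (any(copies < 0) || cell_volume <= 0) {
    stop("copies must be >= 0 and cell_volume > 0", call. = FALSE)
  }
  copies / (cell_volume * 6.02214e23)
}
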