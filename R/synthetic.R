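#' Noise specification for synthetic titrations
#'
#' Additive Gaussian noise on the anisotropy change, constant variance
#' across the curve (matching the least-squares assumption of the
#' fitter), with a seed contract: the same seed always reproduces the
#' same datasets.
#'
#' @param sd Noise standard deviation in anisotropy units (>= 0);
#'   conventionally 5 percent of `delta_r_max`.
#' @param seed Integer seed.
#' @param n_replicates Number of replicate datasets (>= 1).
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(sd, seed = 1L, n_replicates = 1L) {
  if (!is.numeric(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(sd = as.numeric(sd), seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "noise_spec")
}

#' Default titration schedules
#'
#' Titrant monomer schedules mirroring the two experimental designs:
#' trace probe (10 nM DNA, 20 points over 0-2 uM monomer) and
#' stoichiometric (2.5 uM DNA, 20 points over 0-30 uM monomer).
#'
#' @param design `"trace"` or `"stoichiometric"`.
#' @param n Number of points (default 20).
#' @return Numeric vector of monomer totals (M).
#' @export
titration_schedule <- function(design = c("trace", "stoichiometric"),
                               n = 20L) {
  design <- match.arg(design)
  top <- if (design == "trace") 2e-6 else 30e-6
  seq(0, top, length.out = n)
}

#' Generate synthetic anisotropy titrations
#'
#' Simulates the two-tetramer model curve at `true_k` and adds i.i.d.
#' Gaussian noise per point, producing `noise$n_replicates` independent
#' [titration_data()] sets.  Deterministic for a fixed seed; with
#' `sd = 0` the output equals [simulate_curve()] exactly.
#'
#' @param true_k Generating K_DNA (M).
#' @param probe_total Probe total (M).
#' @param schedule Titrant monomer totals (M), e.g. from
#'   [titration_schedule()].
#' @param response A [response_model()].
#' @param noise A [noise_spec()].
#' @param effector,effector_concentration_M Metadata passed through to
#'   the titrations.
#' @return List of [titration_data()] objects.
#' @export
gen_titration <- function(true_k, probe_total, schedule, response,
                          noise, effector = "apo",
                          effector_concentration_M = NA_real_) {
  stopifnot(inherits(response, "response_model"),
            inherits(noise, "noise_spec"))
  ideal <- simulate_curve(true_k, probe_total, schedule, response)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(noise$seed)
  lapply(seq_len(noise$n_replicates), function(i) {
    titration_data(
      probe_total = probe_total,
      titrant_monomer_M = schedule,
      delta_r = ideal + stats::rnorm(length(ideal), 0, noise$sd),
      replicate_id = paste0("r", i),
      effector = effector,
      effector_concentration_M = effector_concentration_M
    )
  })
}

#' Generate a dose series of effector-weakened titrations
#'
#' Emulates apparent-K dose series: for each entry of `fold_changes`
#' the generating constant is `true_k_apo * fold` and a full replicate
#' set is simulated via [gen_titration()].  `fold_changes = 1` reduces
#' to a single apo series.
#'
#' @param true_k_apo Apo K_DNA (M).
#' @param fold_changes Vector of apparent-K fold weakenings (>= each
#'   > 0).
#' @param probe_total,schedule,response,noise As in [gen_titration()].
#' @param effector Effector label stem for the metadata.
#' @return Named list (by fold) of lists of [titration_data()].
#' @export
gen_effector_series <- function(true_k_apo, fold_changes, probe_total,
                                schedule, response, noise,
                                effector = "effector") {
  if (any(fold_changes <= 0)) {
    stop("fold_changes must be > 0", call. = FALSE)
  }
  out <- lapply(seq_along(fold_changes), function(i) {
    fold <- fold_changes[i]
    gen_titration(true_k_apo * fold, probe_total, schedule, response,
                  noise_spec(noise$sd, noise$seed + i - 1L,
                             noise$n_replicates),
                  effector = if (fold == 1) "apo" else effector)
  })
  names(out) <- paste0("fold_", fold_changes)
  out
}
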