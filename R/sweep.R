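# One-parameter sensitivity sweeps of the tissue-with-gap calibration
# mismatch, and the inferred-to-true concentration converter.

SWEEP_PARAMETERS <- c("gap_width", "alpha_b", "v_b", "sensor_size",
                      "theta_b", "v_t")

#' Default sweep grids
#'
#' Stated ranges where the model analysis fixes them (gap width 0-20 um,
#' sensor size 10-100 um); elsewhere a grid spanning one decade around the
#' baseline value, clamped to the parameter's validity range.
#'
#' @param parameter One of `"gap_width"`, `"alpha_b"`, `"v_b"`,
#'   `"sensor_size"`, `"theta_b"`, `"v_t"`.
#' @param params Baseline parameter set.
#' @return Numeric vector of parameter values.
#' @export
default_sweep_values <- function(parameter, params) {
  v <- params$values
  switch(parameter,
    gap_width = seq(0, 20, length.out = 21),
    sensor_size = seq(10, 100, by = 10),
    alpha_b = seq(0.1, 1, length.out = 10),
    theta_b = seq(0.1, 1, length.out = 10),
    v_b = exp(seq(log(v$v_b / sqrt(10)), log(v$v_b * sqrt(10)),
                  length.out = 11)),
    v_t = exp(seq(log(v$v_t / sqrt(10)), log(v$v_t * sqrt(10)),
                  length.out = 11)),
    abort(paste0("unknown sweep parameter '", parameter, "'"),
          class = "biosensim_configuration_error"))
}

#' Sweep the tissue-with-gap calibration mismatch over one parameter
#'
#' Recomputes the inferred-to-true concentration ratio (`kappa_b * gamma_b`)
#' at each value of the varied parameter, all other parameters held at the
#' baseline.  `gap_width` varies `r_s - r2`; `sensor_size` varies the
#' overall sensor diameter with the core radius kept equal to the
#' enzyme-layer thickness (`r1 = size/2`, `r2 = size`) and the gap width
#' fixed.
#'
#' @param params Baseline `biosensor_params`, configuration `"tissue_gap"`
#'   (a `"tissue"` baseline is treated as a zero-width gap).
#' @param parameter One of `"gap_width"`, `"alpha_b"`, `"v_b"`,
#'   `"sensor_size"`, `"theta_b"`, `"v_t"`.
#' @param values Parameter values; defaults to [default_sweep_values()].
#' @return A `sweep_result` tibble with columns `parameter`, `value`,
#'   `mismatch`; the baseline parameter set is kept as attribute
#'   `"baseline"`.
#' @export
sweep_mismatch <- function(params, parameter, values = NULL) {
  parameter <- match.arg(parameter, SWEEP_PARAMETERS)
  if (!params$configuration %in% c("tissue", "tissue_gap")) {
    abort("sweep baseline must be a tissue or tissue_gap configuration",
          class = "biosensim_configuration_error")
  }
  base <- params$values
  if (params$configuration == "tissue") base$r_s <- base$r2
  if (is.null(values)) values <- default_sweep_values(parameter, params)

  mk <- function(x) {
    vals <- base
    if (parameter == "gap_width") {
      vals$r_s <- vals$r2 + x
    } else if (parameter == "sensor_size") {
      gap <- vals$r_s - vals$r2
      vals$r1 <- x / 2
      vals$r2 <- x
      vals$r_s <- x + gap
    } else {
      vals[[parameter]] <- x
    }
    do.call(biosensor_params, c(list(configuration = "tissue_gap"), vals))
  }

  mismatch <- purrr::map_dbl(values, function(x) gap_mismatch(mk(x))$mismatch)
  out <- tibble(parameter = parameter, value = values, mismatch = mismatch)
  attr(out, "baseline") <- params
  class(out) <- c("sweep_result", class(out))
  out
}

#' Convert a measured current into a tissue concentration estimate
#'
#' Divides the measured current by the free-flow calibration sensitivity to
#' get the naive inferred concentration, then corrects it by the
#' configuration's calibration-mismatch factor: `c_t` in tissue,
#' `kappa_b * gamma_b` with a free-diffusion gap, and the agar
#' inferred-to-true ratio (which reduces to `kappa_b` for diffusion-limited
#' sensors) in agar.
#'
#' @param measured_current Measured steady current, pA.
#' @param calibration_current_per_uM Free-flow calibration sensitivity,
#'   pA/uM (positive).
#' @param params Parameter set describing the diffusive environment.
#' @return A one-row tibble with `A_inferred`, `A_true_estimate` (uM) and
#'   the `mismatch` factor applied.
#' @export
infer_tissue_concentration <- function(measured_current,
                                       calibration_current_per_uM,
                                       params) {
  stopifnot(calibration_current_per_uM > 0)
  if (params$configuration == "calibration") {
    abort("no calibration correction applies in the free-flow configuration",
          class = "biosensim_configuration_error")
  }
  A_inferred <- measured_current / calibration_current_per_uM
  mismatch <- switch(params$configuration,
    tissue = tissue_factor(params),
    tissue_gap = gap_mismatch(params)$mismatch,
    agar = agar_factors(params)$inferred_ratio)
  tibble(A_inferred = A_inferred,
         A_true_estimate = A_inferred / mismatch,
         mismatch = mismatch)
}
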