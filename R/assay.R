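#' Cumulative permeation per unit area with aliquot-replacement correction
#'
#' Franz diffusion cells are sampled by withdrawing an aliquot of volume
#' `aliquot_volume` from the receiver chamber at each time point and
#' replacing it with fresh medium, which dilutes the receiver. The
#' cumulative amount permeated per unit area up to the n-th sampling is
#' therefore
#' \deqn{Q_s(n) = \frac{C_{sn} V_s}{A_s} +
#'               \sum_{i=1}^{n-1} \frac{C_{si} S}{A_s}}
#' where \eqn{C_{si}} is the receiver concentration measured at the i-th
#' sampling, \eqn{V_s} the receiver volume, \eqn{A_s} the effective
#' diffusion area and \eqn{S} the aliquot volume: the sum restores the
#' analyte mass already removed in earlier aliquots.
#'
#' @param data A data frame with columns `time_h` (sampling times, h,
#'   strictly increasing) and `conc_ug_ml` (receiver concentrations at each
#'   sampling, ug/mL, non-negative).
#' @param receiver_volume Receiver-chamber volume \eqn{V_s} (mL). No
#'   default: this is apparatus-specific.
#' @param area Effective diffusion area \eqn{A_s} (cm^2).
#' @param aliquot_volume Sampling aliquot \eqn{S} (mL); 1 mL is the usual
#'   protocol volume.
#' @return The input tibble with an appended `q_s` column (ug/cm^2).
#' @examples
#' cumulative_permeation(
#'   tibble::tibble(time_h = 2, conc_ug_ml = 2),
#'   receiver_volume = 6, area = 1.77
#' )$q_s # 2 * 6 / 1.77 = 6.78
#' @export
cumulative_permeation <- function(data, receiver_volume, area,
                                  aliquot_volume = 1) {
  check <- function(ok, field) {
    if (!isTRUE(ok)) {
      abort(paste0("invalid permeation experiment: ", field),
            class = "coformerscout_validation_error")
    }
  }
  check(is.data.frame(data) &&
          all(c("time_h", "conc_ug_ml") %in% names(data)),
        "data must have time_h and conc_ug_ml columns")
  times <- data$time_h
  conc <- data$conc_ug_ml
  check(length(times) >= 1 && !anyNA(times) &&
          all(diff(times) > 0), "times must be strictly increasing")
  check(!anyNA(conc) && all(conc >= 0),
        "concentrations must be non-negative")
  check(length(receiver_volume) == 1 && receiver_volume > 0,
        "receiver_volume must be positive")
  check(length(area) == 1 && area > 0, "area must be positive")
  check(length(aliquot_volume) == 1 && aliquot_volume >= 0 &&
          aliquot_volume <= receiver_volume,
        "aliquot_volume must lie in [0, receiver_volume]")
  n <- length(conc)
  removed <- c(0, cumsum(conc * aliquot_volume))[seq_len(n)]
  qs <- (conc * receiver_volume + removed) / area
  out <- as_tibble(data)
  out$q_s <- qs
  out
}

#' CCK-8 cell viability from optical densities
#'
#' \deqn{\mathrm{viability} = 100 \cdot
#'   \frac{A_{sample} - A_{blank}}{A_{control} - A_{blank}}}
#' where the blank wells contain neither cells nor compound, the control
#' wells untreated cells, and the sample wells treated cells (all optical
#' densities at 450 nm). Values outside \[0, 100\] are reported as-is with
#' a warning, never clipped: they are raw assay signal.
#'
#' @param a_sample,a_control,a_blank Optical densities (vectorized over
#'   `a_sample`).
#' @return Viability in percent.
#' @examples
#' viability(0.6, 1.0, 0.1) # 55.6%
#' @export
viability <- function(a_sample, a_control, a_blank) {
  if (any(a_control == a_blank)) {
    abort("degenerate assay: a_control equals a_blank",
          class = "coformerscout_assay_error")
  }
  v <- 100 * (a_sample - a_blank) / (a_control - a_blank)
  if (any(v < 0 | v > 100)) {
    warn("viability outside [0, 100]%: reported unclipped")
  }
  v
}

#' Estimate IC10 / IC50 from a dose-response table
#'
#' The IC level is the concentration producing the given percent inhibition,
#' i.e. where viability crosses `100 - level` percent. An exactly tested
#' concentration is returned as-is; otherwise the estimate interpolates
#' between the first adjacent pair bracketing the target from above
#' (viability falling through the target), linearly in log10 concentration
#' by default because dose series are conventionally geometric.
#'
#' @param dose_response A data frame with strictly increasing positive
#'   `concentration` and mean `viability` (percent) columns.
#' @param level Percent inhibition, typically 10 or 50.
#' @param interpolation `"log"` (default) or `"linear"`.
#' @return The estimated concentration, in the input's units.
#' @examples
#' dr <- tibble::tibble(concentration = c(0.1, 1), viability = c(60, 40))
#' estimate_ic(dr, 50) # 10^(-1 + 0.5) ~ 0.316
#' @export
estimate_ic <- function(dose_response, level = 50,
                        interpolation = c("log", "linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.data.frame(dose_response),
            all(c("concentration", "viability") %in% names(dose_response)))
  conc <- dose_response$concentration
  viab <- dose_response$viability
  assert_that(all(conc > 0) && all(diff(conc) > 0),
              "concentrations must be strictly increasing and positive",
              class = "coformerscout_validation_error")
  assert_that(level > 0 && level < 100, "level must lie in (0, 100)",
              class = "coformerscout_argument_error")
  target <- 100 - level
  hit <- which(viab == target)
  if (length(hit)) return(conc[hit[1]])
  for (i in seq_len(length(conc) - 1)) {
    if (viab[i] > target && viab[i + 1] < target) {
      f <- (viab[i] - target) / (viab[i] - viab[i + 1])
      if (interpolation == "log") {
        return(10^(log10(conc[i]) + f * (log10(conc[i + 1]) -
                                           log10(conc[i]))))
      }
      return(conc[i] + f * (conc[i + 1] - conc[i]))
    }
  }
  abort(paste0("IC", level, " not estimable: target viability ", target,
               "% is never bracketed by the observed curve"),
        class = "coformerscout_not_estimable_error")
}
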