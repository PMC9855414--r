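#' Reference calibration targets for beat morphology by glycemic state
#'
#' Per-state mean values of the lead-II beat-morphology features that the
#' synthetic generator is calibrated to: the seven interval means (R-R, P-Q,
#' Q-R, R-S, S-T, P-R, Q-T, in seconds), the spanning-tree amplitude
#' differences (P-Q, Q-R, R-S, S-T, in mV), and the R-peak amplitude anchor
#' that fixes the absolute-voltage gauge. The euglycemic and dysglycemic
#' columns reproduce feature statistics reported for an ICU cohort:
#' dysglycemia shortens R-R (0.74 to 0.66 s), lengthens Q-T (0.37 to 0.44 s)
#' and S-T (0.25 to 0.32 s), and lowers the R-wave amplitude differences
#' (Q-R 0.68 to 0.56 mV, R-S 0.75 to 0.71 mV).
#'
#' The interval system is exactly consistent (Q-T = Q-R + R-S + S-T and
#' P-R = P-Q + Q-R in both states), which [solve_wave_params()] requires.
#'
#' @return A tibble with one row per target and columns `target`, `eu`, `dys`.
#' @examples
#' feature_targets()
#' @export
feature_targets <- function() {
  tribble(
    ~target,     ~eu,  ~dys,
    "rr_s",      0.74, 0.66,
    "pq_int_s",  0.13, 0.16,
    "qr_int_s",  0.08, 0.07,
    "rs_int_s",  0.04, 0.05,
    "st_int_s",  0.25, 0.32,
    "pr_int_s",  0.21, 0.23,
    "qt_int_s",  0.37, 0.44,
    "pq_amp_mv", 0.13, 0.15,
    "qr_amp_mv", 0.68, 0.56,
    "rs_amp_mv", 0.75, 0.71,
    "st_amp_mv", 0.64, 0.58,
    "r_amp_mv",  0.60, 0.52
  )
}

wave_names <- function() c("P", "Q", "R", "S", "T")

#' Construct beat wave parameters
#'
#' A beat is modelled as the sum of five Gaussian waves (P, Q, R, S, T), each
#' with a centre offset relative to the R peak, a signed peak amplitude, and a
#' width. Because neighbouring Gaussians overlap slightly, the raw Gaussian
#' coefficients are solved from a 5x5 linear system so that the *summed* trace
#' passes exactly through the designed peak amplitude at each designed centre.
#'
#' @param centers_s Named numeric (P, Q, R, S, T): centre offsets in seconds
#'   relative to R (R must be 0); must be strictly increasing.
#' @param amplitudes_mv Named numeric: designed peak amplitudes (mV, signed) of
#'   the summed trace at each centre.
#' @param widths_s Named numeric: Gaussian standard deviations (s), all > 0.
#' @param heart_period_s Mean R-to-R period in seconds, within `[0.3, 2]`.
#' @return A `wave_params` object.
#' @seealso [solve_wave_params()], [gaussian_beat()]
#' @export
wave_params <- function(centers_s, amplitudes_mv, widths_s, heart_period_s) {
  w <- wave_names()
  centers_s <- centers_s[w]; amplitudes_mv <- amplitudes_mv[w]
  widths_s <- widths_s[w]
  if (anyNA(centers_s) || anyNA(amplitudes_mv) || anyNA(widths_s)) {
    abort("wave_params: centers_s, amplitudes_mv, widths_s must each name P, Q, R, S, T",
          class = "ecgdys_param_error")
  }
  if (any(widths_s <= 0)) {
    abort("wave_params: all wave widths must be positive",
          class = "ecgdys_param_error")
  }
  if (any(diff(centers_s) <= 0) || centers_s[["R"]] != 0) {
    abort("wave_params: centres must be strictly ordered P < Q < R(=0) < S < T",
          class = "ecgdys_param_error")
  }
  if (heart_period_s < 0.3 || heart_period_s > 2) {
    abort("wave_params: heart_period_s must lie in [0.3, 2] s",
          class = "ecgdys_param_error")
  }
  A <- gauss_mix_matrix(centers_s, widths_s)
  gauss_amp <- solve(A, amplitudes_mv)
  structure(
    list(centers_s = centers_s, amplitudes_mv = amplitudes_mv,
         widths_s = widths_s, heart_period_s = heart_period_s,
         gauss_amp = setNames(as.numeric(gauss_amp), w),
         overlap_inv = solve(A)),
    class = "wave_params")
}

gauss_mix_matrix <- function(centers, widths) {
  outer(centers, seq_along(centers), function(ci, j) {
    exp(-(ci - centers[j])^2 / (2 * widths[j]^2))
  })
}

#' Evaluate a noise-free Gaussian beat
#'
#' The deterministic morphology model: `v(t) = sum_w g_w exp(-(t - c_w)^2 /
#' (2 s_w^2))` over the five waves, where the coefficients `g_w` were solved by
#' [wave_params()] so that `v(c_w)` equals the designed peak amplitude.
#'
#' @param params A `wave_params` object.
#' @param t_grid Numeric vector of times (s) relative to the R peak.
#' @return Voltage (mV) at each time in `t_grid`.
#' @examples
#' wp <- solve_wave_params(feature_targets(), state = "eu")
#' t <- seq(-0.4, 0.6 - 1 / 125, by = 1 / 125)
#' v <- gaussian_beat(wp, t)
#' @export
gaussian_beat <- function(params, t_grid) {
  stopifnot(inherits(params, "wave_params"))
  v <- numeric(length(t_grid))
  for (w in wave_names()) {
    v <- v + params$gauss_amp[[w]] *
      exp(-(t_grid - params$centers_s[[w]])^2 / (2 * params$widths_s[[w]]^2))
  }
  v
}

default_wave_widths <- function() {
  c(P = 0.020, Q = 0.010, R = 0.012, S = 0.010, T = 0.040)
}

#' Solve wave parameters from per-state feature targets
#'
#' Inverts the feature definitions to obtain a designed beat geometry whose
#' fiducial features reproduce the target means: interval targets map linearly
#' to centre offsets (Q at -`qr`, P at -`pr`, S at `rs`, T at `rs + st`
#' relative to R) and the amplitude spanning tree (P-Q, Q-R, R-S, S-T plus the
#' R anchor) maps to designed peak amplitudes. Centre offsets are snapped to
#' the sample grid so that designed fiducials sit on integer sample indices;
#' the designed (snapped) fiducials are recorded for round-trip tests.
#'
#' The interval system is checked for internal consistency
#' (`qt = qr + rs + st`, `pr = pq + qr`); an inconsistent system is a
#' calibration error naming the conflict.
#'
#' @param targets A tibble as returned by [feature_targets()] (columns
#'   `target` and one column per state), or a named list for a single state.
#' @param state Which state column to solve, e.g. `"eu"` or `"dys"`. Ignored
#'   when `targets` is a named list.
#' @param widths_s Gaussian widths (defaults chosen so neighbouring waves
#'   barely overlap at the designed geometry).
#' @param cfg A [pipeline_config()].
#' @param tol Consistency tolerance in seconds.
#' @return A `wave_params` object with attribute `"designed"`: a tibble of the
#'   designed fiducial sample offsets (relative to R) and amplitudes.
#' @examples
#' solve_wave_params(feature_targets(), state = "dys")
#' @export
solve_wave_params <- function(targets, state = "eu",
                              widths_s = default_wave_widths(),
                              cfg = pipeline_config(), tol = 1e-6) {
  if (is.data.frame(targets)) {
    if (!state %in% names(targets)) {
      abort(sprintf("state column '%s' not found in targets", state),
            class = "ecgdys_calibration_error")
    }
    tg <- setNames(targets[[state]], targets$target)
  } else {
    tg <- unlist(targets)
  }
  need <- c("rr_s", "pq_int_s", "qr_int_s", "rs_int_s", "st_int_s",
            "pr_int_s", "qt_int_s", "pq_amp_mv", "qr_amp_mv", "rs_amp_mv",
            "st_amp_mv", "r_amp_mv")
  missing <- setdiff(need, names(tg))
  if (length(missing)) {
    abort(sprintf("calibration targets missing: %s",
                  paste(missing, collapse = ", ")),
          class = "ecgdys_calibration_error")
  }
  conflicts <- character()
  if (abs(tg[["qt_int_s"]] -
          (tg[["qr_int_s"]] + tg[["rs_int_s"]] + tg[["st_int_s"]])) > tol) {
    conflicts <- c(conflicts, sprintf(
      "qt_int_s (%.4g) != qr_int_s + rs_int_s + st_int_s (%.4g)",
      tg[["qt_int_s"]], tg[["qr_int_s"]] + tg[["rs_int_s"]] + tg[["st_int_s"]]))
  }
  if (abs(tg[["pr_int_s"]] - (tg[["pq_int_s"]] + tg[["qr_int_s"]])) > tol) {
    conflicts <- c(conflicts, sprintf(
      "pr_int_s (%.4g) != pq_int_s + qr_int_s (%.4g)",
      tg[["pr_int_s"]], tg[["pq_int_s"]] + tg[["qr_int_s"]]))
  }
  if (any(tg[c("pq_int_s", "qr_int_s", "rs_int_s", "st_int_s")] <= 0)) {
    conflicts <- c(conflicts,
                   "interval targets pq, qr, rs, st must all be positive")
  }
  if (length(conflicts)) {
    abort(paste0("inconsistent interval system:\n  ",
                 paste(conflicts, collapse = "\n  ")),
          class = "ecgdys_calibration_error")
  }
  fs <- cfg$sampling_rate_hz
  centers <- c(P = -tg[["pr_int_s"]],
               Q = -tg[["qr_int_s"]],
               R = 0,
               S = tg[["rs_int_s"]],
               T = tg[["rs_int_s"]] + tg[["st_int_s"]])
  centers <- round(centers * fs) / fs   # snap designed fiducials to the grid
  amp_r <- tg[["r_amp_mv"]]
  amps <- c(P = NA_real_, Q = amp_r - tg[["qr_amp_mv"]], R = amp_r,
            S = amp_r - tg[["rs_amp_mv"]], T = NA_real_)
  amps[["P"]] <- amps[["Q"]] + tg[["pq_amp_mv"]]
  amps[["T"]] <- amps[["S"]] + tg[["st_amp_mv"]]
  wp <- wave_params(centers, amps, widths_s[wave_names()], tg[["rr_s"]])
  attr(wp, "designed") <- tibble(
    wave = wave_names(),
    offset_samples = as.integer(round(centers * fs)),
    amplitude_mv = as.numeric(amps))
  wp
}

#' @export
print.wave_params <- function(x, ...) {
  cat("<wave_params>  heart period", format(x$heart_period_s), "s\n")
  df <- data.frame(center_s = x$centers_s, amplitude_mv = x$amplitudes_mv,
                   width_s = x$widths_s)
  print(round(df, 4))
  invisible(x)
}
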