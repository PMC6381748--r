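#' Basal respiration rate of one well
#'
#' Arithmetic mean oxygen consumption rate over the pre-stimulus
#' measurement cycles (by default every cycle strictly before the glucose
#' injection), in pmol O2/min.
#'
#' @param trace tibble/data.frame with `time_min` and `ocr` for one well.
#' @param window two-element numeric `c(start, end)`; cycles with
#'   `start <= time < end` are averaged. Defaults to everything before
#'   the trace's `injection_time` annotation.
#' @return Basal OCR (pmol O2/min).
#' @export
basal_rate <- function(trace, window = NULL) {
  if (is.null(window)) {
    inj <- unique(trace$injection_time)
    inj <- inj[!is.na(inj)]
    if (length(inj) != 1)
      stop("no injection_time annotation; supply an explicit window")
    window <- c(-Inf, inj)
  }
  sel <- trace$time_min >= window[1] & trace$time_min < window[2]
  if (sum(sel) < 2)
    stop("basal window must contain at least 2 measurement cycles")
  mean(trace$ocr[sel])
}

#' Area under the curve over basal respiration
#'
#' Signed trapezoidal integral of `OCR - basal` from the stimulus time to
#' the end of the trace, on the actual timestamps (robust to skipped
#' cycles). Below-basal excursions contribute negatively (no clipping).
#' Units: pmol O2.
#'
#' @param trace tibble with `time_min`, `ocr` for one well.
#' @param stimulus_time injection time (min); points at or after it are
#'   integrated.
#' @param basal basal OCR, e.g. from [basal_rate()].
#' @return Signed AUC over basal (pmol O2).
#' @export
response_auc <- function(trace, stimulus_time, basal) {
  if (stimulus_time < min(trace$time_min) ||
      stimulus_time > max(trace$time_min))
    stop("stimulus_time outside the trace span")
  sel <- trace$time_min >= stimulus_time
  if (sum(sel) < 2) stop("fewer than 2 post-stimulus measurement cycles")
  t <- trace$time_min[sel]
  pracma::trapz(t, trace$ocr[sel] - basal)
}

#' Summarize glucose responses per well
#'
#' @param traces an `ocr_traces` tibble with treatment and
#'   `injection_time` annotations.
#' @param stimulus_time optional common stimulus time overriding the
#'   per-well `injection_time`.
#' @return Tibble `well`, `treatment`, `basal`, `auc_over_basal`.
#' @export
respiration_responses <- function(traces, stimulus_time = NULL) {
  purrr::map_dfr(split(tibble::as_tibble(traces), traces$well),
                 function(tr) {
    st <- if (is.null(stimulus_time)) unique(tr$injection_time)[1]
          else stimulus_time
    b <- basal_rate(tr, window = c(-Inf, st))
    tibble::tibble(well = tr$well[1], treatment = tr$treatment[1],
                   basal = b,
                   auc_over_basal = response_auc(tr, st, b))
  })
}

#' Normalize treatment responses to mock-treated control wells
#'
#' For each treatment: fold change of the mean AUC-over-basal versus the
#' mean mock AUC, a two-sided Welch t-test of treatment versus mock AUCs
#' across replicate wells, and a flag for compounds that already perturb
#' the basal rate before stimulation (Welch test on basal rates,
#' p < 0.05 — the H89/phenformin-style caveat). Groups identical to the
#' control report fold 1 and p = 1 ("no difference").
#'
#' @param responses tibble from [respiration_responses()].
#' @param control_label treatment label of the mock/control group.
#' @param welch use Welch's unequal-variance t-test (default TRUE).
#' @return Tibble of class `resp_report`: `treatment`, `n_wells`,
#'   `fold_vs_control`, `p_value`, `basal_shift_p`, `basal_perturbed`.
#' @export
compare_to_control <- function(responses, control_label = "mock",
                               welch = TRUE) {
  if (!control_label %in% responses$treatment)
    stop("control group '", control_label, "' not found")
  ctrl <- responses[responses$treatment == control_label, ]
  if (nrow(ctrl) < 2) stop("control group needs at least 2 wells")
  safe_t <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    if (stats::sd(c(x, y)) == 0) return(1)
    stats::t.test(x, y, var.equal = !welch)$p.value
  }
  res <- purrr::map_dfr(split(responses, responses$treatment),
                        function(g) {
    tibble::tibble(
      treatment = g$treatment[1],
      n_wells = nrow(g),
      fold_vs_control = mean(g$auc_over_basal) /
        mean(ctrl$auc_over_basal),
      p_value = safe_t(g$auc_over_basal, ctrl$auc_over_basal),
      basal_shift_p = safe_t(g$basal, ctrl$basal))
  })
  res <- res |>
    dplyr::mutate(basal_perturbed = !is.na(.data$basal_shift_p) &
                    .data$basal_shift_p < 0.05 &
                    .data$treatment != control_label) |>
    dplyr::arrange(.data$treatment != control_label, .data$treatment)
  structure(res, class = c("resp_report", class(res)))
}
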