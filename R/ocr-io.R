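#' Read oxygen-consumption-rate plate traces
#'
#' Expects a CSV with columns `well`, `time_min`, `ocr` (pmol O2/min), one
#' row per measurement cycle; the instrument cadence is nominally one cycle
#' per 6 min but only monotone timestamps are enforced. An optional plate
#' layout CSV (`well`, `treatment`, `injection_time`, optionally `dose`)
#' annotates wells; wells absent from the layout are kept unannotated with
#' a warning.
#'
#' @param path trace CSV path.
#' @param layout optional layout CSV path, or a data.frame.
#' @return A tibble of class `ocr_traces` with columns `well`, `time_min`,
#'   `ocr`, `treatment`, `injection_time` (and `dose` if provided),
#'   time-sorted within each well.
#' @export
read_ocr_traces <- function(path, layout = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("well", "time_min", "ocr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("OCR trace file lacks column '", miss[1], "'")
  df <- tibble::as_tibble(df) |>
    dplyr::arrange(.data$well, .data$time_min)
  nonmono <- df |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(dup = anyDuplicated(.data$time_min) > 0)
  if (any(nonmono$dup))
    stop("non-monotone timestamps in well ",
         nonmono$well[nonmono$dup][1])
  if (!is.null(layout)) {
    lay <- if (is.character(layout)) utils::read.csv(layout) else layout
    if (!all(c("well", "treatment") %in% names(lay)))
      stop("plate layout needs columns 'well' and 'treatment'")
    orphan <- setdiff(unique(df$well), lay$well)
    if (length(orphan))
      warning("well(s) missing from layout kept unannotated: ",
              paste(orphan, collapse = ", "))
    df <- dplyr::left_join(df, tibble::as_tibble(lay), by = "well")
  } else {
    df$treatment <- NA_character_
    df$injection_time <- NA_real_
  }
  structure(df, class = c("ocr_traces", class(df)))
}

#' Write oxygen-consumption traces to CSV
#'
#' @param traces an `ocr_traces` tibble (only `well`, `time_min`, `ocr`
#'   are written; annotations belong in the layout file).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ocr_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces)[c("well", "time_min", "ocr")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
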