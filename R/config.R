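#' Analysis run configuration
#'
#' Collects the tunable parameters shared by the pipeline stages. Defaults
#' follow the published beta-cell time-course design: paired two-condition
#' comparison (2.5 vs 16.7 mM glucose) at 5/30/60 min with five replicates,
#' significance at p <= 0.05 and a log2 fold-change gate of 0.3 (a 23%
#' change), four trajectory clusters, and the "mean of second differences"
#' measure excluded from clustering.
#'
#' @param alpha significance level for regulation calls.
#' @param lfc_threshold log2 fold-change magnitude a site must exceed to be
#'   called regulated.
#' @param times stimulation time points in minutes.
#' @param replicates number of paired replicates per condition.
#' @param min_replicates minimum complete replicate pairs per condition and
#'   time point for a site to be retained.
#' @param min_loc_prob minimum phosphosite localization probability.
#' @param k number of trajectory clusters.
#' @param excluded_measure trajectory measure name(s) excluded from
#'   clustering (by name, not index).
#' @param ksea_min_m minimum substrate-group size scored by KSEA.
#' @param values_are_log2 whether quantitative input values are already on
#'   the log2 scale (`FALSE` log2-transforms on read).
#' @param paired use the paired t-test (`FALSE` gives Welch's unpaired test).
#' @param seed default random seed for stochastic stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05,
                       lfc_threshold = 0.3,
                       times = c(5, 30, 60),
                       replicates = 5L,
                       min_replicates = 2L,
                       min_loc_prob = 0.95,
                       k = 4L,
                       excluded_measure = "mean_second_diff",
                       ksea_min_m = 1L,
                       values_are_log2 = TRUE,
                       paired = TRUE,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, lfc_threshold > 0, k >= 2,
            min_loc_prob >= 0, min_loc_prob <= 1,
            min_replicates >= 1, ksea_min_m >= 1)
  structure(
    list(alpha = alpha, lfc_threshold = lfc_threshold,
         times = sort(unique(as.numeric(times))),
         replicates = as.integer(replicates),
         min_replicates = as.integer(min_replicates),
         min_loc_prob = min_loc_prob, k = as.integer(k),
         excluded_measure = excluded_measure,
         ksea_min_m = as.integer(ksea_min_m),
         values_are_log2 = isTRUE(values_are_log2),
         paired = isTRUE(paired),
         seed = as.integer(seed)),
    class = "run_config")
}

#' Write a run configuration as a flat key/value file
#'
#' @param config a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) {
    s <- if (is.logical(v)) ifelse(v, "true", "false") else as.character(v)
    paste(s, collapse = ",")
  }
  lines <- vapply(names(config),
                  function(nm) paste0(nm, " = ", fmt(config[[nm]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value run configuration file
#'
#' Unknown keys are an error; missing keys take their defaults.
#'
#' @param path file of `key = value` lines (`#` comments allowed).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  args <- stats::setNames(as.list(vals), keys)
  cast <- function(key, val) {
    proto <- defaults[[key]]
    parts <- strsplit(val, ",")[[1]]
    if (is.logical(proto)) return(tolower(parts) %in% c("true", "t", "1"))
    if (is.numeric(proto)) return(as.numeric(parts))
    parts
  }
  args <- Map(cast, names(args), args)
  do.call(run_config, args)
}
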