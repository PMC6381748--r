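#' Construct a phosphosite quantification table
#'
#' Container for a paired two-condition, multi-time-point, multi-replicate
#' log2 quantification matrix plus per-site annotations. Sample columns are
#' labelled `<cond>_<time>_r<rep>` with `cond` in `{low, high}` (resting
#' versus stimulating glucose).
#'
#' @param meta tibble with columns `psite`, `protein`, `gene`, `loc_prob`,
#'   `peptide` (one row per quantified feature; `psite` unique).
#' @param values numeric matrix of log2 quantitative values, rows matching
#'   `meta$psite`, columns matching `samples$label`.
#' @param samples tibble with columns `label`, `condition`, `time`,
#'   `replicate` describing the value columns.
#' @param dropped tibble of rows removed by filtering (`psite`, `reason`).
#' @return An object of class `psite_quant`.
#' @export
psite_quant <- function(meta, values, samples,
                        dropped = tibble::tibble(psite = character(),
                                                 reason = character())) {
  meta <- tibble::as_tibble(meta)
  samples <- tibble::as_tibble(samples)
  stopifnot(!anyDuplicated(meta$psite),
            nrow(values) == nrow(meta),
            ncol(values) == nrow(samples),
            all(samples$condition %in% c("low", "high")))
  rownames(values) <- meta$psite
  colnames(values) <- samples$label
  # paired design: identical replicate structure across conditions per time
  grid <- samples |>
    dplyr::count(.data$condition, .data$time) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n")
  if (nrow(grid) && !all(grid$low == grid$high))
    stop("replicate structure differs between conditions within a time point")
  structure(list(meta = meta, values = values, samples = samples,
                 dropped = tibble::as_tibble(dropped)),
            class = "psite_quant")
}

#' @export
print.psite_quant <- function(x, ...) {
  cat("<psite_quant> ", nrow(x$meta), " p-sites x ", nrow(x$samples),
      " samples (", length(unique(x$samples$time)), " time points, ",
      max(x$samples$replicate), " replicates); ", nrow(x$dropped),
      " rows dropped by filters\n", sep = "")
  invisible(x)
}

#' @export
dim.psite_quant <- function(x) dim(x$values)

parse_sample_labels <- function(labels) {
  m <- regmatches(labels,
                  regexec("^(low|high)_([0-9]+)_r([0-9]+)$", labels))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed sample column header: '", labels[bad][1],
         "' (expected <cond>_<time>_r<rep>)")
  tibble::tibble(label = labels,
                 condition = vapply(m, `[[`, "", 2L),
                 time = as.numeric(vapply(m, `[[`, "", 3L)),
                 replicate = as.integer(vapply(m, `[[`, "", 4L)))
}

#' Apply the localization, pairing and presence filters
#'
#' Three filters, in order: (1) sites below the minimum localization
#' probability are dropped; (2) within each time point, a replicate pair
#' with a missing member in either condition is blanked pairwise (so the
#' replicate index sets with data are identical between conditions); (3)
#' sites missing from any condition, or with fewer than
#' `config$min_replicates` complete pairs at any time point, are dropped.
#' Filtering is idempotent. Dropped rows are recorded with reasons.
#'
#' @param qt a `psite_quant`.
#' @param config a [run_config()].
#' @return The filtered `psite_quant`.
#' @export
filter_quant_table <- function(qt, config = run_config()) {
  stopifnot(inherits(qt, "psite_quant"))
  vals <- qt$values
  s <- qt$samples
  keep <- rep(TRUE, nrow(qt$meta))
  reason <- rep(NA_character_, nrow(qt$meta))

  low_loc <- !is.na(qt$meta$loc_prob) & qt$meta$loc_prob < config$min_loc_prob
  keep[low_loc] <- FALSE
  reason[low_loc] <- "localization probability below threshold"

  times <- sort(unique(s$time))
  for (tm in times) {
    reps <- sort(unique(s$replicate[s$time == tm]))
    for (r in reps) {
      i_lo <- which(s$condition == "low" & s$time == tm & s$replicate == r)
      i_hi <- which(s$condition == "high" & s$time == tm & s$replicate == r)
      if (!length(i_lo) || !length(i_hi)) next
      incomplete <- is.na(vals[, i_lo]) | is.na(vals[, i_hi])
      vals[incomplete, c(i_lo, i_hi)] <- NA_real_
    }
    cols <- which(s$time == tm & s$condition == "low")
    n_pairs <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    short <- keep & n_pairs < config$min_replicates
    keep[short] <- FALSE
    reason[short] <- sprintf(
      "fewer than %d complete replicate pairs at %g min",
      config$min_replicates, tm)
  }

  dropped <- dplyr::bind_rows(
    qt$dropped,
    tibble::tibble(psite = qt$meta$psite[!keep], reason = reason[!keep]))
  psite_quant(qt$meta[keep, , drop = FALSE],
              vals[keep, , drop = FALSE],
              s, dropped)
}

#' Read a phosphosite quantification TSV
#'
#' Expected header: `psite`, `protein`, `gene`, `loc_prob`, `peptide`, then
#' one column per sample named `<cond>_<time>_r<rep>` (e.g. `high_30_r2`).
#' Missing values are empty cells or `NA`; they are never zero-imputed
#' (zero is a legal log2 value). Unless `config$values_are_log2`, values
#' are log2-transformed on read. The localization, pairing and presence
#' filters of [filter_quant_table()] are applied; dropped rows are counted
#' in the returned object.
#'
#' @param path TSV file path.
#' @param config a [run_config()].
#' @return A filtered `psite_quant`.
#' @export
read_quant_table <- function(path, config = run_config()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = c("", "NA"),
                          colClasses = "character")
  need <- c("psite", "protein", "gene", "loc_prob", "peptide")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("quant table header lacks column '", miss[1], "'")
  value_cols <- setdiff(names(df), need)
  samples <- parse_sample_labels(value_cols)
  if (nrow(df) == 0) {
    return(psite_quant(
      tibble::tibble(psite = character(), protein = character(),
                     gene = character(), loc_prob = numeric(),
                     peptide = character()),
      matrix(numeric(), 0, nrow(samples)), samples))
  }
  vals <- matrix(NA_real_, nrow(df), length(value_cols))
  for (j in seq_along(value_cols)) {
    raw <- df[[value_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad))
      stop("non-numeric value in column '", value_cols[j], "', row '",
           df$psite[which(bad)[1]], "'")
    vals[, j] <- num
  }
  if (!config$values_are_log2) vals <- log2(vals)
  parse_psite_key(df$psite)  # validates key syntax
  meta <- tibble::tibble(psite = toupper(df$psite), protein = df$protein,
                         gene = toupper(df$gene),
                         loc_prob = as.numeric(df$loc_prob),
                         peptide = df$peptide)
  filter_quant_table(psite_quant(meta, vals, samples), config)
}

#' Write a phosphosite quantification TSV
#'
#' Inverse of [read_quant_table()] (values written on the log2 scale).
#'
#' @param qt a `psite_quant`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(qt, path) {
  stopifnot(inherits(qt, "psite_quant"))
  df <- as.data.frame(c(as.list(qt$meta),
                        as.list(as.data.frame(qt$values))),
                      check.names = FALSE, optional = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Per-replicate paired log2 fold changes at one time point
#'
#' @param qt a `psite_quant`.
#' @param time time point (min).
#' @return Matrix of `high - low` log2 differences, p-sites x replicates.
#' @export
paired_log2fc <- function(qt, time) {
  s <- qt$samples
  reps <- sort(unique(s$replicate[s$time == time]))
  if (!length(reps)) stop("no samples at time ", time)
  fc <- sapply(reps, function(r) {
    hi <- qt$values[, s$label[s$condition == "high" & s$time == time &
                                s$replicate == r], drop = TRUE]
    lo <- qt$values[, s$label[s$condition == "low" & s$time == time &
                                s$replicate == r], drop = TRUE]
    hi - lo
  })
  fc <- matrix(fc, nrow = nrow(qt$meta),
               dimnames = list(qt$meta$psite, paste0("r", reps)))
  fc
}
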