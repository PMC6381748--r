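#' Read kinase-substrate relationship tables
#'
#' Reads one or more TSVs in the column contract `enzyme`, `class`,
#' `substrate_gene`, `substrate_acc`, `site`, `window` (the last three may
#' be partially empty; `window` is the +/-7-residue sequence context with
#' the phospho-acceptor at the centre). The contract mirrors what
#' PhosphoSitePlus / Signor exports reduce to. Files are merged and
#' deduplicated on (enzyme, substrate, site); records lacking an enzyme
#' name or any substrate identifier are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param paths character vector of TSV paths.
#' @return A tibble of class `ksdb` with columns `enzyme`, `class`
#'   (kinase/phosphatase), `substrate_gene`, `substrate_acc`, `site`
#'   (e.g. "S9"), `window`.
#' @export
read_ksdb <- function(paths) {
  tabs <- lapply(paths, function(p) {
    df <- utils::read.delim(p, sep = "\t", header = TRUE,
                            check.names = FALSE, na.strings = c("", "NA"),
                            colClasses = "character")
    need <- c("enzyme", "class", "substrate_gene", "substrate_acc",
              "site", "window")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("kinase-substrate table '", p,
                           "' lacks column '", miss[1], "'")
    tibble::as_tibble(df[need])
  })
  db <- dplyr::bind_rows(tabs)
  bad <- is.na(db$enzyme) |
    (is.na(db$substrate_gene) & is.na(db$substrate_acc)) | is.na(db$site)
  n_skipped <- sum(bad)
  if (n_skipped) {
    warning(n_skipped,
            " record(s) lacking enzyme or substrate identifier skipped")
    db <- db[!bad, , drop = FALSE]
  }
  if (nrow(db) && !all(db$class %in% c("kinase", "phosphatase")))
    stop("enzyme class must be 'kinase' or 'phosphatase' for every record")
  db <- db |>
    dplyr::mutate(enzyme = toupper(.data$enzyme),
                  substrate_gene = toupper(.data$substrate_gene),
                  substrate_acc = toupper(.data$substrate_acc),
                  site = toupper(.data$site)) |>
    dplyr::distinct(.data$enzyme,
                    .data$substrate_gene, .data$substrate_acc, .data$site,
                    .keep_all = TRUE)
  structure(db, class = c("ksdb", class(db)), n_skipped = n_skipped)
}

#' Write a kinase-substrate relationship table
#'
#' @param db a `ksdb` tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ksdb <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  invisible(path)
}

#' Per-enzyme substrate record counts
#'
#' @param db a `ksdb` tibble.
#' @return Tibble `enzyme`, `class`, `n_records`.
#' @export
ksdb_counts <- function(db) {
  db |>
    dplyr::count(.data$enzyme, .data$class, name = "n_records") |>
    dplyr::arrange(dplyr::desc(.data$n_records))
}
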