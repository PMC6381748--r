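#' Parse canonical phosphosite keys
#'
#' The canonical key form is `"ACCESSION_S123"` for single sites and
#' `"ACCESSION_S519/S523"` for multi-site features quantified as one unit
#' (e.g. a doubly phosphorylated peptide). Residue letters are restricted to
#' the phospho-acceptors S, T and Y; parsing is case-insensitive and keys
#' are stored uppercase. Positions within a key must be strictly increasing.
#'
#' @param keys character vector of p-site keys.
#' @return A tibble with one row per (key, site): `psite`, `accession`,
#'   `residue`, `position`, `site_index`.
#' @examples
#' parse_psite_key(c("P12345_S519/S523", "q9z2a5_t41"))
#' @export
parse_psite_key <- function(keys) {
  keys <- toupper(as.character(keys))
  parts <- regmatches(keys, regexpr("_[STY][0-9]+(/[STY][0-9]+)*$", keys))
  ok <- lengths(regmatches(keys,
        gregexpr("^[A-Z0-9.-]+_[STY][0-9]+(/[STY][0-9]+)*$", keys))) == 1L
  if (!all(ok)) stop("malformed p-site key: ", keys[!ok][1])
  acc <- sub("_[STY][0-9]+(/[STY][0-9]+)*$", "", keys)
  sites <- strsplit(sub("^_", "", parts), "/", fixed = TRUE)
  out <- purrr::map2_dfr(seq_along(keys), sites, function(i, s) {
    tibble::tibble(psite = keys[i], accession = acc[i],
                   residue = substr(s, 1, 1),
                   position = as.integer(substring(s, 2)),
                   site_index = seq_along(s))
  })
  bad <- out |>
    dplyr::group_by(.data$psite) |>
    dplyr::summarise(mono = all(diff(.data$position) > 0) ||
                       dplyr::n() == 1L) |>
    dplyr::filter(!.data$mono)
  if (nrow(bad)) stop("p-site positions not strictly increasing: ",
                      bad$psite[1])
  out
}

#' Format a phosphosite key from its components
#'
#' @param accession protein accession.
#' @param residues phospho-acceptor residue letters (S/T/Y).
#' @param positions 1-based residue positions, strictly increasing.
#' @return Canonical key string.
#' @export
format_psite_key <- function(accession, residues, positions) {
  residues <- toupper(residues)
  stopifnot(all(residues %in% c("S", "T", "Y")),
            length(residues) == length(positions),
            length(positions) >= 1,
            length(positions) == 1 || all(diff(positions) > 0))
  paste0(toupper(accession), "_",
         paste0(residues, as.integer(positions), collapse = "/"))
}
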