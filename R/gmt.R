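#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene symbols. Symbols are case-normalized to uppercase.
#' Duplicate set names and empty member lists are errors.
#'
#' @param path GMT file path.
#' @return A named list of class `gene_set_collection`; each element is a
#'   character vector of member symbols, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    nm <- vapply(fields[short], function(f) f[1], "")
    stop("gene set '", nm[1], "' has an empty member list")
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  dup <- names_[duplicated(names_)]
  if (length(dup)) stop("duplicate gene set name: '", dup[1], "'")
  sets <- lapply(fields, function(f) {
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      stop("gene set '", f[1], "' has an empty member list")
    attr(members, "description") <- f[2]
    members
  })
  structure(stats::setNames(sets, names_), class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    d <- attr(s, "description")
    paste(c(nm, if (is.null(d)) "" else d, as.character(s)),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
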