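#' Hypergeometric over-representation of a query gene list
#'
#' For every set in the collection, tests whether the overlap between the
#' query genes and the set (both intersected with the universe first) is
#' larger than expected by chance: the upper-tail hypergeometric
#' probability `P(X >= k)` of drawing `k` or more set members in `n`
#' draws from a universe of `N` genes of which `K` are in the set.
#' Benjamini-Hochberg FDR is computed across the collection. The default
#' universe in the pipeline is the set of all quantified proteins, not
#' the whole genome.
#'
#' @param query character vector of query gene symbols (subset of the
#'   universe; case-insensitive).
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param universe character vector of background gene symbols.
#' @return Tibble of class `enrichment_result`: `set`, `N`, `K`, `n`,
#'   `k`, `p_value`, `fdr`, `overlap_genes` (list column), sorted by
#'   p-value.
#' @export
hypergeom_enrichment <- function(query, collection, universe) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 3), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  res <- purrr::map_dfr(names(collection), function(nm) {
    set <- intersect(toupper(collection[[nm]]), universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, N = N, K = K, n = n, k = k,
                   p_value = p, overlap_genes = list(sort(ov)))
  })
  res <- res |>
    dplyr::mutate(fdr = stats::p.adjust(.data$p_value, "BH")) |>
    dplyr::arrange(.data$p_value, .data$set) |>
    dplyr::select("set", "N", "K", "n", "k", "p_value", "fdr",
                  "overlap_genes")
  structure(res, class = c("enrichment_result", class(res)))
}

#' Rank gene sets by cross-group variability of enrichment
#'
#' Given the same collection tested in several groups (e.g. the regulated
#' proteins at each time point), scores every set by the standard
#' deviation of `-log10(p)` across the groups and sorts descending: the
#' sets whose enrichment differs most between groups rank first. A set
#' missing from a group is treated as unenriched there (p = 1) and
#' flagged. The display convention truncates to the top 30 terms.
#'
#' @param enrichments named list of `enrichment_result` tibbles, one per
#'   group, all from the same collection.
#' @param top_n number of sets retained in `top` (default 30).
#' @return List of class `differential_go_ranking`: `ranking` (tibble
#'   `set`, per-group `-log10(p)` columns, `sd_neg_log10_p`,
#'   `imputed`), `top` (head of the ranking).
#' @export
differential_go_ranking <- function(enrichments, top_n = 30L) {
  stopifnot(is.list(enrichments), length(enrichments) >= 2)
  if (is.null(names(enrichments)))
    names(enrichments) <- paste0("group", seq_along(enrichments))
  all_sets <- sort(unique(unlist(lapply(enrichments, `[[`, "set"))))
  cols <- lapply(enrichments, function(e) {
    p <- stats::setNames(e$p_value, e$set)[all_sets]
    p[is.na(p)] <- 1
    -log10(p)
  })
  mat <- do.call(cbind, cols)
  imputed <- vapply(all_sets, function(s)
    any(vapply(enrichments, function(e) !s %in% e$set, TRUE)), TRUE)
  ranking <- tibble::as_tibble(mat) |>
    dplyr::mutate(set = all_sets,
                  sd_neg_log10_p = unname(apply(mat, 1, stats::sd)),
                  imputed = unname(imputed), .before = 1) |>
    dplyr::arrange(dplyr::desc(.data$sd_neg_log10_p), .data$set)
  structure(list(ranking = ranking,
                 top = utils::head(ranking, top_n)),
            class = "differential_go_ranking")
}
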