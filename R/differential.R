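#' Per-time-point differential phosphorylation test
#'
#' For every p-site with at least `min_pairs` complete replicate pairs at
#' the given time point, computes the mean paired log2 fold change
#' (high minus low glucose) and a two-sided t-test p-value, then calls
#' regulation: a site is regulated iff `p <= alpha` AND `|log2FC| >
#' lfc_threshold`. The fold-change gate means a significant site with
#' |log2FC| at or below the threshold (e.g. 0.25) is *not* called
#' regulated. Degenerate variance is handled explicitly: identical
#' all-zero differences give p = 1 (no change); identical non-zero
#' differences give the smallest representable p with a `degenerate`
#' flag, since the t statistic is unbounded there.
#'
#' The default is the paired test on within-replicate differences;
#' `paired = FALSE` gives Welch's two-sample test on the same data.
#'
#' @param qt a `psite_quant`.
#' @param time time point in minutes.
#' @param alpha significance level.
#' @param lfc_threshold log2 fold-change gate.
#' @param paired paired (default) or Welch unpaired t-test.
#' @param min_pairs minimum complete pairs required to test a row.
#' @return Tibble of class `diff_result`: `psite`, `time`, `log2fc`,
#'   `t_stat`, `p_value`, `p_adj` (Benjamini-Hochberg, informational),
#'   `n_pairs`, `regulated`, `direction` (up/down/none), `degenerate`.
#'   Rows with too few pairs are excluded and listed in the
#'   `excluded` attribute.
#' @export
paired_diff_test <- function(qt, time, alpha = 0.05, lfc_threshold = 0.3,
                             paired = TRUE, min_pairs = 2L) {
  stopifnot(inherits(qt, "psite_quant"))
  fc <- paired_log2fc(qt, time)
  s <- qt$samples
  hi <- qt$values[, s$label[s$condition == "high" & s$time == time],
                  drop = FALSE]
  lo <- qt$values[, s$label[s$condition == "low" & s$time == time],
                  drop = FALSE]
  n_pairs <- rowSums(!is.na(fc))
  testable <- n_pairs >= min_pairs
  excluded <- tibble::tibble(psite = rownames(fc)[!testable],
                             n_pairs = n_pairs[!testable])

  res <- purrr::map_dfr(which(testable), function(i) {
    d <- fc[i, !is.na(fc[i, ])]
    lfc <- mean(d)
    degen <- FALSE
    if (stats::sd(d) == 0) {
      if (lfc == 0) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- list(statistic = sign(lfc) * Inf,
                   p.value = .Machine$double.xmin)
        degen <- TRUE
      }
    } else if (paired) {
      tt <- stats::t.test(d)
    } else {
      tt <- stats::t.test(hi[i, ], lo[i, ], var.equal = FALSE)
    }
    tibble::tibble(psite = rownames(fc)[i], time = time, log2fc = lfc,
                   t_stat = unname(tt$statistic),
                   p_value = tt$p.value, n_pairs = length(d),
                   degenerate = degen)
  })
  if (nrow(res) == 0)
    res <- tibble::tibble(psite = character(), time = numeric(),
                          log2fc = numeric(), t_stat = numeric(),
                          p_value = numeric(), n_pairs = integer(),
                          degenerate = logical())
  res <- res |>
    dplyr::mutate(
      p_adj = stats::p.adjust(.data$p_value, "BH"),
      regulated = .data$p_value <= alpha &
        abs(.data$log2fc) > lfc_threshold,
      direction = dplyr::case_when(
        regulated & log2fc > 0 ~ "up",
        regulated & log2fc < 0 ~ "down",
        TRUE ~ "none"))
  structure(res, class = c("diff_result", class(res)), excluded = excluded)
}

#' Percent change equivalent of a log2 fold-change threshold
#'
#' A log2 fold-change gate of `x` corresponds to a relative change of
#' `100 * (2^x - 1)` percent; the default gate 0.3 is a 23% change.
#'
#' @param lfc_threshold non-negative log2 fold-change threshold.
#' @return Percent change (not rounded).
#' @examples
#' round(lfc_percent_equivalent(0.3)) # 23
#' @export
lfc_percent_equivalent <- function(lfc_threshold) {
  if (!is.numeric(lfc_threshold) || any(lfc_threshold < 0))
    stop("lfc_threshold must be non-negative")
  100 * (2^lfc_threshold - 1)
}

#' Cross-time overlap (Venn) analysis of regulated p-site sets
#'
#' Exact set algebra on the regulated identifiers per time point: per-set
#' sizes, all pairwise intersections, the all-way intersection, the union,
#' and the percentage of the union shared across every time point.
#'
#' @param sets named list (>= 2 elements) of character vectors of p-site
#'   keys regulated at each time.
#' @return List of class `overlap_counts`: `sizes`, `pairwise` (tibble),
#'   `common` (all-way intersection size), `common_keys`, `union_size`,
#'   `pct_shared`.
#' @export
overlap_analysis <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  sizes <- lengths(sets)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(a = p[1], b = p[2],
                   n = length(intersect(sets[[p[1]]], sets[[p[2]]])))
  })
  common_keys <- Reduce(intersect, sets)
  union_keys <- Reduce(union, sets)
  structure(
    list(sizes = sizes, pairwise = pairwise,
         common = length(common_keys),
         common_keys = sort(common_keys),
         union_size = length(union_keys),
         pct_shared = if (length(union_keys))
           100 * length(common_keys) / length(union_keys) else NA_real_),
    class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("<overlap_counts> sizes:",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "),
      "| common:", x$common, "| union:", x$union_size,
      sprintf("| shared: %.1f%%\n", x$pct_shared))
  invisible(x)
}

#' Reconcile p-site regulation with protein-level regulation
#'
#' For one time point, counts the distinct proteins that carry at least one
#' regulated p-site, how many of those are also regulated at the total
#' protein level (same thresholds, non-enriched fraction), and the
#' fraction — the "10/76"-style ratio. Each regulated p-site whose parent
#' protein is itself regulated is annotated protein-confounded, because its
#' apparent phospho-change may reflect abundance change.
#'
#' @param psite_diffs `diff_result` for p-sites at the time point.
#' @param protein_diffs `diff_result` from the protein-level run (its
#'   `psite` column holds protein accessions).
#' @param time time point (informational, carried into the report).
#' @return List of class `reconciliation`: `time`, `n_psite_reg_proteins`,
#'   `n_also_protein_reg`, `fraction` (in percent), `confounded_sites`
#'   (tibble `psite`, `protein`).
#' @export
reconcile_protein_level <- function(psite_diffs, protein_diffs, time) {
  key <- parse_psite_key(psite_diffs$psite)
  acc <- key |> dplyr::distinct(.data$psite, .data$accession)
  reg_sites <- psite_diffs |>
    dplyr::filter(.data$regulated) |>
    dplyr::left_join(acc, by = "psite")
  psite_reg_proteins <- unique(reg_sites$accession)
  protein_reg <- unique(protein_diffs$psite[protein_diffs$regulated])
  both <- intersect(psite_reg_proteins, toupper(protein_reg))
  confounded <- reg_sites |>
    dplyr::filter(.data$accession %in% both) |>
    dplyr::select(psite = "psite", protein = "accession")
  structure(
    list(time = time,
         n_psite_reg_proteins = length(psite_reg_proteins),
         n_also_protein_reg = length(both),
         fraction = if (length(psite_reg_proteins))
           100 * length(both) / length(psite_reg_proteins) else 0,
         confounded_sites = confounded),
    class = "reconciliation")
}

#' Volcano-plot export table
#'
#' @param diffs a `diff_result` for one time point.
#' @param p_cap cap applied to `-log10(p)` when p underflows to 0.
#' @return Tibble `psite`, `log2fc`, `neg_log10_p`, `regulated`,
#'   `direction`, sorted by p-value (most significant first).
#' @export
volcano_table <- function(diffs, p_cap = 300) {
  diffs |>
    dplyr::mutate(
      neg_log10_p = pmin(-log10(pmax(.data$p_value,
                                     .Machine$double.xmin)), p_cap)) |>
    dplyr::arrange(.data$p_value) |>
    dplyr::select("psite", "log2fc", "neg_log10_p", "regulated",
                  "direction")
}
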