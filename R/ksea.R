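#' Build substrate groups by matching quantified p-sites to a database
#'
#' Arranges the quantified p-sites into substrate groups: one group per
#' kinase or phosphatase, containing the dataset p-sites annotated as its
#' substrates. Matching is by uppercase gene symbol plus site position by
#' default (`mode = "gene"`), or by exact accession (`mode =
#' "accession"`). A multi-site feature joins a group when any of its sites
#' matches, contributing a single fold change (no double counting within
#' one group). Optionally, named motif patterns (regular expressions over
#' the amino-acid alphabet, written with the phospho-acceptor last, e.g.
#' `"R.R..[ST]"`) are matched against each p-site's sequence window — a
#' motif matches when some regex match ends exactly at the window centre,
#' i.e. at the phospho-residue.
#'
#' @param qt a `psite_quant` (its `peptide` column is used as the
#'   +/-7-residue window for motif matching).
#' @param ksdb a `ksdb` from [read_ksdb()].
#' @param mode `"gene"` (default) or `"accession"` identifier matching.
#' @param motifs optional named character vector of motif regexes; each
#'   becomes a kinase-class group named after it.
#' @return Tibble of class `substrate_groups` with columns `enzyme`,
#'   `class`, `psite`, `match_mode`; the `coverage` attribute reports
#'   matched and total p-site counts.
#' @export
match_substrates <- function(qt, ksdb, mode = c("gene", "accession"),
                             motifs = NULL) {
  mode <- match.arg(mode)
  if (nrow(ksdb) == 0) stop("empty kinase-substrate database")
  sites <- parse_psite_key(qt$meta$psite) |>
    dplyr::mutate(site = paste0(.data$residue, .data$position)) |>
    dplyr::left_join(dplyr::select(qt$meta, "psite", "gene"),
                     by = "psite")
  db <- tibble::as_tibble(ksdb)
  hits <- if (mode == "gene") {
    dplyr::inner_join(sites, db,
                      by = c(gene = "substrate_gene", site = "site"))
  } else {
    dplyr::inner_join(sites, db,
                      by = c(accession = "substrate_acc", site = "site"))
  }
  hits <- hits |>
    dplyr::distinct(.data$enzyme, .data$class, .data$psite) |>
    dplyr::mutate(match_mode = "db-site")

  if (!is.null(motifs)) {
    stopifnot(!is.null(names(motifs)), all(nzchar(names(motifs))))
    win <- qt$meta$peptide
    center_hit <- function(w, motif) {
      if (is.na(w) || !nzchar(w)) return(FALSE)
      ctr <- (nchar(w) + 1L) %/% 2L
      m <- gregexpr(motif, w)[[1]]
      if (m[1] == -1L) return(FALSE)
      any(m + attr(m, "match.length") - 1L == ctr)
    }
    mot <- purrr::map_dfr(names(motifs), function(nm) {
      sel <- vapply(win, center_hit, TRUE, motif = motifs[[nm]],
                    USE.NAMES = FALSE)
      tibble::tibble(enzyme = nm, class = "kinase",
                     psite = qt$meta$psite[sel], match_mode = "motif")
    })
    hits <- dplyr::bind_rows(hits, mot)
  }
  if (nrow(hits) == 0)
    warning("no p-sites matched the kinase-substrate database")
  structure(hits,
            class = c("substrate_groups", class(hits)),
            coverage = list(matched = length(unique(hits$psite)),
                            total = nrow(qt$meta)))
}

#' KSEA enrichment z-score for one substrate group
#'
#' The kinase-substrate enrichment score of a group of m substrate
#' fold changes s within a background of all quantified fold changes is
#' `z = (mean(s) - mean(all)) * sqrt(m) / sd(all)`: the standardized
#' shift of the group mean away from the dataset mean, with a two-sided
#' normal p-value. A positive z reads as kinase activation (its
#' substrates are hyper-phosphorylated relative to the dataset); for a
#' phosphatase the reading is inverted. The normal p-value neglects the
#' finite-population correction of subset sampling, so it is slightly
#' conservative for small backgrounds; at dataset scale (thousands of
#' quantified sites) it agrees with the permutation law (see
#' [ksea_permutation_p()]).
#'
#' @param group_fcs numeric fold changes of the group members.
#' @param all_fcs numeric fold changes of every quantified p-site in the
#'   same replicate/time (the background; must include the group).
#' @return List: `z`, `p_value`, `m`.
#' @export
ksea_zscore <- function(group_fcs, all_fcs) {
  m <- length(group_fcs)
  if (m == 0) return(list(z = NA_real_, p_value = NA_real_, m = 0L))
  delta <- stats::sd(all_fcs)
  if (!is.finite(delta) || delta == 0) stop("degenerate background")
  z <- (mean(group_fcs) - mean(all_fcs)) * sqrt(m) / delta
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), m = as.integer(m))
}

#' Permutation p-value for a KSEA score
#'
#' Monte-Carlo check of the normal approximation: draws `n_perm` random
#' same-size subsets of the background, scores each, and returns the
#' two-sided permutation p-value `(1 + #{|z*| >= |z|}) / (n_perm + 1)`.
#'
#' @param group_fcs the observed group fold changes.
#' @param all_fcs the background fold changes.
#' @param n_perm number of permutations (>= 1000).
#' @param seed RNG seed (reproducible).
#' @return Permutation p-value.
#' @export
ksea_permutation_p <- function(group_fcs, all_fcs, n_perm = 10000L,
                               seed = 1L) {
  m <- length(group_fcs)
  if (n_perm < 1000) stop("n_perm must be at least 1000")
  if (m >= length(all_fcs))
    stop("group size must be smaller than the background")
  obs <- abs(mean(group_fcs) - mean(all_fcs))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  mu <- mean(all_fcs)
  perm <- vapply(seq_len(n_perm), function(i) {
    abs(mean(all_fcs[sample.int(length(all_fcs), m)]) - mu)
  }, 0)
  (1 + sum(perm >= obs - 1e-15)) / (n_perm + 1)
}

#' Time-resolved KSEA over every replicate
#'
#' Computes the KSEA z-score of every substrate group in every replicate
#' at every time point, using the per-replicate paired log2 fold changes
#' of *all* quantified p-sites as the background. Replicate-averaged
#' enzyme x time scores are assembled into a matrix ordered by
#' complete-linkage hierarchical clustering of the mean profiles, and the
#' top and bottom 30 enzymes by overall mean score are extracted. Scores
#' beyond +/-2 are flagged `highlight`. p-values (and Benjamini-Hochberg
#' adjustment across enzymes within each time/replicate) are reported
#' only for groups with at least two members; groups below `min_m` are
#' excluded and listed.
#'
#' @param qt a `psite_quant`.
#' @param groups a `substrate_groups` tibble.
#' @param min_m minimum group size scored (default 1).
#' @param top_n how many top/bottom enzymes to extract (default 30).
#' @return List of class `ksea_result`: `scores` (long tibble: enzyme,
#'   class, time, replicate, m, z, p_value, p_adj, highlight),
#'   `mean_scores` (tibble enzyme, class, time, z, n_replicates,
#'   highlight), `mean_matrix` (enzyme x time), `row_order`, `top`,
#'   `bottom`, `excluded_enzymes`.
#' @export
ksea_over_time <- function(qt, groups, min_m = 1L, top_n = 30L) {
  times <- sort(unique(qt$samples$time))
  glist <- split(groups$psite, groups$enzyme)
  classes <- groups |> dplyr::distinct(.data$enzyme, .data$class)

  scores <- purrr::map_dfr(times, function(tm) {
    fc <- paired_log2fc(qt, tm)
    purrr::map_dfr(seq_len(ncol(fc)), function(r) {
      bg <- fc[, r]
      bg <- bg[!is.na(bg)]
      purrr::map_dfr(names(glist), function(enz) {
        members <- intersect(unique(glist[[enz]]), names(bg))
        if (length(members) == 0) return(NULL)
        sc <- ksea_zscore(bg[members], bg)
        tibble::tibble(enzyme = enz, time = tm, replicate = r,
                       m = sc$m, z = sc$z,
                       p_value = if (sc$m >= 2) sc$p_value else NA_real_)
      })
    })
  })
  scores <- scores |>
    dplyr::left_join(classes, by = "enzyme") |>
    dplyr::group_by(.data$time, .data$replicate) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(highlight = abs(.data$z) > 2)

  small <- scores |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(m = max(.data$m)) |>
    dplyr::filter(.data$m < min_m)
  scores <- scores |> dplyr::filter(!.data$enzyme %in% small$enzyme)

  mean_scores <- scores |>
    dplyr::group_by(.data$enzyme, .data$class, .data$time) |>
    dplyr::summarise(z = mean(.data$z, na.rm = TRUE),
                     n_replicates = sum(!is.na(.data$z)),
                     .groups = "drop") |>
    dplyr::mutate(highlight = abs(.data$z) > 2)

  mm <- mean_scores |>
    dplyr::select("enzyme", "time", "z") |>
    tidyr::pivot_wider(names_from = "time", values_from = "z") |>
    dplyr::arrange(.data$enzyme)
  mean_matrix <- as.matrix(mm[, -1, drop = FALSE])
  rownames(mean_matrix) <- mm$enzyme

  row_order <- if (nrow(mean_matrix) > 2) {
    stats::hclust(stats::dist(mean_matrix), method = "complete")$order
  } else seq_len(nrow(mean_matrix))

  overall <- rowMeans(mean_matrix, na.rm = TRUE)
  ord <- order(-overall, names(overall))
  top <- names(overall)[utils::head(ord, top_n)]
  bottom <- names(overall)[utils::head(rev(ord), top_n)]

  structure(list(scores = scores, mean_scores = mean_scores,
                 mean_matrix = mean_matrix, row_order = row_order,
                 top = top, bottom = bottom,
                 excluded_enzymes = small$enzyme),
            class = "ksea_result")
}

#' @export
print.ksea_result <- function(x, ...) {
  cat("<ksea_result>", nrow(x$mean_matrix), "enzymes x",
      ncol(x$mean_matrix), "time points;",
      length(x$excluded_enzymes), "excluded (group too small)\n")
  invisible(x)
}

#' Classify enzyme activity trajectories by direction and timing
#'
#' Each enzyme's replicate-mean score profile (with an implicit 0 before
#' stimulation) is classified by its largest-magnitude score change over
#' consecutive time points: the sign of that change gives the direction
#' (positive/negative score movement) and the interval in which it occurs
#' gives the timing (first = early, second = intermediate, third = late).
#' An all-zero profile is "unchanged". The activity interpretation reads a
#' positive direction as activation for kinases and — with the sign
#' inversion — as inhibition for phosphatases, and conversely.
#'
#' @param ksea a `ksea_result`.
#' @return Tibble `enzyme`, `class`, `direction`, `timing`,
#'   `interpreted_activity`.
#' @export
classify_activity_trajectories <- function(ksea) {
  classes <- ksea$mean_scores |> dplyr::distinct(.data$enzyme, .data$class)
  mm <- ksea$mean_matrix
  purrr::map_dfr(rownames(mm), function(enz) {
    prof <- c(0, mm[enz, ])
    cls <- classes$class[classes$enzyme == enz][1]
    if (all(prof == 0)) {
      return(tibble::tibble(enzyme = enz, class = cls,
                            direction = "unchanged",
                            timing = "unchanged",
                            interpreted_activity = "unchanged"))
    }
    steps <- diff(prof)
    j <- which.max(abs(steps))
    dir <- if (steps[j] > 0) "positive" else "negative"
    timing <- c("early", "intermediate", "late")[min(j, 3)]
    act <- if (cls == "phosphatase") {
      if (dir == "positive") "inhibited" else "activated"
    } else {
      if (dir == "positive") "activated" else "inhibited"
    }
    tibble::tibble(enzyme = enz, class = cls, direction = dir,
                   timing = timing, interpreted_activity = act)
  })
}
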