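#' Assemble log2 fold-change trajectories for regulated p-sites
#'
#' Takes the per-time differential results and builds one trajectory per
#' p-site in the union of regulated sites (a site regulated at any single
#' time point is included with its full fold-change vector). Each
#' trajectory is the vector of mean log2 fold changes at the measured
#' times, prepended with an implicit 0 at t = 0: before stimulation the
#' glucose-relative change is zero by construction, and the extra point
#' keeps second-difference measures well defined on a three-point course.
#' Sites missing a fold change at any time point are excluded and listed.
#'
#' An optional `top_n` restricts to the most markedly changed sites,
#' ranked by maximum |log2FC| across time points.
#'
#' @param diffs a `diff_result` tibble covering every time point (rows
#'   for all tested sites, regulated or not).
#' @param top_n optional integer; keep only the `top_n` sites by
#'   max |log2FC|.
#' @param baseline prepend the t = 0 zero baseline (default TRUE).
#' @return A numeric matrix of class `trajectories` (rows = p-sites,
#'   columns = time points) with attributes `times` and `excluded`.
#' @export
build_trajectories <- function(diffs, top_n = NULL, baseline = TRUE) {
  times <- sort(unique(diffs$time))
  reg <- unique(diffs$psite[diffs$regulated])
  if (length(reg) == 0) {
    m <- matrix(numeric(), 0, length(times) + baseline,
                dimnames = list(NULL,
                                c(if (baseline) "0", times)))
    return(structure(m, class = c("trajectories", "matrix"),
                     times = c(if (baseline) 0, times),
                     excluded = tibble::tibble(psite = character(),
                                               reason = character())))
  }
  wide <- diffs |>
    dplyr::filter(.data$psite %in% reg) |>
    dplyr::select("psite", "time", "log2fc") |>
    tidyr::pivot_wider(names_from = "time", values_from = "log2fc") |>
    dplyr::arrange(.data$psite)
  m <- as.matrix(wide[, as.character(times), drop = FALSE])
  rownames(m) <- wide$psite
  complete <- stats::complete.cases(m)
  excluded <- tibble::tibble(
    psite = rownames(m)[!complete],
    reason = "missing log2FC at one or more time points")
  m <- m[complete, , drop = FALSE]
  if (!is.null(top_n) && nrow(m) > top_n) {
    score <- apply(abs(m), 1, max)
    keep <- rownames(m)[order(-score, rownames(m))[seq_len(top_n)]]
    m <- m[sort(keep), , drop = FALSE]
  }
  if (baseline) {
    m <- cbind(`0` = 0, m)
    times <- c(0, times)
  }
  structure(m, class = c("trajectories", "matrix"),
            times = times, excluded = excluded)
}

#' Descriptive measures of a short longitudinal trajectory
#'
#' Scalar descriptors of trajectory shape used as clustering features:
#' level (mean, SD, CV, range), change (total, per unit time, relative to
#' first and mean), linear trend (least-squares slope and its R2), first
#' differences (computed per unit time, i.e. interval slopes) and second
#' differences (differences of consecutive interval slopes; exactly zero
#' for a linear-in-time trajectory), plus ratios relating second- to
#' first-difference magnitudes. Ratios with a zero denominator are
#' returned as `NA` (flagged missing). The `mean_second_diff` measure is
#' computed here but excluded from clustering by default (see
#' [select_informative_measures()]).
#'
#' @param y numeric trajectory values (>= 3 points).
#' @param times matching time grid.
#' @return Named numeric vector of measures.
#' @export
trajectory_measures <- function(y, times) {
  if (length(y) < 3) stop("a trajectory needs at least 3 points")
  stopifnot(length(y) == length(times), all(is.finite(y)))
  dt <- diff(times)
  d1 <- diff(y) / dt          # interval slopes
  d2 <- diff(d1)              # change of slope between intervals
  fit <- stats::lm.fit(cbind(1, times), y)
  slope <- unname(fit$coefficients[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  total <- y[length(y)] - y[1]
  span <- times[length(times)] - times[1]
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(range            = max(y) - min(y),
    mean             = mean(y),
    sd               = stats::sd(y),
    cv               = safe_div(stats::sd(y), abs(mean(y))),
    total_change     = total,
    mean_change_per_time = total / span,
    change_rel_first = safe_div(total, abs(y[1])),
    change_rel_mean  = safe_div(total, abs(mean(y))),
    slope            = slope,
    slope_r2         = r2,
    max_first_diff   = max(d1),
    sd_first_diff    = stats::sd(d1),
    mean_abs_first_diff = mean(abs(d1)),
    max_abs_first_diff  = max(abs(d1)),
    ratio_mean_abs_diff_range = safe_div(mean(abs(d1)), max(y) - min(y)),
    ratio_max_abs_diff_total  = safe_div(max(abs(d1)), abs(total)),
    mean_second_diff     = mean(d2),
    mean_abs_second_diff = mean(abs(d2)),
    max_abs_second_diff  = max(abs(d2)),
    ratio_mean_abs_second_first =
      safe_div(mean(abs(d2)), mean(abs(d1))),
    ratio_max_abs_second_first =
      safe_div(max(abs(d2)), max(abs(d1))))
}

#' Measure matrix for a set of trajectories
#'
#' @param traj a `trajectories` matrix from [build_trajectories()], or any
#'   numeric matrix with a `times` attribute / supplied `times`.
#' @param times time grid (defaults to the `times` attribute).
#' @return Matrix trajectories x measures.
#' @export
trajectory_measure_matrix <- function(traj, times = attr(traj, "times")) {
  stopifnot(!is.null(times))
  t(apply(unclass(traj), 1, trajectory_measures, times = times))
}

#' Select informative trajectory measures by factor analysis
#'
#' Standardizes the measure matrix, drops the excluded measure(s) and any
#' constant or non-finite-ridden columns, extracts principal factors from
#' the correlation matrix, retains those with eigenvalue > 1, applies a
#' varimax rotation, and keeps the single measure with the highest
#' absolute loading on each retained factor. This yields a small set of
#' near-orthogonal shape descriptors for clustering.
#'
#' @param m measure matrix (trajectories x measures).
#' @param exclude measure names excluded up front (default the mean of
#'   second differences).
#' @return Character vector of selected measure names, with the retained
#'   rotated loadings in the `loadings` attribute.
#' @export
select_informative_measures <- function(m,
                                        exclude = "mean_second_diff") {
  m <- m[, setdiff(colnames(m), exclude), drop = FALSE]
  usable <- apply(m, 2, function(x) {
    x <- x[is.finite(x)]
    length(x) == nrow(m) && stats::sd(x) > 0
  })
  m <- m[, usable, drop = FALSE]
  if (ncol(m) == 0) stop("no variance to factor")
  if (ncol(m) == 1) return(colnames(m))
  z <- scale(m)
  ev <- eigen(stats::cor(z), symmetric = TRUE)
  nf <- sum(ev$values > 1)
  if (nf == 0) nf <- 1
  load <- ev$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(nf)]), nf)
  if (nf > 1) load <- varimax_best(load)$loadings
  load <- matrix(as.numeric(load), ncol(m), nf,
                 dimnames = list(colnames(m), paste0("F", seq_len(nf))))
  picked <- character(0)
  for (j in seq_len(nf)) {
    ord <- order(-abs(load[, j]))
    cand <- colnames(m)[ord]
    cand <- setdiff(cand, picked)
    if (length(cand)) picked <- c(picked, cand[1])
  }
  structure(picked, loadings = load)
}

#' Factor scores of the trajectory measures
#'
#' Projects the standardized measure matrix onto the retained principal
#' factors (eigenvalue > 1) and applies the varimax rotation to the
#' scores, yielding one score column per factor. These factor scores are
#' the clustering features used by the pipeline: they aggregate each
#' block of correlated measures into a single denoised axis, which
#' separates the kinetic archetypes more reliably than any single
#' representative measure (see the methods vignette).
#'
#' @inheritParams select_informative_measures
#' @return Numeric matrix (trajectories x retained factors) with the
#'   rotated loadings in the `loadings` attribute.
#' @export
trajectory_factor_scores <- function(m, exclude = "mean_second_diff") {
  m <- m[, setdiff(colnames(m), exclude), drop = FALSE]
  usable <- apply(m, 2, function(x) {
    x <- x[is.finite(x)]
    length(x) == nrow(m) && stats::sd(x) > 0
  })
  m <- m[, usable, drop = FALSE]
  if (ncol(m) == 0) stop("no variance to factor")
  z <- scale(m)
  if (ncol(m) == 1) {
    return(structure(z, loadings = matrix(1, 1, 1,
                                          dimnames = list(colnames(m),
                                                          "F1"))))
  }
  ev <- eigen(stats::cor(z), symmetric = TRUE)
  nf <- max(1L, sum(ev$values > 1))
  scores <- z %*% ev$vectors[, seq_len(nf), drop = FALSE]
  load <- ev$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(nf)]), nf)
  if (nf > 1) {
    rot <- varimax_best(load)
    load <- rot$loadings
    scores <- scores %*% rot$rotmat
  }
  load <- matrix(as.numeric(load), ncol(m), nf,
                 dimnames = list(colnames(m), paste0("F", seq_len(nf))))
  dimnames(scores) <- list(rownames(m), colnames(load))
  structure(scores, loadings = load)
}

#' Cluster trajectories by k-medoids under the 1-norm
#'
#' Partitions trajectories into `k` kinetic archetypes by k-medoids (PAM)
#' on the standardized selected measures under the Manhattan (1-norm)
#' distance. On top of the deterministic PAM build, `restarts` random
#' initial-medoid restarts are tried under a fixed seed and the solution
#' with the lowest total within-cluster cost is kept, so reruns with the
#' same seed are bit-identical.
#'
#' @param m measure matrix (trajectories x measures); typically the
#'   columns chosen by [select_informative_measures()].
#' @param k number of clusters (2 <= k <= n).
#' @param seed RNG seed for the restarts.
#' @param restarts number of random restarts (default 50).
#' @return List of class `trajectory_clusters`: `assignments` (named
#'   integer vector), `medoids` (row names), `sizes`, `k`, `measures`
#'   (column names used), `cost`.
#' @export
cluster_trajectories <- function(m, k, seed = 1L, restarts = 50L) {
  n <- nrow(m)
  if (k > n) stop("k must not exceed the number of trajectories")
  z <- scale(m)
  z[, attr(z, "scaled:scale") == 0] <- 0
  d <- stats::dist(z, method = "manhattan")
  if (k == n) {
    assign <- stats::setNames(seq_len(n), rownames(m))
    return(structure(list(assignments = assign, medoids = rownames(m),
                          sizes = rep(1L, n), k = k,
                          measures = colnames(m), cost = 0),
                     class = "trajectory_clusters"))
  }
  best <- cluster::pam(d, k = k, do.swap = TRUE)
  best_cost <- best$objective[["swap"]]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_len(restarts)) {
    init <- sample.int(n, k)
    fit <- cluster::pam(d, k = k, medoids = init, do.swap = TRUE)
    if (fit$objective[["swap"]] < best_cost - 1e-12) {
      best <- fit
      best_cost <- fit$objective[["swap"]]
    }
  }
  structure(
    list(assignments = stats::setNames(best$clustering, rownames(m)),
         medoids = rownames(m)[best$id.med],
         sizes = as.integer(table(best$clustering)),
         k = k, measures = colnames(m), cost = best_cost),
    class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat("<trajectory_clusters> k =", x$k, "| sizes:",
      paste(x$sizes, collapse = ", "), "| cost:",
      format(x$cost, digits = 4), "\n")
  invisible(x)
}

#' Label clusters with kinetic archetypes
#'
#' Assigns each cluster one of the four published kinetic classes from its
#' mean trajectory. Timing is the onset: the first time point at which the
#' mean |value| reaches 50% of its peak magnitude (first = early, second =
#' intermediate, third = late). An early cluster whose final value has
#' returned within 50% of the peak magnitude is "early-transient",
#' otherwise "early-sustained". The sign of the value at onset gives the
#' direction (up/down). An onset threshold on values rather than on steps
#' keeps transient profiles (whose recovery step rivals the onset step)
#' classified as early.
#'
#' @param traj a `trajectories` matrix (with the t = 0 baseline).
#' @param clusters a `trajectory_clusters` fit on (a subset of) its rows.
#' @return Tibble `cluster`, `archetype`, `direction`, `n`.
#' @export
label_archetypes <- function(traj, clusters) {
  times <- attr(traj, "times")
  purrr::map_dfr(seq_len(clusters$k), function(cl) {
    ids <- names(clusters$assignments)[clusters$assignments == cl]
    mt <- colMeans(unclass(traj)[ids, , drop = FALSE])
    peak <- max(abs(mt))
    onset <- which(abs(mt) >= 0.5 * peak)[1]  # index on the full grid
    lab <- if (onset <= 2) {
      if (abs(mt[length(mt)]) < 0.5 * peak) "early-transient"
      else "early-sustained"
    } else if (onset == length(mt)) "late" else "intermediate"
    tibble::tibble(cluster = cl, archetype = lab,
                   direction = if (mt[onset] > 0) "up" else "down",
                   n = length(ids))
  })
}

#' Heatmap row ordering by Gower/Manhattan complete linkage
#'
#' Computes pairwise Gower dissimilarities (which for all-quantitative
#' input reduce to the Manhattan metric after per-variable range scaling;
#' zero-range variables are dropped), clusters rows by complete-linkage
#' hierarchical clustering, and returns the leaf order. Subtree
#' orientation is canonicalized by the leaves' dissimilarity row sums
#' (ties broken by row id), so the ordering is a function of the
#' dissimilarity matrix alone: permuting the input rows permutes the
#' ordering consistently.
#'
#' @param m numeric matrix (rows to order); missing values allowed (Gower
#'   handles them pairwise).
#' @return Integer vector: the row indices in display order.
#' @export
order_for_heatmap <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 1) return(1L)
  rng <- apply(m, 2, function(x) diff(range(x, na.rm = TRUE)))
  m2 <- m[, rng > 0 | !is.finite(rng), drop = FALSE]
  if (ncol(m2) == 0) return(seq_len(nrow(m)))
  d <- cluster::daisy(as.data.frame(m2), metric = "gower")
  h <- stats::hclust(d, method = "complete")
  rs <- rowSums(as.matrix(d))
  node_leaves <- vector("list", nrow(h$merge))
  side <- function(j) if (j < 0) -j else node_leaves[[j]]
  for (i in seq_len(nrow(h$merge))) {
    a <- side(h$merge[i, 1])
    b <- side(h$merge[i, 2])
    flip <- min(rs[b]) < min(rs[a]) ||
      (min(rs[b]) == min(rs[a]) && min(b) < min(a))
    node_leaves[[i]] <- if (flip) c(b, a) else c(a, b)
  }
  node_leaves[[nrow(h$merge)]]
}
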