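test_that("trajectory assembly follows the union rule and top-n ranking", {
  mk <- function(psite, fcs, reg) {
    tibble::tibble(psite = psite, time = c(5, 30, 60), log2fc = fcs,
                   t_stat = 0, p_value = ifelse(reg, 0.01, 0.5),
                   n_pairs = 5L, degenerate = FALSE, p_adj = 1,
                   regulated = reg,
                   direction = ifelse(reg, "up", "none"))
  }
  diffs <- dplyr::bind_rows(
    mk("AAA1_S1", c(0.1, 0.1, 0.9), c(FALSE, FALSE, TRUE)),  # late only
    mk("BBB2_S2", c(0.5, 0.5, 0.5), c(TRUE, TRUE, TRUE)),
    mk("CCC3_S3", c(0, 0, 0.1), c(FALSE, FALSE, FALSE)))     # never reg
  tr <- build_trajectories(diffs)
  expect_setequal(rownames(tr), c("AAA1_S1", "BBB2_S2"))
  expect_equal(attr(tr, "times"), c(0, 5, 30, 60))
  expect_equal(unclass(tr)["AAA1_S1", ], c(`0` = 0, `5` = 0.1,
                                           `30` = 0.1, `60` = 0.9))
  # top-n selection by max |log2FC|
  tr1 <- build_trajectories(diffs, top_n = 1)
  expect_equal(rownames(tr1), "AAA1_S1")  # max |FC| 0.9 > 0.5
  # empty when nothing is regulated
  tr0 <- build_trajectories(mk("CCC3_S3", c(0, 0, 0.1), rep(FALSE, 3)))
  expect_equal(nrow(tr0), 0)
})

test_that("top-n selection matches an independent sort oracle", {
  set.seed(5)
  n <- 20
  fcs <- matrix(rnorm(n * 3), n)
  ids <- sprintf("SITE%02d_S1", 1:n)
  diffs <- purrr::map_dfr(1:n, function(i)
    tibble::tibble(psite = ids[i], time = c(5, 30, 60),
                   log2fc = fcs[i, ], t_stat = 0, p_value = 0.01,
                   n_pairs = 5L, degenerate = FALSE, p_adj = 1,
                   regulated = TRUE, direction = "up"))
  expected <- ids[order(-apply(abs(fcs), 1, max))][1:10]
  tr <- build_trajectories(diffs, top_n = 10)
  expect_setequal(rownames(tr), expected)
})

test_that("measures behave on constant and linear trajectories", {
  times <- c(0, 5, 30, 60)
  m_const <- trajectory_measures(rep(2, 4), times)
  expect_equal(m_const[["range"]], 0)
  expect_equal(m_const[["sd"]], 0)
  expect_equal(m_const[["slope"]], 0)
  expect_equal(m_const[["mean_abs_first_diff"]], 0)
  expect_equal(m_const[["mean_second_diff"]], 0)
  expect_equal(m_const[["mean"]], 2)

  # strictly linear in time: all second differences exactly zero
  m_lin <- trajectory_measures(0.05 * times + 1, times)
  expect_equal(m_lin[["mean_second_diff"]], 0)
  expect_equal(m_lin[["mean_abs_second_diff"]], 0)
  expect_equal(m_lin[["slope"]], 0.05)
  expect_equal(m_lin[["slope_r2"]], 1)

  expect_error(trajectory_measures(c(1, 2), c(0, 5)), "at least 3")
})

test_that("least-squares slope equals the normal-equation oracle", {
  y <- c(0, 0.8, 0.9, 1.0)
  t <- c(0, 5, 30, 60)
  m <- trajectory_measures(y, t)
  beta <- solve(t(cbind(1, t)) %*% cbind(1, t),
                t(cbind(1, t)) %*% y)
  expect_equal(m[["slope"]], beta[2], tolerance = 1e-12)
})

test_that("measures are translation-consistent", {
  set.seed(3)
  times <- c(0, 5, 30, 60)
  for (i in 1:10) {
    y <- rnorm(4)
    a <- trajectory_measures(y, times)
    b <- trajectory_measures(y + 3, times)
    for (nm in c("range", "sd", "slope", "total_change",
                 "mean_abs_first_diff", "max_abs_second_diff",
                 "mean_second_diff"))
      expect_equal(b[[nm]], a[[nm]], tolerance = 1e-12)
    expect_equal(b[["mean"]], a[["mean"]] + 3, tolerance = 1e-12)
  }
})

test_that("measure selection keeps one representative per correlated block", {
  set.seed(21)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  # two independent blocks of internally near-duplicate measures
  m <- cbind(a1 = f1, a2 = f1 + rnorm(n, 0, 0.01),
             a3 = f1 + rnorm(n, 0, 0.01),
             b1 = f2, b2 = f2 + rnorm(n, 0, 0.01))
  sel <- select_informative_measures(m, exclude = character(0))
  expect_length(sel, 2)
  expect_equal(sort(substr(sel, 1, 1)), c("a", "b"))
})

test_that("measure selection handles degenerate inputs", {
  m <- cbind(only = rnorm(10), flat = rep(1, 10))
  expect_equal(select_informative_measures(m, exclude = character(0)),
               "only")
  expect_error(select_informative_measures(
    cbind(flat = rep(1, 10)), exclude = character(0)), "no variance")
})

test_that("the mean of second differences is excluded by default", {
  tr <- generate_archetype_trajectories(n_per_archetype = 10, seed = 2)
  mm <- trajectory_measure_matrix(tr)
  expect_true("mean_second_diff" %in% colnames(mm))
  sel <- select_informative_measures(mm)
  expect_false("mean_second_diff" %in% sel)
})

test_that("two well-separated archetypes are recovered exactly at k = 2", {
  tr <- generate_archetype_trajectories(n_per_archetype = 15,
                                        effect_size = 1,
                                        noise_sd = 0.02, seed = 4)
  keep <- attr(tr, "truth") %in% c("early-sustained", "late")
  m <- trajectory_measure_matrix(structure(
    unclass(tr)[keep, ], times = attr(tr, "times")))
  sel <- select_informative_measures(m)
  fit <- cluster_trajectories(m[, sel, drop = FALSE], k = 2, seed = 1)
  ari <- adjusted_rand_index(fit$assignments, attr(tr, "truth")[keep])
  expect_equal(ari, 1)
})

test_that("k = n yields singletons and the same seed reproduces bits", {
  tr <- generate_archetype_trajectories(n_per_archetype = 3, seed = 9)
  m <- trajectory_measure_matrix(tr)
  sel <- select_informative_measures(m)
  n <- nrow(m)
  fit_n <- cluster_trajectories(m[, sel, drop = FALSE], k = n)
  expect_equal(sort(unique(fit_n$assignments)), 1:n)
  expect_error(cluster_trajectories(m[, sel, drop = FALSE], k = n + 1),
               "exceed")
  a <- cluster_trajectories(m[, sel, drop = FALSE], k = 4, seed = 11)
  b <- cluster_trajectories(m[, sel, drop = FALSE], k = 4, seed = 11)
  expect_identical(a, b)
})

test_that("factor scores aggregate measures with one axis per block", {
  set.seed(22)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- cbind(a1 = f1, a2 = f1 + rnorm(n, 0, 0.05),
             b1 = f2, b2 = f2 + rnorm(n, 0, 0.05))
  sc <- trajectory_factor_scores(m, exclude = character(0))
  expect_equal(ncol(sc), 2)
  # each score column tracks one latent factor almost perfectly
  cors <- abs(cor(cbind(f1, f2), sc))
  expect_true(all(apply(cors, 1, max) > 0.99))
  expect_error(trajectory_factor_scores(cbind(flat = rep(1, 10)),
                                        exclude = character(0)),
               "no variance")
})

test_that("planted archetypes are recovered with ARI >= 0.9 over 20 seeds", {
  # trajectory-level noise at one tenth of the planted effect
  aris <- vapply(1:20, function(s) {
    tr <- generate_archetype_trajectories(n_per_archetype = 12,
                                          effect_size = 1,
                                          noise_sd = 0.1, seed = s)
    sc <- trajectory_factor_scores(trajectory_measure_matrix(tr))
    fit <- cluster_trajectories(sc, k = 4, seed = s)
    adjusted_rand_index(fit$assignments, attr(tr, "truth"))
  }, 0)
  expect_gte(mean(aris), 0.9)
})

test_that("archetype labels map one-to-one onto the four kinetic classes", {
  tr <- generate_archetype_trajectories(n_per_archetype = 12,
                                        effect_size = 1,
                                        noise_sd = 0.05, seed = 6)
  sc <- trajectory_factor_scores(trajectory_measure_matrix(tr))
  fit <- cluster_trajectories(sc, k = 4, seed = 1)
  labels <- label_archetypes(tr, fit)
  expect_setequal(labels$archetype,
                  c("early-sustained", "early-transient",
                    "intermediate", "late"))
  # each cluster's label equals its members' planted archetype
  truth <- attr(tr, "truth")
  for (cl in 1:4) {
    members <- names(fit$assignments)[fit$assignments == cl]
    planted <- unique(truth[match(members, rownames(tr))])
    expect_length(planted, 1)
    expect_equal(labels$archetype[labels$cluster == cl], planted)
  }
})

test_that("heatmap ordering matches a brute-force Gower/complete oracle", {
  set.seed(14)
  m <- matrix(rnorm(8 * 3), 8)
  d_pkg <- as.matrix(cluster::daisy(as.data.frame(m), metric = "gower"))
  d_oracle <- brute_gower(m)
  expect_equal(unname(d_pkg), d_oracle, tolerance = 1e-12)
  h <- stats::hclust(stats::as.dist(d_oracle), method = "complete")
  oracle <- brute_complete_linkage(d_oracle)
  expect_equal(sort(h$height), sort(oracle$heights), tolerance = 1e-12)
  ord <- order_for_heatmap(m)
  expect_setequal(ord, 1:8)
  # ordered dissimilarity: identical rows must end up adjacent
  m2 <- rbind(m, m[3, ])
  ord2 <- order_for_heatmap(m2)
  expect_equal(abs(which(ord2 == 3) - which(ord2 == 9)), 1)
})

test_that("heatmap ordering ignores constant columns and permutes consistently", {
  set.seed(15)
  m <- matrix(rnorm(6 * 4), 6)
  expect_equal(order_for_heatmap(cbind(m, 5)), order_for_heatmap(m))
  expect_equal(order_for_heatmap(m[1, , drop = FALSE]), 1L)
  # permuting input rows permutes the ordering consistently
  p <- sample(6)
  ord_a <- order_for_heatmap(m)
  ord_b <- order_for_heatmap(m[p, ])
  expect_equal(p[ord_b], ord_a)
})
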