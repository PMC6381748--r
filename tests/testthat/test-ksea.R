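test_that("substrate matching joins by gene+site and motif at the centre", {
  peptides <- c("AAAAAAASAAAAAAA",   # plain centre S
                "AARGRDQSFAAAAAA")   # matches R.R..[ST] ending at centre
  qt <- make_quant(list(
    GSKB1_S9 = stats::setNames(c(1:5, 2:6),
                               c(paste0("low_5_r", 1:5),
                                 paste0("high_5_r", 1:5))),
    TARG2_S50 = stats::setNames(c(1:5, 2:6),
                                c(paste0("low_5_r", 1:5),
                                  paste0("high_5_r", 1:5)))),
    genes = c("GSK3B", "TARGET2"), peptides = peptides)
  db <- tibble::tibble(enzyme = "AKT1", class = "kinase",
                       substrate_gene = "GSK3B",
                       substrate_acc = "GSKB1",
                       site = "S9", window = NA_character_)
  groups <- match_substrates(qt, db)
  expect_equal(groups$psite[groups$enzyme == "AKT1"], "GSKB1_S9")
  expect_equal(attr(groups, "coverage"),
               list(matched = 1L, total = 2L))

  with_motif <- match_substrates(qt, db,
                                 motifs = c(PKA_MOTIF = "R.R..[ST]"))
  expect_equal(with_motif$psite[with_motif$enzyme == "PKA_MOTIF"],
               "TARG2_S50")
  expect_equal(unique(
    with_motif$match_mode[with_motif$enzyme == "PKA_MOTIF"]), "motif")
  # accession mode
  acc_groups <- match_substrates(qt, db, mode = "accession")
  expect_equal(acc_groups$psite, "GSKB1_S9")
})

test_that("KSEA z-score matches its formula and trivial identities", {
  # group mean equals background mean -> z = 0, p = 1
  bg <- c(1, 0, 0, 0, -1)
  sc <- ksea_zscore(c(0, 0), bg)
  expect_equal(sc$z, 0)
  expect_equal(sc$p_value, 1)
  # the full background as a group has z = 0 exactly
  expect_equal(ksea_zscore(bg, bg)$z, 0)

  set.seed(31)
  all <- rnorm(200)
  g <- all[1:10] + 0  # subset of background
  sc <- ksea_zscore(g, all)
  expect_equal(sc$z, (mean(g) - mean(all)) * sqrt(10) / sd(all),
               tolerance = 1e-12)
  expect_equal(sc$p_value, 2 * pnorm(-abs(sc$z)), tolerance = 1e-12)
  expect_equal(sc$m, 10L)
  expect_error(ksea_zscore(c(1, 1), rep(2, 5)), "degenerate background")
})

test_that("KSEA z is invariant under affine fold-change transforms", {
  set.seed(32)
  all <- rnorm(300)
  idx <- sample(300, 15)
  z0 <- ksea_zscore(all[idx], all)$z
  for (c_shift in c(-2, 0.5)) {
    expect_equal(ksea_zscore(all[idx] + c_shift, all + c_shift)$z, z0,
                 tolerance = 1e-10)
  }
  for (lambda in c(0.2, 7)) {
    expect_equal(ksea_zscore(lambda * all[idx], lambda * all)$z, z0,
                 tolerance = 1e-10)
  }
})

test_that("permutation p is seed-reproducible and near 1 for null groups", {
  set.seed(33)
  all <- rnorm(400)
  g <- all[1:20]
  p1 <- ksea_permutation_p(g, all, n_perm = 2000, seed = 5)
  p2 <- ksea_permutation_p(g, all, n_perm = 2000, seed = 5)
  expect_identical(p1, p2)
  # a z = 0 group: permutation p ~ 1
  sym <- c(-(1:50) / 10, (1:50) / 10)
  g0 <- c(-0.1, 0.1)  # mean equal to background mean
  p0 <- ksea_permutation_p(g0, sym, n_perm = 2000, seed = 1)
  expect_gt(p0, 0.9)
  expect_error(ksea_permutation_p(all, all, 2000, 1), "smaller")
  expect_error(ksea_permutation_p(g, all, n_perm = 10), "1000")
})

test_that("normal p agrees with the permutation law at dataset scale", {
  for (s in 1:3) {
    set.seed(s)
    all <- c(rnorm(2990), rnorm(10) + 0.8)
    g <- all[2991:3000]
    sc <- ksea_zscore(g, all)
    pp <- ksea_permutation_p(g, all, n_perm = 1e5, seed = s)
    se <- sqrt(max(pp, 1 / 1e5) * (1 - pp) / 1e5)
    expect_lt(abs(sc$p_value - pp), 3 * se)
  }
})

test_that("background exclusion of one site moves z only O(1/N)", {
  set.seed(34)
  all <- rnorm(500)
  g <- all[1:10]
  z_full <- ksea_zscore(g, all)$z
  z_minus <- ksea_zscore(g, all[-500])$z
  expect_lt(abs(z_full - z_minus), 10 / length(all))
})

test_that("time-resolved KSEA averages replicates and flags extremes", {
  d <- generate_phospho_dataset(n_sites = 120, n_enzymes = 4,
                                m_per_enzyme = 10, seed = 41)
  groups <- match_substrates(d$quant, d$ksdb)
  ks <- ksea_over_time(d$quant, groups)
  # averaged entry equals the arithmetic mean of replicate z-scores
  for (enz in rownames(ks$mean_matrix)) {
    for (tm in colnames(ks$mean_matrix)) {
      reps <- ks$scores$z[ks$scores$enzyme == enz &
                            ks$scores$time == as.numeric(tm)]
      expect_equal(ks$mean_matrix[enz, tm], mean(reps),
                   tolerance = 1e-12)
    }
  }
  expect_equal(ks$mean_scores$highlight,
               abs(ks$mean_scores$z) > 2)
  # planted direction shows in the replicate-mean z at 60 min
  # (all four archetypes are active at 60 except early-transient)
  truth <- d$truth$enzymes
  active <- truth[truth$archetype != "early-transient", ]
  z60 <- ks$mean_matrix[active$enzyme, "60"]
  expect_true(all(sign(z60) == sign(active$substrate_shift)))
})

test_that("single-replicate KSEA mean equals the per-replicate score", {
  d <- generate_phospho_dataset(n_sites = 80, n_enzymes = 2,
                                m_per_enzyme = 8, replicates = 1,
                                seed = 42)
  groups <- match_substrates(d$quant, d$ksdb)
  ks <- ksea_over_time(d$quant, groups)
  expect_equal(unname(ks$mean_matrix["ENZ01", ]),
               ks$scores$z[ks$scores$enzyme == "ENZ01"])
})

test_that("planted enzyme directions are recovered in >= 95% of runs", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    d <- generate_phospho_dataset(n_sites = 150, n_enzymes = 4,
                                  m_per_enzyme = 10,
                                  effect_size = 0.8, noise_sd = 0.2,
                                  replicates = 5, seed = s)
    groups <- match_substrates(d$quant, d$ksdb)
    ks <- ksea_over_time(d$quant, groups)
    truth <- d$truth$enzymes
    # judge each enzyme at a time its archetype is active
    judge_time <- c("early-sustained" = "5", "early-transient" = "5",
                    "intermediate" = "30", "late" = "60")
    for (e in seq_len(nrow(truth))) {
      z <- ks$mean_matrix[truth$enzyme[e],
                          judge_time[[truth$archetype[e]]]]
      total <- total + 1
      if (sign(z) == sign(truth$substrate_shift[e])) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("activity classes follow direction, timing and enzyme class", {
  mk_ksea <- function(profiles, classes) {
    mm <- do.call(rbind, profiles)
    colnames(mm) <- c("5", "30", "60")
    ms <- purrr::imap_dfr(profiles, function(p, nm)
      tibble::tibble(enzyme = nm, class = classes[[nm]],
                     time = c(5, 30, 60), z = p,
                     n_replicates = 5, highlight = abs(p) > 2))
    structure(list(mean_matrix = mm, mean_scores = ms),
              class = "ksea_result")
  }
  ks <- mk_ksea(list(K1 = c(3, 3, 3), K2 = c(0, -0.2, -3),
                     P1 = c(-3, -3, -3), K3 = c(0, 0, 0)),
                c(K1 = "kinase", K2 = "kinase",
                  P1 = "phosphatase", K3 = "kinase"))
  cls <- classify_activity_trajectories(ks)
  expect_equal(cls[cls$enzyme == "K1", ]$direction, "positive")
  expect_equal(cls[cls$enzyme == "K1", ]$timing, "early")
  expect_equal(cls[cls$enzyme == "K1", ]$interpreted_activity,
               "activated")
  expect_equal(cls[cls$enzyme == "K2", ]$direction, "negative")
  expect_equal(cls[cls$enzyme == "K2", ]$timing, "late")
  # strongly negative phosphatase scores read as activation
  expect_equal(cls[cls$enzyme == "P1", ]$interpreted_activity,
               "activated")
  expect_equal(cls[cls$enzyme == "K3", ]$direction, "unchanged")
})
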