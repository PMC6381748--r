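#' Generate a ground-truthed synthetic phosphoproteomic dataset
#'
#' Emulates the study design: a paired two-condition (resting 2.5 vs
#' stimulating 16.7 mM glucose), three-time-point (5/30/60 min),
#' five-replicate TMT-style log2-intensity table with planted
#' kinase/phosphatase-driven effects, trajectory-archetype structure and
#' additive Gaussian log-scale noise. Enzymes are assigned disjoint
#' substrate groups of `m_per_enzyme` sites; each enzyme carries one of
#' the four kinetic archetypes (early-sustained, early-transient,
#' intermediate, late) and a direction, realized as a piecewise-constant
#' effect over the time grid. All other sites are null. For each
#' replicate, the high-glucose value is the low-glucose value plus the
#' archetype effect at that time plus `N(0, noise_sd)`, so paired
#' differences of null sites are exactly Gaussian. A configurable
#' fraction of regulated proteins also receives the effect at the total
#' protein level (abundance-confounded sites). Output is deterministic
#' given the seed.
#'
#' @param n_sites total number of p-sites.
#' @param n_enzymes number of planted enzymes (alternating
#'   kinase/phosphatase classes and up/down substrate shifts, cycling
#'   through the four archetypes).
#' @param m_per_enzyme substrate-group size; `n_enzymes * m_per_enzyme`
#'   must not exceed `n_sites`.
#' @param effect_size absolute planted log2 effect.
#' @param noise_sd SD of the additive log2 noise on paired differences.
#' @param replicates paired replicates per condition.
#' @param times time grid in minutes.
#' @param protein_coreg_fraction fraction of enzyme-regulated proteins
#'   whose total protein level is also shifted.
#' @param seed RNG seed.
#' @return List: `quant` (a `psite_quant`), `protein` (a protein-level
#'   `psite_quant`, rows keyed by accession), `ksdb` (matching `ksdb`
#'   tibble), `truth` (list with `enzymes`, `sites` tibbles and the
#'   generator parameters).
#' @export
generate_phospho_dataset <- function(n_sites = 300L,
                                     n_enzymes = 8L,
                                     m_per_enzyme = 10L,
                                     effect_size = 0.8,
                                     noise_sd = 0.2,
                                     replicates = 5L,
                                     times = c(5, 30, 60),
                                     protein_coreg_fraction = 0.15,
                                     seed = 1L) {
  if (n_enzymes * m_per_enzyme > n_sites)
    stop("m_per_enzyme * n_enzymes exceeds n_sites")
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  archetypes <- c("early-sustained", "early-transient",
                  "intermediate", "late")
  profile_of <- function(arch) {
    switch(arch,
           "early-sustained" = c(1, 1, 1),
           "early-transient" = c(1, 0, 0),
           "intermediate"    = c(0, 1, 1),
           "late"            = c(0, 0, 1))
  }
  enz <- tibble::tibble(
    enzyme = sprintf("ENZ%02d", seq_len(n_enzymes)),
    class = rep_len(c("kinase", "phosphatase"), n_enzymes),
    archetype = rep_len(archetypes, n_enzymes),
    direction = rep_len(c("up", "down"), n_enzymes),
    substrate_shift = effect_size *
      ifelse(rep_len(c("up", "down"), n_enzymes) == "up", 1, -1))

  acc <- sprintf("SYN%04d", seq_len(n_sites))
  pos <- sample(10:900, n_sites, replace = TRUE)
  res <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                prob = c(0.8, 0.15, 0.05))
  psites <- paste0(acc, "_", res, pos)
  genes <- sprintf("GENE%04d", seq_len(n_sites))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  windows <- vapply(seq_len(n_sites), function(i) {
    w <- sample(aa, 15, replace = TRUE)
    w[8] <- res[i]
    paste(w, collapse = "")
  }, "")

  site_enzyme <- rep(NA_character_, n_sites)
  member_idx <- seq_len(n_enzymes * m_per_enzyme)
  site_enzyme[member_idx] <- rep(enz$enzyme, each = m_per_enzyme)
  effect_mat <- matrix(0, n_sites, length(times))
  for (e in seq_len(n_enzymes)) {
    rows <- which(site_enzyme == enz$enzyme[e])
    effect_mat[rows, ] <- rep(enz$substrate_shift[e] *
                                profile_of(enz$archetype[e]),
                              each = length(rows))
  }

  samples <- tidyr::expand_grid(condition = c("low", "high"),
                                time = times,
                                replicate = seq_len(replicates)) |>
    dplyr::mutate(label = paste0(.data$condition, "_", .data$time,
                                 "_r", .data$replicate)) |>
    dplyr::select("label", "condition", "time", "replicate")

  base <- stats::rnorm(n_sites, 20, 1)
  vals <- matrix(NA_real_, n_sites, nrow(samples))
  # fill low columns first so high columns can reference their pair
  ord <- order(samples$condition != "low")
  for (j in ord) {
    tm_i <- match(samples$time[j], times)
    if (samples$condition[j] == "low") {
      vals[, j] <- base + stats::rnorm(n_sites, 0, 0.5)
    } else {
      lo_j <- which(samples$condition == "low" &
                      samples$time == samples$time[j] &
                      samples$replicate == samples$replicate[j])
      vals[, j] <- vals[, lo_j] + effect_mat[, tm_i] +
        stats::rnorm(n_sites, 0, noise_sd)
    }
  }

  meta <- tibble::tibble(psite = psites, protein = acc, gene = genes,
                         loc_prob = stats::runif(n_sites, 0.95, 1),
                         peptide = windows)
  quant <- psite_quant(meta, vals, samples)

  # protein-level table: every accession, a chosen fraction of the
  # enzyme-regulated ones co-shifted at the protein level
  reg_prot <- unique(acc[!is.na(site_enzyme)])
  n_coreg <- round(protein_coreg_fraction * length(reg_prot))
  coreg <- if (n_coreg > 0) sample(reg_prot, n_coreg) else character(0)
  prot_effect <- matrix(0, n_sites, length(times))
  prot_effect[acc %in% coreg, ] <- effect_mat[acc %in% coreg, ]
  pvals <- matrix(NA_real_, n_sites, nrow(samples))
  for (j in ord) {
    tm_i <- match(samples$time[j], times)
    if (samples$condition[j] == "low") {
      pvals[, j] <- base + stats::rnorm(n_sites, 0, 0.5)
    } else {
      lo_j <- which(samples$condition == "low" &
                      samples$time == samples$time[j] &
                      samples$replicate == samples$replicate[j])
      pvals[, j] <- pvals[, lo_j] + prot_effect[, tm_i] +
        stats::rnorm(n_sites, 0, noise_sd)
    }
  }
  pmeta <- tibble::tibble(psite = acc, protein = acc, gene = genes,
                          loc_prob = 1, peptide = NA_character_)
  protein <- psite_quant(pmeta, pvals, samples)

  member <- !is.na(site_enzyme)
  ksdb <- tibble::tibble(
    enzyme = site_enzyme[member],
    class = enz$class[match(site_enzyme[member], enz$enzyme)],
    substrate_gene = genes[member],
    substrate_acc = acc[member],
    site = paste0(res[member], pos[member]),
    window = windows[member])
  ksdb <- structure(ksdb, class = c("ksdb", class(ksdb)), n_skipped = 0L)

  truth <- list(
    enzymes = enz,
    sites = tibble::tibble(psite = psites, accession = acc, gene = genes,
                           enzyme = site_enzyme,
                           archetype = enz$archetype[
                             match(site_enzyme, enz$enzyme)],
                           protein_coregulated = acc %in% coreg),
    params = list(n_sites = n_sites, n_enzymes = n_enzymes,
                  m_per_enzyme = m_per_enzyme,
                  effect_size = effect_size, noise_sd = noise_sd,
                  replicates = replicates, times = times,
                  protein_coreg_fraction = protein_coreg_fraction,
                  seed = seed))
  list(quant = quant, protein = protein, ksdb = ksdb, truth = truth)
}

#' Generate labelled archetype trajectories
#'
#' Directly generates baseline-augmented log2 fold-change trajectories on
#' the grid (0, 5, 30, 60) from the four kinetic archetypes, with
#' additive Gaussian noise on the post-baseline points. The default
#' directions alternate up/down across archetypes, mirroring the planted
#' enzyme structure of [generate_phospho_dataset()] (the study reports
#' both hyper- and hypo-phosphorylated kinetic classes). Used for
#' clustering-recovery experiments.
#'
#' @param n_per_archetype trajectories per archetype.
#' @param effect_size absolute plateau effect (log2).
#' @param noise_sd noise SD on non-baseline points.
#' @param directions signs (+1/-1) of the four archetype effects, in the
#'   order early-sustained, early-transient, intermediate, late.
#' @param seed RNG seed.
#' @return A `trajectories` matrix with a `truth` attribute (archetype
#'   label per row).
#' @export
generate_archetype_trajectories <- function(n_per_archetype = 20L,
                                            effect_size = 1,
                                            noise_sd = 0.05,
                                            directions = c(1, -1, 1, -1),
                                            seed = 1L) {
  stopifnot(length(directions) == 4, all(directions %in% c(-1, 1)))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  profiles <- list("early-sustained" = c(0, 1, 1, 1),
                   "early-transient" = c(0, 1, 0, 0),
                   "intermediate"    = c(0, 0, 1, 1),
                   "late"            = c(0, 0, 0, 1))
  rows <- purrr::map(seq_along(profiles), function(i) {
    nm <- names(profiles)[i]
    m <- matrix(rep(profiles[[i]] * effect_size * directions[i],
                    n_per_archetype),
                n_per_archetype, 4, byrow = TRUE)
    m[, -1] <- m[, -1] + stats::rnorm(3 * n_per_archetype, 0, noise_sd)
    rownames(m) <- sprintf("%s_%03d", gsub("-", "", nm),
                           seq_len(n_per_archetype))
    m
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("0", "5", "30", "60")
  structure(m, class = c("trajectories", "matrix"),
            times = c(0, 5, 30, 60),
            truth = rep(names(profiles), each = n_per_archetype))
}

#' Generate a synthetic oxygen-consumption plate
#'
#' Simulates a respirometry run on the instrument's 6-min cadence: wells
#' idle at a basal rate, glucose is injected at `injection_time`, and the
#' OCR rises to a plateau `amplitude` above basal, scaled per treatment
#' by an effect multiplier (1 = mock-like response, 0.7 = a 30%
#' inhibition). Treatments may also shift the basal rate
#' (`basal_shift`), emulating compounds that perturb resting
#' respiration. Gaussian noise is added to every cycle. Ground truth is
#' attached.
#'
#' @param treatments named numeric vector of response multipliers; must
#'   include `mock = 1`-style control (name it via `control_label` in
#'   downstream calls).
#' @param wells_per_group replicate wells per treatment.
#' @param basal basal OCR (pmol O2/min).
#' @param amplitude plateau response above basal for a multiplier of 1.
#' @param basal_shift named numeric vector of basal-rate offsets per
#'   treatment (default none).
#' @param injection_time glucose injection time (min).
#' @param n_cycles number of 6-min measurement cycles.
#' @param noise_sd per-cycle OCR noise SD.
#' @param seed RNG seed.
#' @return An `ocr_traces` tibble with a `truth` attribute.
#' @export
generate_ocr_plate <- function(treatments = c(mock = 1),
                               wells_per_group = 5L,
                               basal = 50,
                               amplitude = 30,
                               basal_shift = NULL,
                               injection_time = 30,
                               n_cycles = 16L,
                               noise_sd = 0.5,
                               seed = 1L) {
  if (basal <= 0) stop("basal must be positive")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  t_grid <- seq(0, by = 6, length.out = n_cycles)
  out <- purrr::imap_dfr(as.list(treatments), function(mult, trt) {
    shift <- if (!is.null(basal_shift) && trt %in% names(basal_shift))
      basal_shift[[trt]] else 0
    purrr::map_dfr(seq_len(wells_per_group), function(w) {
      resp <- ifelse(t_grid > injection_time, amplitude * mult, 0)
      tibble::tibble(
        well = sprintf("%s_w%02d", trt, w),
        time_min = t_grid,
        ocr = basal + shift + resp + stats::rnorm(n_cycles, 0, noise_sd),
        treatment = trt,
        injection_time = injection_time)
    })
  })
  structure(out, class = c("ocr_traces", class(out)),
            truth = list(treatments = treatments, basal = basal,
                         amplitude = amplitude,
                         basal_shift = basal_shift,
                         injection_time = injection_time, seed = seed))
}
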