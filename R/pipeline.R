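#' Run the full time-course analysis
#'
#' Orchestrates the pipeline: differential testing at every time point
#' (p-site level and, when a protein-level table is supplied,
#' protein-level reconciliation), cross-time overlap analysis, trajectory
#' building and archetype clustering, KSEA (when a kinase-substrate
#' database is supplied) with activity classification, and gene-set
#' enrichment of the regulated proteins at each time (when a collection
#' is supplied). Each stage failure halts with a stage-named error.
#' Outputs are pure functions of (inputs, config), so identical runs
#' reproduce identical results; the returned bundle carries a
#' configuration hash and the seed.
#'
#' @param quant a `psite_quant` (or a path read via
#'   [read_quant_table()]).
#' @param config a [run_config()].
#' @param protein optional protein-level `psite_quant` (rows keyed by
#'   accession) or path.
#' @param ksdb optional `ksdb` or path(s); enables KSEA.
#' @param collection optional `gene_set_collection` or GMT path; enables
#'   enrichment.
#' @param output_dir optional directory; when given, per-time
#'   differential TSVs, the overlap summary JSON, cluster assignments,
#'   KSEA scores and enrichment tables are written there.
#' @return List of class `report_bundle`: `diffs` (combined
#'   `diff_result`), `overlap`, `reconciliation` (per time, if protein
#'   table given), `trajectories`, `clusters`, `archetypes`, `ksea`,
#'   `activity_classes`, `enrichment` (per time), `go_ranking`,
#'   `config`, `config_hash`, `log`.
#' @export
run_time_course_analysis <- function(quant, config = run_config(),
                                     protein = NULL, ksdb = NULL,
                                     collection = NULL,
                                     output_dir = NULL) {
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.character(quant)) quant <- read_quant_table(quant, config)
  if (is.character(protein) && length(protein))
    protein <- read_quant_table(protein, config)
  if (is.character(ksdb) && length(ksdb)) ksdb <- read_ksdb(ksdb)
  if (is.character(collection) && length(collection))
    collection <- read_gmt(collection)
  cfg_hash <- rlang::hash(config)
  say("ingest", sprintf("%d p-sites, %d samples, config %s",
                        nrow(quant$meta), nrow(quant$samples), cfg_hash))

  times <- sort(unique(quant$samples$time))
  diffs <- stage("differential", {
    dplyr::bind_rows(lapply(times, function(tm)
      paired_diff_test(quant, tm, alpha = config$alpha,
                       lfc_threshold = config$lfc_threshold,
                       paired = config$paired,
                       min_pairs = config$min_replicates)))
  })
  say("differential", sprintf("%d regulated calls over %d time points",
                              sum(diffs$regulated), length(times)))

  overlap <- stage("overlap", {
    sets <- lapply(stats::setNames(times, paste0("t", times)),
                   function(tm)
                     diffs$psite[diffs$regulated & diffs$time == tm])
    overlap_analysis(sets)
  })

  reconciliation <- NULL
  if (!is.null(protein)) {
    reconciliation <- stage("reconciliation", {
      lapply(stats::setNames(times, paste0("t", times)), function(tm) {
        pd <- paired_diff_test(protein, tm, alpha = config$alpha,
                               lfc_threshold = config$lfc_threshold,
                               paired = config$paired,
                               min_pairs = config$min_replicates)
        reconcile_protein_level(diffs[diffs$time == tm, ], pd, tm)
      })
    })
  }

  traj <- clusters <- archetypes <- NULL
  n_reg <- length(unique(diffs$psite[diffs$regulated]))
  if (n_reg >= config$k) {
    traj <- stage("trajectories", build_trajectories(diffs))
    clusters <- stage("clustering", {
      mm <- trajectory_measure_matrix(traj)
      scores <- trajectory_factor_scores(
        mm, exclude = config$excluded_measure)
      cluster_trajectories(scores, k = config$k, seed = config$seed)
    })
    archetypes <- label_archetypes(traj, clusters)
    say("clustering", sprintf("%d trajectories into %d clusters",
                              nrow(traj), config$k))
  } else {
    say("clustering", "skipped: fewer regulated p-sites than k")
  }

  ksea <- activity <- NULL
  if (!is.null(ksdb)) {
    ksea <- stage("ksea", {
      groups <- match_substrates(quant, ksdb)
      ksea_over_time(quant, groups, min_m = config$ksea_min_m)
    })
    activity <- classify_activity_trajectories(ksea)
    say("ksea", sprintf("%d enzymes scored", nrow(ksea$mean_matrix)))
  }

  enrich <- ranking <- NULL
  if (!is.null(collection)) {
    enrich <- stage("enrichment", {
      gene_of <- stats::setNames(
        ifelse(is.na(quant$meta$gene) | !nzchar(quant$meta$gene),
               parse_psite_key(quant$meta$psite) |>
                 dplyr::distinct(.data$psite, .data$accession) |>
                 dplyr::pull(.data$accession),
               quant$meta$gene),
        quant$meta$psite)
      universe <- unique(gene_of)
      lapply(stats::setNames(times, paste0("t", times)), function(tm) {
        q <- unique(gene_of[diffs$psite[diffs$regulated &
                                          diffs$time == tm]])
        hypergeom_enrichment(q, collection, universe)
      })
    })
    ranking <- if (length(enrich) >= 2)
      differential_go_ranking(enrich) else NULL
    say("enrichment", sprintf("%d gene sets x %d groups",
                              length(collection), length(enrich)))
  }

  bundle <- structure(
    list(diffs = diffs, overlap = overlap,
         reconciliation = reconciliation,
         trajectories = traj, clusters = clusters,
         archetypes = archetypes,
         ksea = ksea, activity_classes = activity,
         enrichment = enrich, go_ranking = ranking,
         config = config, config_hash = cfg_hash, log = log_lines),
    class = "report_bundle")
  if (!is.null(output_dir)) write_report_bundle(bundle, output_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Per-time differential TSVs, an overlap/shared-fraction JSON, cluster
#' assignments, KSEA score tables, enrichment tables and the run log;
#' every file is stamped with the configuration hash in the log.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(as.data.frame(df), file.path(dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  for (tm in unique(bundle$diffs$time))
    w(bundle$diffs[bundle$diffs$time == tm, ],
      sprintf("differential_t%g.tsv", tm))
  ov <- bundle$overlap
  jsonlite::write_json(
    list(config_hash = bundle$config_hash,
         sizes = as.list(ov$sizes), common = ov$common,
         union = ov$union_size, pct_shared = ov$pct_shared),
    file.path(dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$clusters)) {
    w(tibble::tibble(psite = names(bundle$clusters$assignments),
                     cluster = bundle$clusters$assignments),
      "clusters.tsv")
    w(bundle$archetypes, "cluster_archetypes.tsv")
  }
  if (!is.null(bundle$ksea)) {
    w(bundle$ksea$scores, "ksea_replicate_scores.tsv")
    w(bundle$ksea$mean_scores, "ksea_mean_scores.tsv")
    w(bundle$activity_classes, "ksea_activity_classes.tsv")
  }
  if (!is.null(bundle$enrichment)) {
    for (nm in names(bundle$enrichment)) {
      e <- bundle$enrichment[[nm]]
      e$overlap_genes <- vapply(e$overlap_genes, paste, "",
                                collapse = ",")
      w(e, sprintf("enrichment_%s.tsv", nm))
    }
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> config", x$config_hash, "\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
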