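#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()].  Supply either a
#' [sim_scenario()] (data are simulated) or input paths to genotype files.
#' All randomness flows from `seed` through named child seeds (simulation,
#' exclusion, bootstrap), logged in the run log.
#'
#' @param scenario a [sim_scenario()], or `NULL` when reading from files.
#' @param input_path,input_format passed to [read_genotypes()] when
#'   `scenario` is `NULL`.
#' @param qc a [qc_config()].
#' @param panel_size markers to select (default 96; clipped to the number of
#'   QC-passing loci).
#' @param curve_sizes panel sizes for the assignment curve; default is a
#'   10-marker grid up to `panel_size`.
#' @param exclusion an [exclusion_config()].
#' @param thresholds log(LR) test values for the contrast matrices.
#' @param bootstrap_reps tree bootstrap replicates (default 1000).
#' @param r2_threshold LD-screen reporting threshold (default 0.4).
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, input_path = NULL,
                            input_format = "csv", qc = qc_config(),
                            panel_size = 96L, curve_sizes = NULL,
                            exclusion = exclusion_config(),
                            thresholds = c(0, 2), bootstrap_reps = 1000L,
                            r2_threshold = 0.4, out_dir = ".", seed = 1L) {
  if (is.null(scenario) && is.null(input_path))
    stop_val("pipeline_config needs a scenario or an input_path")
  if (panel_size < 1L) stop_val("panel_size must be >= 1")
  structure(list(scenario = scenario, input_path = input_path,
                 input_format = input_format, qc = qc,
                 panel_size = as.integer(panel_size),
                 curve_sizes = curve_sizes, exclusion = exclusion,
                 thresholds = thresholds,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 r2_threshold = r2_threshold, out_dir = out_dir,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' The JSON mirrors [pipeline_config()] fields; `scenario` holds
#' [sim_scenario()] arguments, `qc`/`exclusion` their respective config
#' arguments.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario <- if (!is.null(j$scenario)) {
    if (!is.null(j$scenario$close_pairs) &&
        is.data.frame(j$scenario$close_pairs))
      j$scenario$close_pairs <-
        lapply(seq_len(nrow(j$scenario$close_pairs)), function(i)
          as.list(j$scenario$close_pairs[i, , drop = FALSE]))
    do.call(sim_scenario, j$scenario)
  }
  args <- j[setdiff(names(j), c("scenario", "qc", "exclusion"))]
  args$scenario <- scenario
  if (!is.null(j$qc)) args$qc <- do.call(qc_config, j$qc)
  if (!is.null(j$exclusion)) args$exclusion <- do.call(exclusion_config, j$exclusion)
  do.call(pipeline_config, args)
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

matrix_to_df <- function(m, rowname_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df)[1L] <- rowname_col
  df
}

#' Run the full authentication pipeline and write the report bundle
#'
#' Executes QC -> delta ranking -> assignment curve -> panel selection ->
#' self-assignment -> exclusion test -> contrast matrices -> F_ST /
#' Reynolds / NJ tree with bootstrap -> LD screen -> panel summary, and
#' writes one file per stage into `config$out_dir` (CSV contracts plus a
#' Newick tree, a PNG of the curve and a run log).  Outputs are
#' bit-identical under identical config and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage result and the written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_val("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  paths <- character(0)
  log_lines <- c(paste0("breedassign ", as.character(packageVersion("breedassign"))),
                 paste0("R ", R.version.string),
                 paste0("master_seed ", config$seed),
                 paste0("exclusion_seed ", derive_seed(config$exclusion$seed, "exclusion")),
                 paste0("bootstrap_seed ", derive_seed(config$seed, "bootstrap")))

  data <- stage("input", {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      log_lines <- c(log_lines, paste0("scenario_seed ", sc$seed))
      simulate_dataset(sc)
    } else {
      read_genotypes(config$input_path, config$input_format)
    }
  })

  qc_res <- stage("qc", filter_call_rate(data, config$qc))
  data <- qc_res$data
  paths["qc_loci"] <- write_stage_csv(qc_res$locus_report, out_dir,
                                      "qc_report.csv")
  paths["qc_samples"] <- write_stage_csv(qc_res$sample_report, out_dir,
                                         "qc_samples.csv")

  ranking <- stage("rank", rank_markers(data))
  paths["ranking"] <- write_stage_csv(ranking, out_dir, "delta_ranking.csv")

  panel_size <- min(config$panel_size, n_loci(data))
  sizes <- config$curve_sizes %||%
    unique(sort(c(seq(10L, panel_size, by = 10L), panel_size)))
  sizes <- sizes[sizes >= 1 & sizes <= n_loci(data)]
  curve <- stage("curve", assignment_curve(data, ranking, sizes))
  paths["curve"] <- write_stage_csv(curve, out_dir, "assignment_curve.csv")
  grDevices::png(file.path(out_dir, "assignment_curve.png"), 700, 500)
  plot(curve)
  grDevices::dev.off()
  paths["curve_png"] <- file.path(out_dir, "assignment_curve.png")

  panel <- stage("select", select_panel(ranking, panel_size))
  writeLines(as.character(panel), file.path(out_dir, "panel.txt"))
  paths["panel"] <- file.path(out_dir, "panel.txt")

  assignments <- stage("assign", self_assign_all(data, panel))
  paths["assignments"] <- write_stage_csv(assignments, out_dir,
                                          "assignments.csv")

  excl <- stage("exclude", exclusion_test(data, panel, config$exclusion))
  excl_ll <- as.data.frame(excl$loglik, row.names = NULL)
  names(excl_ll) <- paste0("loglik_", colnames(excl$loglik))
  excl_df <- cbind(excl$records, excl_ll)
  paths["exclusions"] <- write_stage_csv(excl_df, out_dir, "exclusions.csv")

  post <- stage("power", contrast_matrix(data, panel, config$thresholds))
  for (k in seq_along(config$thresholds)) {
    nm <- paste0("posterior_matrix_t", config$thresholds[k], ".csv")
    paths[nm] <- write_stage_csv(matrix_to_df(post[[k]], "claimed_breed"),
                                 out_dir, nm)
  }

  fst <- stage("diffstats", fst_matrix(data))
  rey <- stage("diffstats", reynolds_matrix(data))
  fst_df <- matrix_to_df(fst$values, "breed")
  fst_df$mean_fst <- fst$breed_means$mean
  fst_df$sd_fst <- fst$breed_means$sd
  paths["fst"] <- write_stage_csv(fst_df, out_dir, "fst_matrix.csv")
  rey_df <- matrix_to_df(rey$values, "breed")
  rey_df$mean_distance <- rey$breed_means$mean
  paths["reynolds"] <- write_stage_csv(rey_df, out_dir, "reynolds_matrix.csv")

  tree <- stage("tree", bootstrap_support(data, panel,
                                          n_reps = config$bootstrap_reps,
                                          seed = config$seed))
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  paths["tree"] <- file.path(out_dir, "tree.nwk")

  ld <- stage("ld", panel_ld_screen(data, panel, config$r2_threshold))
  paths["ld"] <- write_stage_csv(ld, out_dir, "ld_screen.csv")

  summary_df <- stage("report", summarize_panel(panel, data$loci))
  paths["panel_summary"] <- write_stage_csv(summary_df, out_dir,
                                            "panel_summary.csv")

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths["log"] <- file.path(out_dir, "run_log.txt")

  invisible(list(data = data, qc = qc_res, ranking = ranking, curve = curve,
                 panel = panel, assignments = assignments, exclusion = excl,
                 posterior = post, fst = fst, reynolds = rey, tree = tree,
                 ld = ld, panel_summary = summary_df, paths = paths))
}

#' Per-chromosome summary of a selected panel
#'
#' For each chromosome present in the locus map (plus `"Undetermined"`):
#' the count of panel loci and, where two or more are mapped, the mean and
#' min-max range of all pairwise bp distances (`NA` -- printed as "n.a." in
#' reports -- for 0-1 loci).
#'
#' @param panel a [select_panel()] result (or character vector of ids).
#' @param loci the dataset's locus map (`data$loci`).
#' @return `data.frame` with `chromosome`, `n_loci`, `mean_distance_bp`,
#'   `min_distance_bp`, `max_distance_bp`.
#' @export
summarize_panel <- function(panel, loci) {
  ids <- as.character(panel)
  sub <- loci[match(ids, loci$locus_id), ]
  if (anyNA(sub$locus_id)) stop_val("panel locus missing from the map")
  chroms <- unique(loci$chromosome)
  # numeric-first, X next, Undetermined last
  suppressWarnings(ord <- order(is.na(as.numeric(chroms)),
                                as.numeric(chroms),
                                chroms == "Undetermined", chroms))
  chroms <- chroms[ord]
  rows <- lapply(chroms, function(ch) {
    pos <- sub$position_bp[sub$chromosome == ch]
    n <- length(pos)
    if (ch != "Undetermined" && n >= 2L) {
      d <- as.vector(stats::dist(pos))
      data.frame(chromosome = ch, n_loci = n, mean_distance_bp = mean(d),
                 min_distance_bp = min(d), max_distance_bp = max(d),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chromosome = ch, n_loci = n, mean_distance_bp = NA_real_,
                 min_distance_bp = NA_real_, max_distance_bp = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
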