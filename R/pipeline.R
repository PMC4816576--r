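#' End-to-end pipeline configuration
#'
#' Bundles the simulation, preprocessing and analysis settings of a full
#' run: every subject is simulated, preprocessed (band-pass, linked
#' mastoid re-reference, RT exclusion, statistical artifact rejection)
#' and analyzed in all four modes (two within-task, two cross-task
#' directions) for each requested feature set.
#'
#' @param simulation a `simulation_config`.
#' @param filter a `filter_spec` or `NULL`.
#' @param rejection a `rejection_config` or `NULL`.
#' @param feature_sets subset of `c("ne", "pe", "combined")`.
#' @param modes analysis modes; defaults to all four.
#' @param n_repeats repeats of the balanced-sample analysis (default 10).
#' @param n_perm label permutations per repeat (default 1000).
#' @param k CV folds (default 10).
#' @param seed master analysis seed (the simulation has its own).
#' @param grid_options list of arguments forwarded to
#'   [nested_grid_search()] (e.g. smaller grids for quick runs).
#' @param scale_jointly whole-set feature scaling compatibility switch.
#' @param output_dir directory for report tables, stats and the manifest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = make_default_config(),
                            filter = filter_spec(),
                            rejection = rejection_config(),
                            feature_sets = c("ne", "pe", "combined"),
                            modes = c("within-flanker", "within-rotation",
                                      "flanker->rotation", "rotation->flanker"),
                            n_repeats = 10, n_perm = 1000, k = 10,
                            seed = 1, grid_options = list(),
                            scale_jointly = FALSE,
                            output_dir = "results") {
  stopifnot(all(feature_sets %in% c("ne", "pe", "combined")))
  structure(list(simulation = simulation, filter = filter,
                 rejection = rejection, feature_sets = feature_sets,
                 modes = modes, n_repeats = n_repeats, n_perm = n_perm,
                 k = k, seed = as.integer(seed), grid_options = grid_options,
                 scale_jointly = scale_jointly, output_dir = output_dir),
            class = "pipeline_config")
}

report_file_name <- function(mode, feature_set) {
  stem <- gsub("->", "_to_", mode, fixed = TRUE)
  sprintf("report_%s_%s.tsv", gsub("[^a-z0-9_]+", "_", stem), feature_set)
}

#' Write a per-subject classification report table
#'
#' One row per subject. Within-task tables have 7 columns (Subject,
#' Accuracy mean/min/max, p mean/min/max); transfer tables add the
#' correctly classified trial counts and the total (11 columns). Numbers
#' are printed with 3 decimal places.
#'
#' @param reports list of `classification_report` objects sharing one
#'   mode and feature set.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_report_table <- function(reports, path) {
  transfer <- length(reports) > 0 && grepl("->", reports[[1]]$mode, fixed = TRUE)
  header <- c("Subject", "Accuracy (mean)", "Accuracy (min)", "Accuracy (max)",
              "p (mean)", "p (min)", "p (max)")
  if (transfer)
    header <- c(header, "trials correct (mean)", "trials correct (min)",
                "trials correct (max)", "trials (total)")
  rows <- lapply(reports, function(rep) {
    a <- rep$aggregates
    vals <- c(a$accuracy_mean, a$accuracy_min, a$accuracy_max,
              a$p_mean, a$p_min, a$p_max)
    if (transfer)
      vals <- c(vals, a$trials_correct_mean, a$trials_correct_min,
                a$trials_correct_max, a$trials_total)
    c(rep$subject, formatC(vals, format = "f", digits = 3))
  })
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(header, collapse = "\t"), con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  invisible(path)
}

#' Read back a report table written by [write_report_table()]
#'
#' @param path TSV path.
#' @return data.frame with syntactic column names.
#' @export
read_report_table <- function(path) {
  utils::read.delim(path, check.names = TRUE)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, file = f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Streams over the simulated cohort one subject at a time: simulate both
#' tasks, apply the RT exclusion, band-pass filter, linked-mastoid
#' re-reference and statistical artifact rejection, then run every
#' requested mode x feature-set combination through the repeated
#' balanced-sample classification scheme. Emits one report table per
#' combination, condition-level ERP/behavioral statistics, and a run
#' manifest (config hash, seeds, per-stage trial counts).
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with `reports` (nested list
#'   mode -> feature set -> list of `classification_report`), `stats`
#'   (data.frames), `manifest`, and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulation
  reports <- list()
  cond_rows <- list()
  counts <- list()
  for (i in seq_len(sim$n_subjects)) {
    task_epochs <- list()
    for (kk in seq_along(sim$tasks)) {
      tk <- sim$tasks[[kk]]
      ep <- simulate_subject(sim, i, tk, seed = derive_seed(sim$seed, i, kk))
      n0 <- n_trials(ep)
      ep <- rt_filter(ep)
      n1 <- n_trials(ep)
      pp <- preprocess_epochs(ep, filter = config$filter,
                              rejection = config$rejection)
      ep <- pp$epochs
      counts[[length(counts) + 1]] <- data.frame(
        subject = i, task = tk$name, simulated = n0, after_rt_filter = n1,
        rejected_artifacts = length(pp$rejected), analyzed = n_trials(ep))
      ne <- windowed_mean(ep, ne_window())
      pe <- windowed_mean(ep, pe_window())
      for (resp in c("error", "correct")) {
        sel <- ep$trial_meta$response == resp
        cond_rows[[length(cond_rows) + 1]] <- data.frame(
          subject = i, task = tk$name, response = resp,
          ne = mean(ne[sel]), pe = mean(pe[sel]),
          rt = mean(ep$trial_meta$rt[sel]),
          error_rate = mean(ep$trial_meta$response == "error"),
          stringsAsFactors = FALSE)
      }
      task_epochs[[tk$name]] <- ep
    }
    for (mi in seq_along(config$modes)) {
      mode <- config$modes[mi]
      for (fi in seq_along(config$feature_sets)) {
        fs <- config$feature_sets[fi]
        rep <- do.call(repeat_and_aggregate, c(
          list(task_epochs = task_epochs, spec = feature_set_spec(fs),
               mode = mode, n_repeats = config$n_repeats,
               master_seed = derive_seed(config$seed, i, mi, fi),
               k = config$k, n_perm = config$n_perm,
               scale_jointly = config$scale_jointly),
          config$grid_options))
        reports[[mode]][[fs]][[i]] <- rep
      }
    }
  }
  cond <- do.call(rbind, cond_rows)
  stats_out <- pipeline_stats(cond)
  files <- character(0)
  for (mode in config$modes) {
    for (fs in config$feature_sets) {
      f <- file.path(config$output_dir, report_file_name(mode, fs))
      write_report_table(reports[[mode]][[fs]], f)
      files <- c(files, f)
    }
  }
  f_cond <- file.path(config$output_dir, "condition_means.tsv")
  utils::write.table(cond, f_cond, sep = "\t", quote = FALSE, row.names = FALSE)
  f_stats <- file.path(config$output_dir, "erp_rt_anova.tsv")
  utils::write.table(stats_out$anova, f_stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_counts <- file.path(config$output_dir, "stage_counts.tsv")
  utils::write.table(do.call(rbind, counts), f_counts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("errclass")),
    config_hash = config_hash(config),
    simulation_seed = sim$seed, analysis_seed = config$seed,
    n_subjects = sim$n_subjects, modes = config$modes,
    feature_sets = config$feature_sets, n_repeats = config$n_repeats,
    n_perm = config$n_perm, k = config$k,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f_manifest <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f_cond, f_stats, f_counts, f_manifest)
  invisible(list(reports = reports, stats = stats_out,
                 condition_means = cond, manifest = manifest, files = files))
}

# Condition-level ERP and RT statistics: 2x2 repeated-measures ANOVAs on
# the Ne/Pe windowed means and the RTs, plus the error-rate bootstrap
# t-test across tasks.
pipeline_stats <- function(cond, n_boot = 2000, seed = 1) {
  mk_tab <- function(col) data.frame(subject = cond$subject, a = cond$task,
                                     b = cond$response, value = cond[[col]])
  if (length(unique(cond$subject)) >= 3) {
    anova <- do.call(rbind, lapply(c("ne", "pe", "rt"), function(col) {
      res <- rm_anova_2x2(mk_tab(col))
      res$measure <- col
      res
    }))
  } else {
    # the 2x2 rm-ANOVA needs >= 3 subjects; smaller runs skip it
    anova <- data.frame(effect = character(0), F = numeric(0),
                        df1 = numeric(0), df2 = numeric(0), p = numeric(0),
                        eta_p2 = numeric(0), measure = character(0))
  }
  er <- unique(cond[cond$response == "error", c("subject", "task", "error_rate")])
  wide <- stats::reshape(er, idvar = "subject", timevar = "task",
                         direction = "wide")
  bt <- NULL
  if (nrow(wide) >= 3 && ncol(wide) == 3) {
    x <- wide[[2]]; y <- wide[[3]]
    if (stats::sd(x - y) > 0) {
      b <- bootstrap_ttest_paired(x, y, n_boot = n_boot, seed = seed)
      bt <- data.frame(test = "error_rate_task_diff", t_obs = b$t_obs,
                       p_boot = b$p_boot, d_rm = cohens_d_rm(x, y))
    }
  }
  list(anova = anova, error_rate_test = bt)
}
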