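# internal: CSV writer preserving full double precision (%.17g round-trips)
.write_csv_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a trial table as CSV
#'
#' Comma-separated, header row, UTF-8, "." decimal.
#'
#' @param trials Trial table data frame.
#' @param path File path.
#' @return `read_trial_table` returns the data frame;
#'   `write_trial_table` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  .write_csv_precise(trials, path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("trial table not found: ", path)
  tt <- utils::read.csv(path)
  need <- c("trial_id", "block", "theta_cued")
  missing <- setdiff(need, names(tt))
  if (length(missing)) {
    stop("trial table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  tt
}

#' Write / read a run-wise time series
#'
#' The TRs x voxels matrix goes to `<prefix>_data.csv`; the per-trial
#' event map to `<prefix>_events.json`.
#'
#' @param run A [bold_run()].
#' @param prefix Path prefix for the two files.
#' @return `read_bold_run` returns the [bold_run()];
#'   `write_bold_run` returns the prefix invisibly.
#' @export
write_bold_run <- function(run, prefix) {
  stopifnot(inherits(run, "bold_run"))
  .write_csv_precise(as.data.frame(run$data), paste0(prefix, "_data.csv"))
  jsonlite::write_json(list(run_id = run$run_id, events = run$event_map),
                       paste0(prefix, "_events.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_bold_run
#' @export
read_bold_run <- function(prefix) {
  dpath <- paste0(prefix, "_data.csv")
  epath <- paste0(prefix, "_events.json")
  for (p in c(dpath, epath)) {
    if (!file.exists(p)) stop("missing run artifact: ", p)
  }
  data <- as.matrix(utils::read.csv(dpath))
  dimnames(data) <- NULL
  ev <- jsonlite::read_json(epath, simplifyVector = TRUE)
  event_map <- lapply(seq_len(nrow(ev$events)), function(i) {
    e <- lapply(ev$events[i, ], function(v) if (is.list(v)) unlist(v) else v)
    e$trial_id <- as.integer(e$trial_id)
    e
  })
  bold_run(data, event_map, run_id = ev$run_id)
}

#' Read pattern or time-series matrices
#'
#' `format = "csv"`: a delimited matrix, one row per trial (pattern) or
#' per TR (time series). `format = "nifti"`: a 4-D volume plus an ROI
#' mask volume on the same grid; voxels inside the nonzero mask are
#' flattened in native volume index order (first axis fastest), yielding
#' a TRs x voxels matrix. NaN voxels are dropped with a message.
#'
#' @param path Matrix CSV or 4-D NIfTI path.
#' @param format `"csv"` or `"nifti"`.
#' @param mask Mask volume path (NIfTI only).
#' @return A numeric matrix.
#' @export
read_patterns <- function(path, format = c("csv", "nifti"), mask = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input not found: ", path)
  if (format == "csv") {
    mat <- as.matrix(utils::read.csv(path))
    dimnames(mat) <- NULL
    return(mat)
  }
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI requires the RNifti package")
  }
  if (is.null(mask)) stop("NIfTI input requires an ROI mask volume")
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D volume, got ", length(d), "-D")
  if (!all(dim(msk)[1:3] == d[1:3])) {
    stop("mask grid ", paste(dim(msk), collapse = "x"),
         " does not match volume grid ", paste(d[1:3], collapse = "x"))
  }
  vox <- which(as.vector(msk) != 0)  # native volume index order
  if (length(vox) == 0L) stop("ROI mask selects no voxels")
  flat <- matrix(as.vector(img), prod(d[1:3]), d[4])
  out <- t(flat[vox, , drop = FALSE])
  bad <- which(colSums(!is.finite(out)) > 0)
  if (length(bad)) {
    message("dropping ", length(bad), " non-finite voxel(s)")
    out <- out[, -bad, drop = FALSE]
    if (ncol(out) == 0L) stop("all masked voxels are non-finite")
  }
  out
}

#' Read a run configuration
#'
#' YAML (or JSON) file with optional blocks `sim` (arguments to
#' [sim_config()]), `basis` (arguments to [channel_basis()]), `delay`
#' (`weights`, `peak_shift`, `zscore_ddof`) and `analysis` (`conditions`,
#' `small_cut`, `upper_rule`, `n_iter_boot`, `n_iter_resample`,
#' `bonferroni_m`, `seed`).
#'
#' @param path Config file path.
#' @return An object of class `run_config` (a named list with defaults
#'   filled in).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(sim = raw$sim, basis = raw$basis, delay = raw$delay,
             analysis = raw$analysis)
}

#' Assemble a run configuration in code
#'
#' @param sim Named list of [sim_config()] overrides.
#' @param basis Named list of [channel_basis()] overrides.
#' @param delay Named list: `weights`, `peak_shift`, `zscore_ddof`.
#' @param analysis Named list: `conditions`, `small_cut`, `upper_rule`,
#'   `n_iter_boot`, `n_iter_resample`, `bonferroni_m`, `seed`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = NULL, basis = NULL, delay = NULL,
                       analysis = NULL) {
  cfg <- list(
    sim = do.call(sim_config, as.list(sim %||% list())),
    basis = do.call(channel_basis, as.list(basis %||% list())),
    delay = utils::modifyList(
      list(weights = c(0, 1, 2, 1, 0), peak_shift = 0L, zscore_ddof = 0),
      as.list(delay %||% list())),
    analysis = utils::modifyList(
      list(conditions = c("cued", "uncued", "shuffled"), small_cut = 20,
           upper_rule = "three_sd", n_iter_boot = 1000L,
           n_iter_resample = 5000L, bonferroni_m = NULL, seed = 1L),
      as.list(analysis %||% list()))
  )
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: config hash + seed provenance written beside every artifact
.write_provenance <- function(out_dir, stage, cfg, extra = list()) {
  cfg_file <- file.path(out_dir, "config.json")
  ser <- list(sim = unclass(cfg$sim), basis = unclass(cfg$basis),
              delay = cfg$delay, analysis = cfg$analysis)
  jsonlite::write_json(ser, cfg_file, auto_unbox = TRUE, digits = NA)
  prov <- c(list(stage = stage,
                 config_hash = unname(tools::md5sum(cfg_file)),
                 seed = cfg$sim$seed,
                 analysis_seed = cfg$analysis$seed,
                 r_version = as.character(getRversion()),
                 package_version = as.character(
                   utils::packageVersion("wmiem"))),
            extra)
  jsonlite::write_json(prov, file.path(out_dir,
                                       paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("[%s] %s done (config %s)\n", format(Sys.time(), "%H:%M:%S"),
              stage, substr(prov$config_hash, 1, 8)),
      file = file.path(out_dir, "run.log"), append = TRUE)
  invisible(prov)
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes the stages in order against a configuration: `simulate`
#' (designs, behavior, run-wise time series per subject), `extract`
#' (z-scoring + TENT delay patterns), `iem` (leave-one-block-out
#' reconstructions per condition), `rsa` (similarity associations per
#' condition), `link` (error-linked balanced resampling contrast) and
#' `report` (group statistics across subjects). Artifacts are written as
#' CSV/JSON under `out_dir`, each stage with a provenance sidecar
#' (config hash, seeds, versions) and a line in `run.log`. Reruns with an
#' identical configuration reproduce identical numbers.
#'
#' @param config A [run_config()] (or path to a YAML/JSON config).
#' @param out_dir Output directory, created if needed.
#' @param stages Subset of stages to run (in canonical order).
#' @return Invisibly, a list with the per-subject measures and the group
#'   results table.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "extract", "iem", "rsa",
                                    "link", "report")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  basis <- config$basis
  an <- config$analysis
  subjects <- seq_len(sim$n_subjects)

  trials_all <- list(); patterns <- list()
  if ("simulate" %in% stages || "extract" %in% stages) {
    for (s in subjects) {
      sub <- simulate_subject(sim, s, basis = basis)
      trials_all[[s]] <- sub$trials
      write_trial_table(sub$trials,
                        file.path(out_dir, sprintf("sub%02d_trials.csv", s)))
      if ("extract" %in% stages) {
        pat <- extract_delay_patterns(
          sub$runs, weights = config$delay$weights,
          peak_shift = config$delay$peak_shift,
          ddof = config$delay$zscore_ddof, subject_id = s)
        patterns[[s]] <- pat
        .write_csv_precise(as.data.frame(unclass(pat)),
                           file.path(out_dir, sprintf("sub%02d_delay.csv", s)))
      }
    }
    .write_provenance(out_dir, "simulate", config,
                      list(n_subjects = sim$n_subjects))
    if ("extract" %in% stages) {
      .write_provenance(out_dir, "extract", config,
                        list(weights = config$delay$weights,
                             peak_shift = config$delay$peak_shift))
    }
  } else {
    for (s in subjects) {
      trials_all[[s]] <- read_trial_table(
        file.path(out_dir, sprintf("sub%02d_trials.csv", s)))
      patterns[[s]] <- delay_pattern(
        read_patterns(file.path(out_dir, sprintf("sub%02d_delay.csv", s))),
        subject_id = s)
    }
  }

  measures <- NULL
  recons <- list()
  if ("iem" %in% stages) {
    rows <- list()
    for (s in subjects) {
      recons[[s]] <- list()
      for (cond in an$conditions) {
        rec <- lobo_cv(patterns[[s]], trials_all[[s]], basis,
                       condition = cond,
                       seed = .substream_seed(an$seed, s))
        recons[[s]][[cond]] <- rec
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cond, measure = "iem_R",
          value = rec$mean_R)
      }
      utils::write.csv(
        data.frame(trial_id = trials_all[[s]]$trial_id,
                   condition = rep(an$conditions,
                                   each = nrow(trials_all[[s]])),
                   R = unlist(lapply(an$conditions,
                                     function(cc) recons[[s]][[cc]]$R))),
        file.path(out_dir, sprintf("sub%02d_iem_R.csv", s)),
        row.names = FALSE)
    }
    measures <- do.call(rbind, rows)
    .write_provenance(out_dir, "iem", config,
                      list(conditions = an$conditions))
  }

  if ("rsa" %in% stages) {
    rows <- list()
    for (s in subjects) {
      ns <- neural_similarity(patterns[[s]])
      for (cond in intersect(an$conditions, c("cued", "uncued"))) {
        th <- if (cond == "cued") trials_all[[s]]$theta_cued else
          trials_all[[s]]$theta_uncued
        assoc <- similarity_association(ns, stimulus_similarity(th))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cond, measure = "rsa_fisher_z",
          value = assoc$fisher_z)
      }
    }
    rsa_tab <- do.call(rbind, rows)
    measures <- rbind(measures, rsa_tab)
    utils::write.csv(rsa_tab, file.path(out_dir, "rsa_associations.csv"),
                     row.names = FALSE)
    .write_provenance(out_dir, "rsa", config, list())
  }

  link_tab <- NULL
  if ("link" %in% stages) {
    pooled_err <- unlist(lapply(trials_all, function(tt) {
      recall_error(tt$reported, tt$theta_cued)
    }))
    sd_pooled <- aggregate_error_sd(pooled_err)
    rows <- list()
    for (s in subjects) {
      err <- recall_error(trials_all[[s]]$reported,
                          trials_all[[s]]$theta_cued)
      cats <- categorize_trials(err, small_cut = an$small_cut,
                                upper_rule = an$upper_rule,
                                sd_pooled = sd_pooled)
      rec <- lobo_cv(patterns[[s]], trials_all[[s]], basis,
                     condition = "cued",
                     blocks = random_blocks(nrow(trials_all[[s]]),
                                            sim$trials_per_block,
                                            seed = .substream_seed(an$seed,
                                                                   s + 1000L)),
                     seed = .substream_seed(an$seed, s))
      res <- tryCatch(
        error_linked_contrast(rec$R, cats, n_iter = an$n_iter_resample,
                              seed = .substream_seed(an$seed, s + 2000L)),
        error = function(e) {
          message("subject ", s, " excluded from error-linked contrast: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, small_R = res$small, larger_R = res$larger,
          difference = res$difference, n_small = res$n_small,
          n_larger = res$n_larger)
      }
    }
    link_tab <- do.call(rbind, rows)
    utils::write.csv(link_tab, file.path(out_dir, "error_linked.csv"),
                     row.names = FALSE)
    .write_provenance(out_dir, "link", config,
                      list(sd_pooled = sd_pooled,
                           n_iter = an$n_iter_resample))
  }

  report <- NULL
  if ("report" %in% stages && !is.null(measures)) {
    utils::write.csv(measures, file.path(out_dir, "subject_measures.csv"),
                     row.names = FALSE)
    wide <- function(meas, cond) {
      measures$value[measures$measure == meas & measures$condition == cond]
    }
    rows <- list()
    for (meas in unique(measures$measure)) {
      a <- wide(meas, "cued"); b <- wide(meas, "uncued")
      if (length(a) && length(a) == length(b)) {
        pt <- paired_test(a, b)
        bp <- bootstrap_p(a - b, n_iter = an$n_iter_boot,
                          seed = an$seed)
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = paste0(meas, ": cued vs uncued"), t = pt$t, df = pt$df,
          p = pt$p, cohen_d = pt$cohen_d, p_bootstrap = bp$p,
          p_bootstrap_label = bp$label)
      }
    }
    if (!is.null(link_tab) && nrow(link_tab) >= 2) {
      pt <- paired_test(link_tab$small_R, link_tab$larger_R)
      bp <- bootstrap_p(link_tab$difference, n_iter = an$n_iter_boot,
                        seed = an$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = "iem_R: small vs larger error", t = pt$t, df = pt$df,
        p = pt$p, cohen_d = pt$cohen_d, p_bootstrap = bp$p,
        p_bootstrap_label = bp$label)
    }
    report <- do.call(rbind, rows)
    m <- an$bonferroni_m %||% nrow(report)
    bf <- bonferroni(report$p, m = m)
    report$p_bonferroni <- bf$p_adjusted
    utils::write.csv(report, file.path(out_dir, "group_results.csv"),
                     row.names = FALSE)
    .write_provenance(out_dir, "report", config, list(bonferroni_m = m))
  }

  invisible(list(measures = measures, report = report, link = link_tab,
                 reconstructions = recons))
}
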