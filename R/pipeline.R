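#' Experiment configuration
#'
#' Describes a full restoration experiment: which geometries to simulate
#' (or load), which field sizes train the networks versus evaluate them,
#' which network families to train, and all grid/window/training settings.
#' Field sizes not listed in `train_fields_cm` are never seen during
#' training, so the test fields probe interpolation across field size.
#'
#' @param dataset A [dataset_config()] (its field list must cover both the
#'   train and test sets), or a directory containing a dataset written by
#'   [generate_dataset()].
#' @param train_fields_cm Field sizes used for training pairs.
#' @param test_fields_cm Held-out field sizes; must be disjoint from
#'   `train_fields_cm`.
#' @param models Network families to train: any of `"in"`, `"cross"`,
#'   `"combined"`.
#' @param n_hidden Hidden nodes per network (default 18, the sweep optimum).
#' @param grid_step_mm Makima upsampling step (default 0.5 mm).
#' @param training A [training_config()].
#' @param sweep Run [sweep_hidden_nodes()] instead of a fixed `n_hidden`.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(dataset = dataset_config(),
                              train_fields_cm = c(2, 4, 6, 10),
                              test_fields_cm = c(3, 5, 8),
                              models = c("in", "cross", "combined"),
                              n_hidden = 18L, grid_step_mm = 0.5,
                              training = training_config(),
                              sweep = FALSE) {
  if (length(intersect(train_fields_cm, test_fields_cm)))
    stop("train and test field sets must be disjoint")
  stopifnot(all(models %in% c("in", "cross", "combined")),
            inherits(training, "training_config"))
  if (inherits(dataset, "dataset_config")) {
    missing_f <- setdiff(c(train_fields_cm, test_fields_cm),
                         dataset$fields_cm)
    if (length(missing_f))
      stop("dataset does not generate field sizes: ",
           paste(missing_f, collapse = ", "))
  }
  structure(
    list(dataset = dataset, train_fields_cm = train_fields_cm,
         test_fields_cm = test_fields_cm, models = models,
         n_hidden = as.integer(n_hidden), grid_step_mm = grid_step_mm,
         training = training, sweep = isTRUE(sweep)),
    class = "experiment_config"
  )
}

#' Read back a dataset directory written by [generate_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and profile files.
#' @return The same entry list structure [generate_dataset()] returns.
#' @export
load_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  man <- read.csv(man_path)
  lapply(seq_len(nrow(man)), function(i) {
    truth <- read_profile(file.path(dir, man$truth_file[i]))
    meas <- read_profile(file.path(dir, man$measurement_file[i]))
    list(geometry = meas$geometry, truth = truth, measurement = meas,
         replicate = man$replicate[i])
  })
}

# tiny FNV-1a over the serialized config, for run-log provenance
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA, force = TRUE))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

family_label <- function(family)
  c("in" = "in_plane", "cross" = "cross_plane", "combined" = "combined")[[family]]

#' Run the full restoration experiment
#'
#' Generates (or loads) the paired dataset, Makima-upsamples every
#' measurement, builds sliding-window pair sets from the training fields,
#' trains the requested network families, reconstructs every geometry with
#' each applicable model, and scores reconstructions against the reference
#' profiles with PWD, 1-D gamma (1%/1 mm) and MSE.  Deterministic for a
#' given configuration.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for artifacts: per-geometry metrics
#'   CSV, per-(plane, depth) aggregate CSV, model JSON files, and a run
#'   log with seeds and the config hash.
#' @param verbose Print per-stage progress.
#' @return An `evaluation_report`: `$rows` (one row per geometry with
#'   baseline and per-model PWD/gamma/MSE), `$aggregates` (mean/SD of
#'   signed PWD and mean |PWD| per plane, depth and model), `$fits`
#'   (the trained `ann_fit` objects), `$sweeps` (when `sweep = TRUE`),
#'   `$pair_counts`, and `$config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating dataset")
  entries <- if (inherits(config$dataset, "dataset_config"))
    generate_dataset(config$dataset) else load_dataset(config$dataset)
  if (!length(entries)) stop("empty dataset")

  say("upsampling %d measurements (Makima, %.2g mm)", length(entries),
      config$grid_step_mm)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    upsampled <- makima_resample(e$measurement, config$grid_step_mm)
    entries[[i]]$upsampled <- upsampled
    entries[[i]]$reference <- resample_profile(e$truth,
                                               upsampled$positions_mm)
  }

  planes_present <- unique(vapply(entries, function(e) e$geometry$plane,
                                  character(1)))
  for (fam in config$models) {
    need <- if (fam == "combined") c("in", "cross") else fam
    if (!all(need %in% planes_present))
      stop("model family '", fam, "' needs planes missing from the dataset")
  }

  pair_sets <- list("in" = list(), "cross" = list())
  for (e in entries) {
    if (!e$geometry$field_size_cm %in% config$train_fields_cm) next
    pair_sets[[e$geometry$plane]] <-
      c(pair_sets[[e$geometry$plane]],
        list(extract_pairs(e$upsampled, e$reference,
                           config$training$window_mm)))
  }

  fits <- list()
  sweeps <- list()
  pair_counts <- integer()
  for (fam in config$models) {
    sets <- if (fam == "combined") c(pair_sets[["in"]], pair_sets[["cross"]])
            else pair_sets[[fam]]
    if (!length(sets)) stop("no training pairs for model family '", fam, "'")
    pairs <- combine_pairs(sets)
    pair_counts[fam] <- length(pairs$targets)
    tc <- config$training
    tc$seed <- restart_seed(tc$seed,
                            1000L * match(fam, c("in", "cross", "combined")))
    say("training %s model: %d pairs, %d restarts", fam,
        length(pairs$targets), tc$restarts)
    if (config$sweep) {
      sw <- sweep_hidden_nodes(pairs, tc)
      sweeps[[fam]] <- sw$curve
      fits[[fam]] <- sw$best_fit
      say("  sweep selected %d hidden nodes", sw$best_n_hidden)
    } else {
      fits[[fam]] <- train_lm(pairs, config$n_hidden, tc)
    }
    say("  val MSE %.3e (restart %d)", fits[[fam]]$mse["validation"],
        fits[[fam]]$selected_restart)
  }

  say("reconstructing %d geometries", length(entries))
  rows <- lapply(entries, function(e) {
    ref_pen <- penumbra(e$reference)
    row <- data.frame(
      plane = e$geometry$plane, field_cm = e$geometry$field_size_cm,
      depth_cm = e$geometry$depth_cm, replicate = e$replicate,
      role = if (e$geometry$field_size_cm %in% config$train_fields_cm)
        "train" else "test",
      pwd_makima = pwd(penumbra(e$upsampled), ref_pen))
    for (fam in config$models) {
      if (fam != "combined" && e$geometry$plane != fam) next
      recon <- reconstruct_profile(fits[[fam]]$model, e$upsampled)
      lab <- family_label(fam)
      row[[paste0("pwd_", lab)]] <- pwd(penumbra(recon), ref_pen)
      row[[paste0("gamma_", lab)]] <-
        gamma_1d(recon, e$reference)$pass_rate
      row[[paste0("mse_", lab)]] <- mse(recon$values, e$reference$values)
    }
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- do.call(rbind, lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA_real_
    r[all_cols]
  }))

  model_cols <- grep("^pwd_", all_cols, value = TRUE)
  agg <- list()
  for (col in model_cols) {
    model_name <- sub("^pwd_", "", col)
    for (plane in unique(rows$plane)) {
      for (depth in unique(rows$depth_cm)) {
        vals <- rows[[col]][rows$plane == plane & rows$depth_cm == depth]
        vals <- vals[!is.na(vals)]
        if (!length(vals)) next
        agg[[length(agg) + 1L]] <- cbind(
          data.frame(model = model_name, plane = plane, depth_cm = depth),
          pwd_summary(vals))
      }
    }
  }
  aggregates <- do.call(rbind, agg)

  report <- structure(
    list(rows = rows, aggregates = aggregates, fits = fits,
         sweeps = if (length(sweeps)) sweeps else NULL,
         pair_counts = pair_counts, config = config),
    class = "evaluation_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$rows, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(report$aggregates, file.path(out_dir, "aggregates.csv"),
            row.names = FALSE)
  for (fam in names(report$fits))
    save_ann(report$fits[[fam]],
             file.path(out_dir, sprintf("model_%s.json", family_label(fam))),
             metadata = list(family = fam,
                             config_hash = config_hash(report$config)))
  log_lines <- c(
    sprintf("config_hash: %s", config_hash(report$config)),
    sprintf("seed: %d", report$config$training$seed),
    sprintf("pair_counts: %s",
            paste(sprintf("%s=%d", names(report$pair_counts),
                          report$pair_counts), collapse = " ")),
    vapply(names(report$fits), function(fam) {
      f <- report$fits[[fam]]
      sprintf("model %s: n_hidden=%d selected_restart=%d val_mse=%.6e",
              fam, f$n_hidden, f$selected_restart, f$mse["validation"])
    }, character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d geometries\n", nrow(x$rows)))
  print(x$aggregates, digits = 3)
  invisible(x)
}

#' Compare plane-specific and combined reconstructions
#'
#' For each (plane, depth) cell, compares the absolute PWDs of profiles
#' reconstructed by the combined network against those from the matching
#' plane-specific network: the mean difference of |PWD| over the field
#' sizes and the maximum absolute per-field difference of signed PWD.
#'
#' @param report An `evaluation_report` containing both model families.
#' @return Data frame with one row per (plane, depth).
#' @export
compare_models <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  rows <- report$rows
  need <- c("pwd_combined", "pwd_in_plane", "pwd_cross_plane")
  if (!"pwd_combined" %in% names(rows) ||
      !any(c("pwd_in_plane", "pwd_cross_plane") %in% names(rows)))
    stop("report must contain both the combined and plane-specific families")
  out <- list()
  for (plane in unique(rows$plane)) {
    spec_col <- if (plane == "in") "pwd_in_plane" else "pwd_cross_plane"
    if (!spec_col %in% names(rows)) next
    for (depth in unique(rows$depth_cm)) {
      sel <- rows$plane == plane & rows$depth_cm == depth &
        !is.na(rows[[spec_col]]) & !is.na(rows$pwd_combined)
      if (!any(sel)) next
      comb <- rows$pwd_combined[sel]
      spec <- rows[[spec_col]][sel]
      out[[length(out) + 1L]] <- data.frame(
        plane = plane, depth_cm = depth, n_fields = sum(sel),
        mean_abs_pwd_combined = mean(abs(comb)),
        mean_abs_pwd_specific = mean(abs(spec)),
        mean_abs_pwd_diff = mean(abs(comb)) - mean(abs(spec)),
        max_abs_diff = max(abs(comb - spec)))
    }
  }
  do.call(rbind, out)
}
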