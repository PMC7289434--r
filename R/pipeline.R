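#' Read a pipeline run configuration
#'
#' Run configurations are structured YAML: a `seed`, replicate counts, split
#' windows, and a `facilities` section whose entries either name a preset
#' (`preset: F1`) or give [facility_config()] arguments directly.
#'
#' @param path YAML file path.
#' @return A validated run-config list (see [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  if (is.null(config$seed)) {
    stopf("run config: an explicit integer `seed` is required")
  }
  config$replicates <- config$replicates %||% 20L
  config$n_max <- config$n_max %||% 20L
  config$folds <- config$folds %||% 10L
  config$k <- config$k %||% 10L
  config$train_days <- config$train_days %||% 182L
  config$test_days <- config$test_days %||% 14L
  config$run_rf <- isTRUE(config$run_rf %||% FALSE)
  if (is.null(config$facilities) || !length(config$facilities)) {
    stopf("run config: at least one facility is required")
  }
  config
}

build_facility_configs <- function(config) {
  presets <- facility_presets(n_days = config$n_days %||% 250L,
                              seed = config$seed)
  out <- list()
  for (i in seq_along(config$facilities)) {
    fc <- config$facilities[[i]]
    if (is.character(fc) || !is.null(fc$preset)) {
      name <- if (is.character(fc)) fc else fc$preset
      if (!name %in% names(presets)) stopf("unknown facility preset: %s", name)
      out[[name]] <- presets[[name]]
    } else {
      fc$seed <- fc$seed %||% (config$seed + 100L + i)
      fc$n_days <- fc$n_days %||% (config$n_days %||% 250L)
      cfg <- do.call(facility_config, fc)
      out[[cfg$facility_id]] <- cfg
    }
  }
  out
}

#' Run the full simulation-to-transferability pipeline
#'
#' Orchestrates simulate -> featurize -> stepwise-LR selection (optionally RF
#' selection) -> cross-facility transfer into one reproducible run: every
#' stage writes its CSV outputs under `out_dir` and a run manifest records
#' all seeds, the package version and an MD5 checksum for every file.
#'
#' @param config run-config list (or a YAML path): `seed` (required),
#'   `facilities` (preset names or [facility_config()] argument lists),
#'   `replicates`, `n_max`, `folds`, `k`, `train_days`, `test_days`,
#'   `n_days`, `run_rf`.
#' @param out_dir output directory (created if needed).
#' @return The run bundle (invisibly): list with `manifest` plus per-facility
#'   selection results and the transfer matrix.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- feature_catalog()
  write_catalog(catalog, file.path(out_dir, "feature_catalog.csv"))

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cfgs <- stage("configure", build_facility_configs(config))

  matrices <- list()
  summaries <- list()
  sets <- list()
  rf_results <- list()
  for (fid in names(cfgs)) {
    sim <- stage(paste0("simulate:", fid), simulate_facility(cfgs[[fid]]))
    write_event_log(sim$log, file.path(out_dir, paste0("log_", fid, ".csv")))

    profile <- stage(paste0("profile:", fid),
                     facility_profile(sim$log,
                                      slot_minutes = cfgs[[fid]]$slot_minutes,
                                      n_servers = cfgs[[fid]]$n_servers))
    fm <- stage(paste0("featurize:", fid),
                featurize_log(sim$log, catalog, profile))
    write_feature_matrix(fm, file.path(out_dir, paste0("features_", fid, ".csv")))
    matrices[[fid]] <- fm

    sel <- stage(paste0("select-lr:", fid), run_stepwise_selection(
      fm, R = config$replicates, n_max = config$n_max, folds = config$folds,
      seed = config$seed + match(fid, names(cfgs)), k = config$k,
      train_days = config$train_days, test_days = config$test_days))
    summaries[[fid]] <- sel$summary
    utils::write.csv(as.data.frame(sel$summary),
                     file.path(out_dir, paste0("lr_frequency_", fid, ".csv")),
                     row.names = FALSE)
    curves <- do.call(rbind, lapply(seq_along(sel$paths), function(r) {
      data.frame(replicate = r, n_features = 0:sel$paths[[r]]$n_max,
                 pct_error = sel$paths[[r]]$pct_error)
    }))
    utils::write.csv(curves,
                     file.path(out_dir, paste0("lr_error_curve_", fid, ".csv")),
                     row.names = FALSE)
    sets[[fid]] <- feature_set(top_features(sel$summary), fid, catalog)

    if (config$run_rf) {
      rf <- stage(paste0("select-rf:", fid), run_rf_selection(
        fm, R = config$replicates, seed = config$seed + 50L + match(fid, names(cfgs)),
        k = config$k, train_days = config$train_days,
        test_days = config$test_days))
      rf_results[[fid]] <- rf
      utils::write.csv(as.data.frame(rf$ranking),
                       file.path(out_dir, paste0("rf_importance_", fid, ".csv")),
                       row.names = FALSE)
    }
  }

  transfer <- NULL
  if (length(matrices) >= 2L) {
    sets$union <- union_sets(sets[names(cfgs)], "union", catalog)
    transfer <- stage("transfer", transfer_matrix(
      matrices, sets, model = "linear", R = max(2L, config$replicates %/% 2L),
      seed = config$seed + 99L, catalog = catalog,
      train_days = config$train_days, test_days = config$test_days))
    utils::write.csv(as.data.frame(transfer$ratio),
                     file.path(out_dir, "transfer_ratio.csv"))
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "flowsel",
    version = as.character(utils::packageVersion("flowsel")),
    seed = config$seed,
    replicates = config$replicates,
    n_max = config$n_max,
    folds = config$folds,
    facilities = names(cfgs),
    facility_seeds = vapply(cfgs, `[[`, integer(1), "seed"),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  bundle <- list(out_dir = out_dir, config = config, manifest = manifest,
                 summaries = summaries, sets = sets, rf = rf_results,
                 transfer = transfer)
  class(bundle) <- "flowsel_bundle"
  invisible(bundle)
}

#' Render a human-readable run report
#'
#' Summarizes a pipeline bundle: the feature catalog, per-facility selection
#' frequencies (sorted descending), error-curve endpoints and the transfer
#' ratio matrix.
#'
#' @param bundle result of [run_pipeline()] (or its `out_dir`).
#' @param file optional path; when given the report is also written there.
#' @return Character vector of report lines, invisibly; the report is printed.
#' @export
render_report <- function(bundle, file = NULL) {
  if (is.character(bundle)) {
    manifest_path <- file.path(bundle, "manifest.json")
    if (!file.exists(manifest_path)) {
      stopf("render_report: no manifest.json in %s — incomplete bundle", bundle)
    }
    bundle <- list(out_dir = bundle,
                   manifest = jsonlite::read_json(manifest_path))
  }
  if (is.null(bundle$manifest)) stopf("render_report: incomplete bundle")
  catalog <- feature_catalog()
  lines <- c(
    "== flowsel run report ==",
    sprintf("seed: %s   replicates: %s", bundle$manifest$seed,
            bundle$manifest$replicates),
    sprintf("feature catalog: %d features in %d groups (%s)",
            nrow(catalog), length(unique(catalog$group)),
            paste(sprintf("%s=%d", names(table(catalog$group)),
                          as.integer(table(catalog$group))), collapse = ", "))
  )
  for (fid in names(bundle$summaries %||% list())) {
    s <- bundle$summaries[[fid]]
    lines <- c(lines, sprintf("-- %s: top features by selection frequency --", fid))
    top <- utils::head(as.data.frame(s), 10L)
    lines <- c(lines, sprintf("  %-28s %5.1f%%", top$feature, top$frequency_pct))
  }
  if (!is.null(bundle$transfer)) {
    lines <- c(lines, "-- transfer ratios (data facility x feature-set source) --",
               utils::capture.output(print(round(bundle$transfer$ratio, 3))))
  }
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
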