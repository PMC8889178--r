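#' Read a flat key/value run configuration
#'
#' The file holds one `key = value` pair per line (`#` comments allowed).
#' Unknown keys are an error, so a configuration cannot silently drift.
#' Defaults follow the package's reference analysis settings: VIF threshold
#' 0.85, ten methods, three runs, 80/20 calibration split, prevalence 0.5,
#' three importance permutations, ROC gate 0.9 with 0.8 fallback, strict
#' 50% consensus, queen connectivity, 0.1 km^2 patch filter.
#'
#' @param path optional config file; omitted means all defaults.
#' @param ... overrides of individual keys.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    layers_dir = NULL, occurrences = NULL, out_dir = "enm_run",
    lat_min = -49, lat_max = -32, lon_min = 165, lon_max = 180,
    vif_threshold = 0.85, methods = enm_methods(), n_runs = 3,
    calibration_fraction = 0.8, prevalence = 0.5,
    n_importance_perms = 3, roc_gate = 0.9, roc_fallback = 0.8,
    consensus = 0.5, connectivity = 8, min_patch_km2 = 0.1,
    cutoff_rule = "tss_max", seed = 1)
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*", "", lines)
    lines <- lines[grepl("=", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- if (key == "methods") strsplit(val, "[,;] *")[[1]]
        else if (suppressWarnings(!is.na(as.numeric(val)))) as.numeric(val)
        else val
    }
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0) stop("unknown config key: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Run the full ensemble niche-modelling analysis
#'
#' For each species: derives absences from the multi-species compilation,
#' screens continuous layers by VIF, fits the candidate models, builds the
#' ROC-gated weighted-mean ensemble, projects suitability under every
#' scenario, forms consensus binary maps, classifies transitions against
#' the current map, computes range change in both dispersal modes, and
#' produces fragmentation reports.  All tables are written as CSV and all
#' grids as ESRI ASCII under `out_dir`; a run log records settings and
#' per-stage counts.
#'
#' @param occurrences multi-species occurrence data.frame (filtered).
#' @param stack current-conditions `env_stack`.
#' @param scenarios named list of future `env_stack`s (same layers).
#' @param species character vector of target species (default: all with
#'   presences in `occurrences`).
#' @param config a [run_config()].
#' @param write logical; write outputs under `config$out_dir`
#'   (default `TRUE`).
#' @return invisible list of per-species results: the `enm` fit, per
#'   scenario consensus binaries, transitions, `range_change`, and
#'   `frag_report`s.  Species for which no model clears the ROC fallback
#'   are reported and skipped.
#' @export
run_enm_pipeline <- function(occurrences, stack, scenarios,
                             species = NULL, config = run_config(),
                             write = TRUE) {
  if (is.null(species))
    species <- unique(occurrences$species[occurrences$presence == 1])
  out_dir <- config$out_dir
  if (write) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed=%d", config$seed),
                 sprintf("settings: vif=%.2f gate=%.2f fallback=%.2f consensus=%.2f connectivity=%d min_patch=%.2f",
                         config$vif_threshold, config$roc_gate,
                         config$roc_fallback, config$consensus,
                         config$connectivity, config$min_patch_km2))
  results <- list()
  eval_rows <- list(); imp_rows <- list(); rc_rows <- list(); fr_rows <- list()
  for (sp in species) {
    fit <- tryCatch(
      enm(occurrences, stack, species = sp, methods = config$methods,
          n_runs = config$n_runs,
          calib_fraction = config$calibration_fraction,
          prevalence = config$prevalence,
          n_perm = config$n_importance_perms, roc_gate = config$roc_gate,
          roc_fallback = config$roc_fallback,
          vif_threshold = config$vif_threshold, seed = config$seed),
      error = function(e) e)
    if (inherits(fit, "error") || is.null(fit$ensemble)) {
      msg <- if (inherits(fit, "error")) conditionMessage(fit)
             else "no model cleared the ROC fallback gate"
      log_lines <- c(log_lines, sprintf("species=%s SKIPPED (%s)", sp, msg))
      results[[sp]] <- list(skipped = TRUE, reason = msg)
      next
    }
    sc <- summary.enm(fit)
    sc$species <- sp
    eval_rows[[sp]] <- sc
    imp_rows[[sp]] <- data.frame(species = sp,
                                 variable = names(fit$ensemble$importance),
                                 importance_pct =
                                   as.numeric(fit$ensemble$importance),
                                 stringsAsFactors = FALSE)
    cur_bin <- predict(fit, stack, type = "consensus",
                       consensus = config$consensus)
    maps <- list(current = cur_bin)
    rcs <- list(); frs <- list(current = frag_report(
      cur_bin, stack, config$connectivity, config$min_patch_km2))
    trans <- list()
    for (scn in names(scenarios)) {
      fut_bin <- predict(fit, scenarios[[scn]], type = "consensus",
                         consensus = config$consensus)
      maps[[scn]] <- fut_bin
      tm <- classify_transitions(cur_bin, fut_bin)
      trans[[scn]] <- tm
      rcs[[scn]] <- tryCatch(range_change(tm, config$connectivity),
                             error = function(e) NULL)
      frs[[scn]] <- frag_report(fut_bin, stack, config$connectivity,
                                config$min_patch_km2)
      if (!is.null(rcs[[scn]])) {
        s <- rcs[[scn]]$stats
        s$species <- sp; s$scenario <- scn
        s$n_current <- rcs[[scn]]$n_current
        s$n_lost <- rcs[[scn]]$n_lost; s$n_gained <- rcs[[scn]]$n_gained
        rc_rows[[paste(sp, scn)]] <- s
      }
      cnt <- transition_counts(tm)
      log_lines <- c(log_lines, sprintf(
        "species=%s scenario=%s never=%d always=%d lost=%d gained=%d",
        sp, scn, cnt[1], cnt[2], cnt[3], cnt[4]))
    }
    for (scn in names(frs)) {
      f <- frs[[scn]]
      fr_rows[[paste(sp, scn)]] <- data.frame(
        species = sp, scenario = scn, n_patches = f$n_patches,
        total_area = f$total_area, mean_patch_area = f$mean_patch_area,
        splitting_index = f$splitting_index,
        aggregation_index = f$aggregation_index, stringsAsFactors = FALSE)
    }
    n_fail <- sum(vapply(fit$models, function(m) is.null(m$eval),
                         logical(1)))
    log_lines <- c(log_lines, sprintf(
      "species=%s models_evaluated=%d models_failed=%d members=%d gate=%.1f",
      sp, nrow(fit$scores), n_fail, length(fit$ensemble$member_ids),
      fit$ensemble$threshold_used))
    if (write) {
      spdir <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", sp))
      dir.create(spdir, showWarnings = FALSE, recursive = TRUE)
      suit <- predict(fit, stack, type = "ensemble")
      write_ascii_grid(suit, file.path(spdir, "suitability_current.asc"),
                       stack$extent, stack$res)
      for (nm in names(maps))
        write_ascii_grid(maps[[nm]],
                         file.path(spdir, paste0("binary_", nm, ".asc")),
                         stack$extent, stack$res)
      for (nm in names(trans))
        write_ascii_grid(unclass(trans[[nm]]),
                         file.path(spdir, paste0("transition_", nm, ".asc")),
                         stack$extent, stack$res)
    }
    results[[sp]] <- list(fit = fit, binary = maps, transitions = trans,
                          range_change = rcs, frag = frs)
  }
  tables <- list(evaluation = do.call(rbind, eval_rows),
                 importance = do.call(rbind, imp_rows),
                 range_change = do.call(rbind, rc_rows),
                 fragmentation = do.call(rbind, fr_rows))
  for (nm in names(tables)) if (!is.null(tables[[nm]]))
    rownames(tables[[nm]]) <- NULL
  if (write) {
    for (nm in names(tables)) if (!is.null(tables[[nm]]))
      utils::write.csv(tables[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(list(species = results, tables = tables, log = log_lines,
                 config = config))
}

#' Species summary table of range change and top predictors
#'
#' One row per modelled species: the most important ensemble predictor and
#' the net range-change percentage (rounded to integers, as conventional in
#' summary tables) for each scenario under both dispersal assumptions.
#'
#' @param run result of [run_enm_pipeline()].
#' @return data.frame.
#' @export
report_range_change <- function(run) {
  rows <- list()
  for (sp in names(run$species)) {
    res <- run$species[[sp]]
    if (isTRUE(res$skipped)) next
    imp <- variable_importance.enm(res$fit)
    row <- list(species = sp,
                top_predictor = names(which.max(imp)))
    for (scn in names(res$range_change)) {
      rc <- res$range_change[[scn]]
      if (is.null(rc)) next
      s <- rc$stats
      row[[paste0(scn, "_dispersal_net_pct")]] <-
        round(s$net_pct[s$mode == "dispersal"])
      row[[paste0(scn, "_no_dispersal_net_pct")]] <-
        round(s$net_pct[s$mode == "no_dispersal"])
    }
    rows[[sp]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
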