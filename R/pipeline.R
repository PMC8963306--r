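#' Simulate a benchmark dataset to disk
#'
#' Thin orchestration over [make_benchmark()]: writes the protein table, the
#' per-protein native structures, SSE tables, decoy trajectories, ground
#' truth and a manifest recording seeds and counts.
#'
#' @param dir Output directory. Refuses to overwrite a non-empty directory
#'   unless `force = TRUE`.
#' @param config An [fq_config()]; `decoys` and `seed` are honoured.
#' @param force Overwrite an existing non-empty directory.
#' @param fmt Trajectory format, `"dcd"` or `"pdb"`.
#' @param ... Further arguments to [make_benchmark()] (e.g. `n_proteins`).
#' @return The benchmark object, invisibly.
#' @export
run_simulate <- function(dir, config = fq_config(), force = FALSE,
                         fmt = "dcd", ...) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(paste0("Output directory not empty (use force = TRUE): ", dir),
          class = "foldq_error")
  }
  args <- list(...)
  args$decoys_per_protein <- args$decoys_per_protein %||% config$decoys
  args$seed <- args$seed %||% config$seed
  bench <- do.call(make_benchmark, args)
  write_benchmark(bench, dir, fmt = fmt)
  cfg_path <- file.path(dir, "config.txt")
  write_config(config, cfg_path)
  invisible(bench)
}

#' Analyze every decoy trajectory in a dataset directory
#'
#' Walks the per-protein directories written by [run_simulate()], runs the
#' kinetics analysis on each decoy trajectory and stores one JSON call
#' record per decoy under `dir/calls/`. Existing records are not recomputed,
#' so an interrupted run can simply be restarted. Corrupt or unreadable
#' decoys are skipped with a warning; the function errors only if every
#' decoy fails.
#'
#' @param dir Dataset directory.
#' @param config An [fq_config()].
#' @param decoys Optional cap on decoys per protein.
#' @param cache Read/write per-decoy JSON records under `dir/calls/`
#'   (disable when re-analyzing under non-default parameters, e.g. in a
#'   sweep, so stale records are never reused).
#' @return An `fq_calls` tibble, one row per decoy.
#' @export
run_analyze <- function(dir, config = fq_config(), decoys = NULL,
                        cache = TRUE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("No manifest.json in ", dir), class = "foldq_error")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  calls_dir <- file.path(dir, "calls")
  if (cache) dir.create(calls_dir, showWarnings = FALSE)
  ext <- if (identical(manifest$format, "pdb")) ".pdb" else ".dcd"
  rows <- list()
  n_total <- 0L; n_failed <- 0L
  for (pid in manifest$proteins) {
    pdir <- file.path(dir, pid)
    sse_path <- file.path(pdir, "sse.csv")
    if (!file.exists(sse_path)) {
      warn(paste0("Missing SSE file for ", pid, "; protein skipped."))
      next
    }
    native <- read_structure(file.path(pdir, "native.pdb"), protein_id = pid)
    sse <- load_sse(sse_path, min_sse_len = config$min_sse_len)
    contacts <- native_contacts(native, sse, cutoff = config$cutoff)
    truth <- jsonlite::read_json(file.path(pdir, "truth.json"),
                                 simplifyVector = TRUE)
    decoy_files <- sort(list.files(pdir, pattern = paste0("^decoy_\\d+\\", ext, "$")))
    if (!is.null(decoys)) decoy_files <- head(decoy_files, decoys)
    for (df in decoy_files) {
      n_total <- n_total + 1L
      decoy <- as.integer(sub("^decoy_0*(\\d+)\\..*$", "\\1", df))
      record_path <- file.path(calls_dir, sprintf("%s_decoy_%03d.json", pid, decoy))
      if (cache && file.exists(record_path)) {
        rec <- jsonlite::read_json(record_path, simplifyVector = TRUE)
        rows[[record_path]] <- call_record_row(rec)
        next
      }
      res <- tryCatch({
        traj <- read_trajectory(file.path(pdir, "native.pdb"),
                                file.path(pdir, df),
                                fmt = if (ext == ".pdb") "pdb" else "dcd")
        analyze_trajectory(traj, contacts, config)
      }, error = function(e) {
        warn(sprintf("Decoy %s of %s failed: %s", df, pid, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      rec <- list(
        protein_id = pid, decoy = decoy,
        true_class = truth$plan$class[match(decoy, truth$plan$decoy)],
        peaks = res$peaks, label = res$label, onset = res$onset,
        intermediate_vectors = res$intermediate_vectors,
        excluded_pairs = res$excluded_pairs,
        bandwidth = res$bandwidth, seed = config$seed
      )
      if (cache) {
        jsonlite::write_json(rec, record_path, auto_unbox = TRUE, digits = NA)
      }
      rows[[record_path]] <- call_record_row(rec)
    }
  }
  if (n_total > 0 && n_failed == n_total) {
    abort("Every decoy failed to analyze.", class = "foldq_error")
  }
  out <- bind_rows(rows)
  class(out) <- c("fq_calls", class(out))
  out
}

# One tibble row from a (possibly JSON-round-tripped) call record.
call_record_row <- function(rec) {
  iv <- rec$intermediate_vectors
  first <- NULL
  if (!is.null(iv) && length(iv) > 0) {
    v <- if (is.data.frame(iv)) unlist(iv[1, , drop = TRUE]) else iv[[1]]
    first <- setNames(as.integer(v), names(v))
  }
  tibble(
    protein_id = rec$protein_id, decoy = rec$decoy,
    true_class = rec$true_class %||% NA_character_,
    label = rec$label, n_peaks = length(rec$peaks),
    onset = rec$onset, bandwidth = rec$bandwidth,
    first_intermediate = list(first)
  )
}

#' Evaluate a dataset end to end
#'
#' Combines [evaluate_kinetics()], [onset_statistic()],
#' [evaluate_intermediates()] and [consistency_by_protein()] into one report
#' and optionally writes it (JSON report plus per-protein CSV) to `out_dir`.
#'
#' @param calls An `fq_calls` tibble from [run_analyze()] or
#'   [benchmark_calls()].
#' @param records An `fq_protein_table`.
#' @param hdx Optional `fq_hdx` tibble.
#' @param config An [fq_config()].
#' @param cv Run the supervised CV (slow for large `cv_repeats`).
#' @param out_dir Optional output directory for the serialized report.
#' @return A list of class `fq_report` with elements `kinetics`, `rate`
#'   (NULL when no finite `ln_kf` is available), `intermediates` (NULL
#'   without HDX data) and `consistency`.
#' @export
run_evaluate <- function(calls, records, hdx = NULL, config = fq_config(),
                         cv = TRUE, out_dir = NULL) {
  kin <- evaluate_kinetics(calls, records, config, cv = cv)
  rate <- NULL
  if (any(is.finite(records$ln_kf))) {
    rate <- tryCatch(onset_statistic(calls, records),
                     foldq_error = function(e) NULL)
  }
  inter <- NULL
  if (!is.null(hdx)) {
    inter <- tryCatch(
      evaluate_intermediates(calls, hdx, seed = config$seed),
      foldq_error = function(e) NULL)
  }
  consistency <- consistency_by_protein(calls)
  report <- structure(list(
    kinetics = kin, rate = rate, intermediates = inter,
    consistency = consistency, config = config,
    config_hash = config_hash(config)
  ), class = "fq_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(kin$per_protein, file.path(out_dir, "per_protein.csv"))
    jsonlite::write_json(report_json(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_json <- function(report) {
  kin <- report$kinetics
  list(
    config_hash = report$config_hash,
    seed = report$config$seed,
    unsupervised = kin$unsupervised,
    supervised = if (!is.null(kin$supervised)) unclass(kin$supervised),
    auroc = kin$auroc,
    baseline = list(auroc = kin$baseline$auroc,
                    cv = if (!is.null(kin$baseline$cv)) unclass(kin$baseline$cv)),
    bootstrap = unclass(kin$bootstrap),
    permutation_vs_length = unclass(kin$permutation_vs_length),
    rate = if (!is.null(report$rate))
      list(rho = report$rate$rho, p_value = report$rate$p_value,
           n = nrow(report$rate$data)),
    mean_consistency = if (nrow(report$consistency) > 0)
      mean(report$consistency$consistency)
  )
}

#' @export
print.fq_report <- function(x, ...) {
  print(x$kinetics)
  if (!is.null(x$rate)) print(x$rate)
  if (!is.null(x$intermediates)) {
    cat(sprintf("  intermediates vs HDX: mean Jaccard %.3f over %d proteins\n",
                x$intermediates$mean$jaccard_score,
                nrow(x$intermediates$per_protein)))
  }
  if (nrow(x$consistency) > 0) {
    cat(sprintf("  mean decoy consistency: %.3f\n",
                mean(x$consistency$consistency)))
  }
  invisible(x)
}

#' Parameter sweep over contact cutoff and flexibility multiplier
#'
#' Re-runs the analysis on a reduced decoy subset for every (cutoff, xi)
#' grid cell and records the unsupervised balanced accuracy per cell —
#' a sensitivity check that conclusions do not hinge on the two contact
#' parameters.
#'
#' @param bench An `fq_benchmark`, or the path of a dataset directory
#'   written by [run_simulate()].
#' @param cutoffs Numeric vector of contact cutoffs (Angstrom).
#' @param xis Numeric vector of flexibility multipliers.
#' @param decoys Decoys per protein used in each cell.
#' @param config Base [fq_config()].
#' @return A tibble of class `fq_sweep`: `cutoff`, `xi`,
#'   `balanced_accuracy`, `f1`, `auroc`, `config_hash`.
#' @export
run_sweep <- function(bench, cutoffs = c(7, 8, 9), xis = c(1.1, 1.2, 1.3),
                      decoys = NULL, config = fq_config()) {
  if (length(cutoffs) == 0 || length(xis) == 0) {
    abort("Sweep grid is empty.", class = "foldq_error")
  }
  decoys <- decoys %||% config$sweep_decoys
  from_dir <- is.character(bench)
  records <- if (from_dir) {
    load_protein_table(file.path(bench, "protein_table.csv"))
  } else {
    bench$table
  }
  grid <- tidyr::expand_grid(cutoff = cutoffs, xi = xis)
  cells <- purrr::pmap(grid, function(cutoff, xi) {
    cfg <- config
    cfg$cutoff <- cutoff
    cfg$xi <- xi
    calls <- if (from_dir) {
      run_analyze(bench, cfg, decoys = decoys, cache = FALSE)
    } else {
      benchmark_calls(bench, cfg, decoys = decoys)
    }
    ev <- evaluate_kinetics(calls, records, cfg, cv = FALSE)
    tibble(cutoff = cutoff, xi = xi,
           balanced_accuracy = ev$unsupervised$balanced_accuracy,
           f1 = ev$unsupervised$f1, auroc = ev$auroc,
           config_hash = config_hash(cfg))
  })
  out <- bind_rows(cells)
  class(out) <- c("fq_sweep", class(out))
  out
}
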