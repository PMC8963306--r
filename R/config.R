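#' Analysis configuration
#'
#' Bundles every tunable of the pipeline in one list: the native-contact
#' definition, the smoother, the KDE peak caller, and the Monte-Carlo
#' replication counts used by the evaluation statistics.
#'
#' @param cutoff Native-contact distance threshold in Angstrom. Two residues
#'   are in native contact when their beta-carbons (alpha-carbon for glycine)
#'   are strictly closer than `cutoff` in the reference structure.
#' @param xi Flexibility multiplier: a native contact with reference distance
#'   `d` still counts as formed in a trajectory frame when the frame distance
#'   is at most `xi * d`.
#' @param min_sse_len Minimum secondary-structure element span in residues;
#'   shorter elements are dropped before any contact is computed.
#' @param activity_threshold Minimum range (max - min) of a pair's Q series
#'   for the pair to contribute a transition time; pairs that never change
#'   are excluded rather than contributing a noise-driven argmax.
#' @param bass Bass enhancement (0..10) passed to [supersmooth()]; larger
#'   values favour smoother fits.
#' @param grid_points Number of uniform grid points on \[0, 1\] used to
#'   evaluate the transition-time kernel density estimate.
#' @param min_prominence Relative prominence (fraction of the global density
#'   maximum) below which a local KDE maximum is not counted as a peak. The
#'   default is calibrated so that a single-phase trajectory yields one peak
#'   in at least 99% of seeded runs (see the methods vignette).
#' @param onset_method How the folding-event onset of a trajectory is defined:
#'   `"min_t"` (earliest included transition time, the default) or
#'   `"first_peak"` (first KDE mode minus one bandwidth, floored at 0).
#' @param cv_feature Regressor used by the supervised evaluation: the
#'   `"fraction"` of two-state decoys (continuous, default) or the `"binary"`
#'   majority call.
#' @param decoys Default number of decoy trajectories per protein when
#'   simulating a benchmark.
#' @param sweep_decoys Decoys per protein used by the parameter sweep.
#' @param n_boot Bootstrap replicates for the AUROC-vs-random test.
#' @param n_perm Permutation replicates for paired classifier comparison.
#' @param cv_repeats Repeats of the stratified cross-validation.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed recorded in every derived output.
#'
#' @return A list of class `fq_config`.
#' @examples
#' cfg <- fq_config(seed = 7)
#' cfg$cutoff
#' @export
fq_config <- function(cutoff = 8.0,
                      xi = 1.2,
                      min_sse_len = 4L,
                      activity_threshold = 0.2,
                      bass = 0,
                      grid_points = 512L,
                      min_prominence = 0.15,
                      onset_method = c("min_t", "first_peak"),
                      cv_feature = c("fraction", "binary"),
                      decoys = 200L,
                      sweep_decoys = 10L,
                      n_boot = 100000L,
                      n_perm = 10000L,
                      cv_repeats = 1000L,
                      folds = 5L,
                      seed = 1L) {
  onset_method <- match.arg(onset_method)
  cv_feature <- match.arg(cv_feature)
  if (cutoff <= 0) abort("`cutoff` must be positive.", class = "foldq_error")
  if (xi < 1) abort("`xi` must be >= 1.", class = "foldq_error")
  if (min_sse_len < 1) abort("`min_sse_len` must be >= 1.", class = "foldq_error")
  reps <- c(n_boot = n_boot, n_perm = n_perm, cv_repeats = cv_repeats,
            folds = folds, decoys = decoys, sweep_decoys = sweep_decoys)
  if (any(reps < 1)) {
    abort(sprintf("Replication counts must be >= 1 (offending: %s).",
                  paste(names(reps)[reps < 1], collapse = ", ")),
          class = "foldq_error")
  }
  structure(list(
    cutoff = cutoff, xi = xi, min_sse_len = as.integer(min_sse_len),
    activity_threshold = activity_threshold, bass = bass,
    grid_points = as.integer(grid_points), min_prominence = min_prominence,
    onset_method = onset_method, cv_feature = cv_feature,
    decoys = as.integer(decoys), sweep_decoys = as.integer(sweep_decoys),
    n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
    cv_repeats = as.integer(cv_repeats), folds = as.integer(folds),
    seed = as.integer(seed)
  ), class = "fq_config")
}

#' @export
print.fq_config <- function(x, ...) {
  cat("<fq_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read and write a flat key = value configuration file
#'
#' The on-disk form is one `key = value` pair per line; unknown keys raise an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path File path.
#' @param config An `fq_config` list.
#' @return `read_config()` returns an `fq_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path),
                                class = "foldq_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(paste0("Malformed config line: ", lines[bad][1]),
                      class = "foldq_error")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  proto <- fq_config()
  unknown <- setdiff(keys, names(proto))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "foldq_error")
  }
  args <- Map(function(k, v) {
    if (is.character(proto[[k]])) v else as.numeric(v)
  }, keys, vals)
  do.call(fq_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fq_config"))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, scientific = FALSE), "")),
             path)
  invisible(path)
}

#' Stable hash of a configuration (for run manifests)
#' @param config An `fq_config`.
#' @return A hexadecimal string.
#' @keywords internal
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, format, ""), collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Derive a reproducible 32-bit sub-seed from (seed, protein, decoy).
decoy_seed <- function(seed, protein_id, decoy_index) {
  bytes <- utf8ToInt(paste0(protein_id, "#", decoy_index))
  h <- as.numeric(seed) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
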