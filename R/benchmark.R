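#' Generate a synthetic benchmark dataset with known ground truth
#'
#' Builds a cohort of toy proteins whose folding kinetics class, decoy
#' trajectories, folding rate constants and HDX-style intermediate
#' annotations are all generated from known models, so every downstream
#' stage of the pipeline can be scored against ground truth:
#'
#' * Chain length is drawn uniformly in `length_range` (then snapped to the
#'   nearest rod layout); the kinetics class is drawn from a logistic model
#'   on centred length with log-odds slope `coupling` toward multistate and
#'   intercept solved so the expected two-state share is `p_two_state`.
#' * Two-state proteins get a single-phase docking schedule
#'   (time ~ U(0.3, 0.7)); multistate proteins a two-phase schedule
#'   (first ~ U(0.15, 0.35), second ~ U(0.6, 0.85)).
#' * `ln k_f = a + b * onset + e`, with `onset` the scheduled first docking
#'   time and `e ~ N(0, sd)` (`kf_model = list(a, b, sd)`).
#' * Each decoy simulates the protein's schedule with per-decoy jitter and
#'   coordinate noise; with probability `decoy_flip` a decoy follows the
#'   opposite class's schedule instead (trajectory-to-trajectory
#'   variability).
#' * HDX-style vectors for multistate proteins are the ground-truth first
#'   intermediate contact vector.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param decoys_per_protein Decoy trajectories per protein.
#' @param p_two_state Expected share of two-state proteins.
#' @param length_range Chain-length range (residues) before snapping.
#' @param coupling Log-odds slope of class on centred length (per residue).
#' @param kf_model List `a`, `b`, `sd` of the linear onset model for ln k_f.
#' @param n_frames Frames per decoy trajectory.
#' @param noise_sd Coordinate noise in Angstrom.
#' @param transition_width Logistic ramp width (fraction of trajectory).
#' @param jitter_sd Per-decoy jitter of docking times.
#' @param decoy_flip Probability a decoy follows the opposite class.
#' @param seed Integer master seed; every decoy derives its own recorded
#'   sub-seed from it.
#' @param dir Optional output directory; when given, the dataset is written
#'   to disk in the package's file formats (see [run_simulate()]).
#' @return An `fq_benchmark` list: `table` (protein table with ln_kf),
#'   `proteins` (per-protein structure, SSE, contacts, schedules, decoy
#'   plan), `hdx` (long tibble), and the generation parameters.
#' @export
make_benchmark <- function(n_proteins = 170L,
                           decoys_per_protein = 20L,
                           p_two_state = 0.53,
                           length_range = c(54, 103),
                           coupling = 0.08,
                           kf_model = list(a = 2, b = -8, sd = 1),
                           n_frames = 200L,
                           noise_sd = 0.2,
                           transition_width = 0.03,
                           jitter_sd = 0.02,
                           decoy_flip = 0,
                           seed = 1L,
                           dir = NULL) {
  if (n_proteins < 2) abort("Need at least 2 proteins.", class = "foldq_error")
  if (p_two_state < 0 || p_two_state > 1 || decoy_flip < 0 || decoy_flip > 1) {
    abort("Probabilities must lie in [0, 1].", class = "foldq_error")
  }
  set.seed(seed)
  w <- transition_width
  ids <- sprintf("P%03d", seq_len(n_proteins))
  raw_len <- runif(n_proteins, length_range[1], length_range[2])
  n_el <- pmax(2L, as.integer(round((raw_len + 2) / 7)))
  length_actual <- 7L * n_el - 2L            # 5-residue rods, 2-residue linkers
  lc <- length_actual - mean(length_actual)
  if (p_two_state <= 0 || p_two_state >= 1) {
    # degenerate cohort: a single class, no length coupling possible
    p2 <- rep(p_two_state, n_proteins)
  } else {
    # intercept such that the marginal two-state probability is p_two_state
    f <- function(a) mean(plogis(a - coupling * lc)) - p_two_state
    alpha <- if (abs(coupling) < 1e-12) stats::qlogis(p_two_state) else
      uniroot(f, c(-50, 50))$root
    p2 <- plogis(alpha - coupling * lc)      # longer chains -> multistate
  }
  class <- ifelse(runif(n_proteins) < p2, "two_state", "multistate")
  tau1_two <- runif(n_proteins, 0.3, 0.7)
  tau1_multi <- runif(n_proteins, 0.15, 0.3)
  tau2_multi <- runif(n_proteins, 0.65, 0.85)
  onset_sched <- ifelse(class == "two_state", tau1_two, tau1_multi)
  ln_kf <- kf_model$a + kf_model$b * onset_sched +
    rnorm(n_proteins, 0, kf_model$sd)
  flip_mat <- matrix(runif(n_proteins * decoys_per_protein) < decoy_flip,
                     n_proteins, decoys_per_protein)
  proteins <- vector("list", n_proteins)
  names(proteins) <- ids
  hdx_rows <- list()
  for (i in seq_len(n_proteins)) {
    nat <- make_native(n_el[i], element_len = 5L, spacing = 6,
                       seed = decoy_seed(seed, ids[i], 0L))
    el <- nat$sse$element_id
    # floor(n/2) + 1 elements in the first group balances the number of
    # element pairs docking in each phase for the ladder contact topology
    # (cross-group pairs always dock in the later phase)
    half <- min(length(el) - 1L, floor(length(el) / 2) + 1L)
    groups2 <- setNames(c(rep(1L, half), rep(2L, length(el) - half)), el)
    sched_two <- phase_schedule(setNames(rep(1L, length(el)), el),
                                tau1_two[i], transition_width = w,
                                jitter_sd = jitter_sd)
    sched_multi <- phase_schedule(groups2, c(tau1_multi[i], tau2_multi[i]),
                                  transition_width = w, jitter_sd = jitter_sd)
    ct <- native_contacts(nat$structure, nat$sse, cutoff = 8.0)
    decoy_class <- ifelse(xor(class[i] == "multistate", flip_mat[i, ]),
                          "multistate", "two_state")
    plan <- tibble(
      protein_id = ids[i],
      decoy = seq_len(decoys_per_protein),
      class = decoy_class,
      seed = vapply(seq_len(decoys_per_protein),
                    function(d) decoy_seed(seed, ids[i], d), integer(1))
    )
    proteins[[i]] <- list(
      id = ids[i], structure = nat$structure, sse = nat$sse, contacts = ct,
      schedules = list(two_state = sched_two, multistate = sched_multi),
      plan = plan
    )
    if (class[i] == "multistate") {
      pairs <- distinct(as_tibble(ct)[, c("elem_i", "elem_j")])
      g <- groups2
      formed <- as.integer(g[pairs$elem_i] == 1L & g[pairs$elem_j] == 1L)
      hdx_rows[[length(hdx_rows) + 1L]] <- tibble(
        id = ids[i], intermediate_index = 1L,
        pair_i = pairs$elem_i, pair_j = pairs$elem_j, formed = formed
      )
    }
  }
  table <- protein_table(tibble(
    id = ids, length = length_actual, kinetics_label = class, ln_kf = ln_kf
  ))
  bench <- structure(list(
    table = table,
    proteins = proteins,
    hdx = if (length(hdx_rows) > 0) bind_rows(hdx_rows) else NULL,
    true_onset = setNames(onset_sched, ids),
    params = list(n_proteins = n_proteins,
                  decoys_per_protein = decoys_per_protein,
                  p_two_state = p_two_state, coupling = coupling,
                  kf_model = kf_model, n_frames = n_frames,
                  noise_sd = noise_sd, transition_width = w,
                  jitter_sd = jitter_sd, decoy_flip = decoy_flip,
                  seed = seed)
  ), class = "fq_benchmark")
  if (!is.null(dir)) write_benchmark(bench, dir)
  bench
}

#' @export
print.fq_benchmark <- function(x, ...) {
  cat(sprintf("<fq_benchmark> %d proteins x %d decoys (%d two-state, %d multistate)\n",
              x$params$n_proteins, x$params$decoys_per_protein,
              sum(x$table$kinetics_label == "two_state"),
              sum(x$table$kinetics_label == "multistate")))
  invisible(x)
}

#' Simulate one benchmark decoy
#'
#' @param bench An `fq_benchmark`.
#' @param protein_id Protein id.
#' @param decoy Decoy index.
#' @return As [simulate_trajectory()].
#' @export
simulate_decoy <- function(bench, protein_id, decoy) {
  p <- bench$proteins[[protein_id]]
  if (is.null(p)) abort(paste0("Unknown protein: ", protein_id),
                        class = "foldq_error")
  row <- p$plan[p$plan$decoy == decoy, ]
  if (nrow(row) != 1) abort("Unknown decoy index.", class = "foldq_error")
  simulate_trajectory(p$structure, p$sse, p$schedules[[row$class]],
                      n_frames = bench$params$n_frames,
                      noise_sd = bench$params$noise_sd, seed = row$seed)
}

#' Analyze every decoy of a benchmark in memory
#'
#' Simulates each decoy trajectory on the fly (no trajectories are retained)
#' and runs the full kinetics analysis, returning one row per decoy.
#'
#' @param bench An `fq_benchmark`.
#' @param config An [fq_config()].
#' @param decoys Optional cap on decoys per protein (e.g. 10 for sweeps).
#' @return A tibble of class `fq_calls`: `protein_id`, `decoy`, `true_class`,
#'   `label`, `n_peaks`, `onset`, `true_onset`, `bandwidth`, and list columns
#'   `first_intermediate` / `true_intermediate` (binary vectors over native
#'   SSE pairs, `NULL` for two-state calls).
#' @export
benchmark_calls <- function(bench, config = fq_config(), decoys = NULL) {
  rows <- purrr::map(bench$proteins, function(p) {
    plan <- p$plan
    if (!is.null(decoys)) plan <- plan[plan$decoy <= decoys, , drop = FALSE]
    if (!isTRUE(all.equal(config$cutoff, attr(p$contacts, "cutoff")))) {
      p$contacts <- native_contacts(p$structure, p$sse, cutoff = config$cutoff)
    }
    purrr::map(seq_len(nrow(plan)), function(j) {
      sim <- simulate_trajectory(p$structure, p$sse,
                                 p$schedules[[plan$class[j]]],
                                 n_frames = bench$params$n_frames,
                                 noise_sd = bench$params$noise_sd,
                                 seed = plan$seed[j])
      call <- analyze_trajectory(sim$trajectory, p$contacts, config)
      tibble(
        protein_id = p$id,
        decoy = plan$decoy[j],
        true_class = plan$class[j],
        label = call$label,
        n_peaks = length(call$peaks),
        onset = call$onset,
        true_onset = sim$truth$onset,
        bandwidth = call$bandwidth,
        first_intermediate = list(
          if (call$label == "multistate") call$intermediate_vectors[[1]] else NULL),
        true_intermediate = list(
          if (length(sim$truth$intermediate_vectors) > 0)
            sim$truth$intermediate_vectors[[1]] else NULL)
      )
    }) |> bind_rows()
  }) |> bind_rows()
  class(rows) <- c("fq_calls", class(rows))
  rows
}

# Write a benchmark to disk in the formats the readers understand.
write_benchmark <- function(bench, dir, fmt = "dcd") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(bench$table), file.path(dir, "protein_table.csv"))
  if (!is.null(bench$hdx)) {
    readr::write_csv(bench$hdx, file.path(dir, "hdx.csv"))
  }
  for (p in bench$proteins) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    write_structure(p$structure, file.path(pdir, "native.pdb"))
    write_sse(p$sse, file.path(pdir, "sse.csv"))
    truths <- list()
    for (j in seq_len(nrow(p$plan))) {
      sim <- simulate_decoy(bench, p$id, p$plan$decoy[j])
      ext <- if (fmt == "dcd") ".dcd" else ".pdb"
      write_trajectory(sim$trajectory,
                       file.path(pdir, sprintf("decoy_%03d%s", p$plan$decoy[j], ext)),
                       fmt = fmt)
      truths[[j]] <- sim$truth
    }
    jsonlite::write_json(
      list(protein_id = p$id, plan = p$plan, truth = truths),
      file.path(pdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    n_proteins = bench$params$n_proteins,
    decoys_per_protein = bench$params$decoys_per_protein,
    seed = bench$params$seed,
    format = fmt,
    proteins = names(bench$proteins)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
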