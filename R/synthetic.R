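#' Phase schedule for synthetic folding trajectories
#'
#' Assigns every SSE element to a phase group and every group a nominal
#' docking time (fraction of the trajectory). Elements of a group dock onto
#' the native arrangement together around their group time; a single group
#' encodes two-state kinetics, several groups encode a multistate pathway
#' whose intermediates are the configurations between group times.
#'
#' @param group_of_element Named integer vector mapping element id to phase
#'   group (1..G).
#' @param group_times Numeric vector of length G, strictly increasing, in
#'   (0, 1): nominal docking time of each group.
#' @param transition_width Width `w` of the logistic docking ramp, as a
#'   fraction of the trajectory; the ramp is ~98% complete within one `w` of
#'   the group time. Group times must stay at least `w` away from 0 and 1.
#' @param jitter_sd Per-decoy Gaussian jitter applied to each group time.
#' @return A list of class `fq_schedule`.
#' @examples
#' phase_schedule(c(E1 = 1, E2 = 1, E3 = 2, E4 = 2), c(0.25, 0.75))
#' @export
phase_schedule <- function(group_of_element, group_times,
                           transition_width = 0.03, jitter_sd = 0) {
  g <- as.integer(group_of_element)
  G <- length(group_times)
  if (G < 1) abort("Need at least one phase group.", class = "foldq_error")
  if (is.null(names(group_of_element))) {
    abort("`group_of_element` must be named by element id.", class = "foldq_error")
  }
  if (!all(g %in% seq_len(G))) {
    abort("Element groups must index into `group_times`.", class = "foldq_error")
  }
  if (G > 1 && any(diff(group_times) <= 0)) {
    abort("Group times must be strictly increasing.", class = "foldq_error")
  }
  if (any(group_times <= transition_width | group_times >= 1 - transition_width)) {
    abort("Group times within one transition width of 0 or 1: ramp would be truncated.",
          class = "foldq_error")
  }
  structure(list(
    group_of_element = setNames(g, names(group_of_element)),
    group_times = group_times,
    transition_width = transition_width,
    jitter_sd = jitter_sd,
    min_gap = if (G > 1) min(diff(group_times)) else NA_real_
  ), class = "fq_schedule")
}

#' Build a toy native structure of rigid secondary-structure rods
#'
#' Elements are straight rods of beads 3.8 Angstrom apart (the Ca virtual
#' bond length), laid out on a two-column grid with `spacing` Angstrom
#' between neighbouring rods plus a small seeded jitter, and joined by
#' two-residue linkers. Neighbouring rods share native contacts at the
#' default 8 Angstrom cutoff whenever `spacing <= 7`.
#'
#' @param n_elements Number of rods (>= 2).
#' @param element_len Residues per rod (>= 4, the minimum SSE span).
#' @param spacing Inter-rod distance in Angstrom.
#' @param seed Integer seed for the placement jitter.
#' @return A list with `structure` (an `fq_structure`) and `sse`
#'   (an `fq_sse`).
#' @export
make_native <- function(n_elements, element_len = 5L, spacing = 6,
                        seed = 1L) {
  if (n_elements < 2) abort("Need at least 2 elements.", class = "foldq_error")
  if (element_len < 4) {
    abort("Elements must span at least 4 residues.", class = "foldq_error")
  }
  set.seed(seed)
  step <- 3.8
  linker <- 2L
  n_res <- n_elements * element_len + (n_elements - 1L) * linker
  coords <- matrix(NA_real_, n_res, 3L)
  elem_rows <- vector("list", n_elements)
  pos <- 1L
  for (k in seq_len(n_elements)) {
    col_k <- (k - 1L) %% 2L          # two-column grid in y
    row_k <- (k - 1L) %/% 2L         # stacked in z
    jit <- runif(3, -0.4, 0.4)
    origin <- c(0, col_k * spacing, row_k * spacing) + jit
    dir <- if (col_k == 0L) 1 else -1   # serpentine along x
    rows <- pos:(pos + element_len - 1L)
    coords[rows, ] <- cbind(origin[1] + dir * step * (seq_len(element_len) - 1),
                            origin[2], origin[3])
    elem_rows[[k]] <- rows
    pos <- pos + element_len
    if (k < n_elements) {
      a <- coords[rows[element_len], ]
      # linker beads interpolated toward the next rod's origin (filled after
      # the next rod is placed would be cleaner; a straight stub suffices
      # since linkers belong to no element)
      for (l in seq_len(linker)) {
        coords[pos, ] <- a + c(0, 0.5 * spacing * l / (linker + 1), 0)
        pos <- pos + 1L
      }
    }
  }
  native <- new_structure(tibble(
    position = seq_len(n_res),
    resno = seq_len(n_res),
    resname = "ALA",
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  ), protein_id = sprintf("synthetic_%d", seed))
  sse <- sse_segments(tibble(
    element_id = sprintf("E%d", seq_len(n_elements)),
    type = rep(c("helix", "strand"), length.out = n_elements),
    start = vapply(elem_rows, min, integer(1)),
    end = vapply(elem_rows, max, integer(1))
  ))
  # sanity: the geometry must produce inter-element contacts
  ct <- tryCatch(native_contacts(native, sse, cutoff = 8.0),
                 foldq_error = function(e) NULL)
  if (is.null(ct)) {
    abort("Generated geometry has no inter-element contacts at 8 Angstrom.",
          class = "foldq_error")
  }
  list(structure = native, sse = sse)
}

#' Simulate a folding trajectory with a known phase schedule
#'
#' Every element starts displaced 50 Angstrom from its native pose along a
#' random direction and translates rigidly back following a logistic ramp
#' centred at its group's docking time; isotropic Gaussian noise is added to
#' every coordinate. Linker residues follow their nearest element. The
#' returned ground truth records the planted kinetics class, the per-pair
#' formation times (`max` of the two elements' docking times) and the
#' intermediate contact vectors at each phase boundary.
#'
#' @param native,sse Output of [make_native()] (or equivalents).
#' @param schedule An [phase_schedule()] covering every element in `sse`.
#' @param n_frames Frames to simulate (>= 50).
#' @param noise_sd Coordinate noise, Angstrom.
#' @param seed Integer seed.
#' @return A list with `trajectory` (an `fq_trajectory`) and `truth` (a list:
#'   `kinetics_class`, `group_times` as jittered, `formation_time` named per
#'   pair, `intermediate_vectors`, `seed`).
#' @export
simulate_trajectory <- function(native, sse, schedule, n_frames = 200L,
                                noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(schedule, "fq_schedule"))
  if (n_frames < 50) abort("Need n_frames >= 50.", class = "foldq_error")
  missing_el <- setdiff(sse$element_id, names(schedule$group_of_element))
  if (length(missing_el) > 0) {
    abort(paste0("Schedule does not cover elements: ",
                 paste(missing_el, collapse = ", ")), class = "foldq_error")
  }
  set.seed(seed)
  w <- schedule$transition_width
  tau <- schedule$group_times
  if (schedule$jitter_sd > 0) {
    tau <- tau + rnorm(length(tau), 0, schedule$jitter_sd)
    tau <- pmin(pmax(tau, w + 1e-3), 1 - w - 1e-3)
    tau <- sort(tau)
  }
  n_el <- nrow(sse)
  # random unit displacement directions, fixed 50 A magnitude; rejection
  # sampling keeps the relative displacement of any two elements >= 20 A so
  # the dispersed start has no inter-element contacts
  dirs <- matrix(0, n_el, 3L)
  for (k in seq_len(n_el)) {
    repeat {
      v <- rnorm(3)
      v <- 50 * v / sqrt(sum(v^2))
      if (k == 1 || all(sqrt(rowSums(sweep(dirs[seq_len(k - 1), , drop = FALSE],
                                           2, v)^2)) >= 20)) break
    }
    dirs[k, ] <- v
  }
  elem <- element_of_residue(native, sse)
  # linkers ride with the nearest element (by residue position)
  el_index <- match(elem, sse$element_id)
  if (anyNA(el_index)) {
    core <- which(!is.na(el_index))
    for (i in which(is.na(el_index))) {
      el_index[i] <- el_index[core[which.min(abs(core - i))]]
    }
  }
  group <- schedule$group_of_element[sse$element_id]
  xyz0 <- as.matrix(native[, c("x", "y", "z")])
  n_res <- nrow(xyz0)
  # residues lock in around their element's docking time with individual
  # offsets (sd w/2): elements zip into place over ~w rather than snapping,
  # so Q rises over a resolvable window instead of a single frame
  tau_el <- tau[group[el_index]] + rnorm(n_res, 0, w / 2)
  tfrac <- (seq_len(n_frames) - 1) / (n_frames - 1)
  # ramp s in [0,1]: 0 dispersed, 1 native; scale w/4 puts ~98% of the
  # transition within +/- w of the group time
  s <- plogis(outer(tfrac, tau_el, `-`) / (w / 4))     # frames x residues
  # snap the tail of the ramp so elements reach their native pose exactly
  # (contacts must close even under a flexibility multiplier of 1)
  s[s > 0.999] <- 1
  xyz <- matrix(0, n_frames, 3L * n_res)
  disp <- dirs[el_index, , drop = FALSE]               # residues x 3
  for (d in 1:3) {
    cols <- seq(d, 3L * n_res, by = 3L)
    xyz[, cols] <- matrix(xyz0[, d], n_frames, n_res, byrow = TRUE) +
      (1 - s) * matrix(disp[, d], n_frames, n_res, byrow = TRUE)
  }
  if (noise_sd > 0) {
    xyz <- xyz + rnorm(length(xyz), 0, noise_sd)
  }
  traj <- fq_trajectory(xyz, protein_id = attr(native, "protein_id"),
                        resno = native$resno, resname = native$resname)
  # ground truth over native SSE pairs
  ct <- native_contacts(native, sse, cutoff = 8.0)
  pairs <- distinct(as_tibble(ct)[, c("elem_i", "elem_j")])
  g_i <- group[pairs$elem_i]
  g_j <- group[pairs$elem_j]
  formation <- pmax(tau[g_i], tau[g_j])
  names(formation) <- paste(pairs$elem_i, pairs$elem_j, sep = "|")
  G <- length(tau)
  intermediates <- lapply(seq_len(max(G - 1, 0)), function(b) {
    boundary <- (tau[b] + tau[b + 1]) / 2
    setNames(as.integer(formation < boundary), names(formation))
  })
  truth <- list(
    kinetics_class = if (G == 1) "two_state" else "multistate",
    group_times = tau,
    formation_time = formation,
    intermediate_vectors = intermediates,
    onset = min(tau),
    seed = seed
  )
  list(trajectory = traj, truth = truth)
}
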