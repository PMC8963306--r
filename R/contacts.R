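#' Native contacts between secondary-structure elements
#'
#' A native contact is a pair of residues belonging to two different SSE
#' elements whose beads (Cb, Ca for glycine) lie strictly closer than
#' `cutoff` Angstrom in the reference structure. Contacts are grouped by
#' element pair; element pairs without any contact are omitted.
#'
#' @param native An `fq_structure` (see [read_structure()]).
#' @param sse An `fq_sse` tibble of filtered elements.
#' @param cutoff Distance threshold in Angstrom (strict `<`).
#' @return A tibble of class `fq_contacts` with columns `elem_i`, `elem_j`
#'   (element ids, i before j in sequence order), `pos_a`, `pos_b`
#'   (sequential residue positions), `res_a`, `res_b` (author numbers) and
#'   `native_dist`.
#' @examples
#' nat <- make_native(n_elements = 3, seed = 1)
#' native_contacts(nat$structure, nat$sse)
#' @export
native_contacts <- function(native, sse, cutoff = 8.0) {
  stopifnot(inherits(native, "fq_structure"))
  if (nrow(sse) < 2) {
    abort("Need at least 2 SSE elements to define inter-element contacts.",
          class = "foldq_error")
  }
  elem <- element_of_residue(native, sse)
  xyz <- as.matrix(native[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("Non-finite coordinates in native structure.", class = "foldq_error")
  }
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(native)
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    a <- idx[, 1]; b <- idx[, 2]
    keep <- !is.na(elem[a]) & !is.na(elem[b]) & elem[a] != elem[b]
    a <- a[keep]; b <- b[keep]
  } else {
    a <- b <- integer(0)
  }
  if (length(a) == 0) {
    abort("No native inter-element contacts under the cutoff.",
          class = "foldq_error")
  }
  rank_of <- setNames(seq_len(nrow(sse)), sse$element_id)
  ea <- elem[a]; eb <- elem[b]
  swap <- rank_of[ea] > rank_of[eb]
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ea <- elem[a]; eb <- elem[b]
  out <- tibble(
    elem_i = ea, elem_j = eb,
    pos_a = a, pos_b = b,
    res_a = native$resno[a], res_b = native$resno[b],
    native_dist = d[cbind(a, b)]
  )
  out <- arrange(out, rank_of[.data$elem_i], rank_of[.data$elem_j],
                 .data$pos_a, .data$pos_b)
  attr(out, "chain_length") <- n
  attr(out, "cutoff") <- cutoff
  class(out) <- c("fq_contacts", class(out))
  out
}

# Map each residue position to the id of the SSE element containing its
# author number (NA for linker residues outside every element).
element_of_residue <- function(native, sse) {
  elem <- rep(NA_character_, nrow(native))
  for (k in seq_len(nrow(sse))) {
    hit <- native$resno >= sse$start[k] & native$resno <= sse$end[k]
    elem[hit] <- sse$element_id[k]
  }
  elem
}

#' Per-pair fraction of native contacts along a trajectory
#'
#' A native contact with reference distance `d` counts as formed in a frame
#' when the frame distance is at most `xi * d`. For every SSE element pair,
#' `q` is the fraction of that pair's native contacts formed in the frame.
#'
#' @param traj An `fq_trajectory` congruent with the native structure.
#' @param contacts An `fq_contacts` table from [native_contacts()].
#' @param xi Flexibility multiplier (>= 1).
#' @return A tibble of class `fq_qseries` with columns `elem_i`, `elem_j`,
#'   `frame` and `q`; attribute `n_frames`.
#' @export
q_timeseries <- function(traj, contacts, xi = 1.2) {
  stopifnot(inherits(traj, "fq_trajectory"), inherits(contacts, "fq_contacts"))
  nf <- traj$n_frames
  if (max(contacts$pos_a, contacts$pos_b) > traj$n_residues) {
    abort("Contact table refers to residues beyond the trajectory.",
          class = "foldq_error")
  }
  bad_frame <- which(!apply(is.finite(traj$xyz), 1L, all))
  if (length(bad_frame) > 0) {
    abort(sprintf("Non-finite coordinates in frame %d.", bad_frame[1]),
          class = "foldq_error")
  }
  col <- function(pos, d) 3L * (pos - 1L) + d
  dx <- traj$xyz[, col(contacts$pos_a, 1L), drop = FALSE] -
        traj$xyz[, col(contacts$pos_b, 1L), drop = FALSE]
  dy <- traj$xyz[, col(contacts$pos_a, 2L), drop = FALSE] -
        traj$xyz[, col(contacts$pos_b, 2L), drop = FALSE]
  dz <- traj$xyz[, col(contacts$pos_a, 3L), drop = FALSE] -
        traj$xyz[, col(contacts$pos_b, 3L), drop = FALSE]
  dist2 <- dx * dx + dy * dy + dz * dz                 # frames x contacts
  # tiny relative tolerance so a frame that equals the native structure to
  # machine precision counts as formed even at xi = 1
  thr2 <- (xi * contacts$native_dist)^2 * (1 + 1e-9)
  present <- sweep(dist2, 2L, thr2, `<=`)
  pair_key <- paste(contacts$elem_i, contacts$elem_j, sep = "\r")
  pairs <- unique(pair_key)
  q_mat <- vapply(pairs, function(p) {
    rowMeans(present[, pair_key == p, drop = FALSE])
  }, numeric(nf))                                      # frames x pairs
  first_idx <- match(pairs, pair_key)
  out <- tibble(
    elem_i = rep(contacts$elem_i[first_idx], each = nf),
    elem_j = rep(contacts$elem_j[first_idx], each = nf),
    frame = rep(seq_len(nf), times = length(pairs)),
    q = as.numeric(q_mat)
  )
  attr(out, "n_frames") <- nf
  attr(out, "xi") <- xi
  class(out) <- c("fq_qseries", class(out))
  out
}

#' Finite-difference derivative of a series
#'
#' Central differences on interior points, one-sided at both endpoints, in
#' units of change per frame. One-sided endpoints mean the maximum can fall
#' on the first or last frame, so trajectories that start near-native are not
#' silently truncated.
#'
#' @param q Numeric series of length >= 3.
#' @return Numeric derivative series, same length.
#' @examples
#' finite_difference(c(0, 0, 1, 1))
#' @export
finite_difference <- function(q) {
  n <- length(q)
  if (n < 3) abort("Need at least 3 frames to differentiate.", class = "foldq_error")
  c(q[2] - q[1],
    (q[3:n] - q[1:(n - 2)]) / 2,
    q[n] - q[n - 1])
}

#' Add derivative columns to a Q series
#'
#' Computes the finite-difference derivative of each pair's `q` and smooths
#' it with [supersmooth()] (differentiate, then smooth).
#'
#' @param qs An `fq_qseries` from [q_timeseries()].
#' @param bass Bass enhancement handed to the smoother.
#' @return The input with extra columns `dq` and `dq_smooth`.
#' @export
add_derivatives <- function(qs, bass = 0) {
  stopifnot(inherits(qs, "fq_qseries"))
  nf <- attr(qs, "n_frames")
  tfrac <- (seq_len(nf) - 1) / (nf - 1)
  out <- qs |>
    group_by(.data$elem_i, .data$elem_j) |>
    mutate(dq = finite_difference(.data$q),
           dq_smooth = supersmooth(tfrac, .data$dq, bass = bass)) |>
    ungroup()
  attr(out, "n_frames") <- nf
  attr(out, "xi") <- attr(qs, "xi")
  class(out) <- c("fq_qseries", class(out))
  out
}
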