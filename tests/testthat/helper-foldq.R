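# Shared fixture builders; everything is generated in code at test time.

# Minimal hand-written PDB text: one ATOM line per (residue, atom).
pdb_atom_line <- function(eleno, elety, resid, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          eleno, paste0(" ", elety), resid, resno, x, y, z,
          substr(elety, 1, 1))
}

# Write a tiny PDB with explicit models; atoms is a data frame with columns
# elety, resid, resno and per-model coordinate list in `coords` (list of
# n_atoms x 3 matrices).
write_tiny_pdb <- function(path, atoms, coords) {
  lines <- character(0)
  for (m in seq_along(coords)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(atoms))) {
      lines <- c(lines, pdb_atom_line(i, atoms$elety[i], atoms$resid[i],
                                      atoms$resno[i], coords[[m]][i, 1],
                                      coords[[m]][i, 2], coords[[m]][i, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# A transitions table as kde_phases() expects, from raw t* values.
make_transitions <- function(t_star, included = rep(TRUE, length(t_star)),
                             n_frames = 200L) {
  out <- tibble::tibble(
    elem_i = sprintf("E%d", seq_along(t_star)),
    elem_j = sprintf("F%d", seq_along(t_star)),
    t_star = t_star,
    q_range = ifelse(included, 1, 0),
    included = included
  )
  attr(out, "n_frames") <- n_frames
  class(out) <- c("fq_transitions", class(out))
  out
}

# Independent local-linear oracle: per-point lm() over the truncated window.
brute_local_linear <- function(x, y, span) {
  n <- length(x)
  J <- max(2L, as.integer(floor(span * n / 2)))
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - J):min(n, i + J)
    fit <- stats::lm(yy ~ xx, data.frame(xx = x[w], yy = y[w]))
    unname(stats::predict(fit, data.frame(xx = x[i])))
  }, numeric(1))
}

# Small single-phase / two-phase benchmark helpers used across test files.
tiny_two_state_sim <- function(n_elements = 8, tau = 0.5, noise_sd = 0.2,
                               seed = 1) {
  nat <- make_native(n_elements, seed = seed)
  sched <- phase_schedule(
    setNames(rep(1L, n_elements), nat$sse$element_id), tau,
    jitter_sd = 0.02)
  sim <- simulate_trajectory(nat$structure, nat$sse, sched,
                             noise_sd = noise_sd, seed = seed + 1)
  c(nat, sim, list(contacts = native_contacts(nat$structure, nat$sse)))
}
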