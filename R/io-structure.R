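#' Read a reference structure as one bead per residue
#'
#' Extracts the beta-carbon of every residue (the alpha-carbon for glycine)
#' from one model of a PDB file. The result is the reduced representation on
#' which all native-contact analysis operates.
#'
#' @param path Path to a PDB file with at least one model.
#' @param model_index 1-based model to read (NMR ensembles store many).
#' @param protein_id Identifier attached to the result; defaults to the file
#'   name without extension.
#' @return A tibble of class `fq_structure` with columns `position`
#'   (sequential 1..n), `resno` (author residue number), `resname` and
#'   `x`, `y`, `z` (Angstrom).
#' @examples
#' nat <- make_native(n_elements = 2, seed = 1)
#' tmp <- tempfile(fileext = ".pdb")
#' write_structure(nat$structure, tmp)
#' read_structure(tmp)
#' @export
read_structure <- function(path, model_index = 1L, protein_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Structure file not found: ", path), class = "foldq_error")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    abort(sprintf("model_index %d out of range: file has %d model(s).",
                  model_index, n_models), class = "foldq_error")
  }
  at <- pdb$atom
  sel <- bead_selection(at)
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)[sel$atom_row, , drop = FALSE]
  out <- tibble(
    position = seq_along(sel$atom_row),
    resno = sel$resno,
    resname = sel$resname,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  if (anyDuplicated(out$resno)) {
    abort("Duplicated residue identifiers in structure.", class = "foldq_error")
  }
  if (!all(is.finite(xyz))) {
    abort("Non-finite coordinates in structure.", class = "foldq_error")
  }
  new_structure(out, protein_id %||% sub("\\.[^.]*$", "", basename(path)))
}

new_structure <- function(df, protein_id) {
  out <- as_tibble(df)
  attr(out, "protein_id") <- protein_id
  class(out) <- c("fq_structure", class(out))
  out
}

# Pick the CB atom row for each residue (CA for glycine). Residues in file
# order; a non-glycine residue without CB is an error because upstream repair
# of incomplete side chains is out of scope here.
bead_selection <- function(atom) {
  atom <- atom[atom$type %in% c("ATOM", "HETATM") & atom$type == "ATOM", , drop = FALSE]
  key <- paste(atom$chain, atom$resno, atom$insert)
  ord <- !duplicated(key)
  residues <- data.frame(key = key[ord], resno = atom$resno[ord],
                         resname = atom$resid[ord], stringsAsFactors = FALSE)
  rows <- integer(nrow(residues))
  for (i in seq_len(nrow(residues))) {
    idx <- which(key == residues$key[i])
    want <- if (identical(residues$resname[i], "GLY")) "CA" else "CB"
    hit <- idx[atom$elety[idx] == want]
    if (length(hit) == 0 && want == "CB") {
      abort(sprintf("Residue %s %s lacks a CB atom (and is not glycine).",
                    residues$resname[i], residues$resno[i]),
            class = "foldq_error")
    }
    if (length(hit) == 0) {
      abort(sprintf("Residue %s %s lacks both CB and CA atoms.",
                    residues$resname[i], residues$resno[i]),
            class = "foldq_error")
    }
    rows[i] <- hit[1]
  }
  list(atom_row = rows, resno = residues$resno, resname = residues$resname)
}

#' Write a one-bead-per-residue structure to PDB
#'
#' @param structure An `fq_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "fq_structure"))
  elety <- ifelse(structure$resname == "GLY", "CA", "CB")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
                   resno = structure$resno, resid = structure$resname,
                   elety = elety, verbose = FALSE)
  invisible(path)
}

#' Trajectory container
#'
#' A trajectory stores ordered frames of the same one-bead-per-residue
#' representation as [read_structure()]. Coordinates live in an
#' `n_frames x (3 * n_residues)` matrix (`x1, y1, z1, x2, ...` per row, the
#' bio3d convention); [tidy()] or [as_tibble()] unfold it to a long tibble.
#'
#' @param xyz Numeric matrix of frame coordinates.
#' @param protein_id Identifier string.
#' @param resno,resname Residue metadata vectors (length `n_residues`).
#' @return An object of class `fq_trajectory`.
#' @export
fq_trajectory <- function(xyz, protein_id, resno = NULL, resname = NULL) {
  if (!is.matrix(xyz) || ncol(xyz) %% 3L != 0L) {
    abort("`xyz` must be a matrix with 3 columns per residue.",
          class = "foldq_error")
  }
  if (nrow(xyz) < 2L) {
    abort("A trajectory needs at least 2 frames.", class = "foldq_error")
  }
  n_res <- ncol(xyz) %/% 3L
  structure(list(
    xyz = xyz,
    protein_id = protein_id,
    n_frames = nrow(xyz),
    n_residues = n_res,
    resno = resno %||% seq_len(n_res),
    resname = resname %||% rep("ALA", n_res)
  ), class = "fq_trajectory")
}

#' @export
print.fq_trajectory <- function(x, ...) {
  cat(sprintf("<fq_trajectory> %s: %d frames x %d residues\n",
              x$protein_id, x$n_frames, x$n_residues))
  invisible(x)
}

#' @export
as_tibble.fq_trajectory <- function(x, ...) {
  nf <- x$n_frames; nr <- x$n_residues
  xs <- as.numeric(t(x$xyz[, seq(1L, 3L * nr, by = 3L), drop = FALSE]))
  ys <- as.numeric(t(x$xyz[, seq(2L, 3L * nr, by = 3L), drop = FALSE]))
  zs <- as.numeric(t(x$xyz[, seq(3L, 3L * nr, by = 3L), drop = FALSE]))
  tibble(
    frame = rep(seq_len(nf), each = nr),
    position = rep(seq_len(nr), times = nf),
    resno = rep(x$resno, times = nf),
    x = xs, y = ys, z = zs
  )
}

#' @export
tidy.fq_trajectory <- function(x, ...) as_tibble.fq_trajectory(x)

#' Read a trajectory (multi-model PDB or binary DCD)
#'
#' @param topology_path PDB file defining the residues (see
#'   [read_structure()]); its bead selection is applied to every PDB frame.
#' @param traj_path Trajectory file.
#' @param fmt `"dcd"` or `"pdb"` (multi-model).
#' @return An `fq_trajectory` with coordinates in Angstrom, frames in file
#'   order.
#' @export
read_trajectory <- function(topology_path, traj_path, fmt = c("dcd", "pdb")) {
  fmt <- match.arg(fmt)
  topo <- read_structure(topology_path)
  if (!file.exists(traj_path)) {
    abort(paste0("Trajectory file not found: ", traj_path), class = "foldq_error")
  }
  n_res <- nrow(topo)
  if (fmt == "dcd") {
    xyz <- bio3d::read.dcd(traj_path, verbose = FALSE)
    if (ncol(xyz) %/% 3L != n_res) {
      abort(sprintf("Atom count mismatch: topology has %d residues, DCD frames have %d atoms.",
                    n_res, ncol(xyz) %/% 3L), class = "foldq_error")
    }
  } else {
    pdb <- bio3d::read.pdb(traj_path, multi = TRUE, verbose = FALSE)
    sel <- bead_selection(pdb$atom)
    if (length(sel$atom_row) != n_res) {
      abort(sprintf("Atom count mismatch: topology has %d residues, trajectory frames have %d.",
                    n_res, length(sel$atom_row)), class = "foldq_error")
    }
    cols <- as.integer(t(outer(3L * (sel$atom_row - 1L), 1:3, `+`)))
    xyz <- pdb$xyz[, cols, drop = FALSE]
  }
  if (nrow(xyz) < 2L) {
    abort("Trajectory has fewer than 2 frames.", class = "foldq_error")
  }
  fq_trajectory(unclass(xyz)[, , drop = FALSE],
                protein_id = attr(topo, "protein_id"),
                resno = topo$resno, resname = topo$resname)
}

#' Write a trajectory to multi-model PDB or binary DCD
#'
#' DCD coordinates are single precision; round-trips through
#' [read_trajectory()] agree to about 1e-3 Angstrom.
#'
#' @param traj An `fq_trajectory`.
#' @param path Output path.
#' @param fmt `"dcd"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, fmt = c("dcd", "pdb")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(traj, "fq_trajectory"))
  if (traj$n_frames < 2L) {
    abort("Refusing to write a trajectory with fewer than 2 frames.",
          class = "foldq_error")
  }
  if (fmt == "dcd") {
    write_dcd(traj$xyz, path)
  } else {
    elety <- ifelse(traj$resname == "GLY", "CA", "CB")
    bio3d::write.pdb(file = path, xyz = traj$xyz, resno = traj$resno,
                     resid = traj$resname, elety = elety, verbose = FALSE)
  }
  invisible(path)
}

# CHARMM-layout DCD writer (little-endian, single precision, no unit cell).
# Each Fortran record is framed by its byte count; frames store x, y and z
# as three separate float records.
write_dcd <- function(xyz, path) {
  natom <- ncol(xyz) %/% 3L
  nf <- nrow(xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  marker <- function(nbytes) writeBin(as.integer(nbytes), con, size = 4L,
                                      endian = "little")
  icntrl <- integer(20L)
  icntrl[1L] <- nf; icntrl[2L] <- 1L; icntrl[3L] <- 1L; icntrl[4L] <- nf
  icntrl[20L] <- 24L
  marker(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  writeBin(icntrl, con, size = 4L, endian = "little")
  marker(84L)
  title <- formatC("Written by foldq", width = 80L, flag = "-")
  marker(84L)
  writeBin(1L, con, size = 4L, endian = "little")
  writeChar(title, con, nchars = 80L, eos = NULL)
  marker(84L)
  marker(4L); writeBin(as.integer(natom), con, size = 4L, endian = "little"); marker(4L)
  xi <- seq(1L, 3L * natom, by = 3L)
  for (f in seq_len(nf)) {
    for (d in 0:2) {
      marker(4L * natom)
      writeBin(as.numeric(xyz[f, xi + d]), con, size = 4L, endian = "little")
      marker(4L * natom)
    }
  }
  invisible(path)
}
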