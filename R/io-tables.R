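#' Validate and filter secondary-structure element annotations
#'
#' Elements are inclusive residue ranges (`start`..`end`, author numbering).
#' Ranges must not overlap; elements spanning fewer than `min_sse_len`
#' residues are removed, mirroring the convention of ignoring very short
#' helices and strands when aggregating contacts.
#'
#' @param df Data frame with columns `element_id`, `type` (one of `helix`,
#'   `strand`, `other`), `start`, `end`.
#' @param min_sse_len Minimum span (residues) an element must cover.
#' @return A tibble of class `fq_sse`, ordered by `start`, with an attribute
#'   `n_removed` counting filtered elements.
#' @examples
#' sse_segments(data.frame(element_id = c("H1", "S1"),
#'                         type = c("helix", "strand"),
#'                         start = c(1, 10), end = c(6, 14)))
#' @export
sse_segments <- function(df, min_sse_len = 4L) {
  need <- c("element_id", "type", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("SSE table lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "foldq_error")
  }
  df <- as_tibble(df[need])
  bad_type <- !df$type %in% c("helix", "strand", "other")
  if (any(bad_type)) {
    abort(paste0("Unknown SSE type: ", df$type[bad_type][1]), class = "foldq_error")
  }
  if (any(df$start > df$end)) {
    abort("SSE element with start > end.", class = "foldq_error")
  }
  df <- arrange(df, .data$start)
  if (nrow(df) > 1) {
    overlap <- df$start[-1] <= df$end[-nrow(df)]
    if (any(overlap)) {
      abort(sprintf("Overlapping SSE elements: %s and %s.",
                    df$element_id[which(overlap)[1]],
                    df$element_id[which(overlap)[1] + 1L]),
            class = "foldq_error")
    }
  }
  span <- df$end - df$start + 1L
  kept <- df[span >= min_sse_len, , drop = FALSE]
  n_removed <- nrow(df) - nrow(kept)
  if (nrow(kept) == 0) {
    abort(sprintf("No SSE elements survive the >= %d residue filter (%d removed).",
                  min_sse_len, n_removed), class = "foldq_error")
  }
  attr(kept, "n_removed") <- n_removed
  class(kept) <- c("fq_sse", class(kept))
  kept
}

#' Load secondary-structure elements from CSV
#'
#' @param path CSV with header `element_id,type,start,end`.
#' @param min_sse_len Minimum element span in residues.
#' @return An `fq_sse` tibble (see [sse_segments()]).
#' @export
load_sse <- function(path, min_sse_len = 4L) {
  if (!file.exists(path)) {
    abort(paste0("SSE file not found: ", path), class = "foldq_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sse_segments(df, min_sse_len = min_sse_len)
}

#' Write SSE elements to CSV
#' @param sse An `fq_sse` tibble.
#' @param path Output path.
#' @export
write_sse <- function(sse, path) {
  readr::write_csv(as_tibble(sse)[, c("element_id", "type", "start", "end")], path)
  invisible(path)
}

#' Validate a protein reference table
#'
#' One row per protein: chain length, formal kinetics label and optionally the
#' natural log of the folding rate constant. Labels must be the literal
#' strings `"two_state"` or `"multistate"`.
#'
#' @param df Data frame with columns `id`, `length`, `kinetics_label` and
#'   optionally `ln_kf`.
#' @return A tibble of class `fq_protein_table`.
#' @export
protein_table <- function(df) {
  need <- c("id", "length", "kinetics_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Protein table lacks columns: ",
                 paste(missing_cols, collapse = ", ")), class = "foldq_error")
  }
  df <- as_tibble(df)
  bad <- !df$kinetics_label %in% c("two_state", "multistate")
  if (any(bad)) {
    abort(sprintf("Row %d has unknown kinetics label '%s' (expected two_state or multistate).",
                  which(bad)[1], df$kinetics_label[bad][1]), class = "foldq_error")
  }
  if (anyDuplicated(df$id)) {
    abort(paste0("Duplicate protein ids: ",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
          class = "foldq_error")
  }
  if (any(df$length <= 0)) abort("Chain lengths must be positive.", class = "foldq_error")
  if (!"ln_kf" %in% names(df)) df$ln_kf <- NA_real_
  class(df) <- c("fq_protein_table", class(df))
  df
}

#' Load a protein reference table from CSV
#'
#' @param path CSV with header `id,length,kinetics_label[,ln_kf]`.
#' @return An `fq_protein_table` tibble, one record per row.
#' @export
load_protein_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Protein table not found: ", path), class = "foldq_error")
  }
  protein_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Load HDX intermediate annotations
#'
#' Long-format binary annotations: for each protein and experimental
#' intermediate, which native SSE pairs are formed (`1`) or not (`0`).
#'
#' @param path CSV with header `id,intermediate_index,pair_i,pair_j,formed`.
#' @return A tibble of class `fq_hdx`.
#' @export
load_hdx <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("HDX file not found: ", path), class = "foldq_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "intermediate_index", "pair_i", "pair_j", "formed")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("HDX table lacks columns: ",
                 paste(missing_cols, collapse = ", ")), class = "foldq_error")
  }
  if (!all(df$formed %in% c(0L, 1L))) {
    abort("HDX `formed` flags must be 0 or 1.", class = "foldq_error")
  }
  class(df) <- c("fq_hdx", class(df))
  df
}
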