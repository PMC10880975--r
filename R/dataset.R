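#' Construct a dataset of equal-length image sequences
#'
#' @param frames Numeric array of dimension `c(T, M, n)`: `T` frames of `M`
#'   pixels for each of `n` sequences (row-major frame vectorization).
#' @param frame_shape `c(H, W)` with `H * W == M`.
#' @param labels Data frame with one row per sequence (may be empty).
#' @param metadata Optional list of per-sequence metadata (positions,
#'   bounce events, ...).
#' @return An object of class `dpc_dataset`.
#' @export
dpc_dataset <- function(frames, frame_shape, labels = NULL, metadata = NULL) {
  if (length(dim(frames)) != 3) stop_invalid("frames must be a T x M x n array")
  if (prod(frame_shape) != dim(frames)[2])
    stop_invalid("frame_shape does not match pixel count ", dim(frames)[2])
  n <- dim(frames)[3]
  labels <- labels %||% data.frame(row.names = seq_len(n))
  if (nrow(labels) != n) stop_invalid("labels must have one row per sequence")
  structure(list(frames = frames, frame_shape = as.integer(frame_shape),
                 labels = labels, metadata = metadata),
            class = "dpc_dataset")
}

#' Number of sequences in a dataset
#' @param ds A `dpc_dataset`.
#' @return Integer count.
#' @export
n_sequences <- function(ds) dim(ds$frames)[3]

#' Extract one sequence from a dataset
#'
#' @param ds A `dpc_dataset`.
#' @param i Sequence index.
#' @return A [dpc_sequence()] carrying that sequence's labels and metadata.
#' @export
get_sequence <- function(ds, i) {
  i <- check_positive_int(i, "i")
  if (i > n_sequences(ds)) stop_invalid("sequence index out of range")
  md <- c(as.list(ds$labels[i, , drop = FALSE]),
          if (!is.null(ds$metadata)) ds$metadata[[i]])
  dpc_sequence(ds$frames[, , i, drop = TRUE], ds$frame_shape, metadata = md)
}

#' Subset a dataset by sequence index
#' @param ds A `dpc_dataset`.
#' @param idx Integer vector of sequence indices.
#' @return A `dpc_dataset` with the selected sequences.
#' @export
subset_dataset <- function(ds, idx) {
  dpc_dataset(ds$frames[, , idx, drop = FALSE], ds$frame_shape,
              labels = ds$labels[idx, , drop = FALSE],
              metadata = if (!is.null(ds$metadata)) ds$metadata[idx])
}

#' @export
print.dpc_dataset <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dpc_dataset> %d sequences, %d frames of %d x %d; labels: %s\n",
              d[3], d[1], x$frame_shape[1], x$frame_shape[2],
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}
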