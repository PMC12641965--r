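#' Per-cell channel totals for compensation
#'
#' Background-subtracted total intensities per fluorescence channel over
#' the object mask, one row per segmentable cell — the scalar quantities
#' spillover estimation and compensation act on.
#'
#' @param gallery a gallery (list with `records`) or list of
#'   [cell_record()]s.
#' @param channels named list of fluorescence channels (names become the
#'   column labels).
#' @return A data frame with one column per channel.
#' @export
control_totals <- function(gallery, channels = list(compound = 2L,
                                                    viability = 3L)) {
  records <- if (!is.null(gallery$records)) gallery$records else gallery
  rows <- lapply(records, function(rec) {
    tryCatch({
      obj <- object_mask(rec, 1L)
      vals <- lapply(names(channels), function(nm)
        intensity_features(rec, obj, channels[[nm]], object_mask = obj)$total)
      as.data.frame(setNames(vals, names(channels)))
    }, error = function(e) NULL)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Estimate a spillover matrix from single-stain controls
#'
#' For each control gallery, positive events are those whose
#' primary-channel total exceeds the background mean plus three background
#' SDs; the spillover entry S\[i, j\] is the median over positive events of
#' the channel-j total divided by the channel-i total. The diagonal is set
#' to one.
#'
#' @param controls named list: one element per fluorescence channel, named
#'   by that primary channel, each a totals table from [control_totals()]
#'   (columns = channel labels).
#' @param background_stats optional named list per channel with elements
#'   `mean` and `sd` of background totals (e.g. from an unstained tube);
#'   defaults to mean 0, sd 0 (totals are already background-subtracted).
#' @param min_positive minimum number of positive events required per
#'   control (default 20).
#' @return An object of class `spillover_matrix` (labelled square matrix,
#'   unit diagonal, checked invertible).
#' @export
estimate_spillover <- function(controls, background_stats = NULL,
                               min_positive = 20L) {
  labels <- names(controls)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("controls must be a named list (one entry per fluorescence channel)")
  k <- length(labels)
  S <- diag(k)
  dimnames(S) <- list(labels, labels)
  for (i in seq_len(k)) {
    tot <- controls[[i]]
    if (is.null(tot) || nrow(tot) == 0L)
      stop("empty control gallery for channel '", labels[i], "'")
    if (!all(labels %in% colnames(tot)))
      stop("control totals must have one column per channel label")
    bs <- background_stats[[labels[i]]]
    thr <- if (is.null(bs)) 0 else bs$mean + 3 * bs$sd
    pos <- tot[[labels[i]]] > thr
    if (sum(pos) < min_positive)
      stop("insufficient control: only ", sum(pos), " positive events for '",
           labels[i], "' (need >= ", min_positive, ")")
    for (j in seq_len(k)) {
      if (i == j) next
      S[i, j] <- max(median(tot[[labels[j]]][pos] / tot[[labels[i]]][pos]), 0)
    }
  }
  tryCatch(solve(S), error = function(e)
    stop("estimated spillover matrix is singular"))
  structure(S, class = c("spillover_matrix", "matrix", "array"))
}

#' Apply spillover compensation to per-cell channel totals
#'
#' Multiplies observed channel vectors (rows) by the inverse of the
#' spillover matrix; data mixed exactly by `S` are recovered exactly.
#'
#' @param intensities numeric vector (one cell) or matrix/data frame
#'   (cells x channels, columns ordered/named as the matrix labels).
#' @param S a [estimate_spillover()] result or a plain square matrix with
#'   unit diagonal.
#' @return Compensated values in the same shape as the input.
#' @export
apply_compensation <- function(intensities, S) {
  S <- unclass(S)
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be square")
  Sinv <- tryCatch(solve(S), error = function(e) stop("singular spillover matrix"))
  vec <- is.null(dim(intensities))
  x <- if (vec) matrix(as.numeric(intensities), nrow = 1)
       else as.matrix(intensities)
  if (ncol(x) != nrow(S))
    stop("intensity vector length must equal the matrix dimension")
  if (!is.null(colnames(x)) && !is.null(rownames(S)) &&
      all(rownames(S) %in% colnames(x)))
    x <- x[, rownames(S), drop = FALSE]
  out <- x %*% Sinv
  colnames(out) <- rownames(S)
  if (vec) drop(out) else out
}

#' Read/write a spillover matrix as CSV
#'
#' Serialized with a header row and a leading label column.
#'
#' @param S a spillover matrix.
#' @param path CSV path.
#' @return `write_spillover` returns the path invisibly; `read_spillover`
#'   returns a `spillover_matrix`.
#' @export
write_spillover <- function(S, path) {
  df <- data.frame(channel = rownames(S), unclass(S), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spillover
#' @export
read_spillover <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  storage.mode(S) <- "double"
  structure(S, class = c("spillover_matrix", "matrix", "array"))
}
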