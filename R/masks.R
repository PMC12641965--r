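#' Segment the cell object from one channel
#'
#' Builds a binary object mask by Otsu thresholding the absolute deviation
#' of the channel from its modal background value, filling holes and
#' keeping the largest 8-connected component. The tight variant applies a
#' morphological closing followed by a 1-px erosion, giving a strictly
#' snugger boundary (the tight mask is always a subset of the default one).
#'
#' @param record a [cell_record()].
#' @param channel channel index or name (default 1, the brightfield channel).
#' @param tight logical; return the tight variant.
#' @return A logical matrix with attribute `source` (`"object"` or
#'   `"object_tight"`).
#' @export
object_mask <- function(record, channel = 1L, tight = FALSE) {
  img <- .get_channel(record, channel)
  rng <- range(img)
  if (diff(rng) == 0)
    stop("blank image (zero dynamic range): cannot build an object mask")
  bg <- .modal_value(img)
  dev <- abs(img - bg)
  th <- EBImage::otsu(EBImage::Image(dev / max(dev)), range = c(0, 1)) * max(dev)
  bw <- dev > th
  if (!any(bw)) stop("empty object mask after thresholding")
  bw <- as.matrix(EBImage::fillHull(EBImage::Image(bw * 1))) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  bw <- as.matrix(lab) == which.max(tab)
  if (tight) {
    closed <- as.matrix(EBImage::closing(EBImage::Image(bw * 1), .kern3())) > 0.5
    tightm <- .erode1(closed) & bw  # intersect: guarantee tight <= default
    if (!any(tightm)) stop("empty tight object mask")
    return(structure(tightm, source = "object_tight"))
  }
  structure(bw, source = "object")
}

.get_channel <- function(record, channel) {
  if (is.matrix(record)) return(record)
  img <- record$channels[[channel]]
  if (is.null(img)) stop("channel ", channel, " not present in record")
  img
}

#' Shrink a mask to a target area fraction
#'
#' Repeated 1-px 8-connected erosion of the input mask, stopping at the
#' first iterate whose area is at most `coefficient_pct`% of the input
#' area. If a further erosion would empty the mask first, the last
#' nonempty iterate is returned. A coefficient of 100 is the identity.
#' This realizes the percent-retained semantics of an adaptive-erosion
#' cytoplasm mask (coefficient 70 keeps ~70% of the object area).
#'
#' @param mask logical matrix, nonempty.
#' @param coefficient_pct target percentage of retained area in (0, 100].
#' @return A logical matrix with attribute `source = "adaptive_erode"`.
#' @export
adaptive_erode <- function(mask, coefficient_pct) {
  if (!any(mask)) stop("adaptive_erode: empty input mask")
  if (coefficient_pct <= 0 || coefficient_pct > 100)
    stop("coefficient_pct must lie in (0, 100]")
  target <- coefficient_pct / 100 * sum(mask)
  cur <- mask
  while (sum(cur) > target) {
    nxt <- .erode1(cur)
    if (!any(nxt)) break  # would empty: keep last nonempty iterate
    cur <- nxt
  }
  structure(cur, source = "adaptive_erode")
}

#' Erode a mask by a fixed number of pixels
#'
#' @param mask logical matrix.
#' @param n_px number of successive 1-px 8-connected erosions; 0 is the
#'   identity. The result may be empty.
#' @return A logical matrix with attribute `source = "erode"`.
#' @export
erode_mask <- function(mask, n_px) {
  if (n_px < 0) stop("n_px must be >= 0")
  cur <- mask
  for (i in seq_len(as.integer(n_px))) cur <- .erode1(cur)
  structure(cur, source = "erode")
}

#' Build the full mask set for one cell
#'
#' Computes the object and tight-object masks, the cytoplasm mask
#' (adaptive erosion of the object mask to `coefficient_pct`% retained
#' area, intersected with the tight mask), the plasma-membrane ring
#' (tight object AND NOT cytoplasm) and, when a nucleus channel is given,
#' a nucleus mask (object mask on that channel eroded by
#' `nucleus_erode_px`). By construction membrane and cytoplasm partition
#' the tight object: they are disjoint and their union is the tight mask.
#'
#' @param record a [cell_record()].
#' @param object_channel channel used for segmentation (default 1,
#'   brightfield).
#' @param coefficient_pct adaptive-erosion retained-area percentage
#'   (default 70).
#' @param nucleus_channel optional channel for the nucleus mask.
#' @param nucleus_erode_px erosions applied to the nucleus object mask
#'   (default 3).
#' @return An object of class `mask_set`: a list with elements `object`,
#'   `object_tight`, `cytoplasm`, `membrane` and optionally `nucleus`.
#' @export
build_maskset <- function(record, object_channel = 1L, coefficient_pct = 70,
                          nucleus_channel = NULL, nucleus_erode_px = 3L) {
  obj <- object_mask(record, object_channel, tight = FALSE)
  tight <- object_mask(record, object_channel, tight = TRUE)
  cyto <- adaptive_erode(obj, coefficient_pct) & tight
  membrane <- tight & !cyto
  out <- list(
    object = structure(unclass(obj), source = "object"),
    object_tight = structure(unclass(tight), source = "object_tight"),
    cytoplasm = structure(cyto, source = "cytoplasm"),
    membrane = structure(membrane, source = "membrane")
  )
  if (!is.null(nucleus_channel)) {
    nuc <- object_mask(record, nucleus_channel, tight = FALSE)
    nuc <- erode_mask(nuc, nucleus_erode_px) & obj
    out$nucleus <- structure(nuc, source = "nucleus")
  }
  structure(out, class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  areas <- vapply(x, sum, numeric(1))
  cat("<mask_set> areas (px):",
      paste(sprintf("%s=%d", names(areas), as.integer(areas)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export masks as an 8-bit TIFF overlay for visual QC
#'
#' @param maskset a [build_maskset()] result.
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
write_mask_overlay <- function(maskset, path) {
  # encode: cytoplasm 0.4, membrane 0.8, anything else in object 0.2
  ov <- matrix(0, nrow(maskset$object), ncol(maskset$object))
  ov[maskset$object] <- 0.2
  ov[maskset$cytoplasm] <- 0.4
  ov[maskset$membrane] <- 0.8
  tiff::writeTIFF(ov, path, bits.per.sample = 8L)
  invisible(path)
}
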