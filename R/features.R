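#' Estimate the background level of a channel
#'
#' Modal intensity (256-bin histogram mode) over the pixels outside the
#' object mask; robust to bright puncta and to the cell itself.
#'
#' @param record a [cell_record()] or a plain matrix.
#' @param channel channel index or name.
#' @param object_mask logical matrix marking the cell; its complement is
#'   the background region. `NULL` uses the whole image.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(record, channel = 1L, object_mask = NULL) {
  img <- .get_channel(record, channel)
  px <- if (is.null(object_mask)) img else img[!object_mask]
  if (length(px) == 0L) return(0)
  .modal_value(px)
}

#' Background-subtracted intensity features within a mask
#'
#' Subtracts the background (modal intensity outside the object mask),
#' clips negative pixels to zero, then reports the sum, mean and maximum
#' over the mask.
#'
#' @param record a [cell_record()] or matrix.
#' @param mask logical matrix, nonempty.
#' @param channel channel index or name.
#' @param object_mask mask defining the background region (defaults to
#'   `mask` itself).
#' @param background optional explicit background level.
#' @return A list with `total`, `mean` and `max_pixel` (arbitrary units).
#' @export
intensity_features <- function(record, mask, channel, object_mask = mask,
                               background = NULL) {
  if (!any(mask)) stop("intensity_features: empty mask")
  img <- .get_channel(record, channel)
  if (is.null(background))
    background <- estimate_background(record, channel, object_mask)
  v <- pmax(img - background, 0)[mask]
  list(total = sum(v), mean = mean(v), max_pixel = max(v))
}

#' Morphometric features of a mask
#'
#' Area is the pixel count scaled by the squared pixel size; the perimeter
#' is the length of the traced object contour; circularity is the ratio of
#' the mean to the standard deviation of boundary-pixel distances to the
#' centroid (large values = round, capped for degenerate lattice circles);
#' the aspect ratio is minor/major axis of the second-moment ellipse, in
#' (0, 1].
#'
#' @param mask logical matrix, nonempty.
#' @param pixel_size_um physical pixel size.
#' @param circularity_cap value reported when the boundary-distance SD is
#'   (numerically) zero.
#' @return A list with `area_um2`, `perimeter_um`, `circularity`,
#'   `aspect_ratio`.
#' @export
morphometrics <- function(mask, pixel_size_um = 1, circularity_cap = 100) {
  if (!any(mask)) stop("morphometrics: empty mask")
  area <- sum(mask) * pixel_size_um^2

  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  perim <- 0
  if (length(oc) > 0L) {
    pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
    if (nrow(pts) > 1L) {
      closed <- rbind(pts, pts[1L, ])
      perim <- sum(sqrt(rowSums(diff(closed)^2))) * pixel_size_um
    }
  }

  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  boundary <- mask & !.erode1(mask)
  bidx <- which(boundary, arr.ind = TRUE)
  d <- sqrt((bidx[, 1] - centroid[1])^2 + (bidx[, 2] - centroid[2])^2)
  circ <- if (length(d) < 2L || sd(d) < 1e-12) circularity_cap
          else min(mean(d) / sd(d), circularity_cap)

  if (nrow(idx) < 2L) {
    ar <- 1
  } else {
    ev <- eigen(stats::cov(idx), symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    ar <- if (ev[1] <= 0) 1 else sqrt(ev[2] / ev[1])
    ar <- min(max(ar, .Machine$double.eps), 1)
  }

  list(area_um2 = area, perimeter_um = perim, circularity = circ,
       aspect_ratio = ar)
}

#' Focus metric: normalized gradient root-mean-square
#'
#' Root-mean-square of the central-difference gradient magnitude over the
#' mask, normalized by the mean in-mask intensity (plus a small epsilon)
#' and scaled by 100. Sharp, in-focus cells score high; defocused cells
#' score low.
#'
#' @param record a [cell_record()] or matrix.
#' @param mask logical matrix, nonempty.
#' @param channel channel index or name.
#' @return Scalar focus score (dimensionless).
#' @export
gradient_rms <- function(record, mask, channel = 1L) {
  if (!any(mask)) stop("gradient_rms: empty mask")
  img <- .get_channel(record, channel)
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nr > 2L) gx[2:(nr - 1L), ] <- (img[3:nr, ] - img[1:(nr - 2L), ]) / 2
  if (nc > 2L) gy[, 2:(nc - 1L)] <- (img[, 3:nc] - img[, 1:(nc - 2L)]) / 2
  g2 <- gx^2 + gy^2
  sqrt(mean(g2[mask])) / (mean(img[mask]) + 1e-9) * 100
}

#' GLCM parameters
#'
#' @param levels number of grey levels after quantization (default 256,
#'   the 8-bit convention).
#' @param granularity_um co-occurrence offset distance in microns
#'   (default 1); converted to pixels (>= 1) using the record's pixel size.
#' @param directions integer matrix of (row, col) offsets; default the four
#'   Haralick directions (0,1), (1,0), (1,1), (1,-1).
#' @param symmetric count each pair in both orders (default TRUE).
#' @return An object of class `glcm_params`.
#' @export
glcm_params <- function(levels = 256L, granularity_um = 1,
                        directions = rbind(c(0L, 1L), c(1L, 0L),
                                           c(1L, 1L), c(1L, -1L)),
                        symmetric = TRUE) {
  if (levels < 2L) stop("levels must be >= 2")
  structure(list(levels = as.integer(levels), granularity_um = granularity_um,
                 directions = directions, symmetric = isTRUE(symmetric)),
            class = "glcm_params")
}

# quantize in-mask pixels to 0..(N-1) by linear min-max scaling
.quantize <- function(img, mask, levels) {
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  v <- img[mask]
  rng <- range(v)
  if (diff(rng) == 0) {
    q[mask] <- 0L
  } else {
    q[mask] <- pmin(as.integer(floor((v - rng[1]) / diff(rng) * levels)),
                    levels - 1L)
  }
  q
}

#' GLCM entropy of the in-mask signal distribution
#'
#' Quantizes the in-mask intensities to `levels` grey levels by linear
#' min-max scaling (so the statistic is invariant under affine intensity
#' rescaling), accumulates grey-level co-occurrence counts for all pixel
#' pairs with both endpoints in the mask at the offset distance implied by
#' the granularity, over the configured directions (symmetrized), then
#' returns the Shannon entropy of the normalized matrix in bits:
#' \deqn{-\sum_i \sum_j p(i,j)\, \log_2 p(i,j)} with 0 log 0 := 0.
#' High entropy means a spatially uniform signal; low entropy indicates
#' concentrated foci.
#'
#' @param record a [cell_record()] or a plain matrix (pixel size 1).
#' @param mask logical matrix; `NULL` uses the full image.
#' @param channel channel index or name.
#' @param params a [glcm_params()].
#' @return Entropy in bits, or `NA_real_` when no valid pixel pair exists.
#' @export
glcm_entropy <- function(record, mask = NULL, channel = 2L,
                         params = glcm_params()) {
  img <- .get_channel(record, channel)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (sum(mask) < 2L) stop("glcm_entropy: mask must contain >= 2 pixels")
  ps <- if (is.matrix(record)) 1 else record$pixel_size_um
  d <- max(1L, as.integer(round(params$granularity_um / ps)))
  q <- .quantize(img, mask, params$levels)
  N <- params$levels
  nr <- nrow(img); nc <- ncol(img)

  tab <- NULL
  for (k in seq_len(nrow(params$directions))) {
    dr <- params$directions[k, 1] * d
    dc <- params$directions[k, 2] * d
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) == 0L || length(c1) == 0L) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    keys <- a[ok] * N + b[ok] + 1
    t1 <- tabulate(keys, nbins = N * N)
    if (params$symmetric) {
      keys2 <- b[ok] * N + a[ok] + 1
      t1 <- t1 + tabulate(keys2, nbins = N * N)
    }
    tab <- if (is.null(tab)) t1 else tab + t1
  }
  if (is.null(tab) || sum(tab) == 0) return(NA_real_)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}

#' Internalization coefficient
#'
#' The base-10 logarithm of the ratio of the mean background-subtracted
#' intensity over the target mask (typically the cytoplasm) to the mean
#' over the whole-cell mask, clamped to \[-6, 6\]. Positive values mean the
#' per-pixel signal concentrates inside the target region (internalized);
#' negative values mean it concentrates outside (membrane-bound).
#'
#' @param record a [cell_record()] or matrix.
#' @param target_mask interior mask (must be a subset of `cell_mask`).
#' @param cell_mask whole-cell mask.
#' @param channel channel index or name.
#' @param background optional explicit background level (defaults to the
#'   modal intensity outside `cell_mask`).
#' @return The coefficient (log10 units), or `NA_real_` when the cell
#'   carries no whole-cell signal and cannot be scored.
#' @export
internalization_coefficient <- function(record, target_mask, cell_mask,
                                        channel = 2L, background = NULL) {
  if (!any(target_mask) || !any(cell_mask))
    stop("internalization_coefficient: masks must be nonempty")
  if (any(target_mask & !cell_mask))
    stop("target_mask must be a subset of cell_mask")
  img <- .get_channel(record, channel)
  if (is.null(background))
    background <- estimate_background(record, channel, cell_mask)
  v <- pmax(img - background, 0)
  mean_cell <- mean(v[cell_mask])
  if (mean_cell <= 0) return(NA_real_)
  mean_target <- mean(v[target_mask])
  if (mean_target <= 0) return(-6)
  ic <- log10(mean_target / mean_cell)
  min(max(ic, -6), 6)
}

#' Bright-detail similarity of two channels
#'
#' Extracts the bright detail of each channel with a white top-hat filter
#' (disk structuring element of radius `radius_px`, keeping spots of that
#' radius or less), computes the Pearson correlation of the two detail
#' images over the mask and clamps negative values to zero, giving a
#' colocalization score in \[0, 1\].
#'
#' @param record a [cell_record()].
#' @param channelA,channelB channel indices or names.
#' @param mask logical matrix, nonempty.
#' @param radius_px spot radius (default 3).
#' @return Score in \[0, 1\], or `NA_real_` if either detail image has zero
#'   variance within the mask.
#' @export
bright_detail_similarity <- function(record, channelA, channelB, mask,
                                     radius_px = 3L) {
  if (!any(mask)) stop("bright_detail_similarity: empty mask")
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  detail <- function(ch) {
    img <- .get_channel(record, ch)
    sc <- max(img)
    if (sc <= 0) return(img)
    as.matrix(EBImage::whiteTopHat(EBImage::Image(img / sc), brush)) * sc
  }
  a <- detail(channelA)[mask]
  b <- detail(channelB)[mask]
  if (sd(a) < 1e-12 || sd(b) < 1e-12) return(NA_real_)
  max(cor(a, b), 0)
}

#' One-dimensional profile colocalization
#'
#' Samples both channels along a line segment at unit spacing with
#' bilinear interpolation and returns the signed Pearson correlation of
#' the two profiles. Negative values arise when one signal sits inside the
#' ring traced by the other (internalized); positive values when the two
#' run together along the membrane.
#'
#' @param record a [cell_record()].
#' @param channelA,channelB channel indices or names.
#' @param line 2x2 numeric matrix: rows are the (row, col) endpoints.
#' @return Signed Pearson r.
#' @export
profile_colocalization <- function(record, channelA, channelB, line) {
  a <- .get_channel(record, channelA)
  b <- .get_channel(record, channelB)
  line <- as.matrix(line)
  if (!all(dim(line) == c(2L, 2L))) stop("line must be a 2x2 endpoint matrix")
  len <- sqrt(sum((line[2, ] - line[1, ])^2))
  n <- floor(len) + 1L
  t <- if (n == 1L) 0 else seq(0, 1, length.out = n)
  pts <- cbind(line[1, 1] + t * (line[2, 1] - line[1, 1]),
               line[1, 2] + t * (line[2, 2] - line[1, 2]))
  inside <- pts[, 1] >= 1 & pts[, 1] <= nrow(a) &
            pts[, 2] >= 1 & pts[, 2] <= ncol(a)
  pts <- pts[inside, , drop = FALSE]
  if (nrow(pts) < 3L) stop("profile_colocalization: fewer than 3 samples on the image")
  pa <- .bilinear(a, pts); pb <- .bilinear(b, pts)
  if (sd(pa) < 1e-12 || sd(pb) < 1e-12)
    stop("profile_colocalization: zero variance along the profile")
  cor(pa, pb)
}

.bilinear <- function(img, pts) {
  r <- pts[, 1]; c <- pts[, 2]
  r0 <- pmin(pmax(floor(r), 1), nrow(img) - 1L); r1 <- r0 + 1L
  c0 <- pmin(pmax(floor(c), 1), ncol(img) - 1L); c1 <- c0 + 1L
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

#' Compute the full feature row for one cell
#'
#' @param record a [cell_record()].
#' @param maskset a [build_maskset()] result (built on demand if `NULL`).
#' @param channels named list mapping roles to channel indices/names
#'   (`brightfield`, `compound`, `viability`).
#' @param glcm a [glcm_params()].
#' @param mask_cfg list of arguments forwarded to [build_maskset()] when
#'   `maskset` is `NULL`.
#' @return A one-row data frame (the per-cell feature row).
#' @export
compute_features <- function(record, maskset = NULL,
                             channels = list(brightfield = 1L, compound = 2L,
                                             viability = 3L),
                             glcm = glcm_params(), mask_cfg = list()) {
  if (is.null(maskset))
    maskset <- do.call(build_maskset, c(list(record = record), mask_cfg))
  obj <- maskset$object
  morph <- morphometrics(obj, record$pixel_size_um)
  row <- data.frame(
    id = record$id,
    sample_name = record$sample_name,
    timestamp_s = record$timestamp_s,
    area_um2 = morph$area_um2,
    perimeter_um = morph$perimeter_um,
    circularity = morph$circularity,
    aspect_ratio = morph$aspect_ratio,
    gradient_rms = gradient_rms(record, obj, channels$brightfield),
    stringsAsFactors = FALSE
  )
  for (role in c("compound", "viability")) {
    feats <- intensity_features(record, obj, channels[[role]], object_mask = obj)
    row[[paste0("total_", role)]] <- feats$total
    row[[paste0("mean_", role)]] <- feats$mean
    row[[paste0("max_", role)]] <- feats$max_pixel
  }
  ent <- if (sum(maskset$cytoplasm) >= 2L)
    glcm_entropy(record, maskset$cytoplasm, channels$compound, glcm)
  else NA_real_
  row$entropy_bits <- ent
  row$internalization_coefficient <- internalization_coefficient(
    record, maskset$cytoplasm, obj, channels$compound)
  row
}

#' Feature table for a gallery
#'
#' Applies [compute_features()] to every record in a gallery.
#'
#' @param gallery a [generate_gallery()] result or a plain list of
#'   [cell_record()]s.
#' @inheritParams compute_features
#' @return A data frame, one row per cell.
#' @export
feature_table <- function(gallery, channels = list(brightfield = 1L,
                                                   compound = 2L,
                                                   viability = 3L),
                          glcm = glcm_params(), mask_cfg = list()) {
  records <- if (!is.null(gallery$records)) gallery$records else gallery
  rows <- lapply(records, function(rec) {
    tryCatch(
      compute_features(rec, channels = channels, glcm = glcm,
                       mask_cfg = mask_cfg),
      error = function(e) NULL  # unsegmentable event: dropped from features
    )
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
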