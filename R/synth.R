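#' Configuration for the synthetic imaging-flow-cytometry generator
#'
#' Collects every parameter of the seeded synthetic gallery generator. The
#' generator emulates round suspension cells (MT-4-like lymphoblasts) imaged
#' at 1 micron per pixel with three channels: a brightfield-like channel
#' (absorbing dark disk on a bright background with mild internal texture),
#' a compound channel carrying the labelled-compound fluorescence split
#' between a plasma-membrane ring and the cytoplasmic interior, and a
#' viability-dye channel (PI-like: bright in dead cells, dim in live ones).
#'
#' @param image_size_px integer pair, image height and width in pixels.
#' @param pixel_size_um physical pixel size in microns (default 1, i.e. a
#'   1 x 1 micron pixel).
#' @param cell_radius_px integer range (min, max) of cell radii in pixels.
#'   Default 7-9 px, i.e. 14-18 micron diameter at the default pixel size.
#' @param membrane_width_px width of the plasma-membrane ring in pixels;
#'   must be smaller than the minimum cell radius.
#' @param internalized_fraction fraction in [0, 1]. For a single cell
#'   ([generate_cell()]) this is the fraction of the compound-channel signal
#'   placed in the cytoplasmic interior (the rest goes to the membrane ring).
#'   For a gallery ([generate_gallery()]) it is the fraction of cells of the
#'   internalized type (per-cell fraction 1) versus the membrane-bound type
#'   (fraction 0), mirroring the internalized/non-internalized dichotomy the
#'   gating cascade is designed to recover.
#' @param signal_mode `"diffuse"` (flat intracellular field with
#'   multiplicative speckle) or `"punctate"` (a few Gaussian foci, an
#'   endosomal-accumulation look).
#' @param puncta_count number of foci in punctate mode.
#' @param puncta_sigma_px Gaussian sigma of each focus, in pixels.
#' @param total_signal total compound-channel signal per cell before noise,
#'   arbitrary units.
#' @param dead_fraction fraction of dead cells in a gallery.
#' @param pi_dead_intensity,pi_live_intensity total viability-channel signal
#'   for dead and live cells. Defaults 5e4 and 1e3 straddle the 1e4 live-cell
#'   gate threshold so the viability gate is exercisable.
#' @param doublet_fraction fraction of doublet events (two overlapping cells).
#' @param defocus_fraction fraction of out-of-focus events.
#' @param defocus_sigma_px Gaussian blur sigma applied to defocused events.
#' @param noise_sd additive Gaussian noise SD on every channel.
#' @param background_level baseline added to the fluorescence channels.
#' @param flow_rate_events_per_s mean event rate used to draw timestamps.
#' @param seed integer seed; all randomness flows from it, with per-cell
#'   substreams derived by counter.
#'
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(seed = 7, internalized_fraction = 1)
#' cell <- generate_cell(cfg)
#' @export
synth_config <- function(image_size_px = c(64L, 64L),
                         pixel_size_um = 1,
                         cell_radius_px = c(7L, 9L),
                         membrane_width_px = 2L,
                         internalized_fraction = 0.5,
                         signal_mode = c("diffuse", "punctate"),
                         puncta_count = 6L,
                         puncta_sigma_px = 1.2,
                         total_signal = 1e5,
                         dead_fraction = 0.05,
                         pi_dead_intensity = 5e4,
                         pi_live_intensity = 1e3,
                         doublet_fraction = 0.05,
                         defocus_fraction = 0.05,
                         defocus_sigma_px = 3,
                         noise_sd = 2,
                         background_level = 10,
                         flow_rate_events_per_s = 5,
                         seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    cell_radius_px = as.integer(cell_radius_px),
    membrane_width_px = as.integer(membrane_width_px),
    internalized_fraction = internalized_fraction,
    signal_mode = signal_mode,
    puncta_count = as.integer(puncta_count),
    puncta_sigma_px = puncta_sigma_px,
    total_signal = total_signal,
    dead_fraction = dead_fraction,
    pi_dead_intensity = pi_dead_intensity,
    pi_live_intensity = pi_live_intensity,
    doublet_fraction = doublet_fraction,
    defocus_fraction = defocus_fraction,
    defocus_sigma_px = defocus_sigma_px,
    noise_sd = noise_sd,
    background_level = background_level,
    flow_rate_events_per_s = flow_rate_events_per_s,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  fr <- c(internalized = cfg$internalized_fraction, dead = cfg$dead_fraction,
          doublet = cfg$doublet_fraction, defocus = cfg$defocus_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions must lie in [0, 1]; offending: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  }
  if (length(cfg$image_size_px) != 2L || any(cfg$image_size_px < 16L))
    stop("image_size_px must be a pair of integers >= 16")
  if (length(cfg$cell_radius_px) != 2L || cfg$cell_radius_px[1] > cfg$cell_radius_px[2])
    stop("cell_radius_px must be an increasing (min, max) pair")
  if (cfg$membrane_width_px < 1L)
    stop("membrane_width_px must be >= 1")
  if (cfg$membrane_width_px >= cfg$cell_radius_px[1])
    stop("membrane_width_px (", cfg$membrane_width_px,
         ") must be smaller than the minimum cell radius (",
         cfg$cell_radius_px[1], ")")
  if (!(cfg$pi_live_intensity < 1e4 && 1e4 <= cfg$pi_dead_intensity))
    stop("need pi_live_intensity < 1e4 <= pi_dead_intensity so the viability gate is exercisable")
  if (cfg$total_signal < 0 || cfg$flow_rate_events_per_s <= 0)
    stop("total_signal must be >= 0 and flow_rate_events_per_s > 0")
  invisible(cfg)
}

#' Construct a per-event cell record
#'
#' @param id event identifier.
#' @param channels named or indexed list of numeric matrices, all the same
#'   shape, nonnegative and finite.
#' @param pixel_size_um physical pixel size in microns.
#' @param timestamp_s acquisition time of the event, seconds.
#' @param sample_name the `<object>_<Num>` sample identity the event belongs to.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(id, channels, pixel_size_um = 1, timestamp_s = 0,
                        sample_name = "sample_1") {
  if (length(channels) < 1L) stop("a cell record needs at least one channel")
  shapes <- vapply(channels, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    stop("all channel arrays must share the same shape")
  for (m in channels) {
    if (!all(is.finite(m)) || any(m < 0))
      stop("channel intensities must be nonnegative and finite")
  }
  structure(list(id = as.character(id), channels = channels,
                 pixel_size_um = pixel_size_um, timestamp_s = timestamp_s,
                 sample_name = sample_name),
            class = "cell_record")
}

# rasterized disk on an nr x nc grid
.disk <- function(nr, nc, cx, cy, r) {
  x <- matrix(rep(seq_len(nr), nc), nr)
  y <- matrix(rep(seq_len(nc), each = nr), nr)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# distribute `total` over the TRUE pixels of `mask` with multiplicative
# jitter, renormalized so the sum is exactly `total`
.spread <- function(mask, total, jitter_sd) {
  n <- sum(mask)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (n == 0L || total <= 0) return(out)
  w <- pmax(1 + rnorm(n, 0, jitter_sd), 0.05)
  out[mask] <- w / sum(w) * total
  out
}

# punctate field: k Gaussian foci at uniform-random interior pixels,
# truncated to the interior and renormalized to `total`
.puncta_field <- function(interior, total, k, sigma) {
  n <- sum(interior)
  out <- matrix(0, nrow(interior), ncol(interior))
  if (n == 0L || total <= 0) return(out)
  idx <- which(interior, arr.ind = TRUE)
  centers <- idx[sample.int(n, k, replace = TRUE), , drop = FALSE]
  x <- matrix(rep(seq_len(nrow(interior)), ncol(interior)), nrow(interior))
  y <- matrix(rep(seq_len(ncol(interior)), each = nrow(interior)), nrow(interior))
  f <- matrix(0, nrow(interior), ncol(interior))
  for (i in seq_len(nrow(centers))) {
    f <- f + exp(-((x - centers[i, 1])^2 + (y - centers[i, 2])^2) / (2 * sigma^2))
  }
  f[!interior] <- 0
  s <- sum(f)
  if (s <= 0) { f[interior][1] <- 1; s <- 1 }
  out <- f / s * total
  out
}

#' Generate one synthetic cell event
#'
#' Renders a three-channel stack (brightfield, compound, viability) plus a
#' ground-truth row. The compound channel places `(1 - f) * total_signal` on
#' the plasma-membrane ring and `f * total_signal` in the cytoplasmic
#' interior (diffusely or as puncta), where `f` is the internalized
#' fraction. Doublets render two overlapping disks; defocused events are
#' Gaussian-blurred; additive noise is applied last. Identical `(cfg, seed)`
#' give bit-identical stacks.
#'
#' @param cfg a [synth_config()].
#' @param seed integer substream seed for this cell (defaults to `cfg$seed`).
#' @param id,timestamp_s,sample_name event metadata.
#' @param internalized_fraction per-cell override of the signal split.
#' @param signal_mode per-cell override of `"diffuse"`/`"punctate"`.
#' @param dead,doublet,defocused logical class flags for this event.
#' @param spillover optional 2x2 mixing matrix applied to the clean
#'   (compound, viability) signal before background and noise;
#'   `S[i, j]` is the fraction of channel-i signal appearing in channel j.
#' @param return_masks also return the ground-truth `disk`, `interior` and
#'   `ring` masks used for rendering.
#' @return A list with elements `record` (a [cell_record()]) and `truth`
#'   (a one-row data frame), plus `masks` when `return_masks = TRUE`.
#' @export
generate_cell <- function(cfg, seed = cfg$seed, id = "cell_1", timestamp_s = 0,
                          sample_name = "sample_1",
                          internalized_fraction = cfg$internalized_fraction,
                          signal_mode = cfg$signal_mode,
                          dead = FALSE, doublet = FALSE, defocused = FALSE,
                          spillover = NULL, return_masks = FALSE) {
  validate_synth_config(cfg)
  if (internalized_fraction < 0 || internalized_fraction > 1)
    stop("internalized_fraction must lie in [0, 1]")
  set.seed(as.integer(seed))
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  r <- sample(seq(cfg$cell_radius_px[1], cfg$cell_radius_px[2]), 1L)
  cx <- nr / 2 + runif(1, -2, 2)
  cy <- nc / 2 + runif(1, -2, 2)
  mw <- cfg$membrane_width_px

  disk <- .disk(nr, nc, cx, cy, r)
  interior <- .disk(nr, nc, cx, cy, r - mw)
  if (doublet) {
    # overlapping second disk at 1.6 x radius: union aspect ratio ~0.5,
    # below the default singlet gate
    ang <- runif(1, 0, 2 * pi)
    cx2 <- cx + 1.6 * r * cos(ang); cy2 <- cy + 1.6 * r * sin(ang)
    disk2 <- .disk(nr, nc, cx2, cy2, r)
    interior2 <- .disk(nr, nc, cx2, cy2, r - mw)
    disk <- disk | disk2
    interior <- interior | interior2
  }
  ring <- disk & !interior

  f <- internalized_fraction
  comp <- .spread(ring, (1 - f) * cfg$total_signal, 0.10)
  if (identical(signal_mode, "punctate")) {
    comp <- comp + .puncta_field(interior, f * cfg$total_signal,
                                 cfg$puncta_count, cfg$puncta_sigma_px)
  } else {
    comp <- comp + .spread(interior, f * cfg$total_signal, 0.15)
  }

  pi_total <- if (dead) cfg$pi_dead_intensity else cfg$pi_live_intensity
  viab <- .spread(disk, pi_total, 0.10)

  if (!is.null(spillover)) {
    if (!is.matrix(spillover) || nrow(spillover) != 2L || ncol(spillover) != 2L)
      stop("per-cell spillover must be a 2x2 matrix over (compound, viability)")
    mixed_comp <- spillover[1, 1] * comp + spillover[2, 1] * viab
    mixed_viab <- spillover[1, 2] * comp + spillover[2, 2] * viab
    comp <- mixed_comp; viab <- mixed_viab
  }

  bf <- matrix(800, nr, nc)
  bf[disk] <- 300 + rnorm(sum(disk), 0, 30)

  comp <- comp + cfg$background_level
  viab <- viab + cfg$background_level

  if (defocused) {
    s <- cfg$defocus_sigma_px
    bf <- as.matrix(EBImage::gblur(EBImage::Image(bf), sigma = s))
    comp <- as.matrix(EBImage::gblur(EBImage::Image(comp), sigma = s))
    viab <- as.matrix(EBImage::gblur(EBImage::Image(viab), sigma = s))
  }

  if (cfg$noise_sd > 0) {
    bf <- bf + rnorm(nr * nc, 0, cfg$noise_sd)
    comp <- comp + rnorm(nr * nc, 0, cfg$noise_sd)
    viab <- viab + rnorm(nr * nc, 0, cfg$noise_sd)
  }
  bf <- pmax(bf, 0); comp <- pmax(comp, 0); viab <- pmax(viab, 0)

  record <- cell_record(
    id = id,
    channels = list(brightfield = bf, compound = comp, viability = viab),
    pixel_size_um = cfg$pixel_size_um,
    timestamp_s = timestamp_s,
    sample_name = sample_name
  )
  truth <- data.frame(
    id = as.character(id),
    is_doublet = doublet, is_dead = dead, is_defocused = defocused,
    true_internalized_fraction = f,
    true_signal_mode = signal_mode,
    timestamp_s = timestamp_s,
    true_radius_px = r,
    true_area_px = sum(disk),
    stringsAsFactors = FALSE
  )
  out <- list(record = record, truth = truth)
  if (return_masks)
    out$masks <- list(disk = disk, interior = interior, ring = ring)
  out
}

# exact-count class allocation: round(frac * n) events flagged TRUE,
# positions chosen by random permutation
.allocate <- function(n, frac) {
  k <- round(frac * n)
  out <- rep(FALSE, n)
  if (k > 0L) out[sample.int(n, k)] <- TRUE
  out
}

#' Generate a synthetic gallery with ground truth
#'
#' Draws `n_events` cells with timestamps from the configured flow rate and
#' class labels (dead, doublet, defocused, internalized-type) assigned by
#' exact-count allocation under the configured fractions. At the gallery
#' level `cfg$internalized_fraction` is the fraction of cells of the
#' internalized type (per-cell signal fraction 1); the remainder are
#' membrane-bound (fraction 0). See [synth_config()].
#'
#' @param cfg a [synth_config()].
#' @param n_events number of events, >= 1.
#' @param sample_name the `<object>_<Num>` sample identity.
#' @return A list with `records` (list of [cell_record()]) and `truth`
#'   (data frame, one row per event, timestamps strictly increasing).
#' @export
generate_gallery <- function(cfg, n_events, sample_name = "sample_1") {
  validate_synth_config(cfg)
  if (!is.numeric(n_events) || n_events < 1)
    stop("n_events must be >= 1")
  n <- as.integer(n_events)
  set.seed(cfg$seed)
  ts <- cumsum(rexp(n, rate = cfg$flow_rate_events_per_s))
  dead <- .allocate(n, cfg$dead_fraction)
  doublet <- .allocate(n, cfg$doublet_fraction)
  defocus <- .allocate(n, cfg$defocus_fraction)
  internal <- .allocate(n, cfg$internalized_fraction)
  seeds <- vapply(seq_len(n), function(i) .substream_seed(cfg$seed, i), integer(1))

  records <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_cell(cfg, seed = seeds[i],
                       id = sprintf("%s_ev%05d", sample_name, i),
                       timestamp_s = ts[i], sample_name = sample_name,
                       internalized_fraction = as.numeric(internal[i]),
                       dead = dead[i], doublet = doublet[i],
                       defocused = defocus[i])
    records[[i]] <- g$record
    truths[[i]] <- g$truth
  }
  truth <- do.call(rbind, truths)
  truth$sample_name <- sample_name
  list(records = records, truth = truth)
}

#' Generate single-stain compensation control galleries
#'
#' Produces a compound-only gallery (no viability dye) and a viability-only
#' gallery (no compound), whose clean per-pixel channel signals are mixed by
#' the given spillover matrix before background and noise, emulating
#' single-stain controls acquired for spillover estimation.
#'
#' @param cfg a [synth_config()].
#' @param spillover 2x2 matrix over (compound, viability): unit diagonal,
#'   nonnegative off-diagonal entries < 1.
#' @param n_events events per control gallery.
#' @return A list with galleries `compound` and `viability`.
#' @export
generate_single_stain_controls <- function(cfg, spillover = diag(2), n_events = 100L) {
  if (!is.matrix(spillover) || nrow(spillover) != ncol(spillover))
    stop("spillover must be a square matrix")
  if (nrow(spillover) != 2L)
    stop("two-channel controls need a 2x2 spillover matrix")
  if (any(abs(diag(spillover) - 1) > 1e-12))
    stop("spillover must have a unit diagonal")
  off <- spillover[row(spillover) != col(spillover)]
  if (any(off < 0) || any(off >= 1))
    stop("off-diagonal spillover entries must lie in [0, 1)")

  base <- unclass(cfg)
  base$doublet_fraction <- 0; base$defocus_fraction <- 0
  base$internalized_fraction <- 1

  comp_cfg <- base
  comp_cfg$dead_fraction <- 0
  comp_cfg$pi_live_intensity <- 0
  comp_cfg$seed <- .substream_seed(cfg$seed, 900001L)

  viab_cfg <- base
  viab_cfg$dead_fraction <- 1
  viab_cfg$total_signal <- 0
  viab_cfg$seed <- .substream_seed(cfg$seed, 900002L)

  gen_mixed <- function(c0, name) {
    c0 <- structure(c0, class = "synth_config")
    set.seed(c0$seed)
    n <- as.integer(n_events)
    ts <- cumsum(rexp(n, rate = c0$flow_rate_events_per_s))
    dead <- .allocate(n, c0$dead_fraction)
    seeds <- vapply(seq_len(n), function(i) .substream_seed(c0$seed, i), integer(1))
    records <- vector("list", n); truths <- vector("list", n)
    for (i in seq_len(n)) {
      g <- generate_cell(c0, seed = seeds[i],
                         id = sprintf("%s_ev%05d", name, i),
                         timestamp_s = ts[i], sample_name = name,
                         internalized_fraction = c0$internalized_fraction,
                         dead = dead[i], spillover = spillover)
      records[[i]] <- g$record; truths[[i]] <- g$truth
    }
    truth <- do.call(rbind, truths); truth$sample_name <- name
    list(records = records, truth = truth)
  }

  list(compound = gen_mixed(comp_cfg, "control_compound"),
       viability = gen_mixed(viab_cfg, "control_viability"))
}
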