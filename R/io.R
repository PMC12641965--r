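#' Write a gallery to disk
#'
#' One multipage TIFF per event (pages = channels), a CSV ground-truth
#' table and a JSON sidecar with the channel map, pixel size, timestamps
#' and the intensity scale used to store the float data.
#'
#' @param gallery a gallery (list with `records`, optionally `truth`).
#' @param dir output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
write_gallery <- function(gallery, dir) {
  records <- if (!is.null(gallery$records)) gallery$records else gallery
  if (length(records) == 0L) stop("write_gallery: empty gallery")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(vapply(records, function(r) max(unlist(lapply(r$channels, max))),
                      numeric(1)))
  if (scale <= 0) scale <- 1
  files <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    files[i] <- file.path(dir, paste0(rec$id, ".tiff"))
    pages <- lapply(rec$channels, function(m) m / scale)
    tiff::writeTIFF(pages, files[i], bits.per.sample = 16L)
  }
  if (!is.null(gallery$truth))
    write.csv(gallery$truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  sidecar <- list(
    channel_map = as.list(setNames(names(records[[1]]$channels),
                                   seq_along(records[[1]]$channels))),
    pixel_size_um = records[[1]]$pixel_size_um,
    intensity_scale = scale,
    events = data.frame(
      id = vapply(records, `[[`, character(1), "id"),
      file = basename(files),
      timestamp_s = vapply(records, `[[`, numeric(1), "timestamp_s"),
      sample_name = vapply(records, `[[`, character(1), "sample_name"),
      stringsAsFactors = FALSE)
  )
  sidecar_path <- file.path(dir, "gallery.json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(sidecar_path)
}

#' Read a gallery written by [write_gallery()]
#'
#' @param dir gallery directory containing `gallery.json`.
#' @return A list with `records` and (when present) `truth`.
#' @export
read_gallery <- function(dir) {
  sidecar_path <- file.path(dir, "gallery.json")
  if (!file.exists(sidecar_path))
    stop("no gallery.json sidecar in ", dir)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  ev <- sc$events
  records <- lapply(seq_len(nrow(ev)), function(i) {
    pages <- tiff::readTIFF(file.path(dir, ev$file[i]), all = TRUE)
    channels <- lapply(pages, function(p) p * sc$intensity_scale)
    names(channels) <- unlist(sc$channel_map)
    cell_record(id = ev$id[i], channels = channels,
                pixel_size_um = sc$pixel_size_um,
                timestamp_s = ev$timestamp_s[i],
                sample_name = ev$sample_name[i])
  })
  out <- list(records = records)
  truth_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(truth_path)) out$truth <- read.csv(truth_path)
  out
}
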