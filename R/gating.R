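#' Gating cascade configuration
#'
#' Thresholds for the six-step cascade. Boundary conventions follow the
#' workflow's wording: the viability gate is strict (`< viability_max_pi`)
#' and the internalization gate is strict (`> internalization_min_ic`);
#' all other gates are inclusive.
#'
#' @param focus_min_gradient_rms minimum focus score (default 40).
#' @param time_min_s events before this acquisition time are excluded as
#'   potential carryover from the previous sample (default 20 s).
#' @param singlet_area_um2 inclusive area range for single cells.
#' @param singlet_aspect_ratio_min minimum aspect ratio for singlets
#'   (doublets are elongated; default 0.6, inclusive).
#' @param viability_max_pi live cells must have a viability-channel total
#'   strictly below this (default 1e4).
#' @param uptake_min_total compound-channel total threshold (inclusive),
#'   or `"auto"` to use negative-control mean + 3 SD.
#' @param internalization_min_ic internalization-coefficient threshold,
#'   strict (default 0).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(focus_min_gradient_rms = 40,
                        time_min_s = 20,
                        singlet_area_um2 = c(50, 300),
                        singlet_aspect_ratio_min = 0.6,
                        viability_max_pi = 1e4,
                        uptake_min_total = "auto",
                        internalization_min_ic = 0) {
  if (length(singlet_area_um2) != 2L || singlet_area_um2[1] > singlet_area_um2[2])
    stop("singlet_area_um2 must be a nonempty (min, max) range")
  num <- c(focus_min_gradient_rms, time_min_s, singlet_area_um2,
           singlet_aspect_ratio_min, viability_max_pi, internalization_min_ic)
  if (any(!is.finite(num))) stop("gate thresholds must be finite")
  structure(list(focus_min_gradient_rms = focus_min_gradient_rms,
                 time_min_s = time_min_s,
                 singlet_area_um2 = singlet_area_um2,
                 singlet_aspect_ratio_min = singlet_aspect_ratio_min,
                 viability_max_pi = viability_max_pi,
                 uptake_min_total = uptake_min_total,
                 internalization_min_ic = internalization_min_ic),
            class = "gate_config")
}

.members <- function(features, keep) features$id[keep & !is.na(keep)]

#' Individual gates of the cascade
#'
#' Each gate takes the feature table (or a subset of it) and returns the
#' ids of the members that pass.
#'
#' @param features a feature table ([feature_table()]).
#' @param cfg a [gate_config()].
#' @return Character vector of member ids.
#' @name gates
NULL

#' @rdname gates
#' @export
gate_focus <- function(features, cfg = gate_config()) {
  .members(features, features$gradient_rms >= cfg$focus_min_gradient_rms)
}

#' @rdname gates
#' @export
gate_time <- function(features, cfg = gate_config()) {
  .members(features, features$timestamp_s >= cfg$time_min_s)
}

#' @rdname gates
#' @export
gate_singlets <- function(features, cfg = gate_config()) {
  keep <- features$area_um2 >= cfg$singlet_area_um2[1] &
    features$area_um2 <= cfg$singlet_area_um2[2] &
    features$aspect_ratio >= cfg$singlet_aspect_ratio_min
  .members(features, keep)
}

#' @rdname gates
#' @export
gate_viable <- function(features, cfg = gate_config()) {
  .members(features, features$total_viability < cfg$viability_max_pi)
}

#' @rdname gates
#' @param negative_control feature table (or numeric vector of compound
#'   totals) from an unexposed control, required when
#'   `cfg$uptake_min_total == "auto"`.
#' @export
gate_uptake <- function(features, cfg = gate_config(), negative_control = NULL) {
  thr <- cfg$uptake_min_total
  if (identical(thr, "auto")) {
    if (is.null(negative_control))
      stop("uptake threshold 'auto' requires a negative control")
    x <- if (is.numeric(negative_control)) negative_control
         else negative_control$total_compound
    thr <- mean(x) + 3 * sd(x)
  }
  .members(features, features$total_compound >= thr)
}

#' @rdname gates
#' @export
gate_internalized <- function(features, cfg = gate_config()) {
  .members(features, features$internalization_coefficient > cfg$internalization_min_ic)
}

#' Run the full analysis pipeline on a gallery
#'
#' Computes masks and features for every event, optionally compensates the
#' fluorescence totals, then applies the cascade in the fixed order
#' focus -> time -> singlets -> viable -> uptake -> internalized, and
#' summarises the sample.
#'
#' @param gallery a gallery (list with `records`) or list of
#'   [cell_record()]s.
#' @param gate_cfg a [gate_config()].
#' @param mask_cfg arguments forwarded to [build_maskset()].
#' @param glcm a [glcm_params()].
#' @param channels role-to-channel map.
#' @param spillover optional [estimate_spillover()] matrix applied to the
#'   (compound, viability) totals before gating.
#' @param negative_control see [gate_uptake()].
#' @param sample_name overrides the sample identity in the summary.
#' @return An object of class `pipeline_result`: a list with `features`,
#'   `tree` (a `population_tree`) and `summary` (one-row data frame with
#'   the report fields).
#' @export
run_pipeline <- function(gallery, gate_cfg = gate_config(), mask_cfg = list(),
                         glcm = glcm_params(),
                         channels = list(brightfield = 1L, compound = 2L,
                                         viability = 3L),
                         spillover = NULL, negative_control = NULL,
                         sample_name = NULL) {
  records <- if (!is.null(gallery$records)) gallery$records else gallery
  if (length(records) == 0L) stop("run_pipeline: empty gallery")
  feats <- feature_table(records, channels = channels, glcm = glcm,
                         mask_cfg = mask_cfg)
  if (is.null(feats) || nrow(feats) == 0L)
    stop("run_pipeline: no segmentable events")
  if (!is.null(spillover)) {
    comp <- apply_compensation(
      cbind(compound = feats$total_compound, viability = feats$total_viability),
      spillover)
    feats$total_compound <- pmax(comp[, "compound"], 0)
    feats$total_viability <- pmax(comp[, "viability"], 0)
  }
  if (is.null(sample_name)) sample_name <- feats$sample_name[1]

  sub <- function(ids) feats[feats$id %in% ids, , drop = FALSE]
  g_all <- feats$id
  g_focus <- gate_focus(feats, gate_cfg)
  g_time <- gate_time(sub(g_focus), gate_cfg)
  g_singlet <- gate_singlets(sub(g_time), gate_cfg)
  g_viable <- gate_viable(sub(g_singlet), gate_cfg)
  g_uptake <- gate_uptake(sub(g_viable), gate_cfg, negative_control)
  g_intern <- gate_internalized(sub(g_uptake), gate_cfg)

  gates <- list(all = g_all, in_focus = g_focus, time_ok = g_time,
                singlets = g_singlet, viable = g_viable,
                uptake = g_uptake, internalized = g_intern)
  tree <- structure(list(
    gates = lapply(gates, function(ids) list(ids = ids, count = length(ids))),
    order = names(gates)), class = "population_tree")

  uptake_feats <- sub(g_uptake)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  summary <- data.frame(
    File = paste0(sample_name, ".daf"),
    Total_Count = length(g_all),
    Viable_Single_Count = length(g_viable),
    Viable_Single_Pct = pct(length(g_viable), length(g_all)),
    Uptake_Count = length(g_uptake),
    Uptake_Pct = pct(length(g_uptake), length(g_viable)),
    Internalized_Count = length(g_intern),
    Internalized_Pct = pct(length(g_intern), length(g_uptake)),
    Median_Entropy = if (length(g_uptake) > 0)
      median(uptake_feats$entropy_bits, na.rm = TRUE) else NA_real_,
    Median_IC = if (length(g_uptake) > 0)
      median(uptake_feats$internalization_coefficient, na.rm = TRUE)
      else NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(features = feats, tree = tree, summary = summary),
            class = "pipeline_result")
}

#' @export
print.population_tree <- function(x, ...) {
  cat("<population_tree>\n")
  for (g in x$order)
    cat(sprintf("  %-13s %6d\n", g, x$gates[[g]]$count))
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$tree)
  cat("summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# full-precision numeric formatting so report round trips are exact
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' Write a per-sample statistics report
#'
#' One header row, one row per sample; the first column is `File` with
#' `<object>_<Num>.daf` entries. Tab-separated, UTF-8, dot decimal;
#' numeric fields are written at full precision so a write/parse round
#' trip is exact.
#'
#' @param summaries a data frame of sample summaries (rows from
#'   [run_pipeline()]`$summary`) or a list of such one-row frames.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report <- function(summaries, path) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("write_report: need at least one sample summary")
  if (anyDuplicated(summaries$File))
    stop("duplicate File entries: ",
         paste(unique(summaries$File[duplicated(summaries$File)]), collapse = ", "))
  out <- summaries
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(as.list(out), sep = "\t")))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
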