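#' Parse a per-timepoint statistics report into long format
#'
#' Locates the header row (the first line containing a `File` cell), reads
#' the tab-separated table, splits each `File` stem on its LAST underscore
#' into the object name and the replicate (tube) number, and melts every
#' other numeric column into `(object, replicate, time, parameter, value)`
#' rows. Non-numeric cells become missing values.
#'
#' @param path report path (tab-separated, UTF-8, dot decimal).
#' @param time_label label for the timepoint this file represents.
#' @return A data frame fragment of the tidy statistics table.
#' @export
parse_report <- function(path, time_label) {
  if (!file.exists(path)) stop("report not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- which(vapply(lines, function(l) "File" %in% strsplit(l, "\t")[[1]],
                      logical(1)))[1]
  if (is.na(hdr)) stop("no 'File' column found in ", path)
  df <- read.delim(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                   sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  if (!"File" %in% names(df)) stop("no 'File' column found in ", path)

  stem <- sub("\\.daf$", "", df$File)
  m <- regmatches(stem, regexec("^(.*)_([0-9]+)$", stem))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("File entry without an _<integer> suffix at row ",
         paste(which(bad), collapse = ", "), ": ",
         paste(df$File[bad], collapse = ", "))
  object <- vapply(m, `[[`, character(1), 2L)
  replicate <- as.integer(vapply(m, `[[`, character(1), 3L))

  params <- setdiff(names(df), "File")
  frags <- lapply(params, function(p) {
    data.frame(object = object, replicate = replicate,
               time = time_label, parameter = p,
               value = suppressWarnings(as.numeric(df[[p]])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, frags)
}

#' Read several per-timepoint reports into one tidy table
#'
#' @param paths report paths, one per timepoint.
#' @param times timepoint label for each path.
#' @param order level order of the time factor (default: order given).
#' @return A tidy statistics table with `time` as an ordered factor.
#' @export
read_reports <- function(paths, times, order = unique(times)) {
  if (length(paths) != length(times))
    stop("paths and times must have the same length")
  tab <- do.call(rbind, Map(parse_report, paths, times))
  tab$time <- factor(tab$time, levels = order, ordered = TRUE)
  key <- paste(tab$object, tab$replicate, tab$time, tab$parameter, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (object, replicate, time, parameter) entries in reports")
  rownames(tab) <- NULL
  tab
}

#' Descriptive statistics
#'
#' Mean, sample SD (n - 1 denominator; missing when n = 1) and n per
#' (object, time, parameter) cell. Missing values are dropped first.
#'
#' @param table a tidy statistics table.
#' @return A data frame with columns object, time, parameter, mean, sd, n.
#' @export
descriptive_stats <- function(table) {
  if (nrow(table) == 0L) stop("descriptive_stats: empty table")
  tab <- table[!is.na(table$value), , drop = FALSE]
  sp <- split(tab, list(tab$object, tab$time, tab$parameter), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(object = g$object[1], time = as.character(g$time[1]),
               parameter = g$parameter[1],
               mean = mean(g$value),
               sd = if (nrow(g) > 1) sd(g$value) else NA_real_,
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$parameter, out$time, out$object), , drop = FALSE]
}

# group values of one parameter at one timepoint: named list object -> values
.groups_at <- function(table, parameter, time) {
  tab <- table[table$parameter == parameter & table$time == time &
                 !is.na(table$value), , drop = FALSE]
  split(tab$value, tab$object)
}

# between-group sum-of-squares decomposition
.ss_decomp <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  list(ssb = ssb, ssw = ssw, sst = ssb + ssw,
       k = length(groups), N = length(all_v))
}

# 95% CI for omega-squared by inverting the noncentral-F distribution:
# bounds on the noncentrality lambda are mapped through
# omega^2 = lambda / (lambda + N)
.omega_ci <- function(F, df1, df2, N, conf = 0.95) {
  if (!is.finite(F)) return(c(NA_real_, NA_real_))
  alpha <- 1 - conf
  pl <- function(l) pf(F, df1, df2, ncp = l)
  lo <- if (pl(0) < 1 - alpha / 2) 0 else {
    uniroot(function(l) pl(l) - (1 - alpha / 2), c(0, 1e6))$root
  }
  hi_f <- function(l) pl(l) - alpha / 2
  hi <- if (hi_f(0) < 0) 0 else uniroot(hi_f, c(0, 1e7))$root
  c(lo / (lo + N), hi / (hi + N))
}

#' One-way between-group ANOVA with omega-squared
#'
#' Direct sum-of-squares decomposition across objects for one parameter at
#' one timepoint: F = MSB/MSW, omega^2 = (SSB - (k-1) MSW)/(SST + MSW),
#' with a 95% CI obtained by inverting the noncentral-F distribution.
#' Requires >= 2 groups with >= 2 replicates each and nonzero pooled
#' within-group variance; violations raise a condition of class
#' `flowintern_exclusion` carrying the reason.
#'
#' @param table a tidy statistics table.
#' @param parameter,time the cell to analyse.
#' @return A one-row data frame: parameter, time, F, df1, df2, p,
#'   omega_sq, omega_lo, omega_hi, k, N.
#' @export
oneway_anova <- function(table, parameter, time) {
  groups <- .groups_at(table, parameter, time)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) < 2L)
    .exclude("insufficient data",
             sprintf("parameter '%s' at time '%s': fewer than 2 groups with >= 2 replicates",
                     parameter, time))
  dec <- .ss_decomp(groups)
  df1 <- dec$k - 1L; df2 <- dec$N - dec$k
  msw <- dec$ssw / df2
  if (msw <= 0)
    .exclude("zero variance",
             sprintf("parameter '%s' at time '%s': zero within-group variance",
                     parameter, time))
  F <- (dec$ssb / df1) / msw
  omega <- (dec$ssb - df1 * msw) / (dec$sst + msw)
  ci <- .omega_ci(F, df1, df2, dec$N)
  data.frame(parameter = parameter, time = as.character(time),
             F = F, df1 = df1, df2 = df2,
             p = pf(F, df1, df2, lower.tail = FALSE),
             omega_sq = omega, omega_lo = ci[1], omega_hi = ci[2],
             k = dec$k, N = dec$N, stringsAsFactors = FALSE)
}

#' Tukey HSD pairwise comparisons with Cohen's d and BH correction
#'
#' Studentized-range p per object pair (pooled MSW, N - k df,
#' Tukey-Kramer for unequal n), Cohen's d from the pair's pooled SD, and
#' Benjamini-Hochberg adjustment across the whole family of pairs of this
#' (parameter, time) cell.
#'
#' @inheritParams oneway_anova
#' @return A data frame: group_a, group_b, mean_diff, tukey_p, p_adj,
#'   cohens_d, significant.
#' @export
tukey_pairwise <- function(table, parameter, time) {
  groups <- .groups_at(table, parameter, time)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) < 2L)
    .exclude("insufficient data",
             sprintf("parameter '%s' at time '%s': fewer than 2 groups with >= 2 replicates",
                     parameter, time))
  dec <- .ss_decomp(groups)
  k <- dec$k; df2 <- dec$N - k
  msw <- dec$ssw / df2
  if (msw <= 0)
    .exclude("zero variance",
             sprintf("parameter '%s' at time '%s': zero within-group variance",
                     parameter, time))
  nms <- names(groups)
  pairs <- utils::combn(nms, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- groups[[pairs[1, i]]]; b <- groups[[pairs[2, i]]]
    diff <- mean(b) - mean(a)
    se <- sqrt(msw / 2 * (1 / length(a) + 1 / length(b)))
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    d <- if (sp > 0) diff / sp else 0
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               mean_diff = diff, tukey_p = p, cohens_d = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$tukey_p, method = "BH")
  out$significant <- out$p_adj < 0.05
  out$parameter <- parameter
  out$time <- as.character(time)
  out[, c("parameter", "time", "group_a", "group_b", "mean_diff",
          "tukey_p", "p_adj", "cohens_d", "significant")]
}

# wide subjects x times matrix of complete cases for one (parameter, object)
.rm_matrix <- function(table, parameter, object) {
  tab <- table[table$parameter == parameter & table$object == object &
                 !is.na(table$value), , drop = FALSE]
  times <- if (is.factor(tab$time)) levels(droplevels(tab$time))
           else unique(as.character(tab$time))
  reps <- sort(unique(tab$replicate))
  m <- matrix(NA_real_, length(reps), length(times),
              dimnames = list(reps, times))
  m[cbind(match(tab$replicate, reps), match(as.character(tab$time), times))] <-
    tab$value
  complete <- stats::complete.cases(m)
  list(full = m, complete = m[complete, , drop = FALSE],
       dropped = rownames(m)[!complete])
}

# GES from a complete subjects x times matrix
.ges_of <- function(m) {
  grand <- mean(m)
  ss_subj <- ncol(m) * sum((rowMeans(m) - grand)^2)
  ss_time <- nrow(m) * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  ss_err <- sst - ss_subj - ss_time
  list(ss_subject = ss_subj, ss_time = ss_time, ss_error = max(ss_err, 0),
       sst = sst, ges = ss_time / (ss_time + ss_subj + max(ss_err, 0)))
}

#' One-way repeated-measures ANOVA with generalized eta-squared
#'
#' Within-subject decomposition over timepoints for one object:
#' SS_subject + SS_time + SS_error = SS_total, F = MS_time/MS_error,
#' GES = SS_time / (SS_time + SS_subject + SS_error). Only complete cases
#' (replicates observed at every timepoint) enter; incomplete replicates
#' are dropped and reported. The GES 95% CI is a seeded percentile
#' bootstrap over subjects. A zero error SS yields an infinite F, reported
#' as `Inf` with `zero_error = TRUE` and no p-value.
#'
#' @param table a tidy statistics table.
#' @param parameter,object the cell to analyse.
#' @param n_boot bootstrap resamples for the GES CI (default 2000).
#' @param boot_seed seed for the bootstrap.
#' @return A one-row data frame with the decomposition, F, df, p, GES and
#'   its CI, plus attribute `"dropped"` listing incomplete replicates.
#' @export
rm_anova <- function(table, parameter, object, n_boot = 2000L, boot_seed = 1L) {
  rm <- .rm_matrix(table, parameter, object)
  m <- rm$complete
  if (ncol(m) < 2L)
    .exclude("missing timepoint",
             sprintf("parameter '%s', object '%s': fewer than 2 timepoints",
                     parameter, object))
  if (nrow(m) < 2L)
    .exclude("<2 replicates",
             sprintf("parameter '%s', object '%s': fewer than 2 complete replicates",
                     parameter, object))
  dec <- .ges_of(m)
  df_time <- ncol(m) - 1L
  df_err <- (nrow(m) - 1L) * (ncol(m) - 1L)
  ms_time <- dec$ss_time / df_time
  ms_err <- dec$ss_error / df_err
  zero_err <- ms_err <= 1e-12
  F <- if (zero_err) Inf else ms_time / ms_err
  p <- if (zero_err) NA_real_ else pf(F, df_time, df_err, lower.tail = FALSE)

  set.seed(as.integer(boot_seed))
  ges_bs <- replicate(n_boot, {
    idx <- sample.int(nrow(m), replace = TRUE)
    g <- .ges_of(m[idx, , drop = FALSE])
    g$ges
  })
  ges_bs <- ges_bs[is.finite(ges_bs)]
  ci <- if (length(ges_bs) > 0) quantile(ges_bs, c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)

  out <- data.frame(parameter = parameter, object = object,
                    F = F, df1 = df_time, df2 = df_err, p = p,
                    ges = dec$ges, ges_lo = ci[1], ges_hi = ci[2],
                    ss_subject = dec$ss_subject, ss_time = dec$ss_time,
                    ss_error = dec$ss_error,
                    n_subjects = nrow(m), n_times = ncol(m),
                    zero_error = zero_err, stringsAsFactors = FALSE)
  attr(out, "dropped") <- rm$dropped
  out
}

#' Paired t-tests between timepoints with Cohen's dz and BH correction
#'
#' Paired t-test per time pair on the replicates observed at both
#' timepoints; Cohen's dz = mean(diff)/SD(diff); Benjamini-Hochberg
#' adjustment across the family of time pairs of this
#' (parameter, object) cell. Pairs with zero difference SD are flagged
#' `zero_variance` and get no p-value (they are kept out of the BH
#' family).
#'
#' @inheritParams rm_anova
#' @return A data frame: time_a, time_b, mean_diff, t, p, p_adj,
#'   cohens_dz, zero_variance, significant.
#' @export
paired_tests <- function(table, parameter, object) {
  rm <- .rm_matrix(table, parameter, object)
  m <- rm$full
  if (ncol(m) < 2L)
    .exclude("missing timepoint",
             sprintf("parameter '%s', object '%s': fewer than 2 timepoints",
                     parameter, object))
  times <- colnames(m)
  pairs <- utils::combn(times, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- m[, pairs[1, i]]; y <- m[, pairs[2, i]]
    ok <- !is.na(x) & !is.na(y)
    d <- (y - x)[ok]
    if (length(d) < 2L)
      return(data.frame(time_a = pairs[1, i], time_b = pairs[2, i],
                        mean_diff = NA_real_, t = NA_real_, p = NA_real_,
                        cohens_dz = NA_real_, zero_variance = FALSE,
                        insufficient = TRUE, stringsAsFactors = FALSE))
    if (sd(d) < 1e-12)
      return(data.frame(time_a = pairs[1, i], time_b = pairs[2, i],
                        mean_diff = mean(d), t = NA_real_, p = NA_real_,
                        cohens_dz = NA_real_, zero_variance = TRUE,
                        insufficient = FALSE, stringsAsFactors = FALSE))
    tt <- t.test(y[ok], x[ok], paired = TRUE)
    data.frame(time_a = pairs[1, i], time_b = pairs[2, i],
               mean_diff = mean(d), t = unname(tt$statistic),
               p = tt$p.value, cohens_dz = mean(d) / sd(d),
               zero_variance = FALSE, insufficient = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  testable <- !is.na(out$p)
  out$p_adj[testable] <- p.adjust(out$p[testable], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out$parameter <- parameter
  out$object <- object
  out[, c("parameter", "object", "time_a", "time_b", "mean_diff", "t", "p",
          "p_adj", "cohens_dz", "zero_variance", "significant")]
}

# raise a typed exclusion condition the pipeline catches and logs
.exclude <- function(reason, message) {
  cond <- structure(class = c("flowintern_exclusion", "error", "condition"),
                    list(message = message, call = sys.call(-1),
                         reason = reason))
  stop(cond)
}

#' Screen a tidy table for units excludable from comparative analysis
#'
#' Applies the comparative-test preconditions before any test is run:
#' objects with fewer than two replicates at a timepoint (between-group
#' analyses), zero-variance cells, objects with missing timepoints or
#' fewer than two complete replicates (within-object analyses).
#' Descriptive statistics are never affected.
#'
#' @param table a tidy statistics table.
#' @return A list with `log` (data frame: unit, parameter, context,
#'   reason) and `retained` (the table, untouched — exclusions apply to
#'   comparative outputs only).
#' @export
exclusion_screen <- function(table) {
  logs <- list()
  add <- function(unit, parameter, context, reason)
    logs[[length(logs) + 1L]] <<- data.frame(
      unit = unit, parameter = parameter, context = context, reason = reason,
      stringsAsFactors = FALSE)

  params <- unique(table$parameter)
  times <- if (is.factor(table$time)) levels(table$time)
           else unique(as.character(table$time))
  objects <- unique(table$object)

  for (p in params) {
    for (tm in times) {
      groups <- .groups_at(table, p, tm)
      small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
      for (u in small) add(u, p, paste0("time ", tm), "<2 replicates")
      big <- groups[vapply(groups, length, integer(1)) >= 2L]
      if (length(big) >= 2L) {
        if (all(vapply(big, function(v) var(v) == 0, logical(1))))
          add("(all groups)", p, paste0("time ", tm), "zero variance")
      } else {
        add("(family)", p, paste0("time ", tm), "insufficient data")
      }
    }
    for (ob in objects) {
      rm <- .rm_matrix(table, p, ob)
      if (ncol(rm$full) < length(times))
        add(ob, p, "time course", "missing timepoint")
      for (u in rm$dropped)
        add(paste0(ob, "_", u), p, "time course", "missing timepoint")
      if (nrow(rm$complete) < 2L)
        add(ob, p, "time course", "insufficient data")
    }
  }
  log <- if (length(logs)) do.call(rbind, logs)
         else data.frame(unit = character(), parameter = character(),
                         context = character(), reason = character(),
                         stringsAsFactors = FALSE)
  list(log = log, retained = table)
}

#' Run the full statistics pipeline on a tidy table
#'
#' Descriptive statistics, one-way ANOVA + Tukey + omega^2 + Cohen's d per
#' (parameter, timepoint), RM-ANOVA + paired t-tests + GES + Cohen's dz
#' per (parameter, object), and an exclusion log. Cells failing the test
#' preconditions are skipped and logged rather than computed.
#'
#' @param table a tidy statistics table (see [read_reports()]).
#' @param boot_seed seed for the GES bootstrap CIs.
#' @return An object of class `stats_results`: a list with
#'   `descriptives`, `anova`, `tukey`, `rm_anova`, `paired`, `exclusions`
#'   and the input `table`.
#' @export
run_stats <- function(table, boot_seed = 1L) {
  screen <- exclusion_screen(table)
  params <- unique(table$parameter)
  times <- if (is.factor(table$time)) levels(droplevels(table$time))
           else unique(as.character(table$time))
  objects <- unique(table$object)

  an <- list(); tk <- list(); rml <- list(); prl <- list()
  extra <- list()
  note <- function(unit, p, ctx, reason)
    extra[[length(extra) + 1L]] <<- data.frame(
      unit = unit, parameter = p, context = ctx, reason = reason,
      stringsAsFactors = FALSE)

  for (p in params) {
    for (tm in times) {
      res <- tryCatch(list(a = oneway_anova(table, p, tm),
                           t = tukey_pairwise(table, p, tm)),
                      flowintern_exclusion = function(e) e)
      if (inherits(res, "condition")) next  # already captured by the screen
      an[[length(an) + 1L]] <- res$a
      tk[[length(tk) + 1L]] <- res$t
    }
    for (ob in objects) {
      res <- tryCatch(list(r = rm_anova(table, p, ob, boot_seed = boot_seed),
                           pt = paired_tests(table, p, ob)),
                      flowintern_exclusion = function(e) e)
      if (inherits(res, "condition")) next
      rml[[length(rml) + 1L]] <- res$r
      prl[[length(prl) + 1L]] <- res$pt
    }
  }
  bindf <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(list(
    descriptives = descriptive_stats(table),
    anova = bindf(an), tukey = bindf(tk),
    rm_anova = bindf(rml), paired = bindf(prl),
    exclusions = screen$log, table = table,
    boot_seed = boot_seed), class = "stats_results")
}

#' @export
print.stats_results <- function(x, ...) {
  cat("<stats_results>\n")
  cat("  descriptive cells:", nrow(x$descriptives), "\n")
  cat("  ANOVA cells:      ", if (is.null(x$anova)) 0 else nrow(x$anova), "\n")
  cat("  RM-ANOVA cells:   ", if (is.null(x$rm_anova)) 0 else nrow(x$rm_anova), "\n")
  cat("  exclusions:       ", nrow(x$exclusions), "\n")
  invisible(x)
}

#' Export analysis results
#'
#' Writes the four result sections — descriptive statistics, ANOVA &
#' Tukey, RM-ANOVA & t-tests, excluded tubes/samples — as CSV files in
#' `dir`, plus a raw mirror of the tidy input table
#' (`Results_raw.csv`). Numeric fields are written at full precision so a
#' read-back reproduces every number exactly, and output is byte-stable
#' across reruns.
#'
#' @param results a [run_stats()] object.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
export_results <- function(results, dir) {
  if (!inherits(results, "stats_results"))
    stop("export_results expects a stats_results object")
  if (is.null(results$descriptives) || nrow(results$descriptives) == 0L)
    stop("export_results: empty results")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  prep <- function(df) {
    for (nm in names(df)) {
      if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
        df[[nm]] <- .fmt_num(df[[nm]])
      if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
    }
    df
  }
  merge_sections <- function(a, b, type_a, type_b) {
    if (is.null(a) && is.null(b)) return(NULL)
    a2 <- if (!is.null(a)) cbind(row_type = type_a, prep(a)) else NULL
    b2 <- if (!is.null(b)) cbind(row_type = type_b, prep(b)) else NULL
    if (is.null(a2)) return(b2)
    if (is.null(b2)) return(a2)
    all_cols <- union(names(a2), names(b2))
    for (nm in setdiff(all_cols, names(a2))) a2[[nm]] <- ""
    for (nm in setdiff(all_cols, names(b2))) b2[[nm]] <- ""
    rbind(a2[all_cols], b2[all_cols])
  }

  files <- c(
    descriptive = file.path(dir, "Results_descriptive.csv"),
    anova_tukey = file.path(dir, "Results_anova_tukey.csv"),
    rm_ttests = file.path(dir, "Results_rmanova_ttests.csv"),
    excluded = file.path(dir, "Results_excluded.csv"),
    raw = file.path(dir, "Results_raw.csv")
  )
  write.csv(prep(results$descriptives), files["descriptive"], row.names = FALSE)
  at <- merge_sections(results$anova, results$tukey, "anova", "tukey")
  if (!is.null(at)) write.csv(at, files["anova_tukey"], row.names = FALSE)
  rt <- merge_sections(results$rm_anova, results$paired, "rm_anova", "paired_t")
  if (!is.null(rt)) write.csv(rt, files["rm_ttests"], row.names = FALSE)
  write.csv(results$exclusions, files["excluded"], row.names = FALSE)
  write.csv(prep(results$table), files["raw"], row.names = FALSE)
  invisible(files)
}

#' Dot plot of means with SD whiskers
#'
#' Mode `"by_object"` shows each object's time course (one panel per
#' parameter); mode `"by_time"` shows all objects side by side at each
#' timepoint. Dots are means; whiskers span one SD (absent when n = 1).
#'
#' @param table a tidy statistics table.
#' @param mode `"by_object"` or `"by_time"`.
#' @param path optional PNG path; when given the plot is written there.
#' @param width,height,dpi PNG geometry.
#' @return The ggplot object, invisibly.
#' @export
plot_summary <- function(table, mode = c("by_object", "by_time"), path = NULL,
                         width = 7, height = 5, dpi = 150) {
  mode <- match.arg(mode)
  if (nrow(table) == 0L) stop("plot_summary: empty table")
  des <- descriptive_stats(table)
  des$time <- factor(des$time, levels = unique(des$time))
  lo <- ifelse(is.na(des$sd), des$mean, des$mean - des$sd)
  hi <- ifelse(is.na(des$sd), des$mean, des$mean + des$sd)
  des$lo <- lo; des$hi <- hi
  p <- if (mode == "by_object") {
    ggplot2::ggplot(des, ggplot2::aes(x = time, y = mean,
                                      colour = object,
                                      group = object)) +
      ggplot2::geom_line(alpha = 0.5) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi),
                             width = 0.15) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "incubation time", y = "mean ± SD")
  } else {
    ggplot2::ggplot(des, ggplot2::aes(x = object, y = mean,
                                      colour = object)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi),
                             width = 0.15) +
      ggplot2::facet_grid(parameter ~ time, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "mean ± SD") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
  p <- p + ggplot2::theme_bw()
  if (!is.null(path))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi,
                    device = grDevices::png, type = "cairo")
  invisible(p)
}
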