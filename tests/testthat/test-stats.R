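# build a tidy table directly
tidy_tab <- function(values, objects, replicates, times, parameter = "y") {
  data.frame(object = objects, replicate = replicates, time = times,
             parameter = parameter, value = values, stringsAsFactors = FALSE)
}

# three-group toy design with a hand-computed decomposition:
# SSB = 42, SSW = 6, F = 21, omega^2 = 40/49
toy_anova_tab <- function() {
  tidy_tab(c(1, 2, 3, 2, 3, 4, 6, 7, 8),
           rep(c("A", "B", "C"), each = 3),
           rep(1:3, 3), "t1")
}

test_that("file-name parsing follows the last-underscore rule", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.txt")
  writeLines(c("File\tCount\tScore",
               "3'LNA_1.daf\t100\t5.5",
               "A_B_2.daf\t200\t6.5",
               "plain_10.daf\t300\tnot_a_number"), path)
  tab <- parse_report(path, "1h")
  expect_setequal(unique(tab$object), c("3'LNA", "A_B", "plain"))
  expect_setequal(tab$replicate[tab$parameter == "Count"], c(1L, 2L, 10L))
  # non-numeric cells become missing
  expect_true(is.na(tab$value[tab$object == "plain" & tab$parameter == "Score"]))

  writeLines(c("File\tCount", "nosuffix.daf\t1"), path)
  expect_error(parse_report(path, "1h"), "_<integer> suffix")
  writeLines(c("Wrong\tCount", "x_1.daf\t1"), path)
  expect_error(parse_report(path, "1h"), "File")
})

test_that("parser skips preamble lines before the header", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.txt")
  writeLines(c("statistics report", "generated 2026-01-01", "",
               "File\tCount", "Int_1.daf\t42"), path)
  tab <- parse_report(path, "4h")
  expect_equal(tab$value[tab$parameter == "Count"], 42)
})

test_that("descriptive statistics use the sample SD convention", {
  tab <- tidy_tab(c(2, 4, 5, 5, 5, 7), rep(c("A", "B"), each = 3),
                  rep(1:3, 2), "t1")
  d <- descriptive_stats(tab)
  expect_equal(d$mean[d$object == "A"], 11 / 3)
  expect_equal(d$sd[d$object == "B"], sd(c(5, 5, 7)))
  dc <- descriptive_stats(tidy_tab(c(5, 5, 5), "A", 1:3, "t1"))
  expect_equal(dc$sd, 0)
  d1 <- descriptive_stats(tidy_tab(7, "A", 1, "t1"))
  expect_true(is.na(d1$sd))
  expect_equal(d1$n, 1)
})

test_that("one-way ANOVA reproduces the hand-computed toy design", {
  a <- oneway_anova(toy_anova_tab(), "y", "t1")
  expect_equal(a$F, 21, tolerance = 1e-9)
  expect_equal(a$omega_sq, 40 / 49, tolerance = 1e-9)
  expect_equal(a$df1, 2L)
  expect_equal(a$df2, 6L)
  expect_true(a$omega_lo >= 0 && a$omega_hi <= 1 && a$omega_lo <= a$omega_hi)

  # two identical groups: F = 0 and omega^2 <= 0 reported as computed
  tab0 <- tidy_tab(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3),
                   rep(1:3, 2), "t1")
  a0 <- oneway_anova(tab0, "y", "t1")
  expect_equal(a0$F, 0)
  expect_lte(a0$omega_sq, 0)

  # one group only: exclusion condition
  expect_error(oneway_anova(tidy_tab(1:3, "A", 1:3, "t1"), "y", "t1"),
               class = "flowintern_exclusion")
  # all-constant groups: zero variance
  expect_error(oneway_anova(tidy_tab(rep(c(1, 2), each = 3),
                                     rep(c("A", "B"), each = 3),
                                     rep(1:3, 2), "t1"), "y", "t1"),
               class = "flowintern_exclusion")
})

test_that("Tukey pairs, Cohen's d and BH behave on hand cases", {
  tab <- tidy_tab(c(1, 2, 3, 3, 4, 5), rep(c("A", "B"), each = 3),
                  rep(1:3, 2), "t1")
  tk <- tukey_pairwise(tab, "y", "t1")
  expect_equal(tk$cohens_d, 2.0, tolerance = 1e-12)  # pooled SD = 1, diff = 2

  tab3 <- toy_anova_tab()
  tk3 <- tukey_pairwise(tab3, "y", "t1")
  expect_equal(nrow(tk3), 3)
  # identical groups give d = 0
  tab_id <- tidy_tab(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3),
                     rep(1:3, 2), "t1")
  expect_equal(tukey_pairwise(tab_id, "y", "t1")$cohens_d, 0)

  # BH step-up on the canonical p-vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("F, Tukey p and omega^2 agree with base-R aov/TukeyHSD oracles", {
  set.seed(2024)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    n_per <- sample(3:6, k, replace = TRUE)
    mus <- rnorm(k, 0, 2)
    vals <- unlist(lapply(seq_len(k), function(j) rnorm(n_per[j], mus[j], 1)))
    obj <- rep(LETTERS[seq_len(k)], n_per)
    tab <- tidy_tab(vals, obj, unlist(lapply(n_per, seq_len)), "t1")

    a <- oneway_anova(tab, "y", "t1")
    fit <- aov(value ~ object, data = tab)
    s <- summary(fit)[[1]]
    expect_equal(a$F, s[["F value"]][1], tolerance = 1e-6)
    expect_equal(a$p, s[["Pr(>F)"]][1], tolerance = 1e-6)

    # independent omega^2 route through the aov table
    ssb <- s[["Sum Sq"]][1]; ssw <- s[["Sum Sq"]][2]
    msw <- s[["Mean Sq"]][2]
    omega_oracle <- (ssb - s[["Df"]][1] * msw) / (ssb + ssw + msw)
    expect_equal(a$omega_sq, omega_oracle, tolerance = 1e-6)

    tk <- tukey_pairwise(tab, "y", "t1")
    th <- as.data.frame(TukeyHSD(fit)$object)
    key <- paste(tk$group_b, tk$group_a, sep = "-")
    expect_equal(tk$tukey_p, th[key, "p adj"], tolerance = 1e-6)
    expect_equal(tk$mean_diff, th[key, "diff"], tolerance = 1e-9)
  }
})

test_that("RM-ANOVA reproduces the hand decomposition and aov oracle", {
  # subjects x times [[1,2,3],[2,3,4],[3,4,5]]:
  # SS_time = 6, SS_subject = 6, SS_error = 0, GES = 0.5, F infinite
  tab <- tidy_tab(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  "A", rep(1:3, each = 3),
                  rep(c("t1", "t2", "t3"), 3))
  r <- rm_anova(tab, "y", "A", n_boot = 200)
  expect_equal(r$ss_time, 6, tolerance = 1e-9)
  expect_equal(r$ss_subject, 6, tolerance = 1e-9)
  expect_equal(r$ss_error, 0, tolerance = 1e-9)
  expect_equal(r$ges, 0.5, tolerance = 1e-9)
  expect_true(is.infinite(r$F))
  expect_true(r$zero_error)

  # randomized designs against the aov Error-stratum oracle
  set.seed(11)
  for (i in 1:10) {
    ns <- sample(3:6, 1); nt <- sample(2:4, 1)
    vals <- rnorm(ns * nt, rep(rnorm(nt, 0, 1), each = ns), 1) +
      rep(rnorm(ns, 0, 0.5), nt)
    tab <- tidy_tab(vals, "A", rep(seq_len(ns), nt),
                    rep(paste0("t", seq_len(nt)), each = ns))
    r <- rm_anova(tab, "y", "A", n_boot = 50)
    fit <- aov(value ~ time + Error(factor(replicate)),
               data = transform(tab, time = factor(time)))
    s <- summary(fit)[["Error: Within"]][[1]]
    expect_equal(r$F, s[["F value"]][1], tolerance = 1e-6)
    expect_equal(r$p, s[["Pr(>F)"]][1], tolerance = 1e-6)
    ss_sub <- summary(fit)[["Error: factor(replicate)"]][[1]][["Sum Sq"]]
    ges_oracle <- s[["Sum Sq"]][1] / (s[["Sum Sq"]][1] + s[["Sum Sq"]][2] + ss_sub)
    expect_equal(r$ges, ges_oracle, tolerance = 1e-6)
  }
})

test_that("RM-ANOVA invariances and exclusions hold", {
  tab <- tidy_tab(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  "A", rep(1:3, each = 3),
                  rep(c("t1", "t2", "t3"), 3))
  # shuffling subject labels leaves SS_time unchanged
  tab2 <- tab; tab2$replicate <- c(2, 3, 1)[tab$replicate]
  expect_equal(rm_anova(tab, "y", "A", n_boot = 50)$ss_time,
               rm_anova(tab2, "y", "A", n_boot = 50)$ss_time)

  # one timepoint: excluded
  expect_error(rm_anova(tidy_tab(1:3, "A", 1:3, "t1"), "y", "A"),
               class = "flowintern_exclusion")
  # incomplete replicates are dropped and reported
  tab3 <- tab[-1, ]  # replicate 1 missing at t1
  r3 <- rm_anova(tab3, "y", "A", n_boot = 50)
  expect_equal(attr(r3, "dropped"), "1")
  expect_equal(r3$n_subjects, 2)
  # the bootstrap CI is deterministic under a fixed seed
  a <- rm_anova(tab, "y", "A", n_boot = 200, boot_seed = 5)
  b <- rm_anova(tab, "y", "A", n_boot = 200, boot_seed = 5)
  expect_identical(a$ges_lo, b$ges_lo)
})

test_that("paired t-tests give dz = 2 on the toy diffs and handle edge cases", {
  # diffs {1,2,3}: dz = 2
  tab <- tidy_tab(c(1, 2, 3, 2, 4, 6), "A", rep(1:3, 2),
                  rep(c("t1", "t2"), each = 3))
  pt <- paired_tests(tab, "y", "A")
  expect_equal(pt$cohens_dz, 2.0, tolerance = 1e-12)
  expect_equal(pt$p_adj, pt$p)  # single pair: BH leaves p unchanged
  # oracle: base t.test
  tt <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(pt$p, tt$p.value, tolerance = 1e-12)

  # constant diffs: zero-variance exclusion, no p
  tabz <- tidy_tab(c(1, 2, 3, 2, 3, 4), "A", rep(1:3, 2),
                   rep(c("t1", "t2"), each = 3))
  ptz <- paired_tests(tabz, "y", "A")
  expect_true(ptz$zero_variance)
  expect_true(is.na(ptz$p))
})

test_that("BH adjustment is monotone and bounded across a real family", {
  set.seed(5)
  tab <- tidy_tab(rnorm(12, rep(c(0, 1, 3, 2), each = 3), 1),
                  "A", rep(1:3, 4),
                  rep(c("t1", "t2", "t3", "t4"), each = 3))
  pt <- paired_tests(tab, "y", "A")
  expect_false(any(is.na(pt$p)))
  ord <- order(pt$p)
  expect_true(all(diff(pt$p_adj[ord]) >= -1e-12))
  expect_true(all(pt$p_adj <= 1))
  expect_true(all(pt$p_adj >= pt$p))
})

test_that("exclusion screen flags the replicate-minima rules", {
  # object B has one replicate at t1
  tab <- rbind(tidy_tab(c(1, 2, 3), "A", 1:3, "t1"),
               tidy_tab(5, "B", 1, "t1"))
  sc <- exclusion_screen(tab)
  expect_true(any(sc$log$unit == "B" & sc$log$reason == "<2 replicates"))
  # descriptives keep the excluded unit
  d <- descriptive_stats(sc$retained)
  expect_true("B" %in% d$object)

  # all-constant groups: zero variance
  tabz <- tidy_tab(rep(c(1, 2), each = 3), rep(c("A", "B"), each = 3),
                   rep(1:3, 2), "t1")
  scz <- exclusion_screen(tabz)
  expect_true(any(scz$log$reason == "zero variance"))

  # a fully complete two-object, two-time design: no exclusions
  full <- rbind(
    tidy_tab(c(1, 2, 3, 2, 3, 5), rep(c("A", "B"), each = 3), rep(1:3, 2), "t1"),
    tidy_tab(c(2, 3, 5, 3, 5, 6), rep(c("A", "B"), each = 3), rep(1:3, 2), "t2"))
  scf <- exclusion_screen(full)
  expect_equal(nrow(scf$log), 0)
})

test_that("the full analysis exports and round-trips through CSV", {
  dir <- withr::local_tempdir()
  set.seed(3)
  objs <- rep(c("PS", "PS_LNA"), each = 9)
  times <- rep(rep(c("1h", "4h", "12h"), each = 3), 2)
  reps <- rep(1:3, 6)
  vals <- rnorm(18, rep(c(50, 70, 90, 40, 50, 60), each = 3), 5)
  tab <- data.frame(object = objs, replicate = reps,
                    time = factor(times, levels = c("1h", "4h", "12h"),
                                  ordered = TRUE),
                    parameter = "Internalized_Pct", value = vals,
                    stringsAsFactors = FALSE)
  res <- run_stats(tab, boot_seed = 2)
  expect_s3_class(res, "stats_results")
  expect_equal(nrow(res$anova), 3)     # one per timepoint
  expect_equal(nrow(res$rm_anova), 2)  # one per object

  files <- export_results(res, dir)
  expect_true(all(file.exists(files)))
  # the four section files mirror the analysis tabs
  expect_setequal(names(files),
                  c("descriptive", "anova_tukey", "rm_ttests", "excluded", "raw"))
  # raw mirror round-trips exactly
  raw <- read.csv(files["raw"])
  expect_identical(raw$value, tab$value)
  desc <- read.csv(files["descriptive"])
  expect_identical(sort(desc$mean), sort(res$descriptives$mean))
  # byte-stable across reruns
  first <- readLines(files["anova_tukey"])
  export_results(res, dir)
  expect_identical(readLines(files["anova_tukey"]), first)

  expect_error(export_results(list(), dir), "stats_results")
})

test_that("summary dot plots are written as readable PNGs", {
  dir <- withr::local_tempdir()
  tab <- rbind(
    tidy_tab(c(1, 2, 3, 4, 5, 6), "A", rep(1:3, 2),
             rep(c("1h", "4h"), each = 3)),
    tidy_tab(7, "B", 1, "1h"))  # n = 1: dot without whisker
  p1 <- file.path(dir, "by_object.png")
  p2 <- file.path(dir, "by_time.png")
  plot_summary(tab, "by_object", p1)
  plot_summary(tab, "by_time", p2)
  expect_true(file.exists(p1) && file.size(p1) > 1000)
  img <- png::readPNG(p2)
  expect_gte(length(dim(img)), 2)
})
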