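# synthetic lesion-level ROI table with a known longitudinal structure:
# rise at scan II, fall at scan III, no change in the healthy region
fake_roi_stats <- function(n_lesions = 8, seed = 1, drop_scan3 = integer(0)) {
  set.seed(seed)
  rows <- list()
  for (l in seq_len(n_lesions)) {
    base <- rnorm(1, 60, 4)
    for (s in c("I", "II", "III")) {
      eff <- switch(s, I = 0, II = 6, III = -3)
      rows[[length(rows) + 1]] <- data.frame(
        lesion = l, roi = "18Gy", scan = s,
        mean_tsc = base + eff + rnorm(1, 0, 1), flag_missing = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        lesion = l, roi = "HR", scan = s,
        mean_tsc = 45 + rnorm(1, 0, 1), flag_missing = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # drop AFTER generation so the remaining values are unchanged
  out[!(out$scan == "III" & out$lesion %in% drop_scan3), ]
}

test_that("longitudinal aggregation reports the rise-then-fall arrow pattern", {
  rs <- fake_roi_stats()
  an <- analyze_roi_stats(rs)
  t2 <- an$table2[an$table2$region == "18Gy", ]
  expect_equal(t2$dir_I_II, "\u2191")
  expect_equal(t2$dir_I_III, "\u2193")
  expect_equal(t2$dir_II_III, "\u2193")
  expect_lt(t2$p_I_II, 0.05)
  hr <- an$table2[an$table2$region == "HR", ]
  expect_gt(hr$p_I_II, 0.05)
})

test_that("removing a lesion's scan III changes only scan-III comparisons", {
  full <- analyze_roi_stats(fake_roi_stats())
  part <- analyze_roi_stats(fake_roi_stats(drop_scan3 = c(3, 5)))
  f2 <- full$table2[full$table2$region == "18Gy", ]
  p2 <- part$table2[part$table2$region == "18Gy", ]
  expect_equal(p2$p_I_II, f2$p_I_II)
  expect_equal(p2$scan1_mean, f2$scan1_mean)
  expect_equal(part$comparisons[["18Gy I_III"]]$n, 6L)
  expect_equal(part$comparisons[["18Gy I_II"]]$n, 8L)
  expect_false(isTRUE(all.equal(p2$p_I_III, f2$p_I_III)))
})

test_that("study configuration round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_lesions: 3", "noise_sd: 0.1", "seed: 9",
               "registration: 'true'",
               "tsc_params:", "  acute_alpha: 0.5"), f)
  cfg <- read_study_config(f)
  expect_equal(cfg$n_lesions, 3L)
  expect_equal(cfg$tsc_params$acute_alpha, 0.5)
  expect_equal(cfg$registration, "true")
  writeLines("bogus_key: 1", f)
  expect_error(read_study_config(f), "unknown study config keys")
})

test_that("a seeded lesion simulation is reproducible end to end", {
  cfg <- study_config(n_lesions = 1, grid_shape = c(96, 96, 96),
                      voxel_size_mm = 4 / 3, noise_sd = 0.25,
                      registration = "true", seed = 21)
  a <- suppressMessages(simulate_lesion_study(cfg, 1, scans = c("I", "II")))
  b <- suppressMessages(simulate_lesion_study(cfg, 1, scans = c("I", "II")))
  expect_identical(a$stats$mean_tsc, b$stats$mean_tsc)
  expect_identical(a$stats$n_voxels, b$stats$n_voxels)
  # scan II shell means exceed scan I in the irradiated rings
  sh18 <- a$stats[a$stats$roi %in% c("8Gy", "12Gy"), ]
  expect_true(all(sh18$mean_tsc[sh18$scan == "II"] >
                    sh18$mean_tsc[sh18$scan == "I"]))
})

test_that("acute dose-response slope is recovered from shell-mean differences", {
  les <- fx_fine_study()      # noise-free, 1 mm reference, true transforms
  st <- les$stats
  ok <- names(les$dose_by_shell)[is.finite(les$dose_by_shell)]
  d <- les$dose_by_shell[ok]
  diff2 <- vapply(ok, function(rg)
    st$mean_tsc[st$roi == rg & st$scan == "II"] -
      st$mean_tsc[st$roi == rg & st$scan == "I"], numeric(1))
  alpha_hat <- unname(coef(lm(diff2 ~ d))[2])
  expect_lt(abs(alpha_hat / 0.35 - 1), 0.25)
})
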