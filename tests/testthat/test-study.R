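# Configuration validation and the end-to-end study driver.

fast_config <- function(master_seed = 11) {
  cfg <- default_study_config()
  cfg$master_seed <- master_seed
  cfg$grid_shape <- c(16, 16, 8)
  cfg$n_subjects <- 2L
  cfg$rescan_subjects <- 1L
  cfg$modalities <- "T2"
  cfg$fit_pipelines <- list(lm = list(optimizer = "LEAST_SQUARES_LM"))
  cfg$atlas_sets <- list(a = list(n_atlases = 3, perturb_magnitude = 0.5),
                         b = list(n_atlases = 4, perturb_magnitude = 0.5))
  cfg
}

test_that("config validation fills defaults and reports offending keys", {
  cfg <- validate_config(list(master_seed = 1))
  expect_s3_class(cfg, "study_config")
  expect_length(cfg$ir_protocol$times_ms, 7L)
  expect_equal(cfg$me_protocol$times_ms, seq(8, 224, by = 8))

  expect_error(validate_config(list()), "master_seed")
  bad <- list(master_seed = 1,
              centers = list(C1 = list(gain = -2)))
  expect_error(validate_config(bad), "centers.C1")
  tr <- relaxomap:::region_truth_defaults()
  tr$t2_ms[tr$region_name == "Hippocampus L"] <- 400
  expect_error(validate_config(list(master_seed = 1, region_truth = tr)),
               "Hippocampus L")
  # YAML round trip
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(master_seed = 3, n_subjects = 1), f)
  cfg2 <- validate_config(f)
  expect_equal(cfg2$master_seed, 3L)
  expect_equal(cfg2$n_subjects, 1L)
})

test_that("derived seeds are stable, distinct and in integer range", {
  s1 <- derive_seed(7, "subject", 1, "center", "C1")
  expect_identical(s1, derive_seed(7, "subject", 1, "center", "C1"))
  expect_false(s1 == derive_seed(7, "subject", 2, "center", "C1"))
  expect_false(s1 == derive_seed(8, "subject", 1, "center", "C1"))
  seeds <- sapply(1:200, function(i) derive_seed(1, "x", i))
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("a small study runs end to end and emits every report", {
  out <- tempfile("study")
  b <- run_study(fast_config(), out)
  files <- c("region_stats.csv", "manifest.csv", "atlas_dice.csv",
             "parcel_volumes.csv", "intercenter_report.csv",
             "interatlas_report.csv", "scan_rescan.csv", "study_log.txt",
             "effective_config.yaml")
  for (f in files) expect_true(file.exists(file.path(out, f)), info = f)
  # 2 subjects x 2 centers x (2 + 1) scans x 1 pipeline x 2 sets x 29 regions
  expect_equal(nrow(b$region_stats), 2 * 3 * 1 * 2 * 29)
  expect_setequal(unique(b$region_stats$region_name), region_lut()$region_name)
  expect_equal(nrow(b$atlas_dice), 29L)
})

test_that("reruns with the same config are bit-identical", {
  o1 <- tempfile("s1"); o2 <- tempfile("s2")
  run_study(fast_config(), o1)
  run_study(fast_config(), o2)
  for (f in c("region_stats.csv", "intercenter_report.csv", "manifest.csv",
              "atlas_dice.csv", "scan_rescan.csv"))
    expect_identical(unname(tools::md5sum(file.path(o1, f))),
                     unname(tools::md5sum(file.path(o2, f))), info = f)
  o3 <- tempfile("s3")
  run_study(fast_config(master_seed = 12), o3)
  expect_false(identical(unname(tools::md5sum(file.path(o1, "region_stats.csv"))),
                         unname(tools::md5sum(file.path(o3, "region_stats.csv")))))
})

test_that("raising one center's noise raises the inter-center T2 error", {
  mpe_at <- function(sigma_b, seed) {
    cfg <- fast_config(master_seed = seed)
    cfg$n_subjects <- 1L
    cfg$rescan_subjects <- integer(0)
    cfg$atlas_sets <- list(a = list(n_atlases = 1, perturb_magnitude = 0))
    cfg$centers <- list(A = list(gain = 1, bias_field_amplitude = 0,
                                 noise_sigma = 10),
                        B = list(gain = 1, bias_field_amplitude = 0,
                                 noise_sigma = sigma_b))
    b <- run_study(cfg, tempfile("noise"))
    b$intercenter$mean_percent_error[b$intercenter$modality == "T2"]
  }
  sigmas <- c(10, 60, 150)
  curves <- sapply(1:5, function(seed) sapply(sigmas, mpe_at, seed = seed))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > 0))
})
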