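test_that("default configuration carries the study growth conditions", {
  cfg <- default_config()
  expect_equal(cfg$treatments[["S/D"]]$growth$specific_growth_rate, 0.19)
  expect_equal(cfg$treatments[["S/S"]]$growth$exponential_duration, 10.1)
  expect_equal(cfg$treatments[["D/S"]]$growth$specific_growth_rate, 0.11)
  f <- cfg$treatments[["D/S"]]$growth$die_off_fraction
  expect_gt(f, 0); expect_lt(f, 1)
  # inoculum is 30% of source water: 0.3 * 17.6e8 and 0.3 * 70e8
  expect_equal(cfg$treatments[["S/S"]]$growth$initial_abundance, 5.28e8)
  expect_equal(cfg$treatments[["D/S"]]$growth$initial_abundance, 21e8)
  # DOC starts at the conservative-mixing expectation
  expect_equal(cfg$treatments[["S/D"]]$doc$initial, 105.51)
})

test_that("identical (config, seed) pairs give identical bundles", {
  b1 <- generate_experiment(default_config(), seed = 5)
  b2 <- generate_experiment(default_config(), seed = 5)
  expect_identical(b1, b2)
  b3 <- generate_experiment(default_config(), seed = 6)
  expect_false(identical(b1$timeseries, b3$timeseries))
})

test_that("invalid configurations are rejected before generation", {
  cfg <- default_config()
  cfg$treatments[["S/D"]]$growth$specific_growth_rate <- -0.1
  expect_error(generate_experiment(cfg, seed = 1), "growth rate")
  cfg2 <- default_config()
  cfg2$treatments[["D/S"]]$growth$die_off_fraction <- 1.2
  expect_error(generate_experiment(cfg2, seed = 1), "die_off_fraction")
})

test_that("noiseless generation lets the growth stage recover the configured rate exactly", {
  b <- generate_experiment(default_config(noise_scale = 0), seed = 2)
  fits <- fit_growth(b$timeseries)
  expect_equal(unique(round(fits$mu[fits$treatment == "S/D"], 6)), 0.19)
})

test_that("DOC series are monotone non-increasing when the production pulse is disabled", {
  cfg <- default_config(noise_scale = 0)
  cfg$treatments[["D/S"]]$doc$production_pulse <- NULL
  b <- generate_experiment(cfg, seed = 3)
  doc <- dplyr::filter(b$timeseries, analyte == "DOC")
  for (key in split(doc, paste(doc$treatment, doc$bottle))) {
    expect_true(all(diff(key$value[order(key$time_days)]) <= 1e-9))
  }
  # with the pulse, D/S rises somewhere between days 9 and 12
  b2 <- generate_experiment(default_config(noise_scale = 0), seed = 3)
  ds <- dplyr::filter(b2$timeseries, analyte == "DOC", treatment == "D/S",
                      bottle == "E")
  ds <- ds[order(ds$time_days), ]
  expect_true(any(diff(ds$value) > 0))
})

test_that("zero-drift amino-acid profiles sit exactly at the reference composition", {
  cfg <- default_config(noise_scale = 0)
  for (code in names(cfg$treatments)) cfg$treatments[[code]]$aa$drift_rate <- 0
  b <- generate_experiment(cfg, seed = 4)
  di <- degradation_index(b$aa_profiles)
  expect_true(all(abs(di$di) < 1e-9))
})

test_that("generated qPCR standards lie on the configured line", {
  b <- generate_experiment(default_config(noise_scale = 0), seed = 5)
  std <- dplyr::filter(b$qpcr_plate, role == "standard", gene == "cbbL")
  fit <- lm(cq ~ log10(copies), data = std)
  expect_equal(unname(coef(fit)[2]), -2.93, tolerance = 1e-9)
  expect_equal(sort(unique(std$copies)), 10^(1:6))
})

test_that("ASV library sizes meet the rarefaction depth and the deep inoculum is Chlorobi-dominated", {
  b <- generate_experiment(default_config(), seed = 6)
  expect_true(all(rowSums(b$asv_counts) >=
                    default_config()$asv$library_min * 0 + 10000))
  d0 <- b$asv_counts["D/S_d0_r1", ]
  fam <- b$asv_taxonomy$family[match(names(d0), b$asv_taxonomy$asv)]
  frac <- sum(d0[fam == "Chlorobiaceae"]) / sum(d0)
  expect_gt(frac, 0.6)
  expect_equal(b$copy_map$copies[b$copy_map$taxon == "Chlorobiaceae"], 3)
})

test_that("median recovered mu stays within 10% of truth under up-to-5% noise", {
  truth <- c("S/S" = 0.03, "S/D" = 0.19, "D/S" = 0.11)
  res <- sapply(1:50, function(s) {
    cfg <- default_config(noise_scale = 0)
    cfg$noise$pa_sdlog <- 0.05
    b <- generate_experiment(cfg, seed = s)
    fits <- fit_growth(b$timeseries)
    sapply(names(truth), function(tr) mean(fits$mu[fits$treatment == tr]))
  })
  med <- apply(res, 1, stats::median)
  expect_true(all(abs(med - truth) / truth < 0.10))
})

test_that("bundles round-trip through the plain-text directory format", {
  b <- generate_experiment(default_config(), seed = 8)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_equal(back$timeseries, b$timeseries)
  expect_equal(back$asv_counts, b$asv_counts)
  expect_equal(names(back$feature_tables), sort(names(b$feature_tables)))
  expect_equal(back$manifest$seed, 8)
})
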