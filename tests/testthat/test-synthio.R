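test_that("bundles are byte-identical under a fixed seed", {
  b1 <- generate_survey(survey_config(seed = 42, n_species = 8))
  b2 <- generate_survey(survey_config(seed = 42, n_species = 8))
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  b3 <- generate_survey(survey_config(seed = 43, n_species = 8))
  expect_false(identical(b1$read_table$counts, b3$read_table$counts))
})

test_that("config invariants are enforced", {
  st <- default_stations()
  st$distance_m[1] <- 10 # no station at the reef
  expect_error(survey_config(stations = st), "distance 0")
  expect_error(survey_config(target_reads = 0), "target_reads")
  expect_error(survey_config(decay = -1), "decay")
})

test_that("zero noise and zero decay give station-symmetric expected reads", {
  cfg <- noiseless_config()
  b <- generate_survey(cfg)
  fish <- fish_counts(b$read_table)
  meta <- b$metadata[!b$metadata$is_control, ]
  fish <- fish[meta$sample_id, , drop = FALSE]
  for (layer in c("middle", "bottom")) {
    rows <- fish[meta$depth_layer == layer, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(x) length(unique(x)) == 1)))
  }
})

test_that("positive decay makes reef-associated concentrations fall with distance", {
  cfg <- survey_config(seed = 5, n_species = 10, sigma_bio = 0, decay = 0.4,
                       read_noise = "none")
  cfg$species$reef_assoc <- rep(c(1, 0), length.out = 10) # pin both kinds
  b <- generate_survey(cfg)
  meta <- b$metadata[!b$metadata$is_control, ]
  assoc <- cfg$species$species[cfg$species$reef_assoc == 1]
  for (spp in assoc) {
    bot <- meta$sample_id[meta$depth_layer == "bottom" & meta$replicate == 1]
    d <- meta$distance_m[match(bot, meta$sample_id)]
    # east and west stations share absolute distances: average per distance
    md <- tapply(b$truth$species[bot, spp], d, mean)
    expect_true(all(diff(md[order(as.numeric(names(md)))]) < 0))
  }
  # non-associated species are flat in distance
  flat <- cfg$species$species[cfg$species$reef_assoc == 0]
  bot <- meta$sample_id[meta$depth_layer == "bottom" & meta$replicate == 1]
  expect_equal(length(unique(round(b$truth$species[bot, flat[1]], 12))), 1)
})

test_that("fixed slope 10 reproduces the expected standard-read ladder", {
  cfg <- survey_config(seed = 9, n_species = 2, slope_meanlog = log(10),
                       slope_sdlog = 0, read_noise = "none")
  b <- generate_survey(cfg)
  std <- standard_counts(b$read_table)
  for (s in rownames(std)) {
    expect_equal(unname(std[s, paste0("Std", LETTERS[1:5])]),
                 c(1000, 500, 250, 125, 25))
  }
  # and under Poisson noise the across-sample means converge to the same ladder
  cfgp <- survey_config(seed = 9, n_species = 2, n_replicates = 20,
                        slope_meanlog = log(10), slope_sdlog = 0,
                        read_noise = "poisson")
  bp <- generate_survey(cfgp)
  stdp <- standard_counts(bp$read_table)
  n <- nrow(stdp)
  expected <- 10 * c(100, 50, 25, 12.5, 2.5)
  for (k in 1:5) {
    se <- sqrt(expected[k] / n)
    expect_lt(abs(mean(stdp[, k]) - expected[k]), 3 * se)
  }
})

test_that("standard totals scale linearly with the sample slope", {
  totals <- sapply(c(2, 5, 10, 20), function(sl) {
    cfg <- survey_config(seed = 3, n_species = 2, slope_meanlog = log(sl),
                         slope_sdlog = 0, read_noise = "none")
    sum(standard_counts(generate_survey(cfg)$read_table)[1, ])
  })
  # "none" mode rounds expected reads, so ratios are exact only to ~0.5 read
  expect_equal(totals / totals[1], c(2, 5, 10, 20) / 2, tolerance = 0.01)
})

test_that("empirical mean of reads/slope recovers the true extract concentration", {
  cfg <- survey_config(seed = 17, n_species = 3, n_replicates = 400,
                       stations = default_stations()[1, ], sigma_bio = 0,
                       slope_sdlog = 0, include_control = FALSE)
  b <- generate_survey(cfg)
  fish <- fish_counts(b$read_table)
  est <- fish / b$slopes[rownames(fish)]
  tru <- b$truth$copies_per_ul[rownames(fish), colnames(fish)]
  for (j in seq_len(ncol(fish))) {
    for (layer in c("middle", "bottom")) {
      rows <- b$metadata$sample_id[b$metadata$depth_layer == layer]
      dev <- est[rows, j] - tru[rows, j]
      se <- sd(dev) / sqrt(length(dev))
      expect_lt(abs(mean(dev)), 3 * se + 1e-12)
    }
  }
})

test_that("bundle pieces agree on ids and assignment coverage", {
  b <- generate_survey(small_config())
  field <- b$metadata$sample_id[!b$metadata$is_control]
  expect_setequal(rownames(b$truth$otu), field)
  expect_true(all(rownames(b$truth$otu) %in% rownames(b$read_table$counts)))
  fish_otus <- names(b$read_table$otu_class[b$read_table$otu_class == "fish"])
  expect_setequal(b$assignments$otu_id, fish_otus)
  expect_equal(anyDuplicated(b$assignments$otu_id), 0L)
  # control carries standards but no fish reads
  expect_equal(sum(fish_counts(b$read_table)["FNC", ]), 0)
  expect_gt(sum(standard_counts(b$read_table)["FNC", ]), 0)
})

test_that("multinomial read model hits the target depth exactly", {
  cfg <- survey_config(seed = 31, n_species = 6, read_noise = "multinomial",
                       target_reads = 50000)
  b <- generate_survey(cfg)
  expect_true(all(rowSums(b$read_table$counts) == 50000))
})

test_that("catch record has the requested rank structure and the congeneric pair", {
  b <- generate_survey(survey_config(seed = 13, n_species = 40))
  catch <- b$catch
  expect_equal(nrow(catch), 41)
  expect_equal(sum(catch$rank == "species"), 38)
  expect_equal(sum(catch$rank %in% c("genus", "family")), 3)
  expect_true(all(c("Ambigenus primus", "Ambigenus secundus") %in%
                    catch$classification))
  expect_true(all(catch$biomass_kg >= 0 & is.finite(catch$biomass_kg)))
  # zero species -> empty record
  empty <- generate_catch_record(matrix(0, 4, 0), survey_config(seed = 1),
                                 n_classifications = 0)
  expect_equal(nrow(empty), 0)
})

test_that("echograms respond to station fish density", {
  b <- generate_survey(small_config(seed = 77))
  es <- summarise_echograms(b$echograms, b$start_times)
  dens <- sapply(es$station_id, function(stn) {
    rows <- b$metadata$sample_id[b$metadata$station_id == stn &
                                   !b$metadata$is_control]
    mean(rowSums(b$truth$otu[rows, , drop = FALSE]))
  })
  expect_gt(cor(log(dens), log(es$mean_sv_linear)), 0.5)
})
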