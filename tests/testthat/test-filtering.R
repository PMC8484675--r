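test_that("assignment filters drop non-fish, low-identity and short alignments", {
  recs <- rbind(
    rec("a", identity = 98.5, len = 172),            # boundary identity: kept
    rec("b", identity = 99.9, len = 150),            # boundary length: dropped
    rec("c", identity = 100, group = "other"),       # non-fish: dropped
    rec("d", identity = 98.4, len = 172),            # below identity: dropped
    rec("e", identity = 99.0, len = 151),            # just long enough: kept
    rec("f", identity = 99.0, len = 172, group = "shark") # sharks stay
  )
  out <- apply_blast_filters(recs)
  expect_equal(out$kept, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$drop_reason[!out$kept], c("length", "non_fish", "identity"))
})

checklist <- regional_checklist(c(
  "Scomber japonicus", "Scomber australasicus", "Acanthopagrus schlegelii",
  "Pagrus major", "Parapristipoma trilineatum"
))

test_that("multi-species hits collapse to genus unless one congener is regional", {
  scomber <- collapse_assignments(
    rec(hits = "Scomber japonicus;Scomber australasicus"), checklist)
  expect_equal(scomber$label, "Scomber spp.")
  expect_equal(scomber$rank, "genus_spp")

  acantho <- collapse_assignments(
    rec(hits = "Acanthopagrus schlegelii;Acanthopagrus sivicolus"), checklist)
  expect_equal(acantho$label, "Acanthopagrus schlegelii")
  expect_equal(acantho$rank, "species")

  single <- collapse_assignments(rec(hits = "Pagrus major"), checklist)
  expect_equal(single$label, "Pagrus major")
  expect_equal(single$rank, "species")

  multi <- collapse_assignments(
    rec(hits = "Pagrus major;Scomber japonicus"), checklist)
  expect_equal(multi$rank, "higher")

  expect_warning(
    out <- collapse_assignments(rec(hits = "Ignotus piscis"), checklist),
    "checklist")
  expect_equal(out$label, "Ignotus piscis") # label kept, warning only
})

test_that("labels never invent species outside hits or checklist", {
  set.seed(401)
  pool <- c(checklist$Scomber, checklist$Pagrus, checklist$Acanthopagrus,
            "Acanthopagrus sivicolus")
  for (i in 1:25) {
    hits <- sample(pool, sample(1:3, 1))
    out <- suppressWarnings(
      collapse_assignments(rec(hits = paste(hits, collapse = ";")), checklist))
    if (out$rank == "species") {
      expect_true(out$label %in% c(hits, unlist(checklist)))
    }
  }
})

test_that("noise filter zeroes reads strictly below 0.05% of the sample total", {
  m <- rbind(s1 = c(OTU1 = 99900, OTU2 = 50, OTU3 = 49, OTU4 = 1,
                    StdA = 5000, StdB = 2500, StdC = 1250, StdD = 625,
                    StdE = 125))
  rt <- noise_filter(rt_from(m))
  expect_equal(unname(fish_counts(rt)[1, ]), c(99900, 50, 0, 0))
  expect_equal(unname(standard_counts(rt)[1, ]), c(5000, 2500, 1250, 625, 125))
  # all-zero fish sample is unchanged
  z <- rt_from(rbind(s1 = c(OTU1 = 0, StdA = 10, StdB = 5, StdC = 3,
                            StdD = 2, StdE = 1)))
  expect_identical(noise_filter(z)$counts, z$counts)
})

test_that("noise filter is idempotent, never increases counts, keeps ids", {
  set.seed(402)
  m <- matrix(rpois(6 * 30, 40), 6, 30,
              dimnames = list(paste0("s", 1:6), paste0("OTU", 1:30)))
  m[, 1] <- 1e5 # dominant OTU makes small counts sub-threshold
  rt <- rt_from(m, standard_ids = character())
  once <- noise_filter(rt)
  twice <- noise_filter(once)
  expect_identical(once$counts, twice$counts)
  expect_true(all(once$counts <= rt$counts))
  expect_identical(dimnames(once$counts), dimnames(rt$counts))
  # denominator option: including standards raises the cut
  m2 <- cbind(m, StdA = 2e5, StdB = 1e5, StdC = 5e4, StdD = 2.5e4, StdE = 5e3)
  rt2 <- rt_from(m2)
  with_std <- noise_filter(rt2, include_standards = TRUE)
  expect_true(sum(with_std$counts == 0) >= sum(noise_filter(rt2)$counts == 0))
})

test_that("contaminant blocklist removes whole OTUs and is safe when absent", {
  m <- rbind(s1 = c(OTU1 = 10, OTU2 = 20, StdA = 5, StdB = 3, StdC = 2,
                    StdD = 2, StdE = 1))
  labels <- data.frame(otu_id = c("OTU1", "OTU2"),
                       label = c("Oncorhynchus nerka", "Pagrus major"))
  out <- remove_contaminants(rt_from(m), labels)
  expect_false("OTU1" %in% colnames(out$counts))
  expect_true("OTU2" %in% colnames(out$counts))
  expect_identical(remove_contaminants(rt_from(m), labels, blocklist = character())$counts,
                   rt_from(m)$counts)
  expect_identical(remove_contaminants(rt_from(m), labels,
                                       blocklist = "Gadus chalcogrammus")$counts,
                   rt_from(m)$counts)
})

test_that("habitat classification looks up the map and defaults with warning", {
  labels <- data.frame(otu_id = c("o1", "o2"),
                       label = c("Pagrus major", "Scomber spp."))
  map <- c("Pagrus major" = "demersal", "Scomber spp." = "pelagic")
  expect_equal(classify_habitat(labels, map), c("demersal", "pelagic"))
  expect_warning(h <- classify_habitat(labels, map["Pagrus major"]),
                 "Scomber")
  expect_equal(h[2], "demersal")
  # demersal + pelagic totals partition the total fish copies
  b <- generate_survey(small_config())
  q <- quantify_table(b$read_table, b$standards, b$metadata)
  hab <- b$habitat_map[b$assignments$otu_id]
  names(hab) <- b$assignments$otu_id
  hab[is.na(hab)] <- "demersal"
  tot <- rowSums(q$copies_per_ml)
  dem <- rowSums(q$copies_per_ml[, hab[colnames(q$copies_per_ml)] == "demersal",
                                 drop = FALSE])
  pel <- rowSums(q$copies_per_ml[, hab[colnames(q$copies_per_ml)] == "pelagic",
                                 drop = FALSE])
  expect_equal(dem + pel, tot)
})

test_that("full preprocessing runs the stages in order with an audit trail", {
  b <- generate_survey(small_config())
  recs <- b$assignments
  victim <- "OTU003" # not the shared pair OTU
  recs$identity_pct[recs$otu_id == victim] <- 90 # force one identity drop
  out <- preprocess_reads(b$read_table, recs, b$checklist)
  expect_setequal(names(out), c("read_table", "labels", "audit",
                                "n_contaminants_removed"))
  expect_equal(out$audit$fate[out$audit$otu_id == victim], "identity")
  expect_false(victim %in% colnames(out$read_table$counts))
  expect_setequal(out$labels$otu_id,
                  colnames(fish_counts(out$read_table)))
  # the synthetic congeneric pair collapses to a genus label
  expect_true("Ambigenus spp." %in% out$labels$label)
})
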