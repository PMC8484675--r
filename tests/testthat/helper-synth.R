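# Small deterministic configurations used across tests.

# integer-friendly noiseless world: fixed slope 10, flat baselines, no decay,
# so expected reads are exact integers and quantification must round-trip.
noiseless_config <- function(seed = 11, n_species = 10) {
  cfg <- survey_config(seed = seed, n_species = n_species,
                       sigma_bio = 0, decay = 0,
                       slope_meanlog = log(10), slope_sdlog = 0,
                       read_noise = "none")
  cfg$species$baseline <- rep(0.5, nrow(cfg$species))
  cfg
}

small_config <- function(seed = 21, ...) {
  survey_config(seed = seed, n_species = 12, ...)
}

# one-row assignment record
rec <- function(otu_id = "OTU1", hits = "Pagrus major", identity = 99.5,
                len = 172, group = "bony_fish") {
  data.frame(otu_id = otu_id, hit_species = hits, identity_pct = identity,
             aln_length = len, taxon_group = group)
}

# read_table from a plain matrix, standards named Std*
rt_from <- function(m, standard_ids = grep("^Std", colnames(m), value = TRUE)) {
  read_table(m, standard_ids = standard_ids)
}
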