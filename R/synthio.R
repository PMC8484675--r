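#' Default station layout for a reef survey
#'
#' One focal high-rise reef at distance 0, a second reef found mid-survey at
#' 220 m, and six stations along the transect at 150/500/750 m on either
#' side. Distances are signed (east positive, west negative); models use the
#' absolute value.
#'
#' @return Data frame: `station_id`, `distance_m` (signed), `is_reef`.
#' @export
default_stations <- function() {
  data.frame(
    station_id = c("AR1", "AR2", "E150", "E500", "E750",
                   "W150", "W500", "W750"),
    distance_m = c(0, 220, 150, 500, 750, -150, -500, -750),
    is_reef = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Configuration for the synthetic survey generator
#'
#' Describes the world the generator emulates: a coastal survey of eight
#' stations x two depth layers x two replicates (32 samples) plus one field
#' negative control, each library spiked with a five-point internal-standard
#' ladder. Species concentrations decay with log distance from the focal
#' reef for reef-associated species, samples have individual amplification
#' slopes (log-normal, matching the strictly positive, sample-varying slopes
#' seen on real runs), and per-station echograms carry backscatter
#' proportional to summed fish density.
#'
#' The species pool (names, baseline concentrations, reef association, depth
#' preference, habitat) is drawn here, deterministically from `seed`, and
#' stored in the config. One congeneric species pair shares a single OTU to
#' emulate taxa the marker cannot separate.
#'
#' @param stations Station table as in [default_stations()]; exactly one
#'   station must sit at distance 0.
#' @param n_replicates Replicates per station x depth layer.
#' @param n_species Species-pool size.
#' @param baseline_meanlog,baseline_sdlog Log-normal hyperparameters of the
#'   per-species baseline concentration (copies/ml water).
#' @param prop_reef_associated Fraction of species with reef association 1
#'   (others 0).
#' @param decay Decay rate per unit log(distance + 0.1) for reef-associated
#'   species.
#' @param depth_pref_multiplier Concentration multiplier in a species'
#'   preferred layer; the other layer gets its reciprocal.
#' @param sigma_bio Log-normal sd of sample-level biological noise on
#'   concentrations (0 = deterministic concentrations).
#' @param slope_meanlog,slope_sdlog Log-normal parameters of the per-sample
#'   amplification slope (reads per copy/µl); `slope_sdlog = 0` fixes the
#'   slope at `exp(slope_meanlog)`.
#' @param target_reads Target total reads per sample; used directly by the
#'   multinomial read model (per-sample depth is not reported for the design
#'   emulated here, so the default ~65,000 is inferred from run totals).
#' @param read_noise `"poisson"` (independent per OTU, keeps the standards'
#'   linearity exact), `"multinomial"` (conditioned on `target_reads`,
#'   stresses compositional distortion) or `"none"` (expected reads, rounded).
#' @param echo_gain Linear S_V per (copy/ml) of summed fish concentration.
#' @param echo_noise_sd_db Cell-level dB noise on fish echoes.
#' @param echo_fill Fraction of cells containing fish echo (the rest sit at
#'   the background level, below any sensible threshold).
#' @param standards A [standard_spec()].
#' @param filtered_volume_ml,elution_volume_ul Water and elution volumes.
#' @param include_control Add one field negative control (standards spiked,
#'   no fish reads).
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @return A validated list of class `survey_config` (with `$species`, the
#'   generated species table).
#' @export
survey_config <- function(stations = default_stations(),
                          n_replicates = 2,
                          n_species = 40,
                          baseline_meanlog = log(0.8),
                          baseline_sdlog = 1,
                          prop_reef_associated = 0.6,
                          decay = 0.3,
                          depth_pref_multiplier = 2,
                          sigma_bio = 0.5,
                          slope_meanlog = log(15),
                          slope_sdlog = 0.5,
                          target_reads = 65000,
                          read_noise = c("poisson", "multinomial", "none"),
                          echo_gain = 2e-9,
                          echo_noise_sd_db = 2,
                          echo_fill = 0.3,
                          standards = standard_spec(),
                          filtered_volume_ml = 2000,
                          elution_volume_ul = 100,
                          include_control = TRUE,
                          seed = 1L) {
  read_noise <- match.arg(read_noise)
  if (sum(stations$distance_m == 0) != 1) {
    stop("exactly one station must sit at distance 0 (the focal reef)")
  }
  if (target_reads <= 0) stop("target_reads must be positive")
  if (slope_sdlog < 0 || sigma_bio < 0) stop("sd parameters must be >= 0")
  if (n_species < 0) stop("n_species must be >= 0")
  if (decay < 0) stop("decay must be >= 0")
  if (depth_pref_multiplier <= 0) stop("depth_pref_multiplier must be > 0")

  set.seed(seed)
  species <- if (n_species > 0) {
    name <- sprintf("Synthogenus%02d speciosus", seq_len(n_species))
    pref <- sample(c("bottom", "middle", "none"), n_species, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
    sp <- data.frame(
      species = name,
      otu_id = sprintf("OTU%03d", seq_len(n_species)),
      baseline = stats::rlnorm(n_species, baseline_meanlog, baseline_sdlog),
      reef_assoc = as.numeric(stats::runif(n_species) < prop_reef_associated),
      depth_pref = pref,
      habitat = ifelse(pref == "bottom", "demersal",
                       ifelse(pref == "middle", "pelagic",
                              sample(c("demersal", "pelagic"), n_species,
                                     replace = TRUE)))
    )
    if (n_species >= 2) {
      # congeneric pair indistinguishable at the marker: one shared OTU
      sp$species[1:2] <- c("Ambigenus primus", "Ambigenus secundus")
      sp$otu_id[2] <- sp$otu_id[1]
    }
    sp
  } else {
    data.frame(species = character(), otu_id = character(),
               baseline = numeric(), reef_assoc = numeric(),
               depth_pref = character(), habitat = character())
  }

  structure(
    list(stations = stations, n_replicates = n_replicates,
         n_species = n_species, species = species, decay = decay,
         depth_pref_multiplier = depth_pref_multiplier,
         sigma_bio = sigma_bio, slope_meanlog = slope_meanlog,
         slope_sdlog = slope_sdlog, target_reads = target_reads,
         read_noise = read_noise, echo_gain = echo_gain,
         echo_noise_sd_db = echo_noise_sd_db, echo_fill = echo_fill,
         standards = standards, filtered_volume_ml = filtered_volume_ml,
         elution_volume_ul = elution_volume_ul,
         include_control = include_control, seed = seed),
    class = "survey_config"
  )
}

# concentration multiplier for one species (scalar pref) across samples
.depth_multiplier <- function(pref, layer, m) {
  if (pref == "none") return(rep(1, length(layer)))
  ifelse(layer == pref, m, 1 / m)
}

#' Generate a complete synthetic survey bundle
#'
#' Draws, deterministically from the config seed: true per-sample species
#' concentrations mu (copies/ml) = baseline x exp(-decay x reef_assoc x
#' log(|distance| + 0.1)) x depth-preference multiplier x log-normal noise;
#' sequence reads r ~ Poisson(slope_s x copies/µl) for fish OTUs and
#' standards alike (copies/µl = copies/ml x filtered_ml / elution_µl for
#' fish; the ladder concentrations for standards); an assignment record per
#' fish OTU; a set-net catch record drawn from the same species pool; and one
#' echogram per station whose cell intensities track summed fish density.
#'
#' @param config A [survey_config()].
#' @return A list of class `survey_bundle`: `read_table`, `standards`,
#'   `assignments`, `metadata`, `catch`, `echograms` (named list),
#'   `truth` (list: `species` and `otu` matrices of copies/ml water, and
#'   `copies_per_ul` per OTU), `slopes` (named vector), `checklist`,
#'   `habitat_map`, `config`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed)
  st <- config$stations
  layers <- c("middle", "bottom")
  grid <- expand.grid(rep = seq_len(config$n_replicates), depth_layer = layers,
                      station_id = st$station_id, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$station_id, st$station_id)), ]
  sample_id <- sprintf("%s_%s_%d", grid$station_id,
                       substr(grid$depth_layer, 1, 3), grid$rep)
  dist_abs <- abs(st$distance_m[match(grid$station_id, st$station_id)])
  start_time <- 3600 * seq_along(unique(grid$station_id)) # one station per hour
  names(start_time) <- unique(grid$station_id)

  meta <- sample_metadata(
    sample_id = sample_id, station_id = grid$station_id,
    distance_m = dist_abs, depth_layer = grid$depth_layer,
    replicate = grid$rep,
    filtered_volume_ml = config$filtered_volume_ml,
    elution_volume_ul = config$elution_volume_ul,
    sampling_time = start_time[grid$station_id], is_control = FALSE
  )
  if (config$include_control) {
    meta <- rbind(meta, sample_metadata(
      sample_id = "FNC", station_id = "FNC", distance_m = NA,
      depth_layer = "middle", replicate = 1,
      filtered_volume_ml = config$filtered_volume_ml,
      elution_volume_ul = config$elution_volume_ul,
      sampling_time = max(start_time) + 3600, is_control = TRUE
    ))
    class(meta) <- c("sample_metadata", "data.frame")
  }

  sp <- config$species
  n_s <- nrow(meta)
  n_field <- sum(!meta$is_control)
  # true copies/ml water, field samples x species
  mu <- matrix(0, n_field, nrow(sp),
               dimnames = list(meta$sample_id[!meta$is_control], sp$species))
  for (i in seq_len(nrow(sp))) {
    base <- sp$baseline[i] *
      exp(-config$decay * sp$reef_assoc[i] *
            log_distance(meta$distance_m[!meta$is_control])) *
      .depth_multiplier(sp$depth_pref[i], meta$depth_layer[!meta$is_control],
                        config$depth_pref_multiplier)
    noise <- if (config$sigma_bio > 0) {
      stats::rlnorm(n_field, -config$sigma_bio^2 / 2, config$sigma_bio)
    } else 1
    mu[, i] <- base * noise
  }
  # collapse species sharing an OTU (marker-indistinguishable congeners)
  otus <- unique(sp$otu_id)
  mu_otu <- matrix(0, n_field, length(otus),
                   dimnames = list(rownames(mu), otus))
  for (o in otus) {
    mu_otu[, o] <- rowSums(mu[, sp$otu_id == o, drop = FALSE])
  }

  extract_factor <- config$filtered_volume_ml / config$elution_volume_ul
  slopes <- stats::rlnorm(n_s, config$slope_meanlog, config$slope_sdlog)
  names(slopes) <- meta$sample_id

  std_ids <- config$standards$standard_id
  counts <- matrix(0, n_s, length(otus) + length(std_ids),
                   dimnames = list(meta$sample_id, c(otus, std_ids)))
  for (s in meta$sample_id) {
    fish_rate <- if (meta$is_control[meta$sample_id == s] || !length(otus)) {
      rep(0, length(otus))
    } else {
      slopes[s] * mu_otu[s, ] * extract_factor
    }
    std_rate <- slopes[s] * config$standards$copies_per_ul
    rate <- c(fish_rate, std_rate)
    counts[s, ] <- switch(
      config$read_noise,
      poisson = stats::rpois(length(rate), rate),
      none = round(rate),
      multinomial = stats::rmultinom(1, config$target_reads,
                                     rate / sum(rate))[, 1]
    )
  }
  rt <- read_table(counts, standard_ids = std_ids)

  assignments <- data.frame(
    otu_id = otus,
    hit_species = vapply(otus, function(o) {
      paste(sp$species[sp$otu_id == o], collapse = ";")
    }, character(1)),
    identity_pct = round(stats::runif(length(otus), 98.6, 100), 1),
    aln_length = 172L,
    taxon_group = "bony_fish",
    row.names = NULL
  )

  catch <- generate_catch_record(mu, config,
                                 n_classifications = min(41, nrow(sp) + 3))

  echograms <- lapply(st$station_id, function(stn) {
    dens <- if (any(meta$station_id == stn & !meta$is_control)) {
      mean(rowSums(mu_otu[meta$sample_id[meta$station_id == stn &
                                           !meta$is_control], , drop = FALSE]))
    } else 0
    .simulate_echogram(dens, config, t0 = start_time[[stn]])
  })
  names(echograms) <- st$station_id

  habitat_map <- stats::setNames(sp$habitat, sp$species)
  # genus-level labels inherit the habitat of their first member
  label_of <- vapply(otus, function(o) {
    hits <- sp$species[sp$otu_id == o]
    if (length(hits) == 1) hits else {
      paste(strsplit(hits[1], " ")[[1]][1], "spp.")
    }
  }, character(1))
  habitat_map <- c(habitat_map,
                   stats::setNames(sp$habitat[match(otus, sp$otu_id)],
                                   label_of))
  habitat_map <- habitat_map[!duplicated(names(habitat_map))]

  structure(
    list(read_table = rt, standards = config$standards,
         assignments = assignments, metadata = meta, catch = catch,
         echograms = echograms,
         truth = list(species = mu, otu = mu_otu,
                      copies_per_ul = mu_otu * extract_factor),
         slopes = slopes,
         checklist = regional_checklist(sp$species),
         habitat_map = habitat_map,
         start_times = start_time,
         config = config),
    class = "survey_bundle"
  )
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat(sprintf("<survey_bundle> %d samples, %d fish OTUs, %d stations, seed %d\n",
              nrow(x$read_table$counts), sum(x$read_table$otu_class == "fish"),
              nrow(x$config$stations), x$config$seed))
  invisible(x)
}

.simulate_echogram <- function(density, config, t0 = 0, n_pings = 60,
                               n_depth = 40, bottom = 80) {
  time <- t0 + seq(0, by = 10, length.out = n_pings)
  depth <- seq(2, bottom, length.out = n_depth)
  background_db <- -85
  sv_db <- matrix(background_db, n_pings, n_depth)
  has_fish <- matrix(stats::runif(n_pings * n_depth) < config$echo_fill,
                     n_pings, n_depth)
  if (density > 0 && any(has_fish)) {
    signal_db <- 10 * log10(config$echo_gain * density / config$echo_fill)
    sv_db[has_fish] <- signal_db +
      stats::rnorm(sum(has_fish), 0, config$echo_noise_sd_db)
  }
  echogram(time, depth, sv_db, bottom_depth = bottom)
}

#' Generate a set-net catch record from the true concentrations
#'
#' Catch biomass per classification is proportional to the species' mean true
#' concentration with log-normal error. A configurable number of records sit
#' above species rank (genus/family classifications, as real catch ledgers
#' contain), and — when the species pool has one — the marker-ambiguous
#' congeneric pair appears as two separate species records.
#'
#' @param truth Field-sample x species matrix of true copies/ml (e.g.
#'   `bundle$truth$species`).
#' @param config The [survey_config()] that produced `truth`.
#' @param n_classifications Total records to emit.
#' @param n_above_species How many records are genus/family rank.
#' @param biomass_scale Expected kg per (copy/ml) of mean concentration.
#' @param biomass_sdlog Log-normal error on biomass.
#' @return Data frame: `classification`, `rank`, `biomass_kg`.
#' @export
generate_catch_record <- function(truth, config, n_classifications = 41,
                                  n_above_species = 3, biomass_scale = 500,
                                  biomass_sdlog = 1) {
  if (ncol(truth) == 0 || n_classifications == 0) {
    return(data.frame(classification = character(), rank = character(),
                      biomass_kg = numeric()))
  }
  n_sp <- n_classifications - n_above_species
  if (n_sp > ncol(truth)) {
    stop("species pool too small for ", n_sp, " species-rank records")
  }
  dens <- colMeans(truth)
  # keep the ambiguous congeneric pair in the record, fill with the densest
  pair <- grep("^Ambigenus ", names(dens), value = TRUE)
  others <- setdiff(names(sort(dens, decreasing = TRUE)), pair)
  chosen <- c(pair, others)[seq_len(n_sp)]
  biomass <- biomass_scale * dens[chosen] *
    stats::rlnorm(length(chosen), -biomass_sdlog^2 / 2, biomass_sdlog)
  out <- data.frame(classification = chosen, rank = "species",
                    biomass_kg = as.numeric(biomass), row.names = NULL)
  if (n_above_species > 0) {
    n_gen <- ceiling(n_above_species / 3)
    hi <- data.frame(
      classification = c(sprintf("Synthogenus%02d sp.", seq_len(n_gen)),
                         sprintf("Synthidae%d", seq_len(n_above_species - n_gen))),
      rank = c(rep("genus", n_gen), rep("family", n_above_species - n_gen)),
      biomass_kg = stats::rlnorm(n_above_species, log(5), 1)
    )
    out <- rbind(out, hi)
  }
  out
}
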