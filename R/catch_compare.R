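#' Detection rate of metabarcoding against a set-net catch record
#'
#' Computes the proportion of net-caught species also detected by eDNA
#' metabarcoding, with the standard exclusions: catch records identified only
#' above species rank are dropped from the denominator, as are species
#' belonging to a pair the marker cannot separate (e.g. two congeneric
#' mackerels). An optional biomass floor further restricts the denominator to
#' species caught at or above a given mass; the floor changes only the
#' denominator's membership, never whether a species counts as detected.
#'
#' A catch species counts as detected if its exact binomial appears among the
#' detected taxon labels, or if a genus-level label ("Genus spp.") covers it.
#'
#' @param catch Data frame with columns `classification`, `rank`
#'   (`"species"`, `"genus"` or `"family"`) and `biomass_kg`.
#' @param detected_taxa Character vector of labels produced by the
#'   metabarcoding pipeline (species binomials and/or "Genus spp." labels).
#' @param ambiguous_pairs List of character vectors; each vector holds species
#'   indistinguishable at the marker, all excluded from the denominator.
#' @param min_biomass_kg Biomass floor in kg (default 0 = no floor).
#' @return A list of class `detection_report`: `n_catch_total`,
#'   `n_excluded_rank`, `n_excluded_ambiguous`, `denominator`, `n_detected`,
#'   `rate` (proportion, `NA` with `undefined = TRUE` when the denominator is
#'   empty), and `flags` (per-species data frame with `detected`).
#' @export
detection_rate <- function(catch, detected_taxa, ambiguous_pairs = list(),
                           min_biomass_kg = 0) {
  stopifnot(all(c("classification", "rank", "biomass_kg") %in% names(catch)))
  if (any(!is.finite(catch$biomass_kg)) || any(catch$biomass_kg < 0)) {
    stop("biomass_kg must be finite and non-negative")
  }
  n_total <- nrow(catch)
  sp <- catch[catch$rank == "species", , drop = FALSE]
  n_excl_rank <- n_total - nrow(sp)

  ambiguous <- unique(unlist(ambiguous_pairs))
  is_amb <- sp$classification %in% ambiguous
  n_excl_amb <- sum(is_amb)
  sp <- sp[!is_amb, , drop = FALSE]

  genus_of <- function(x) vapply(strsplit(x, " "), `[`, character(1), 1)
  genus_labels <- detected_taxa[grepl(" spp\\.$", detected_taxa)]
  covered_genera <- sub(" spp\\.$", "", genus_labels)
  detected <- sp$classification %in% detected_taxa |
    genus_of(sp$classification) %in% covered_genera

  flags <- data.frame(classification = sp$classification,
                      biomass_kg = sp$biomass_kg,
                      detected = detected, row.names = NULL)

  in_floor <- sp$biomass_kg >= min_biomass_kg
  denom <- sum(in_floor)
  n_det <- sum(detected & in_floor)
  structure(
    list(n_catch_total = n_total,
         n_excluded_rank = n_excl_rank,
         n_excluded_ambiguous = n_excl_amb,
         denominator = denom,
         n_detected = n_det,
         rate = if (denom > 0) n_det / denom else NA_real_,
         undefined = denom == 0,
         min_biomass_kg = min_biomass_kg,
         flags = flags),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> %d catch records; %d above species rank, %d marker-ambiguous excluded\n",
    x$n_catch_total, x$n_excluded_rank, x$n_excluded_ambiguous))
  if (x$min_biomass_kg > 0) {
    cat(sprintf("  biomass floor %.1f kg\n", x$min_biomass_kg))
  }
  if (x$undefined) {
    cat("  detection rate undefined (empty denominator)\n")
  } else {
    cat(sprintf("  detected %d / %d = %.1f%%\n",
                x$n_detected, x$denominator, 100 * x$rate))
  }
  invisible(x)
}

#' Read a catch record table from TSV
#'
#' @param path TSV with columns `classification`, `rank`, `biomass_kg` (and
#'   optionally `detected`, used by worked examples to carry a known
#'   detection outcome alongside the record).
#' @return Data frame.
#' @export
read_catch_record <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("classification", "rank", "biomass_kg") %in% names(df)))
  df
}
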