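#' Post-assignment quality filters for OTU hits
#'
#' Applies the standard exclusion rules to a table of per-OTU sequence
#' assignment summaries: drop OTUs belonging to organisms other than bony
#' fishes, sharks and rays; drop when the top-hit identity is below 98.5%;
#' drop when the alignment is 150 bp or shorter (the target amplicon is
#' ~172 bp, so genuine amplicons comfortably exceed this). Identity exactly
#' at 98.5% is kept; alignment length exactly 150 is dropped.
#'
#' @param records Data frame with columns `otu_id`, `hit_species`
#'   (semicolon-joined species names), `identity_pct`, `aln_length`,
#'   `taxon_group` (one of `"bony_fish"`, `"shark"`, `"ray"`, `"other"`).
#' @param min_identity Identity threshold in percent; strictly-below drops.
#' @param max_drop_length Alignment lengths at or below this are dropped.
#' @return `records` with added logical `kept` and character `drop_reason`
#'   (`NA` for kept rows; otherwise `"non_fish"`, `"identity"` or `"length"`,
#'   the first rule that fired).
#' @export
apply_blast_filters <- function(records, min_identity = 98.5,
                                max_drop_length = 150) {
  stopifnot(all(c("otu_id", "identity_pct", "aln_length", "taxon_group") %in%
                  names(records)))
  if (any(records$identity_pct < 0 | records$identity_pct > 100)) {
    stop("identity_pct must lie in [0, 100]")
  }
  if (any(records$aln_length <= 0)) stop("aln_length must be positive")
  reason <- rep(NA_character_, nrow(records))
  reason[records$aln_length <= max_drop_length] <- "length"
  reason[records$identity_pct < min_identity] <- "identity"
  reason[records$taxon_group == "other"] <- "non_fish"
  records$kept <- is.na(reason)
  records$drop_reason <- reason
  records
}

#' Regional species checklist
#'
#' Maps each genus to the set of species known from the study region. Used to
#' re-assign species rank to OTUs whose sequence matches several congeners of
#' which only one occurs locally.
#'
#' @param species Character vector of binomial species names.
#' @return A list of class `regional_checklist`, genus -> character vector.
#' @export
regional_checklist <- function(species) {
  genus <- vapply(strsplit(species, " "), `[`, character(1), 1)
  structure(split(species, genus), class = "regional_checklist")
}

#' Collapse multi-species assignments to a single taxon label
#'
#' Marker genes often cannot separate close congeners, so an OTU whose reads
#' match several species is demoted to genus rank ("Genus spp.") — unless the
#' regional checklist contains exactly one species of that genus, in which
#' case the OTU is re-assigned to that species. Hits spanning several genera
#' fall back to a higher rank. Single-species hits keep species rank.
#'
#' @param records Assignment data frame (rows that passed
#'   [apply_blast_filters()]), with `otu_id` and `hit_species`
#'   (semicolon-joined).
#' @param checklist A [regional_checklist()].
#' @param higher_rank_label Label used when hits span genera (a family name
#'   lookup is out of scope for the marker table; a generic label is used).
#' @return Data frame of class `taxon_labels`: `otu_id`, `label`, `rank`
#'   (`"species"`, `"genus_spp"` or `"higher"`).
#' @export
collapse_assignments <- function(records, checklist,
                                 higher_rank_label = "Unresolved higher taxon") {
  stopifnot(inherits(checklist, "regional_checklist"))
  one <- function(hits_str) {
    hits <- trimws(strsplit(hits_str, ";", fixed = TRUE)[[1]])
    hits <- hits[nzchar(hits)]
    if (!length(hits)) stop("empty hit list")
    genera <- unique(vapply(strsplit(hits, " "), `[`, character(1), 1))
    if (length(hits) == 1) {
      if (is.null(checklist[[genera]]) || !(hits %in% checklist[[genera]])) {
        warning("species not in regional checklist: ", hits, call. = FALSE)
      }
      return(c(hits, "species"))
    }
    if (length(genera) == 1) {
      regional <- intersect(hits, checklist[[genera]])
      if (length(checklist[[genera]]) == 1) {
        # only one congener occurs regionally: species rank is recoverable
        return(c(checklist[[genera]][1], "species"))
      }
      return(c(paste(genera, "spp."), "genus_spp"))
    }
    c(higher_rank_label, "higher")
  }
  out <- t(vapply(records$hit_species, one, character(2)))
  structure(
    data.frame(otu_id = records$otu_id, label = out[, 1], rank = out[, 2],
               row.names = NULL),
    class = c("taxon_labels", "data.frame")
  )
}

#' Per-sample relative-abundance noise filter
#'
#' Zeroes, within each sample, any fish OTU whose reads fall strictly below
#' `threshold` (default 0.05%) of that sample's total fish reads. The total
#' is computed once per sample before any zeroing (single pass); standards
#' are untouched and by default excluded from the denominator. Singleton
#' reads in deeply sequenced samples are always removed by this rule.
#'
#' @param rt A [read_table()].
#' @param threshold Proportion of the sample total below which reads are
#'   treated as noise (default 5e-4, i.e. 0.05%).
#' @param include_standards Include standard reads in the denominator.
#' @param iterative Re-apply until a fixed point is reached (the total drops
#'   as OTUs are zeroed, so the threshold shrinks; the single pass is already
#'   idempotent, the iterative variant exists for sensitivity checks).
#' @return A `read_table` with noisy counts set to zero; ids preserved.
#' @export
noise_filter <- function(rt, threshold = 5e-4, include_standards = FALSE,
                         iterative = FALSE) {
  stopifnot(inherits(rt, "read_table"))
  repeat {
    fish_cols <- rt$otu_class == "fish"
    denom <- if (include_standards) rowSums(rt$counts) else
      rowSums(rt$counts[, fish_cols, drop = FALSE])
    cut <- denom * threshold
    noisy <- rt$counts[, fish_cols, drop = FALSE] < cut &
      rt$counts[, fish_cols, drop = FALSE] > 0
    if (!any(noisy)) break
    rt$counts[, fish_cols][noisy] <- 0
    if (!iterative) break
  }
  rt
}

#' Remove contaminant taxa from a read table
#'
#' Drops OTUs whose assigned label is on a contaminant blocklist. The default
#' names three cold-water or market species that cannot plausibly occur in a
#' warm-temperate Pacific bay and are common human food items, the signature
#' of laboratory or field contamination.
#'
#' @param rt A [read_table()].
#' @param labels A `taxon_labels` data frame mapping `otu_id` to `label`.
#' @param blocklist Character vector of labels to remove.
#' @return A `read_table` without the blocklisted OTU columns.
#' @export
remove_contaminants <- function(rt, labels,
                                blocklist = c("Oncorhynchus nerka",
                                              "Gadus chalcogrammus",
                                              "Trachurus trachurus")) {
  stopifnot(inherits(rt, "read_table"))
  bad_otus <- labels$otu_id[labels$label %in% blocklist]
  keep <- !(colnames(rt$counts) %in% bad_otus)
  rt$counts <- rt$counts[, keep, drop = FALSE]
  rt$otu_class <- rt$otu_class[keep]
  rt
}

#' Classify OTU labels as demersal or pelagic
#'
#' Deterministic lookup in a user-supplied habitat map (a stand-in for a
#' FishBase query). Labels missing from the map receive `default` with a
#' warning.
#'
#' @param labels A `taxon_labels` data frame.
#' @param habitat_map Named character vector, label -> `"demersal"`/`"pelagic"`.
#' @param default Habitat assigned to unmapped labels.
#' @return Character vector of habitats, one per label row.
#' @export
classify_habitat <- function(labels, habitat_map, default = "demersal") {
  stopifnot(default %in% c("demersal", "pelagic"))
  hab <- unname(habitat_map[labels$label])
  if (anyNA(hab)) {
    warning("no habitat entry for: ",
            paste(unique(labels$label[is.na(hab)]), collapse = ", "),
            "; using '", default, "'")
    hab[is.na(hab)] <- default
  }
  if (!all(hab %in% c("demersal", "pelagic"))) {
    stop("habitat_map values must be 'demersal' or 'pelagic'")
  }
  hab
}

#' Full OTU preprocessing pipeline
#'
#' Applies the filtering stages in their fixed order — assignment-quality
#' filters, taxonomy collapsing, per-sample noise filter, contaminant
#' removal — and returns the cleaned table together with an audit trail.
#' The order is asserted by construction: each stage consumes the previous
#' stage's output only.
#'
#' @param rt A [read_table()] whose fish OTU ids appear in `records`.
#' @param records Assignment records (see [apply_blast_filters()]).
#' @param checklist A [regional_checklist()].
#' @param blocklist Contaminant labels, see [remove_contaminants()].
#' @param threshold Noise threshold, see [noise_filter()].
#' @param include_standards Denominator choice for the noise filter.
#' @return List with `read_table` (cleaned), `labels` (kept OTUs), and
#'   `audit` (per-OTU fate: kept, or the first filter that removed it).
#' @export
preprocess_reads <- function(rt, records, checklist,
                             blocklist = c("Oncorhynchus nerka",
                                           "Gadus chalcogrammus",
                                           "Trachurus trachurus"),
                             threshold = 5e-4, include_standards = FALSE) {
  stopifnot(inherits(rt, "read_table"))
  filt <- apply_blast_filters(records)
  audit <- data.frame(otu_id = filt$otu_id,
                      fate = ifelse(filt$kept, "kept", filt$drop_reason))
  dropped <- filt$otu_id[!filt$kept]
  keep_cols <- !(colnames(rt$counts) %in% dropped)
  rt$counts <- rt$counts[, keep_cols, drop = FALSE]
  rt$otu_class <- rt$otu_class[keep_cols]

  labels <- collapse_assignments(filt[filt$kept, , drop = FALSE], checklist)
  rt <- noise_filter(rt, threshold = threshold,
                     include_standards = include_standards)
  n_before <- ncol(rt$counts)
  rt <- remove_contaminants(rt, labels, blocklist = blocklist)
  removed <- setdiff(labels$otu_id, colnames(rt$counts))
  audit$fate[audit$otu_id %in% removed] <- "contaminant"
  labels <- labels[!(labels$otu_id %in% removed), , drop = FALSE]
  list(read_table = rt, labels = labels, audit = audit,
       n_contaminants_removed = n_before - ncol(rt$counts))
}
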