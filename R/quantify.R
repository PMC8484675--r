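#' Internal-standard ladder specification
#'
#' The spike-in ladder: each library receives the same mix of synthetic
#' standard DNAs at known concentrations, so that within every sample the
#' observed standard reads trace out a per-sample calibration line. The
#' default is the five-point ladder used in coastal fish surveys.
#'
#' @param standard_id Character vector of standard OTU ids.
#' @param copies_per_ul Positive, distinct concentrations (copies/µl) matching
#'   `standard_id`.
#' @return A data frame of class `standard_spec`.
#' @export
standard_spec <- function(standard_id = paste0("Std", LETTERS[1:5]),
                          copies_per_ul = c(100, 50, 25, 12.5, 2.5)) {
  if (length(standard_id) != length(copies_per_ul) || length(standard_id) < 2) {
    stop("need >= 2 standards with one concentration each")
  }
  if (anyDuplicated(standard_id)) stop("standard ids must be unique")
  if (any(copies_per_ul <= 0) || anyDuplicated(copies_per_ul)) {
    stop("copies_per_ul must be strictly positive and distinct")
  }
  structure(
    data.frame(standard_id = as.character(standard_id),
               copies_per_ul = as.numeric(copies_per_ul)),
    class = c("standard_spec", "data.frame")
  )
}

#' Fit a per-sample zero-intercept standard curve
#'
#' Regresses a sample's standard-DNA reads on the known spike-in
#' concentrations with the intercept fixed at zero:
#' reads = slope x copies/µl. The least-squares estimator is the closed form
#' slope = sum(x*y) / sum(x^2), and fit quality is the uncentered
#' R^2 = 1 - RSS / sum(y^2), the zero-intercept convention (the centered
#' version can be negative when the line is forced through the origin).
#'
#' Samples whose standards all read zero cannot be calibrated; they are
#' returned flagged with slope 0 rather than raising, so that a whole-run
#' quantification can skip them with a warning.
#'
#' @param standard_reads Named numeric vector of reads, names matching
#'   `spec$standard_id`.
#' @param spec A [standard_spec()].
#' @param sample_id Optional id carried into the result.
#' @return A list of class `calibration` with `sample_id`, `slope` (reads per
#'   copy/µl), `r_squared`, `n_standards`, and `flagged` (TRUE when the
#'   sample cannot be used for quantification).
#' @export
fit_standard_curve <- function(standard_reads, spec, sample_id = NA_character_) {
  stopifnot(inherits(spec, "standard_spec"))
  missing_ids <- setdiff(spec$standard_id, names(standard_reads))
  if (length(missing_ids)) {
    stop("standard reads missing for: ", paste(missing_ids, collapse = ", "))
  }
  y <- as.numeric(standard_reads[spec$standard_id])
  x <- spec$copies_per_ul
  if (any(y < 0)) stop("standard reads must be non-negative")
  if (all(y == 0)) {
    return(structure(
      list(sample_id = sample_id, slope = 0, r_squared = NA_real_,
           n_standards = length(x), flagged = TRUE),
      class = "calibration"
    ))
  }
  slope <- sum(x * y) / sum(x^2)
  rss <- sum((y - slope * x)^2)
  r2 <- 1 - rss / sum(y^2)
  structure(
    list(sample_id = sample_id, slope = slope, r_squared = r2,
         n_standards = length(x), flagged = FALSE),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> sample %s: slope %.4g reads/(copy/µl), R² %.3f%s\n",
              x$sample_id, x$slope,
              if (is.na(x$r_squared)) NaN else x$r_squared,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Convert sequence reads to copies per microlitre of extract
#'
#' Divides fish-OTU reads by the sample's calibration slope:
#' copies/µl = reads / slope. Zero reads map to zero copies.
#'
#' @param reads Non-negative numeric vector of reads.
#' @param cal A `calibration` from [fit_standard_curve()].
#' @return Copies per µl of DNA extract, same length as `reads`.
#' @export
convert_reads_to_copies <- function(reads, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$flagged || cal$slope <= 0) {
    stop("cannot convert reads for sample ", cal$sample_id,
         ": calibration flagged or slope non-positive")
  }
  if (any(reads < 0)) stop("reads must be non-negative")
  reads / cal$slope
}

#' Convert extract concentration to copies per millilitre of water
#'
#' The extract concentration refers to the DNA eluate; scaling by the elution
#' volume and dividing by the filtered water volume gives the concentration
#' in the sampled water: copies/ml = copies/µl x elution_µl / filtered_ml.
#' Defaults correspond to a 100 µl elution from a 2 L filtration.
#'
#' @param copies_per_ul Copies per µl of extract.
#' @param meta A list or one-row data frame with `elution_volume_ul` and
#'   `filtered_volume_ml`, e.g. a row of [sample_metadata()].
#' @return Copies per ml of water.
#' @export
copies_per_ml_water <- function(copies_per_ul, meta) {
  ev <- meta$elution_volume_ul
  fv <- meta$filtered_volume_ml
  if (is.null(ev) || is.null(fv) || any(ev <= 0) || any(fv <= 0)) {
    stop("elution_volume_ul and filtered_volume_ml must be positive")
  }
  copies_per_ul * ev / fv
}

#' Sample metadata table
#'
#' @param sample_id,station_id,distance_m,depth_layer,replicate Vectors
#'   describing each water sample; `distance_m` is the absolute distance from
#'   the focal reef in metres and `depth_layer` is `"middle"` or `"bottom"`.
#' @param filtered_volume_ml,elution_volume_ul Filtration and elution volumes.
#' @param sampling_time Sampling times (POSIXct or character).
#' @param is_control Logical; field negative controls receive standards but
#'   their fish reads are never converted to concentrations.
#' @return A data frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, station_id, distance_m, depth_layer,
                            replicate, filtered_volume_ml = 2000,
                            elution_volume_ul = 100,
                            sampling_time = NA, is_control = FALSE) {
  depth_layer <- as.character(depth_layer)
  if (!all(depth_layer %in% c("middle", "bottom"))) {
    stop("depth_layer must be 'middle' or 'bottom'")
  }
  if (any(filtered_volume_ml <= 0) || any(elution_volume_ul <= 0)) {
    stop("volumes must be positive")
  }
  structure(
    data.frame(sample_id = as.character(sample_id),
               station_id = as.character(station_id),
               distance_m = as.numeric(distance_m),
               depth_layer = depth_layer,
               replicate = replicate,
               filtered_volume_ml = filtered_volume_ml,
               elution_volume_ul = elution_volume_ul,
               sampling_time = sampling_time,
               is_control = is_control),
    class = c("sample_metadata", "data.frame")
  )
}

#' Calibrate every sample and quantify all fish OTUs
#'
#' Runs [fit_standard_curve()] for each sample (field negative controls
#' included — they receive standards too), then converts every fish OTU's
#' reads to copies/µl extract and copies/ml water. Controls are calibrated
#' but never quantified; samples with a flagged calibration are excluded
#' from the concentration tables with a warning. Calibrations whose R²
#' falls below `r2_floor` are marked in the QC table but retained.
#'
#' @param rt A [read_table()].
#' @param spec A [standard_spec()].
#' @param meta A [sample_metadata()] covering every sample in `rt`.
#' @param r2_floor QC floor for the uncentered R² (default 0.7, about the
#'   minimum seen in practice on real runs).
#' @return A list of class `quant_table`: `copies_per_ul` and `copies_per_ml`
#'   (matrices, quantified samples x fish OTUs), `calibrations` (per-sample QC
#'   data frame with slope, R², flags), `excluded` (sample ids not
#'   quantified), and `meta`.
#' @export
quantify_table <- function(rt, spec, meta, r2_floor = 0.7) {
  stopifnot(inherits(rt, "read_table"), inherits(spec, "standard_spec"))
  ids <- rownames(rt$counts)
  if (!all(ids %in% meta$sample_id)) {
    stop("metadata missing for some samples")
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  std <- standard_counts(rt)
  cals <- lapply(ids, function(s) {
    fit_standard_curve(std[s, ], spec, sample_id = s)
  })
  cal_df <- data.frame(
    sample_id = ids,
    slope = vapply(cals, `[[`, numeric(1), "slope"),
    r_squared = vapply(cals, `[[`, numeric(1), "r_squared"),
    n_standards = vapply(cals, `[[`, numeric(1), "n_standards"),
    flagged = vapply(cals, `[[`, logical(1), "flagged"),
    is_control = meta$is_control,
    row.names = NULL
  )
  cal_df$below_qc_floor <- !cal_df$flagged & !is.na(cal_df$r_squared) &
    cal_df$r_squared < r2_floor
  names(cals) <- ids

  usable <- !cal_df$flagged & !meta$is_control
  if (any(cal_df$flagged)) {
    warning("excluded from quantification (all-zero standards): ",
            paste(ids[cal_df$flagged], collapse = ", "))
  }
  fish <- fish_counts(rt)
  keep <- ids[usable]
  cpul <- matrix(0, length(keep), ncol(fish),
                 dimnames = list(keep, colnames(fish)))
  cpml <- cpul
  for (s in keep) {
    cpul[s, ] <- convert_reads_to_copies(fish[s, ], cals[[s]])
    cpml[s, ] <- copies_per_ml_water(cpul[s, ], meta[meta$sample_id == s, ])
  }
  structure(
    list(copies_per_ul = cpul, copies_per_ml = cpml,
         calibrations = cal_df,
         excluded = ids[!usable],
         meta = meta),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d quantified samples x %d fish OTUs (%d calibrations, %d excluded)\n",
              nrow(x$copies_per_ul), ncol(x$copies_per_ul),
              nrow(x$calibrations), length(x$excluded)))
  invisible(x)
}

#' Contamination level of a negative control
#'
#' Expresses the total copy number detected in a field negative control as a
#' percentage of the mean total copy number across field-positive samples.
#' A clean run reports 0%.
#'
#' @param control_copies Total copies attributed to the control (any unit,
#'   consistent with `positive_copies`).
#' @param positive_copies Numeric vector of per-sample total copies for the
#'   field-positive samples.
#' @return Percentage (0–100 scale).
#' @export
contamination_pct <- function(control_copies, positive_copies) {
  if (length(positive_copies) == 0 || mean(positive_copies) == 0) {
    stop("need positive samples with non-zero mean copies")
  }
  100 * control_copies / mean(positive_copies)
}
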