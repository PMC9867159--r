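#' Summary statistics of a temperature region
#'
#' Six summarizing statistics of the temperatures in one region: mean,
#' standard deviation, maximum, minimum, skewness and kurtosis. The standard
#' deviation uses the population convention (divisor n), and skewness and
#' kurtosis are the standardized third and fourth central moments (kurtosis
#' is not excess kurtosis, so a normal sample gives values near 3). A
#' constant region has zero variance; its skewness and kurtosis are defined
#' as 0 so that every region yields a complete vector.
#'
#' @param temps Numeric vector of region temperatures (Celsius), non-empty.
#' @param region Region name used in error messages.
#' @return Named numeric vector `mean`, `std`, `max`, `min`, `skew`,
#'   `kurtosis`.
#' @export
summary_stats <- function(temps, region = "region") {
  if (length(temps) == 0) {
    stop(sprintf("region '%s' is empty", region))
  }
  stopifnot(is.numeric(temps), all(is.finite(temps)))
  n <- length(temps)
  m <- mean(temps)
  d <- temps - m
  v <- mean(d^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean(d^3) / s^3
    kurt <- mean(d^4) / s^4
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = m, std = s, max = max(temps), min = min(temps),
    skew = skew, kurtosis = kurt)
}

#' NTR occupancy fractions of a region
#'
#' Fraction of region pixels falling in each temperature class of the NTR
#' table. Fractions sum to one.
#'
#' @inheritParams summary_stats
#' @param table Class table from [ntr_class_table()].
#' @return Numeric vector of length `nrow(table)`, named by `table$ntr`.
#' @export
ntr_occupancy <- function(temps, table = ntr_class_table(), region = "region") {
  if (length(temps) == 0) {
    stop(sprintf("region '%s' is empty", region))
  }
  idx <- assign_class(temps, table)
  counts <- tabulate(idx, nbins = nrow(table))
  frac <- counts / length(temps)
  names(frac) <- table$ntr
  frac
}

#' Estimated temperature (ET) of a region
#'
#' Occupancy-weighted average of the classmarks: `ET = sum_c f_c * mark_c`
#' where `f_c` is the fraction of region pixels in class `c`. Always lies
#' between the smallest and largest classmark of the occupied classes.
#'
#' @param occupancy Occupancy fractions as returned by [ntr_occupancy()];
#'   must sum to 1 within 1e-9.
#' @param table Class table matching `occupancy`.
#' @return ET in degrees Celsius.
#' @export
estimated_temperature <- function(occupancy, table = ntr_class_table()) {
  stopifnot(length(occupancy) == nrow(table))
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy fractions must sum to 1")
  }
  sum(occupancy * table$classmark)
}

#' Estimated temperature difference (ETD) between feet
#'
#' Unsigned difference of the estimated temperature between corresponding
#' regions of the left and right foot. Because it is symmetric in the two
#' feet, ETD features carry no foot prefix (e.g. `Foot_ETD`, `MCA_ETD`).
#'
#' @param et_left,et_right ET of the matching region on each foot (Celsius).
#' @return `|et_left - et_right|`.
#' @export
etd <- function(et_left, et_right) {
  stopifnot(is.finite(et_left), is.finite(et_right))
  abs(et_left - et_right)
}

#' Hot spot estimator (HSE) of a region
#'
#' Representative temperature of the hottest meaningfully occupied class:
#' the classmark of the hottest class whose occupancy reaches
#' `min_occupancy`. If no class reaches the floor the hottest occupied
#' class is used, so isolated warm pixels below the floor do not drive the
#' estimate.
#'
#' @inheritParams estimated_temperature
#' @param min_occupancy Minimum occupancy fraction for a class to count as
#'   meaningfully occupied; default 0.05.
#' @return HSE in degrees Celsius.
#' @export
hot_spot_estimator <- function(occupancy, table = ntr_class_table(),
                               min_occupancy = 0.05) {
  stopifnot(length(occupancy) == nrow(table))
  if (all(occupancy == 0)) {
    stop("all-zero occupancy: region has no pixels in any class")
  }
  hot <- which(occupancy >= min_occupancy)
  if (length(hot) == 0) hot <- which(occupancy > 0)
  table$classmark[max(hot)]
}

#' Thermal change index (TCI)
#'
#' Deviation of a subject's angiosome mean temperatures from fixed control
#' references: per angiosome, `TCI_k = |mean_k - ref_k|`; the whole-foot
#' TCI is the arithmetic mean of the four per-angiosome values. The control
#' means are held fixed (see [reference_temps()]) rather than re-estimated
#' from the data at hand.
#'
#' @param region_means Named numeric vector of angiosome mean temperatures;
#'   names `MPA`, `LPA`, `MCA`, `LCA`.
#' @param refs Reference table from [reference_temps()].
#' @return Named numeric vector with elements `MPA`, `LPA`, `MCA`, `LCA`
#'   and `foot` (the whole-foot TCI).
#' @export
thermal_change_index <- function(region_means, refs = reference_temps()) {
  regions <- refs$angiosome
  missing <- setdiff(regions, names(region_means))
  if (length(missing) > 0) {
    stop("missing angiosome mean(s): ", paste(missing, collapse = ", "))
  }
  m <- region_means[regions]
  stopifnot(all(is.finite(m)))
  tci <- abs(m - refs$mean)
  names(tci) <- regions
  c(tci, foot = mean(tci))
}
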