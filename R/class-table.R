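#' Normalized temperature range (NTR) class table
#'
#' Builds the table of temperature classes used to discretize plantar
#' thermograms. The default table partitions \[18, 37) degrees Celsius into 10
#' half-open intervals: two wide cold classes (\[18,22) and \[22,26)), seven
#' 1-degree classes between 26 and 33, and a wide hot class \[33,37). Each
#' class carries a classmark, the interval midpoint, used as that class's
#' representative temperature when computing the estimated temperature (ET)
#' and the hot spot estimator (HSE).
#'
#' @param breaks Numeric vector of interval boundaries in degrees Celsius,
#'   strictly increasing. The i-th class is `[breaks[i], breaks[i+1])`.
#' @return A data.frame with columns `class` (e.g. `"C1"`), `ntr`
#'   (e.g. `"NTR_C1"`), `lo`, `hi` and `classmark` (all Celsius).
#' @examples
#' tab <- ntr_class_table()
#' tab[tab$class == "C7", ]  # the [30, 31) class, classmark 30.5
#' @export
ntr_class_table <- function(breaks = c(18, 22, 26, 27, 28, 29, 30, 31, 32, 33, 37)) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2, all(is.finite(breaks)))
  if (any(diff(breaks) <= 0)) {
    stop("`breaks` must be strictly increasing")
  }
  n <- length(breaks) - 1L
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  data.frame(
    class = paste0("C", seq_len(n)),
    ntr = paste0("NTR_C", seq_len(n)),
    lo = lo,
    hi = hi,
    classmark = (lo + hi) / 2,
    stringsAsFactors = FALSE
  )
}

#' Assign a temperature to its NTR class
#'
#' Finds the class whose half-open interval `[lo, hi)` contains each
#' temperature. Values below the coldest boundary saturate into the first
#' class and values at or above the hottest boundary into the last, so the
#' mapping is total over finite inputs.
#'
#' @param temperature Numeric vector of temperatures in degrees Celsius.
#' @param table Class table from [ntr_class_table()].
#' @return Integer vector of class indices (1-based into `table`).
#' @export
assign_class <- function(temperature, table = ntr_class_table()) {
  if (any(is.na(temperature))) {
    stop("`temperature` contains NA/NaN values")
  }
  stopifnot(is.numeric(temperature), all(is.finite(temperature)))
  breaks <- c(table$lo, table$hi[nrow(table)])
  idx <- findInterval(temperature, breaks, rightmost.closed = FALSE)
  pmin(pmax(idx, 1L), nrow(table))
}

#' Control reference temperatures per angiosome
#'
#' Mean and standard deviation of each angiosome's temperature in the
#' control (healthy) group, used as the fixed reference for the thermal
#' change index (TCI). Defaults are the published control values for the
#' four plantar angiosomes: MPA 25.8 (1.4), LPA 25.7 (1.3), MCA 26.4 (1.3),
#' LCA 26.1 (1.4) degrees Celsius.
#'
#' @param mean Named numeric vector of reference means; names must be
#'   `MPA`, `LPA`, `MCA`, `LCA`.
#' @param sd Named numeric vector of reference standard deviations (same
#'   names, all positive).
#' @return A data.frame with columns `angiosome`, `mean`, `sd`.
#' @export
reference_temps <- function(mean = c(MPA = 25.8, LPA = 25.7, MCA = 26.4, LCA = 26.1),
                            sd = c(MPA = 1.4, LPA = 1.3, MCA = 1.3, LCA = 1.4)) {
  regions <- c("MPA", "LPA", "MCA", "LCA")
  stopifnot(setequal(names(mean), regions), setequal(names(sd), regions))
  if (any(sd[regions] <= 0)) stop("reference SDs must be positive")
  data.frame(
    angiosome = regions,
    mean = unname(mean[regions]),
    sd = unname(sd[regions]),
    stringsAsFactors = FALSE
  )
}
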