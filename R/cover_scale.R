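#' Construct a cover-class scale
#'
#' Builds an ordinal cover-class scale from a vector of class boundaries.
#' The default is the modified Daubenmire scale used for visual cover
#' estimation in vegetation plots: 0-1, 1-5, 5-25, 25-50, 50-75, 75-95 and
#' 95-100 percent, analysed through the integer midpoint of each class
#' (1, 3, 15, 38, 63, 85, 98).
#'
#' Midpoints are the arithmetic mean of the class bounds rounded half-up to
#' the nearest whole integer (so 37.5 becomes 38 and 97.5 becomes 98).
#' Classes are contiguous and treated as half-open intervals
#' \code{[lower, upper)}, except the last, which is closed at 100. A cover
#' value falling exactly on a shared boundary therefore belongs to the upper
#' class of the pair (1 percent is in the 1-5 class); the field convention
#' for boundary estimates is not standardised, and this deterministic rule
#' is documented here as the package's choice.
#'
#' @param bounds Numeric vector of strictly increasing class boundaries
#'   starting at 0 and ending at 100.
#' @return An object of class \code{cover_class_scale}: a data frame with
#'   columns \code{lower}, \code{upper} and \code{midpoint}, one row per
#'   class in increasing order.
#' @examples
#' sc <- cover_class_scale()
#' sc$midpoint           # 1 3 15 38 63 85 98
#' cover_class_of(30, sc) # class 4, the 25-50 class
#' @export
cover_class_scale <- function(bounds = c(0, 1, 5, 25, 50, 75, 95, 100)) {
  if (!is.numeric(bounds) || length(bounds) < 2L || anyNA(bounds))
    stop("'bounds' must be a numeric vector of at least two finite values")
  if (is.unsorted(bounds, strictly = TRUE))
    stop("'bounds' must be strictly increasing")
  if (bounds[1L] != 0 || bounds[length(bounds)] != 100)
    stop("'bounds' must span [0, 100]")
  lower <- bounds[-length(bounds)]
  upper <- bounds[-1L]
  midpoint <- round_half_up((lower + upper) / 2)
  if (is.unsorted(midpoint, strictly = TRUE))
    stop("class midpoints must be strictly increasing; widen the classes")
  structure(
    data.frame(lower = lower, upper = upper, midpoint = midpoint),
    class = c("cover_class_scale", "data.frame")
  )
}

# round-half-up (1.5 -> 2), unlike base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Assign cover values to cover classes
#'
#' @param cover Numeric vector of percent cover values in \code{[0, 100]}.
#' @param scale A \code{\link{cover_class_scale}}.
#' @return Integer vector of class indices (1-based, increasing with cover).
#' @examples
#' cover_class_of(c(0.5, 30, 100))
#' @export
cover_class_of <- function(cover, scale = cover_class_scale()) {
  stopifnot(inherits(scale, "cover_class_scale"))
  if (!is.numeric(cover) || anyNA(cover))
    stop("'cover' must be numeric without missing values")
  if (any(cover < 0 | cover > 100))
    stop("cover values must lie in [0, 100]; got ",
         paste(cover[cover < 0 | cover > 100], collapse = ", "))
  # half-open [lower, upper) classes; findInterval puts a boundary value in
  # the class whose lower bound it equals, and 100 lands in the last class
  findInterval(cover, scale$lower)
}

#' Midpoint of a cover class
#'
#' @param class_index Integer vector of class indices.
#' @param scale A \code{\link{cover_class_scale}}.
#' @return Integer midpoints (percent cover) of the requested classes.
#' @examples
#' midpoint_of(cover_class_of(30)) # 38
#' @export
midpoint_of <- function(class_index, scale = cover_class_scale()) {
  stopifnot(inherits(scale, "cover_class_scale"))
  idx <- as.integer(class_index)
  if (anyNA(idx) || any(idx < 1L | idx > nrow(scale)))
    stop("class index out of range 1..", nrow(scale))
  scale$midpoint[idx]
}

#' Average subplot cover classes into plot-level mean cover
#'
#' Each vegetation plot is sampled as four 1 m^2 nested subplots; cover is
#' recorded per species as a cover class in each subplot and the class
#' midpoints are averaged across the four subplots. A species absent from a
#' subplot contributes 0 to its mean.
#'
#' @param subplots A list of exactly four named numeric vectors, one per
#'   subplot, each mapping species name to the class-midpoint cover recorded
#'   there (species absent from a subplot are simply omitted).
#' @return Named numeric vector: per-species mean cover (percent) across the
#'   four subplots.
#' @examples
#' plot_cover_from_subplots(list(c(fern = 38), c(), c(), c()))  # fern = 9.5
#' @export
plot_cover_from_subplots <- function(subplots) {
  if (!is.list(subplots) || length(subplots) != 4L)
    stop("'subplots' must be a list of exactly 4 subplot cover vectors")
  species <- unique(unlist(lapply(subplots, names)))
  if (length(species) == 0L) return(stats::setNames(numeric(0), character(0)))
  acc <- stats::setNames(numeric(length(species)), species)
  for (sp in subplots) {
    if (length(sp) == 0L) next
    if (is.null(names(sp)) || any(!nzchar(names(sp))))
      stop("subplot cover vectors must be named by species")
    acc[names(sp)] <- acc[names(sp)] + sp
  }
  acc / 4
}
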