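#' @title High-content mitotic-fraction statistic
#' @description Per-nucleus maximum-intensity distributions, cumulative
#'   frequency curves, a control-derived intensity threshold, and the
#'   fraction of cells above threshold per condition.  Mitotic nuclei
#'   (condensed chromatin) stain brighter than interphase nuclei, so the
#'   fraction of nuclei whose maximum DNA-stain intensity exceeds a
#'   threshold set from control wells estimates the mitotic index.
#' @name mitotic
NULL

#' Measure nuclei in a single-channel image
#'
#' Segments nuclei as connected components above a global Otsu threshold,
#' keeps components with area within the configured bounds, and reports each
#' nucleus's maximum pixel value (on the original intensity scale).
#' Requires the `EBImage` package; the rest of the module consumes
#' per-nucleus tables and has no image dependency.
#'
#' @param image numeric matrix (single-channel, background-dominated).
#' @param minArea,maxArea nucleus area bounds in pixels.
#' @return data.frame with `nucleus`, `area`, `max_intensity` (empty for a
#'   blank or flat image).
#' @export
measureNuclei <- function(image, minArea = 20, maxArea = Inf) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("measureNuclei requires the EBImage package")
  empty <- data.frame(nucleus = integer(), area = integer(),
                      max_intensity = numeric())
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(empty)
  # threshold on log intensity: nuclear brightness spans decades (dim
  # interphase vs bright mitotic), and Otsu on the raw scale would split
  # the two nuclear populations instead of background vs foreground
  lg <- log1p(image - rng[1])
  norm <- lg / max(lg)
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > th
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- as.integer(EBImage::imageData(lab))
  if (!any(lab > 0)) return(empty)
  areas <- tabulate(lab)
  keep <- which(areas >= minArea & areas <= maxArea)
  if (!length(keep)) return(empty)
  maxI <- vapply(keep, function(k) max(image[lab == k]), 0)
  data.frame(nucleus = seq_along(keep), area = areas[keep],
             max_intensity = maxI)
}

#' Empirical cumulative frequency curve
#'
#' Right-continuous empirical CDF of the measurements, reaching 1 at the
#' maximum observation, sampled on a grid for plotting/export.
#'
#' @param measurements numeric vector, or a data.frame with a
#'   `max_intensity` column.
#' @param grid evaluation grid (default: the sorted unique observations).
#' @return list with `ecdf` (the step function), `grid` and `cdf`.
#' @examples
#' cumulativeCurve(c(1, 2, 3))$ecdf(2)  # 2/3
#' @export
cumulativeCurve <- function(measurements, grid = NULL) {
  x <- if (is.data.frame(measurements)) measurements$max_intensity
       else measurements
  if (!length(x)) stop("at least one measurement required")
  f <- ecdf(x)
  if (is.null(grid)) grid <- sort(unique(x))
  list(ecdf = f, grid = grid, cdf = f(grid))
}

#' Choose the mitotic intensity threshold from control wells
#'
#' Default method: a quantile of the control max-intensity distribution
#' (linear-interpolated, type-7 quantile; default `q = 0.99`).
#' Alternatives: a fixed user value, or a two-component split of the
#' log-intensity distribution (k-means with two centers; the threshold is
#' the midpoint between the clusters' boundary values).  The chosen method
#' and parameter are recorded as attributes.
#'
#' @param control numeric control intensities, or a data.frame with a
#'   `max_intensity` column.
#' @param method `"quantile"`, `"fixed"` or `"mixture"`.
#' @param param quantile (for `"quantile"`), the threshold itself (for
#'   `"fixed"`), ignored for `"mixture"`.
#' @return the threshold, with attributes `method` and `param`.
#' @examples
#' chooseThreshold(1:100, "quantile", 0.99)  # 99.01
#' @export
chooseThreshold <- function(control, method = c("quantile", "fixed",
                                                "mixture"), param = 0.99) {
  method <- match.arg(method)
  x <- if (is.data.frame(control)) control$max_intensity else control
  th <- switch(method,
    quantile = unname(quantile(x, param, type = 7)),
    fixed = param,
    mixture = {
      lx <- log(x[x > 0])
      km <- stats::kmeans(lx, centers = range(lx), iter.max = 50)
      lower <- which.min(km$centers)
      exp((max(lx[km$cluster == lower]) +
           min(lx[km$cluster != lower])) / 2)
    })
  attr(th, "method") <- method
  attr(th, "param") <- if (method == "mixture") NA_real_ else param
  th
}

#' Mitotic fraction per condition
#'
#' The fraction of cells whose maximum intensity lies strictly above the
#' threshold; cells are pooled across wells within each condition.
#'
#' @param measurements data.frame with `condition` and `max_intensity`
#'   columns (a plain numeric vector is treated as one condition).
#' @param threshold the intensity threshold (see [chooseThreshold()]).
#' @return data.frame with `condition`, `n_cells`, `threshold`, `fraction`.
#' @examples
#' mitoticFraction(c(1, 1, 1, 10, 10), threshold = 5)  # 0.4
#' @export
mitoticFraction <- function(measurements, threshold) {
  if (!is.data.frame(measurements))
    measurements <- data.frame(condition = "all",
                               max_intensity = measurements)
  if (!nrow(measurements)) stop("at least one measurement required")
  out <- lapply(split(measurements, measurements$condition), function(d)
    data.frame(condition = d$condition[1L], n_cells = nrow(d),
               threshold = as.numeric(threshold),
               fraction = mean(d$max_intensity > threshold),
               stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$condition), , drop = FALSE]
}
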