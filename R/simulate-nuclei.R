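#' Simulate per-nucleus maximum-intensity measurements
#'
#' Emulates a fixed-cell high-content mitotic-fraction assay: per condition,
#' a stated fraction of nuclei is mitotic (condensed chromatin, bright DNA
#' stain) and the rest interphase.  Maximum intensities are drawn from two
#' lognormal distributions whose location parameters must be separable
#' (mitotic brighter than interphase).  Exactly `round(fraction * n)` cells
#' per condition are mitotic in truth.
#'
#' @param nCellsPerCondition nuclei per condition.
#' @param mitoticFraction named numeric vector of true mitotic fractions per
#'   condition, each in \[0, 1\].
#' @param intensityParams list with elements `interphase` and `mitotic`,
#'   each `c(meanlog, sdlog)` of the lognormal max-intensity distribution
#'   (arbitrary fluorescence units).
#' @param nWells wells per condition (cells assigned round-robin).
#' @param seed integer seed.
#' @return data.frame with `condition`, `well`, `max_intensity` and the
#'   ground-truth flag `is_mitotic`.
#' @examples
#' nuc <- simulateNuclei(500, c(DMSO = 0.02, noc = 0.4), seed = 5)
#' table(nuc$condition, nuc$is_mitotic)
#' @export
simulateNuclei <- function(nCellsPerCondition, mitoticFraction,
                           intensityParams = list(
                             interphase = c(meanlog = log(1000), sdlog = 0.2),
                             mitotic = c(meanlog = log(6000), sdlog = 0.15)),
                           nWells = 3L, seed = 1) {
  if (any(mitoticFraction < 0 | mitoticFraction > 1))
    stop("mitotic fractions must lie in [0, 1]")
  ip <- intensityParams$interphase
  mp <- intensityParams$mitotic
  if (mp[1] <= ip[1])
    stop("mitotic location parameter must exceed the interphase one")
  if (is.null(names(mitoticFraction)))
    names(mitoticFraction) <- paste0("cond", seq_along(mitoticFraction))
  set.seed(as.integer(seed))
  out <- lapply(names(mitoticFraction), function(cond) {
    n <- nCellsPerCondition
    nMit <- round(mitoticFraction[[cond]] * n)
    isMit <- sample(c(rep(TRUE, nMit), rep(FALSE, n - nMit)))
    intensity <- numeric(n)
    intensity[isMit] <- rlnorm(nMit, mp[1], mp[2])
    intensity[!isMit] <- rlnorm(n - nMit, ip[1], ip[2])
    data.frame(condition = cond,
               well = paste0(cond, "_w", rep_len(seq_len(nWells), n)),
               max_intensity = intensity, is_mitotic = isMit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Render a synthetic nuclear image
#'
#' Places non-touching Gaussian nuclei on a dark background, for exercising
#' [measureNuclei()].  Nuclei are laid out on a jittered grid so they never
#' touch; each has a known peak intensity.
#'
#' @param peaks numeric vector of peak intensities, one per nucleus.
#' @param dim image dimensions (pixels).
#' @param sigma Gaussian radius (pixels).
#' @param background additive background level.
#' @param seed integer seed.
#' @return list with `image` (numeric matrix) and `truth` (data.frame `x`,
#'   `y`, `peak`).
#' @examples
#' img <- simulateNucleusImage(peaks = rep(1000, 4), dim = c(96, 96))
#' dim(img$image)
#' @export
simulateNucleusImage <- function(peaks, dim = c(256L, 256L), sigma = 4,
                                 background = 10, seed = 1) {
  set.seed(as.integer(seed))
  n <- length(peaks)
  cell <- ceiling(8 * sigma)  # grid pitch guaranteeing separation
  perRow <- max(1L, floor((dim[1] - cell) / cell))
  if (perRow^2 < n) stop("image too small for ", n, " non-touching nuclei")
  slots <- sample(seq_len(perRow^2), n)
  cx <- cell / 2 + cell * ((slots - 1) %% perRow) + cell / 2
  cy <- cell / 2 + cell * ((slots - 1) %/% perRow) + cell / 2
  # jitter by whole pixels and land on pixel centers, so each nucleus's
  # maximum pixel value equals its planted peak exactly
  cx <- round(cx + runif(n, -sigma, sigma))
  cy <- round(cy + runif(n, -sigma, sigma))
  img <- matrix(background, nrow = dim[1], ncol = dim[2])
  xs <- row(img); ys <- col(img)
  for (i in seq_len(n)) {
    img <- img + peaks[i] *
      exp(-((xs - cx[i])^2 + (ys - cy[i])^2) / (2 * sigma^2))
  }
  list(image = img,
       truth = data.frame(x = cx, y = cy, peak = peaks + background))
}
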