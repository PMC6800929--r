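## First-order texture statistics of the segmented nodule volume: the HU
## density histogram and its mean (MEN), variance (VAR), skewness (SKW) and
## excess kurtosis (KUR).

#' Build the HU density histogram of a segmented nodule
#'
#' Tallies the HU values of the masked voxels into bins of width
#' `bin_width` over `range` (default the segmentation inclusion interval
#' \eqn{[-450, +1500]} HU).  Bins are half-open `[edge, edge + width)`
#' except the last, which includes its upper edge.  For integer HU at unit
#' bin width the bin representative value equals the HU value itself, so
#' histogram-based moments agree exactly with voxel-based moments.
#'
#' @param volume a [ct_volume].
#' @param mask a `segmentation_result` (or logical lattice) selecting the
#'   nodule voxels.
#' @param bin_width bin width in HU (default 1).
#' @param range histogram support `(lo, hi)` in HU.
#' @return A `nodule_histogram` with fields `bin_edges` (length `G + 1`),
#'   `bin_centers`, `counts`, `H` (normalised frequencies, summing to 1),
#'   `G` and `n_voxels`.
#' @export
build_histogram <- function(volume, mask, bin_width = 1,
                            range = c(-450, 1500)) {
  stopifnot(inherits(volume, "ct_volume"))
  m <- if (inherits(mask, "segmentation_result")) mask$mask else mask
  x <- volume$voxels[m]
  if (length(x) == 0L) stop("empty segmentation")
  if (any(x < range[1] | x > range[2]))
    stop("masked voxels outside the histogram range")
  histogram_from_values(x, bin_width, range)
}

histogram_from_values <- function(x, bin_width = 1, range = c(-450, 1500)) {
  if (any(x < range[1] | x > range[2]))
    stop("values outside the histogram range")
  G <- ceiling((range[2] - range[1]) / bin_width)
  edges <- range[1] + bin_width * (0:G)
  idx <- pmin(floor((x - range[1]) / bin_width) + 1L, G)  # last bin closed
  counts <- tabulate(idx, nbins = G)
  # representative value: midpoint of the integer HU values a bin covers
  # when the width is integer (so width 1 => the value itself), else the
  # geometric bin midpoint
  centers <- if (bin_width == round(bin_width))
    edges[-(G + 1L)] + (bin_width - 1) / 2
  else edges[-(G + 1L)] + bin_width / 2
  structure(list(bin_edges = edges, bin_centers = centers,
                 counts = counts, H = counts / length(x),
                 G = G, n_voxels = length(x)),
            class = "nodule_histogram")
}

#' @export
print.nodule_histogram <- function(x, ...) {
  occ <- range(which(x$counts > 0))
  cat(sprintf("nodule_histogram: %d voxels in %d bins, occupied HU range [%g, %g]\n",
              x$n_voxels, x$G, x$bin_centers[occ[1]], x$bin_centers[occ[2]]))
  invisible(x)
}

hist_moment <- function(hist, k, center = 0)
  sum((hist$bin_centers - center)^k * hist$H)

#' First-order statistics of a nodule histogram
#'
#' `mean_hu` and `variance_hu` are the histogram-weighted mean and
#' population variance (no small-sample correction: the sums run over the
#' full voxel population of the nodule).  `skewness` is the third
#' standardised moment \eqn{\mu_3 / VAR^{3/2}} and `kurtosis` the excess
#' fourth standardised moment \eqn{\mu_4 / VAR^2 - 3}, so a Gaussian
#' scores 0, a peaked heavy-tailed (leptokurtic) histogram scores
#' positive, and a flat-topped (platykurtic) histogram scores negative.
#'
#' @param hist a `nodule_histogram`.
#' @param literal if `TRUE`, use the literal denominators `VAR^3` (SKW)
#'   and `VAR^4` (KUR) instead of the standardised-moment denominators.
#'   Audit-only compatibility mode; the default is the standard form.
#' @return A scalar: HU for `mean_hu`, HU^2 for `variance_hu`,
#'   dimensionless for `skewness`/`kurtosis`.
#' @name first_order
NULL

#' @rdname first_order
#' @export
mean_hu <- function(hist) {
  stopifnot(inherits(hist, "nodule_histogram"))
  hist_moment(hist, 1)
}

#' @rdname first_order
#' @export
variance_hu <- function(hist) {
  stopifnot(inherits(hist, "nodule_histogram"))
  hist_moment(hist, 2, mean_hu(hist))
}

#' @rdname first_order
#' @export
skewness <- function(hist, literal = FALSE) {
  stopifnot(inherits(hist, "nodule_histogram"))
  men <- mean_hu(hist); v <- hist_moment(hist, 2, men)
  if (v == 0) stop("degenerate distribution")
  mu3 <- hist_moment(hist, 3, men)
  if (literal) mu3 / v^3 else mu3 / v^1.5
}

#' @rdname first_order
#' @export
kurtosis <- function(hist, literal = FALSE) {
  stopifnot(inherits(hist, "nodule_histogram"))
  men <- mean_hu(hist); v <- hist_moment(hist, 2, men)
  if (v == 0) stop("degenerate distribution")
  mu4 <- hist_moment(hist, 4, men)
  if (literal) mu4 / v^4 - 3 else mu4 / v^2 - 3
}

#' All four first-order statistics from the voxel list
#'
#' Cross-check path: computes MEN, VAR, SKW and KUR directly from the
#' masked voxel values rather than through the histogram.  For integer HU
#' at unit bin width the two paths agree exactly.
#'
#' @param volume a [ct_volume].
#' @param mask a `segmentation_result` or logical lattice.
#' @return A `first_order_stats` list with fields `MEN`, `VAR`, `SKW`,
#'   `KUR` (excess).
#' @export
stats_from_voxels <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"))
  m <- if (inherits(mask, "segmentation_result")) mask$mask else mask
  x <- as.numeric(volume$voxels[m])
  if (length(x) == 0L) stop("empty segmentation")
  first_order_from_values(x)
}

first_order_from_values <- function(x) {
  men <- mean(x)
  v <- mean((x - men)^2)
  if (v == 0) stop("degenerate distribution")
  structure(list(MEN = men, VAR = v,
                 SKW = mean((x - men)^3) / v^1.5,
                 KUR = mean((x - men)^4) / v^2 - 3),
            class = "first_order_stats")
}

#' @rdname stats_from_voxels
#' @param hist a `nodule_histogram`.
#' @export
stats_from_histogram <- function(hist) {
  structure(list(MEN = mean_hu(hist), VAR = variance_hu(hist),
                 SKW = skewness(hist), KUR = kurtosis(hist)),
            class = "first_order_stats")
}

#' @export
print.first_order_stats <- function(x, ...) {
  cat(sprintf("first_order_stats: MEN %.2f HU, VAR %.2f, SKW %.3f, KUR %.3f (excess)\n",
              x$MEN, x$VAR, x$SKW, x$KUR))
  invisible(x)
}
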