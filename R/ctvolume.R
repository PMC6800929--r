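#' CT volume container
#'
#' A `ct_volume` holds a 3D lattice of Hounsfield-unit (HU) values together
#' with the physical voxel spacing and a free-form record of acquisition
#' metadata.  The voxel array is indexed `[x, y, z]` (0-based coordinates in
#' the seed/mask interfaces), with `x` the column direction, `y` the row
#' direction and `z` the slice axis.
#'
#' @param voxels 3D numeric array of HU values, dims `(nx, ny, nz)`.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm;
#'   all components must be strictly positive.
#' @param slice_thickness slice thickness in mm (defaults to `spacing[3]`).
#' @param metadata named list of acquisition metadata (kV, mA, kernel, ...).
#'
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `slice_thickness`, `matrix_size` (rows, cols) and `metadata`.
#' @export
ct_volume <- function(voxels, spacing, slice_thickness = spacing[3],
                      metadata = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (dx, dy, dz) in mm")
  if (!is.numeric(slice_thickness) || length(slice_thickness) != 1L ||
      slice_thickness <= 0)
    stop("slice_thickness must be a positive scalar (mm)")
  d <- dim(voxels)
  structure(list(
    voxels = voxels,
    spacing = spacing,
    slice_thickness = as.numeric(slice_thickness),
    matrix_size = c(rows = d[2], cols = d[1]),
    metadata = metadata
  ), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  slice thickness %.3g mm, HU range [%g, %g]\n",
              x$slice_thickness, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

hu_min_12bit <- -1024L
hu_max_12bit <- 3071L

#' Quantise a CT volume onto the 12-bit HU grid
#'
#' Clamps and rounds HU values onto the 4096 integer levels spanning
#' \eqn{[-1024, 3071]}, the stored range of 12-bit CT data.  Rounding is
#' half-away-from-zero so the mapping is deterministic across platforms.
#' The operation is idempotent and order preserving.
#'
#' @param volume a [ct_volume].
#' @return A [ct_volume] with integer HU values in `[-1024, 3071]`.
#' @export
quantize_12bit <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- round_half_away(volume$voxels)
  v[v < hu_min_12bit] <- hu_min_12bit
  v[v > hu_max_12bit] <- hu_max_12bit
  storage.mode(v) <- "integer"
  volume$voxels <- v
  volume
}

## round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Validate a volume against the acquisition protocol
#'
#' Checks the inclusion rules used for the study cohort: slice thickness in
#' \eqn{[0.90, 1.25]} mm and an in-plane matrix of 512 x 512 points.  All
#' violations are reported, not just the first.
#'
#' @param volume a [ct_volume].
#' @return A `protocol_report` list with fields `conformant` (logical) and
#'   `violations` (data.frame with columns `field`, `observed`, `required`).
#' @export
validate_protocol <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- list()
  st <- volume$slice_thickness
  if (st < 0.90 || st > 1.25)
    v[[length(v) + 1L]] <- data.frame(
      field = "slice_thickness", observed = format(st),
      required = "[0.90, 1.25] mm", stringsAsFactors = FALSE)
  ms <- volume$matrix_size
  if (ms[["rows"]] != 512L || ms[["cols"]] != 512L)
    v[[length(v) + 1L]] <- data.frame(
      field = "matrix_size",
      observed = sprintf("%dx%d", ms[["rows"]], ms[["cols"]]),
      required = "512x512", stringsAsFactors = FALSE)
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), observed = character(),
               required = character(), stringsAsFactors = FALSE)
  structure(list(conformant = nrow(violations) == 0L, violations = violations),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  if (x$conformant) cat("protocol_report: conformant\n")
  else {
    cat("protocol_report: NOT conformant\n")
    print(x$violations)
  }
  invisible(x)
}
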