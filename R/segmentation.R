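## Seeded 3D region growing inside a HU inclusion interval, plus the
## follow-up operations used in nodule volumetry.

neighbor_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26L) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
  } else stop("connectivity must be 6 or 26")
}

## breadth-first flood fill over a logical inclusion lattice, vectorised by
## frontier; dims = c(nx, ny, nz); seed_lin is a 1-based linear index
flood_fill <- function(include, dims, seed_lin, connectivity = 6L) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  offs <- neighbor_offsets(connectivity)
  lin_off <- offs[, 1] + offs[, 2] * nx + offs[, 3] * nx * ny
  visited <- logical(length(include))
  if (!include[seed_lin]) return(visited)
  visited[seed_lin] <- TRUE
  frontier <- seed_lin
  while (length(frontier)) {
    i0 <- frontier - 1L
    x <- i0 %% nx; rest <- i0 %/% nx
    y <- rest %% ny; z <- rest %/% ny
    cand <- integer(0)
    for (k in seq_len(nrow(offs))) {
      ok <- x + offs[k, 1] >= 0 & x + offs[k, 1] < nx &
            y + offs[k, 2] >= 0 & y + offs[k, 2] < ny &
            z + offs[k, 3] >= 0 & z + offs[k, 3] < nz
      cand <- c(cand, frontier[ok] + lin_off[k])
    }
    cand <- unique(cand)
    cand <- cand[include[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

new_segmentation_result <- function(mask, spacing, seed, hu_interval,
                                    connectivity) {
  n <- sum(mask)
  structure(list(
    mask = mask,
    voxel_count = as.integer(n),
    volume_mm3 = n * prod(spacing),
    spacing = spacing,
    seed = seed,
    hu_interval = hu_interval,
    connectivity = as.integer(connectivity)
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("segmentation_result: %d voxels, %.1f mm^3, ",
                     "HU interval [%g, %g], %d-connectivity\n"),
              x$voxel_count, x$volume_mm3, x$hu_interval[1], x$hu_interval[2],
              x$connectivity))
  invisible(x)
}

#' Seeded 3D region growing
#'
#' Grows a nodule mask from a seed voxel by iteratively adding neighbouring
#' voxels whose HU value lies inside the inclusion interval.  The default
#' interval of \eqn{[-450, +1500]} HU (endpoints inclusive) admits soft
#' tissue and calcification while excluding aerated lung, so the growth
#' stops at the nodule boundary.  The result is the maximal connected
#' in-interval component containing the seed and is deterministic for fixed
#' inputs.
#'
#' @param volume a [ct_volume].
#' @param seed integer length-3, 0-based voxel coordinates `(x, y, z)` with
#'   `z` the slice axis.
#' @param hu_interval inclusion interval `(lo, hi)` in HU, both endpoints
#'   inclusive.
#' @param connectivity 6 (face-adjacent, default) or 26 (face, edge and
#'   corner adjacent).
#' @param slice_range optional half-open slice window `(first, last)` in
#'   0-based slice indices; growth is restricted to slices
#'   `first <= z < last`.  Must contain the seed slice.
#' @return A `segmentation_result` with fields `mask` (logical lattice),
#'   `voxel_count`, `volume_mm3`, `spacing`, `seed`, `hu_interval`,
#'   `connectivity`.
#' @export
region_grow_3d <- function(volume, seed, hu_interval = c(-450, 1500),
                           connectivity = 6L, slice_range = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 0L) || any(seed >= d))
    stop("seed outside lattice bounds")
  if (length(hu_interval) != 2L || hu_interval[1] > hu_interval[2])
    stop("hu_interval must be (lo, hi) with lo <= hi")
  seed_hu <- volume$voxels[seed[1] + 1L, seed[2] + 1L, seed[3] + 1L]
  if (seed_hu < hu_interval[1] || seed_hu > hu_interval[2])
    stop("seed outside inclusion interval")
  include <- volume$voxels >= hu_interval[1] & volume$voxels <= hu_interval[2]
  if (!is.null(slice_range)) {
    slice_range <- as.integer(slice_range)
    if (length(slice_range) != 2L || slice_range[1] >= slice_range[2])
      stop("slice_range must be a half-open (first, last) with first < last")
    if (seed[3] < slice_range[1] || seed[3] >= slice_range[2])
      stop("slice_range does not contain the seed slice")
    z <- slice_range[1]:(slice_range[2] - 1L)
    keep <- array(FALSE, d)
    keep[, , z[z >= 0L & z < d[3]] + 1L] <- TRUE
    include <- include & keep
  }
  seed_lin <- 1L + seed[1] + seed[2] * d[1] + seed[3] * d[1] * d[2]
  mask <- flood_fill(as.vector(include), d, seed_lin, connectivity)
  new_segmentation_result(array(mask, d), volume$spacing, seed, hu_interval,
                          connectivity)
}

#' Subtract attached structures from a segmentation
#'
#' Removes voxels covered by an exclusion lattice (vessels, bronchi, scars
#' marked by a reader or taken from phantom ground truth), then keeps only
#' the connected component that still contains the seed, mirroring the
#' interactive subtraction step of the original workflow.
#'
#' @param result a `segmentation_result`.
#' @param exclusion logical lattice of the same shape as the mask; `TRUE`
#'   voxels are removed.
#' @param opening if `TRUE`, a morphological opening (6-neighbour ball of
#'   radius 1 voxel) is applied to the mask before subtraction to shave
#'   thin attachments automatically.  Off by default.
#' @return A new `segmentation_result` with updated mask, count and volume.
#' @export
subtract_structures <- function(result, exclusion, opening = FALSE) {
  stopifnot(inherits(result, "segmentation_result"))
  exclusion <- as.logical(exclusion)
  if (length(exclusion) != length(result$mask))
    stop("exclusion lattice shape does not match the mask")
  d <- dim(result$mask)
  mask <- result$mask
  if (opening) mask <- binary_opening6(mask)
  mask <- mask & !array(exclusion, d)
  seed <- result$seed
  seed_lin <- 1L + seed[1] + seed[2] * d[1] + seed[3] * d[1] * d[2]
  if (!mask[seed_lin]) stop("seed removed by subtraction")
  kept <- flood_fill(as.vector(mask), d, seed_lin, result$connectivity)
  new_segmentation_result(array(kept, d), result$spacing, seed,
                          result$hu_interval, result$connectivity)
}

## morphological opening with the 6-neighbour cross structuring element
binary_opening6 <- function(mask) {
  d <- dim(mask)
  shift <- function(m, dx, dy, dz, fill) {
    out <- array(fill, d)
    sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
    fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
    ok_x <- fx >= 1 & fx <= d[1]; ok_y <- fy >= 1 & fy <= d[2]
    ok_z <- fz >= 1 & fz <= d[3]
    out[sx[ok_x], sy[ok_y], sz[ok_z]] <- m[fx[ok_x], fy[ok_y], fz[ok_z]]
    out
  }
  offs <- neighbor_offsets(6L)
  er <- mask
  for (k in seq_len(nrow(offs)))
    er <- er & shift(mask, offs[k, 1], offs[k, 2], offs[k, 3], FALSE)
  di <- er
  for (k in seq_len(nrow(offs)))
    di <- di | shift(er, offs[k, 1], offs[k, 2], offs[k, 3], FALSE)
  di
}

#' Physical nodule volume
#'
#' @param result a `segmentation_result`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm; defaults to the
#'   spacing recorded in the result.
#' @return Volume in mm^3: `voxel_count * dx * dy * dz`.
#' @export
nodule_volume <- function(result, spacing = result$spacing) {
  stopifnot(inherits(result, "segmentation_result"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive numbers")
  result$voxel_count * prod(spacing)
}

#' Volume doubling time and radiological stability
#'
#' Computes the volume doubling time
#' \eqn{VDT = \Delta t \cdot \ln 2 / \ln(V_2 / V_1)} between two volumetric
#' measurements and applies the stability rule used to label a nodule
#' radiologically benign: a nodule is stable when it did not grow
#' (\eqn{V_2 \le V_1}, VDT reported as infinite) or when VDT exceeds
#' 2000 days.
#'
#' @param v1,v2 nodule volumes in mm^3 at the two time points; must be
#'   positive.
#' @param delta_t_days time between the scans in days; must be positive.
#' @return A `growth_assessment` list with fields `v1`, `v2`,
#'   `delta_t_days`, `vdt_days` and `stable`.
#' @export
volume_doubling_time <- function(v1, v2, delta_t_days) {
  if (!is.numeric(v1) || !is.numeric(v2) || !is.numeric(delta_t_days) ||
      v1 <= 0 || v2 <= 0 || delta_t_days <= 0)
    stop("v1, v2 and delta_t_days must be positive")
  vdt <- if (v2 <= v1) Inf else delta_t_days * log(2) / log(v2 / v1)
  structure(list(v1 = v1, v2 = v2, delta_t_days = delta_t_days,
                 vdt_days = vdt, stable = vdt > 2000 || v2 <= v1),
            class = "growth_assessment")
}

#' @export
print.growth_assessment <- function(x, ...) {
  cat(sprintf("growth_assessment: V1 %.1f -> V2 %.1f mm^3 over %g days; VDT %s days; %s\n",
              x$v1, x$v2, x$delta_t_days,
              if (is.finite(x$vdt_days)) sprintf("%.0f", x$vdt_days) else "Inf",
              if (x$stable) "stable (radiologically benign behaviour)"
              else "growing"))
  invisible(x)
}
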