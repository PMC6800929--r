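## Synthetic CT phantom nodules and cohorts.
##
## A phantom is a cropped ROI lattice of aerated-lung background (Gaussian
## noise around -800 HU, kept strictly below the -450 HU inclusion bound so
## segmentation is exact by construction), a smooth ellipsoidal nodule whose
## voxel intensities are drawn from the texture family of
## `texture_family_moments()`, and optionally a cylindrical vessel stub
## (in-interval HU) attached to the nodule surface to exercise structure
## subtraction.

## ---- reproducible seeding -------------------------------------------------

## MINSTD step, exact in doubles (48271 * 2^31 < 2^53)
mix31 <- function(x) (x * 48271) %% 2147483647

## counter-based seed splitting: one substream per (phantom index, stage),
## independent of generation order
phantom_seed <- function(master_seed, index, stream = 0L) {
  a <- mix31((abs(master_seed) %% 2147483646) + 1)
  b <- mix31((a + index * 2) %% 2147483646 + 1)
  as.integer(mix31((b + stream) %% 2147483646 + 1))
}

## evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rnorm_trunc1 <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)  # pathological bounds: fall back to the clamp
}

## ---- class profiles -------------------------------------------------------

#' Default texture calibration of a phantom class
#'
#' The class-level hyper-distributions from which per-nodule texture
#' parameters are drawn.  The per-nodule skewness target SKW* comes from
#' a truncated Gaussian whose spread is the published cohort standard
#' deviation (benign 0.94, malignant 1.01); the kurtosis target KUR* is
#' the moment-feasibility floor (SKW*^2 - 2 plus a margin) plus an
#' exponential excess, so every draw is an admissible distribution.  The
#' hyper-means were calibrated once by Monte Carlo so that the *sample*
#' moments of segmented phantom cohorts reproduce the published cohort
#' means (benign KUR 3.37 / SKW 1.73, malignant KUR 5.88 / SKW 2.07),
#' absorbing truncation effects and the finite-voxel-sample bias of the
#' moment estimators; the implied cohort SDs come out close to the
#' published ones without further tuning.  Malignant nodules get a
#' peaked (low beta) body concentrated in the 0-100 HU band; benign
#' nodules a broad flat-topped (high beta) body.
#'
#' @param label `"benign"` or `"malignant"`.
#' @return A list of hyper-parameters used by [generate_cohort()].
#' @export
class_profile <- function(label = c("benign", "malignant")) {
  label <- match.arg(label)
  if (label == "benign") list(
    label = "benign",
    skw_target = list(mean = 1.61, sd = 0.94, lo = 0.25, hi = 4.5),
    kur_target = list(gap_mean = 1.35, lo_margin = 0.3, gap_hi = 22),
    representative = list(skw = 1.73, kur = 3.37),
    body_beta = list(meanlog = log(5.5), sdlog = 0.38, lo = 0.8, hi = 16),
    location = list(mean = 25, sd = 10),
    scale = list(meanlog = log(40), sdlog = 0.18),
    sigma_t = 0.6,
    radius_mm = c(4.5, 10.5),
    vessel_prob = 0.5
  ) else list(
    label = "malignant",
    skw_target = list(mean = 1.99, sd = 1.01, lo = 0.25, hi = 5),
    kur_target = list(gap_mean = 2.45, lo_margin = 0.3, gap_hi = 28),
    representative = list(skw = 2.07, kur = 5.88),
    body_beta = list(meanlog = log(1.15), sdlog = 0.38, lo = 0.8, hi = 16),
    location = list(mean = 45, sd = 8),
    scale = list(meanlog = log(16), sdlog = 0.15),
    sigma_t = 0.6,
    radius_mm = c(4.5, 10.5),
    vessel_prob = 0.5
  )
}

## draw one nodule's texture parameters from a class profile
draw_texture <- function(profile) {
  skw <- rnorm_trunc1(profile$skw_target$mean, profile$skw_target$sd,
                      profile$skw_target$lo, profile$skw_target$hi)
  beta <- exp(rnorm_trunc1(profile$body_beta$meanlog, profile$body_beta$sdlog,
                           log(profile$body_beta$lo),
                           log(profile$body_beta$hi)))
  sol <- NULL
  for (try in 1:40) {
    ## the kurtosis target is the feasibility floor (KUR >= SKW^2 - 2 plus a
    ## margin) plus an exponential excess, so the excess is always
    ## admissible and its calibrated mean responds linearly
    kur_lo <- skw^2 - 2 + profile$kur_target$lo_margin
    kur <- kur_lo + min(stats::rexp(1, 1 / profile$kur_target$gap_mean),
                        profile$kur_target$gap_hi)
    cand <- solve_tail_params(beta, profile$sigma_t, skw, kur)
    if (is.null(sol) || cand$residual < sol$residual) {
      sol <- cand; sol$skw_target <- skw; sol$kur_target <- kur
    }
    if (sol$ok) break
    skw <- rnorm_trunc1(profile$skw_target$mean, profile$skw_target$sd,
                        profile$skw_target$lo, profile$skw_target$hi)
  }
  list(
    location = stats::rnorm(1, profile$location$mean, profile$location$sd),
    scale = exp(stats::rnorm(1, profile$scale$meanlog, profile$scale$sdlog)),
    beta = beta, p = sol$p, mu_t = sol$mu_t, sigma_t = profile$sigma_t,
    skw_target = sol$skw_target, kur_target = sol$kur_target,
    solve_residual = sol$residual)
}

#' A class-representative texture parameter set
#'
#' Texture parameters solved so the family's population skewness and
#' excess kurtosis equal the class's published cohort means (no
#' per-nodule variation); convenient for single-phantom examples and
#' oracle checks against [texture_family_moments()].
#'
#' @param label `"benign"` or `"malignant"`.
#' @return A texture parameter list (see [texture_family_moments()]).
#' @export
default_texture <- function(label = c("benign", "malignant")) {
  label <- match.arg(label)
  pr <- class_profile(label)
  sol <- solve_tail_params(exp(pr$body_beta$meanlog), pr$sigma_t,
                           pr$representative$skw, pr$representative$kur)
  list(location = pr$location$mean, scale = exp(pr$scale$meanlog),
       beta = exp(pr$body_beta$meanlog), p = sol$p, mu_t = sol$mu_t,
       sigma_t = pr$sigma_t,
       skw_target = pr$representative$skw, kur_target = pr$representative$kur,
       solve_residual = sol$residual)
}

## ---- phantom specification ------------------------------------------------

#' Specify a phantom nodule
#'
#' @param label `"benign"` or `"malignant"`.
#' @param radius_mm nodule radius in mm, in `(0, 15]` (a solitary
#'   pulmonary nodule is at most 3 cm across).
#' @param texture texture parameter list (default: the class
#'   representative from [default_texture()]).
#' @param center nodule centre in 0-based voxel coordinates (default:
#'   lattice centre).
#' @param dims lattice dimensions `(nx, ny, nz)`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param background_hu background level in HU (aerated lung, default
#'   -800; must stay below the -450 HU inclusion bound for segmentation
#'   to be exact by construction).
#' @param background_noise_sd background Gaussian noise SD in HU.
#' @param vessel `NULL`, or a list `(direction, radius_mm, hu)` with
#'   `direction` one of `"+x" "-x" "+y" "-y" "+z" "-z"`, describing a
#'   cylindrical vessel stub attached to the nodule surface.
#' @param rng_seed integer seed; phantoms are deterministic given the
#'   full spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(label, radius_mm, texture = default_texture(label),
                         center = NULL, dims = c(44L, 44L, 30L),
                         spacing = c(0.75, 0.75, 1.0),
                         background_hu = -800, background_noise_sd = 15,
                         vessel = NULL, rng_seed = 1L) {
  label <- match.arg(label, c("benign", "malignant"))
  if (!is.numeric(radius_mm) || radius_mm <= 0 || radius_mm > 15)
    stop("radius_mm must be in (0, 15]: an SPN is at most 3 cm across")
  dims <- as.integer(dims)
  if (is.null(center)) center <- (dims - 1) / 2
  spec <- structure(list(
    label = label, radius_mm = radius_mm, texture = texture,
    center = center, dims = dims, spacing = as.numeric(spacing),
    background_hu = background_hu,
    background_noise_sd = background_noise_sd,
    vessel = vessel, rng_seed = as.integer(rng_seed)), class = "phantom_spec")
  lo_mm <- center * spec$spacing - radius_mm
  hi_mm <- center * spec$spacing + radius_mm
  if (any(lo_mm < spec$spacing) || any(hi_mm > (dims - 2) * spec$spacing))
    stop("nodule does not fit inside the lattice")
  spec
}

## ---- phantom generation ---------------------------------------------------

ellipsoid_mask <- function(dims, spacing, center, radius_mm) {
  dx2 <- ((0:(dims[1] - 1) - center[1]) * spacing[1])^2
  dy2 <- ((0:(dims[2] - 1) - center[2]) * spacing[2])^2
  dz2 <- ((0:(dims[3] - 1) - center[3]) * spacing[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  d2 <= radius_mm^2
}

vessel_mask_for <- function(spec, nodule_mask) {
  v <- spec$vessel
  ax <- match(substr(v$direction, 2, 2), c("x", "y", "z"))
  sgn <- if (substr(v$direction, 1, 1) == "-") -1 else 1
  dims <- spec$dims; sp <- spec$spacing; ce <- spec$center
  co <- list(0:(dims[1] - 1), 0:(dims[2] - 1), 0:(dims[3] - 1))
  perp <- setdiff(1:3, ax)
  d2p <- list()
  for (a in perp) d2p[[length(d2p) + 1]] <- ((co[[a]] - ce[a]) * sp[a])^2
  along_ok <- if (sgn > 0) co[[ax]] >= ce[ax] else co[[ax]] <= ce[ax]
  grids <- vector("list", 3)
  grids[[perp[1]]] <- d2p[[1]]; grids[[perp[2]]] <- d2p[[2]]
  grids[[ax]] <- ifelse(along_ok, 0, Inf)
  d2 <- outer(outer(grids[[1]], grids[[2]], "+"), grids[[3]], "+")
  (d2 <= v$radius_mm^2) & !nodule_mask
}

#' Generate a phantom CT volume with ground truth
#'
#' Builds the CT lattice described by a [phantom_spec()]: Gaussian
#' background noise around `background_hu` (clamped below -550 HU so it
#' can never enter the segmentation interval), nodule voxels drawn
#' independently from the spec's texture family (clamped into
#' `[-449, 1499]` HU), and an optional vessel stub at in-interval HU.
#' Deterministic for a fixed spec.
#'
#' @param spec a `phantom_spec`.
#' @return A `phantom_truth` list: `volume` ([ct_volume]), `mask`
#'   (ground-truth nodule lattice), `vessel_mask`, `label`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  mask <- ellipsoid_mask(dims, spec$spacing, spec$center, spec$radius_mm)
  if (!any(mask)) stop("nodule radius below voxel size: empty ground truth")
  vmask <- if (!is.null(spec$vessel)) vessel_mask_for(spec, mask)
           else array(FALSE, dims)
  vol <- with_seed(spec$rng_seed, {
    bg <- stats::rnorm(prod(dims), spec$background_hu,
                       spec$background_noise_sd)
    bg <- pmin(round_half_away(bg), -550)
    v <- array(as.integer(bg), dims)
    v[mask] <- rtexture_hu(sum(mask), spec$texture)
    if (any(vmask)) v[vmask] <- as.integer(spec$vessel$hu)
    v
  })
  structure(list(
    volume = ct_volume(vol, spec$spacing, slice_thickness = spec$spacing[3],
                       metadata = list(kvp = 120, kernel = "PHANTOM")),
    mask = mask, vessel_mask = vmask, label = spec$label, spec = spec),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s nodule, radius %.1f mm, %d voxels%s\n",
              x$label, x$spec$radius_mm, sum(x$mask),
              if (any(x$vessel_mask)) " (+vessel)" else ""))
  invisible(x)
}

## ---- cohorts --------------------------------------------------------------

## build the spec for phantom `index` (1-based, benign first) of a cohort
cohort_spec <- function(index, label, master_seed, profile = NULL) {
  if (is.null(profile)) profile <- class_profile(label)
  with_seed(phantom_seed(master_seed, index, 1L), {
    radius <- stats::runif(1, profile$radius_mm[1], profile$radius_mm[2])
    dims <- c(44L, 44L, 30L)
    center <- (dims - 1) / 2 + stats::runif(3, -1.5, 1.5)
    texture <- draw_texture(profile)
    vessel <- if (stats::runif(1) < profile$vessel_prob)
      list(direction = sample(c("+x", "-x", "+y", "-y"), 1),
           radius_mm = 1.5, hu = 60)
    phantom_spec(label, radius, texture, center = center, dims = dims,
                 vessel = vessel,
                 rng_seed = phantom_seed(master_seed, index, 2L))
  })
}

#' Generate a phantom cohort
#'
#' Generates `n_benign` benign and `n_malignant` malignant phantoms with
#' per-nodule texture parameters drawn from the calibrated class
#' hyper-distributions ([class_profile()]) and per-nodule seeds split
#' reproducibly from `master_seed` (independent of generation order).
#' Geometry (radius, centre) and vessel attachment vary per nodule.
#'
#' @param n_benign,n_malignant cohort sizes (default 50 each, the study
#'   design); both must be >= 1.
#' @param master_seed integer master seed.
#' @return A list of `phantom_truth` objects, benign first.
#' @export
generate_cohort <- function(n_benign = 50L, n_malignant = 50L, master_seed) {
  if (n_benign < 1L || n_malignant < 1L)
    stop("cohort sizes must be >= 1")
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  lapply(seq_along(labels), function(i)
    generate_phantom(cohort_spec(i, labels[i], master_seed)))
}

#' Segment a phantom and extract its feature row
#'
#' Runs the analysis pipeline stages on one phantom: region growing from
#' a seed at the nodule centre with the default HU interval, subtraction
#' of the vessel ground truth, unit-width histogram, first-order
#' statistics and shape classification.
#'
#' @param truth a `phantom_truth`.
#' @param id identifier for the output row.
#' @param shape_threshold,shape_window,shape_rule forwarded to
#'   [classify_shape()].
#' @return One-row data.frame: `id`, `label`, `n_voxels`, `volume_mm3`,
#'   `MEN`, `VAR`, `SKW`, `KUR`, `shape_label`, `peakedness`.
#' @export
phantom_features <- function(truth, id = "phantom",
                             shape_threshold = 5.0, shape_window = 5L,
                             shape_rule = "ratio") {
  stopifnot(inherits(truth, "phantom_truth"))
  seg <- region_grow_3d(truth$volume, round(truth$spec$center))
  seg <- subtract_structures(seg, truth$vessel_mask)
  hist <- build_histogram(truth$volume, seg)
  st <- stats_from_histogram(hist)
  sh <- classify_shape(hist, smooth_window = shape_window,
                       threshold = shape_threshold, rule = shape_rule)
  data.frame(id = id, label = truth$label, n_voxels = seg$voxel_count,
             volume_mm3 = seg$volume_mm3, MEN = st$MEN, VAR = st$VAR,
             SKW = st$SKW, KUR = st$KUR, shape_label = sh$label,
             peakedness = sh$peakedness, stringsAsFactors = FALSE)
}

#' Feature table of a freshly simulated cohort
#'
#' Streams cohort generation and feature extraction (phantoms are
#' discarded after their feature row is computed, keeping memory flat for
#' large calibration cohorts).
#'
#' @inheritParams generate_cohort
#' @inheritParams phantom_features
#' @return data.frame with one [phantom_features()] row per nodule.
#' @export
cohort_feature_table <- function(n_benign = 50L, n_malignant = 50L,
                                 master_seed, shape_threshold = 5.0,
                                 shape_window = 5L, shape_rule = "ratio") {
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  rows <- lapply(seq_along(labels), function(i) {
    truth <- generate_phantom(cohort_spec(i, labels[i], master_seed))
    phantom_features(truth, id = sprintf("%s_%03d", labels[i], i),
                     shape_threshold = shape_threshold,
                     shape_window = shape_window, shape_rule = shape_rule)
  })
  do.call(rbind, rows)
}

## ---- growth pairs ---------------------------------------------------------

#' Generate a baseline/follow-up phantom pair with a target VDT
#'
#' The follow-up nodule's radius is scaled so the implied volume ratio is
#' \eqn{2^{\Delta t / VDT}}; running both phantoms through segmentation
#' and [volume_doubling_time()] recovers `vdt_days` up to voxelisation
#' error.  An infinite `vdt_days` yields an identical nodule volume.
#'
#' @param spec baseline `phantom_spec`.
#' @param vdt_days target volume doubling time (positive or `Inf`).
#' @param delta_t_days time between the two scans in days.
#' @return List of two `phantom_truth` objects (baseline, follow-up).
#' @export
generate_growth_pair <- function(spec, vdt_days, delta_t_days) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!(vdt_days > 0)) stop("vdt_days must be positive or infinite")
  if (delta_t_days <= 0) stop("delta_t_days must be positive")
  ratio <- if (is.finite(vdt_days)) 2^(delta_t_days / vdt_days) else 1
  r2 <- spec$radius_mm * ratio^(1 / 3)
  spec2 <- tryCatch(
    phantom_spec(spec$label, r2, spec$texture, center = spec$center,
                 dims = spec$dims, spacing = spec$spacing,
                 background_hu = spec$background_hu,
                 background_noise_sd = spec$background_noise_sd,
                 vessel = spec$vessel, rng_seed = spec$rng_seed),
    error = function(e) stop("growth exceeds lattice: ", conditionMessage(e)))
  list(generate_phantom(spec), generate_phantom(spec2))
}
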