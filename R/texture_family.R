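## Voxel-intensity distribution family for phantom nodules.
##
## A nodule's HU distribution is modelled as a two-component mixture in a
## dimensionless frame, then mapped to HU by an affine location/scale:
##
##   X = (1 - p) . body + p . tail
##
##   body ~ symmetric generalized Gaussian, density prop. to exp(-|x|^beta)
##          (beta < 2 peaked/leptokurtic, beta = 2 Gaussian, beta > 2
##          flat-topped/platykurtic)
##   tail ~ Normal(mu_t, sigma_t) with mu_t > 0, a small high-density
##          sub-population (denser tissue, microcalcification) that
##          carries the positive skew and the heavy right tail
##
## All raw moments are closed-form, so per-nodule (SKW, KUR) targets can
## be hit exactly at the population level by solving for (p, mu_t), and
## the analytic moments serve as the oracle for sampling tests.  The body
## shape beta controls the peak-vs-plateau appearance of the histogram
## quasi-independently of the tail-driven skewness/kurtosis.

## E|body|^r for the unit generalized Gaussian exp(-|x|^beta)
gn_abs_moment <- function(r, beta) gamma((r + 1) / beta) / gamma(1 / beta)

## raw moments 1..4 of the dimensionless mixture
mixture_raw_moments <- function(beta, p, mu_t, sigma_t) {
  b2 <- gn_abs_moment(2, beta); b4 <- gn_abs_moment(4, beta)
  t1 <- mu_t
  t2 <- mu_t^2 + sigma_t^2
  t3 <- mu_t^3 + 3 * mu_t * sigma_t^2
  t4 <- mu_t^4 + 6 * mu_t^2 * sigma_t^2 + 3 * sigma_t^4
  c((1 - p) * 0 + p * t1,
    (1 - p) * b2 + p * t2,
    (1 - p) * 0 + p * t3,
    (1 - p) * b4 + p * t4)
}

## central moments -> (mean, var, skew, excess kurtosis)
mixture_shape_moments <- function(beta, p, mu_t, sigma_t) {
  m <- mixture_raw_moments(beta, p, mu_t, sigma_t)
  mu <- m[1]
  v <- m[2] - mu^2
  mu3 <- m[3] - 3 * mu * m[2] + 2 * mu^3
  mu4 <- m[4] - 4 * mu * m[3] + 6 * mu^2 * m[2] - 3 * mu^4
  c(mean = mu, var = v, skew = mu3 / v^1.5, kurtosis = mu4 / v^2 - 3)
}

#' Analytic moments of a phantom texture
#'
#' Population mean/variance (HU, HU^2) and skewness/excess kurtosis of
#' the nodule voxel-intensity family for a given parameter set; the
#' oracle against which sampled phantom moments are checked.
#'
#' @param texture list with `location`, `scale` (HU), `beta` (body
#'   shape), `p` (tail weight), `mu_t`, `sigma_t` (tail position/width in
#'   body units).
#' @return Named numeric `mean`, `var`, `skew`, `kurtosis`.
#' @export
texture_family_moments <- function(texture) {
  s <- mixture_shape_moments(texture$beta, texture$p, texture$mu_t,
                             texture$sigma_t)
  c(mean = texture$location + texture$scale * s[["mean"]],
    var = texture$scale^2 * s[["var"]],
    skew = s[["skew"]], kurtosis = s[["kurtosis"]])
}

## Solve (p, mu_t) so the mixture's (skew, kurtosis) equal the targets,
## for fixed body shape and tail width.  Returns ok = FALSE when the
## target lies outside the family's reachable region.
solve_tail_params <- function(beta, sigma_t, target_skw, target_kur,
                              p_max = 0.4) {
  obj <- function(th) {
    p <- p_max * stats::plogis(th[1]); mu_t <- exp(th[2])
    s <- mixture_shape_moments(beta, p, mu_t, sigma_t)
    if (!all(is.finite(s))) return(1e6)
    (s[["skew"]] - target_skw)^2 + ((s[["kurtosis"]] - target_kur) / 4)^2
  }
  best <- NULL
  for (start in list(c(-2, log(3)), c(-3.5, log(5)), c(-1, log(2)),
                     c(-4.5, log(8)))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value < 1e-12) break
  }
  p <- p_max * stats::plogis(best$par[1]); mu_t <- exp(best$par[2])
  list(p = p, mu_t = mu_t, residual = sqrt(best$value),
       ok = best$value < 1e-8)
}

## sample n draws from the dimensionless mixture
rtexture_unit <- function(n, beta, p, mu_t, sigma_t) {
  tail <- stats::runif(n) < p
  n_t <- sum(tail)
  x <- numeric(n)
  if (n - n_t > 0) {
    g <- stats::rgamma(n - n_t, shape = 1 / beta, rate = 1)
    x[!tail] <- ifelse(stats::runif(n - n_t) < 0.5, -1, 1) * g^(1 / beta)
  }
  if (n_t > 0) x[tail] <- stats::rnorm(n_t, mu_t, sigma_t)
  x
}

## sample n HU values (integer, clamped into the inclusion interval)
rtexture_hu <- function(n, texture) {
  x <- texture$location +
    texture$scale * rtexture_unit(n, texture$beta, texture$p,
                                  texture$mu_t, texture$sigma_t)
  pmax.int(pmin.int(as.integer(round_half_away(x)), 1499L), -449L)
}
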