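#' Solution scattering profile by the Debye formula
#'
#' Orientation-averaged intensity of an atomic model in vacuum:
#' \deqn{I(q) = \sum_i \sum_j f_i f_j \frac{\sin(q r_{ij})}{q r_{ij}},}
#' with the i = j self terms contributing \eqn{f_i^2} (sinc(0) = 1). Form
#' factors are constant effective electron counts per element; no solvation
#' shell or excluded-volume term is included, so absolute intensities are
#' vacuum values — downstream fitting absorbs the scale.
#'
#' Two evaluation paths are provided: \code{"direct"} sums over all atom
#' pairs; \code{"binned"} histograms the pairwise distances on a fine grid
#' first (pair-distance distribution), cutting the cost for large models
#' while agreeing with the direct path to ~1e-6 relative at the default bin
#' width.
#'
#' @param model An [atomic_model()].
#' @param q A [q_grid()] or increasing numeric vector (default 170 points,
#'   0.08–1.5 Å\eqn{^{-1}}).
#' @param method \code{"direct"} or \code{"binned"}.
#' @param bin_width Distance-histogram resolution in Å for the binned path.
#' @return A \code{radial_profile} of theoretical intensities (positive for
#'   any finite model).
#' @export
debye_profile <- function(model, q = q_grid(), method = c("direct", "binned"),
                          bin_width = 1e-4) {
  method <- match.arg(method)
  grid <- as_q_grid(q)
  qv <- grid$values
  f <- model$weight
  n <- length(f)
  self <- sum(f^2)
  if (n == 1) return(radial_profile(grid, rep(self, length(qv))))
  if (method == "direct") {
    d <- as.matrix(dist(model$coords))
    iu <- upper.tri(d)
    r <- d[iu]
    ff <- (f %o% f)[iu]
    qr <- outer(qv, r)            # nq x npairs
    cross <- as.numeric((sin(qr) / qr) %*% ff)
  } else {
    r <- as.numeric(dist(model$coords))
    # dist() enumerates the lower triangle column-major; align the weights
    ff <- (f %o% f)[lower.tri(diag(n))]
    # histogram pair distances; evaluate sinc at bin-center distances
    breaks <- seq(0, max(r) + bin_width, by = bin_width)
    idx <- findInterval(r, breaks)
    w <- rowsum(ff, idx)
    rc <- (breaks[as.integer(rownames(w))] + bin_width / 2)
    qr <- outer(qv, rc)
    cross <- as.numeric((sin(qr) / qr) %*% w)
  }
  radial_profile(grid, self + 2 * cross)
}

#' Radius of gyration of an atomic model
#'
#' Weight-averaged RMS distance from the scattering-weighted centroid:
#' \eqn{R_g^2 = \sum_i f_i \|x_i - \bar x_f\|^2 / \sum_i f_i}.
#'
#' @param model An [atomic_model()].
#' @return Rg in Å (0 for a single atom).
#' @export
radius_of_gyration <- function(model) {
  f <- model$weight
  ctr <- colSums(model$coords * f) / sum(f)
  d2 <- rowSums(sweep(model$coords, 2, ctr)^2)
  sqrt(sum(f * d2) / sum(f))
}

#' Guinier estimate of Rg from a scattering profile
#'
#' Linear fit of \eqn{\ln I} vs \eqn{q^2} over the Guinier regime
#' \eqn{qR_g < q_rg_max}; the slope is \eqn{-R_g^2/3}. The fit window is
#' found by one round of iteration from an initial estimate using the full
#' low-q range.
#'
#' @param profile A \code{radial_profile}.
#' @param q_rg_max Upper limit of the dimensionless product qRg (default 1.0).
#' @return Estimated Rg in Å.
#' @export
guinier_rg <- function(profile, q_rg_max = 1.0) {
  qv <- profile$q$values
  I <- profile$intensity
  ok <- is.finite(I) & I > 0
  fit_rg <- function(sel) {
    if (sum(sel) < 3) stop("too few points in the Guinier window")
    co <- stats::coef(stats::lm(log(I[sel]) ~ I(qv[sel]^2)))
    slope <- unname(co[2])
    if (slope >= 0) stop("non-negative Guinier slope; no decaying low-q regime")
    sqrt(-3 * slope)
  }
  rg <- fit_rg(ok & qv <= stats::quantile(qv, 0.25))
  fit_rg(ok & qv * rg <= q_rg_max)
}

#' Theoretical difference scattering between two models
#'
#' \eqn{\Delta S_{model}(q) = I_{candidate}(q) - I_{native}(q)}, both
#' computed by [debye_profile()] on the same grid.
#'
#' @param candidate,native [atomic_model()]s.
#' @param q Common q grid.
#' @param ... Passed to [debye_profile()].
#' @return A \code{radial_profile} of the difference (signed).
#' @export
model_difference <- function(candidate, native, q = q_grid(), ...) {
  grid <- as_q_grid(q)
  ic <- debye_profile(candidate, grid, ...)
  iv <- debye_profile(native, grid, ...)
  radial_profile(grid, ic$intensity - iv$intensity)
}
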