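#' Robin-boundary eigenvalues for the 1D series solutions
#'
#' Positive roots of the transcendental eigenvalue conditions for transient
#' conduction with a convective (Robin) boundary:
#' cylinder, `x * J1(x) = Bi * J0(x)`; slab, `x * sin(x) = Bi * cos(x)`.
#' Roots are bracketed by scanning for sign changes (the roots are separated
#' by approximately pi) and polished with [stats::uniroot()].
#'
#' @param kind `"cylinder"` or `"slab"`.
#' @param Bi Biot number (> 0).
#' @param n_terms Number of eigenvalues requested.
#' @return Increasing numeric vector of length `n_terms`.
#' @export
robin_eigenvalues <- function(kind = c("cylinder", "slab"), Bi, n_terms) {
  kind <- match.arg(kind)
  if (!is.finite(Bi) || Bi <= 0) stop("Bi must be > 0", call. = FALSE)
  if (n_terms < 1) stop("n_terms must be >= 1", call. = FALSE)
  f <- switch(kind,
    cylinder = function(x) x * besselJ(x, 1) - Bi * besselJ(x, 0),
    slab     = function(x) x * sin(x) - Bi * cos(x))
  upper <- (n_terms + 2) * pi
  xs <- seq(1e-8, upper, by = 0.01)
  fs <- f(xs)
  sc <- which(diff(sign(fs)) != 0)
  if (length(sc) < n_terms)
    stop(sprintf(
      "eigenvalue search: only %d sign changes found in (0, %.1f]",
      length(sc), upper), call. = FALSE)
  vapply(sc[seq_len(n_terms)], function(i) {
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-13)$root
  }, numeric(1))
}

#' Analytic finite-cylinder transient temperature (verification oracle)
#'
#' Separation-of-variables product solution for a finite cylinder of radius
#' R and half-length L_h, initially uniform at `T0`, suddenly exposed on the
#' lateral and end surfaces to a medium at `Tp` with constant heat-transfer
#' coefficient `h` (symmetry at the axis and mid-plane):
#' `T = Tp + (T0 - Tp) * Theta_cyl(r, t) * Theta_slab(z, t)`,
#' where each factor is the Robin-boundary eigenfunction series of the
#' infinite cylinder and the symmetric slab. Implemented independently of
#' the finite-volume solver; used as its verification oracle on
#' single-stage constant-coefficient problems.
#'
#' Truncation: the slab factor converges slowly at very small times
#' (Fourier number below about 1e-4); the default 300 terms keeps the
#' truncation error negligible for t of a few minutes and longer on the
#' packaged geometry.
#'
#' @param geometry A [cyl_geometry()].
#' @param props A [thermo_props()].
#' @param h Constant heat-transfer coefficient (W/(m^2 K)).
#' @param Tp Constant medium temperature (K).
#' @param T0 Uniform initial temperature (K).
#' @param t Time(s) (s), vectorized.
#' @param r,z Evaluation point, r in `[0, R]`, z measured from the mid-plane
#'   in `[0, L_h]`. Defaults to the product centre.
#' @param n_terms Series terms per factor (>= 10).
#' @return Temperature (K), vectorized over `t`.
#' @export
#' @examples
#' g <- cyl_geometry(0.0425, 0.27)
#' p <- thermo_props(1064.5, 3535.5, 0.47)
#' analytic_finite_cylinder(g, p, h = 2000, Tp = 351.15, T0 = 280.65,
#'                          t = c(600, 3600))
analytic_finite_cylinder <- function(geometry, props, h, Tp, T0, t,
                                     r = 0, z = 0, n_terms = 300) {
  if (n_terms < 10) stop("n_terms must be >= 10", call. = FALSE)
  R <- geometry$radius; Lh <- geometry$half_length
  if (r < 0 || r > R || z < 0 || z > Lh)
    stop("evaluation point outside the domain", call. = FALSE)
  alpha <- props$alpha
  lam <- robin_eigenvalues("cylinder", h * R / props$k, n_terms)
  Ccyl <- 2 * (h * R / props$k) /
    ((lam^2 + (h * R / props$k)^2) * besselJ(lam, 0))
  Jr <- besselJ(lam * r / R, 0)
  mu <- robin_eigenvalues("slab", h * Lh / props$k, n_terms)
  Cslab <- 2 * sin(mu) / (mu + sin(mu) * cos(mu))
  cz <- cos(mu * z / Lh)
  vapply(t, function(tt) {
    if (tt < 0) stop("t must be >= 0", call. = FALSE)
    th_c <- sum(Ccyl * Jr * exp(-lam^2 * alpha * tt / R^2))
    th_s <- sum(Cslab * cz * exp(-mu^2 * alpha * tt / Lh^2))
    Tp + (T0 - Tp) * th_c * th_s
  }, numeric(1))
}
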