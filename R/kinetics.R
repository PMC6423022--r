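#' Adsorption kinetics parameters
#'
#' Rates of the adsorption kinetics ODE
#' \eqn{d\theta/dt = k_a n B(\theta) - k_d \theta}.  Defaults are typical
#' albumin values: \eqn{k_a = 10^4} L mol^-1 s^-1 and
#' \eqn{k_d = 5.78\times10^{-4}} s^-1, giving
#' \eqn{K_{eq} = k_a / k_d = 1.73\times10^7} L/mol.
#'
#' @param k_a adsorption rate constant (L mol^-1 s^-1).
#' @param k_d desorption rate constant (s^-1).
#' @param n bulk protein concentration (mol/L); the ODE assumes adsorption
#'   does not deplete the bulk.
#' @return An object of class \code{kinetics_spec} with the derived
#'   \code{K_eq}.
#' @export
kinetics_spec <- function(k_a = 1e4, k_d = 5.78e-4, n = 5.3e-4) {
  if (k_a < 0 || k_d < 0 || n < 0)
    stop("domain error: rates and concentration must be non-negative")
  structure(list(k_a = k_a, k_d = k_d, n = n,
                 K_eq = if (k_d > 0) k_a / k_d else Inf),
            class = "kinetics_spec")
}

## internal: turn a blocking description into a clamped function of theta.
## Accepts a blocking_fit, a list(coef, theta_inf), or a bare function.
## Polynomial forms are clamped to zero below and beyond theta_inf (the
## first positive root), the physical monotone-decay reading of a fit that
## is only valid on the observed coverage range.
blocking_as_function <- function(blocking) {
  if (is.function(blocking)) return(list(B = blocking, theta_inf = NA_real_))
  cf <- blocking$coef
  theta_inf <- blocking$theta_inf
  if (is.null(theta_inf) || is.na(theta_inf)) theta_inf <- first_positive_root(cf)
  if (is.na(theta_inf))
    stop("blocking polynomial has no positive root: cannot define theta_inf")
  B <- function(theta) {
    val <- drop(outer(theta, seq_along(cf) - 1, "^") %*% cf)
    ifelse(theta >= theta_inf, 0, pmax(val, 0))
  }
  list(B = B, theta_inf = theta_inf)
}

#' Solve the adsorption kinetics ODE
#'
#' Integrates \eqn{d\theta/dt = k_a n B(\theta) - k_d \theta} from
#' \eqn{\theta(0) = 0} with an adaptive solver (relative tolerance 1e-8).
#' The blocking polynomial is clamped to zero below and beyond its first
#' positive root \eqn{\theta_\infty}.
#'
#' @param spec a \code{kinetics_spec}.
#' @param blocking a \code{\link{fit_blocking_poly}} result, a
#'   \code{list(coef, theta_inf)} with polynomial coefficients
#'   \code{c(c0, c1, ...)}, or a function of theta.
#' @param t_end integration end time (s).
#' @param n_out number of output times.
#' @return An object of class \code{kinetics_trajectory}: data frame
#'   \code{t}, \code{theta} with the \code{plateau} value (final theta) as
#'   an attribute and in the returned list.
#' @examples
#' # Langmuir blocking B = theta_inf - theta has the closed form
#' # theta(t) = theta_inf * (1 - exp(-k_a n t)) when k_d = 0
#' sp <- kinetics_spec(k_a = 1e4, k_d = 0, n = 1e-4)
#' tr <- solve_kinetics(sp, list(coef = c(0.5, -1), theta_inf = 0.5), t_end = 10)
#' @export
solve_kinetics <- function(spec, blocking, t_end, n_out = 500L) {
  stopifnot(inherits(spec, "kinetics_spec"))
  if (t_end <= 0) stop("domain error: t_end must be > 0")
  bl <- blocking_as_function(blocking)
  rhs <- function(t, y, parms)
    list(spec$k_a * spec$n * bl$B(y[1]) - spec$k_d * y[1])
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = c(theta = 0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-8, atol = 1e-12)
  traj <- data.frame(t = sol[, 1], theta = sol[, 2])
  structure(list(trajectory = traj, plateau = traj$theta[nrow(traj)],
                 theta_inf = bl$theta_inf, spec = spec),
            class = "kinetics_trajectory")
}

#' Langmuir adsorption isotherm
#'
#' \deqn{\theta = \frac{K_{eq} n}{1 + K_{eq} n} \theta_\infty}
#'
#' @param spec a \code{kinetics_spec} (supplies \code{K_eq}).
#' @param theta_inf saturation coverage.
#' @param n bulk concentration(s) in mol/L; defaults to \code{spec$n}.
#' @return Equilibrium coverage(s).
#' @export
langmuir_isotherm <- function(spec, theta_inf, n = spec$n) {
  stopifnot(inherits(spec, "kinetics_spec"))
  K <- spec$K_eq
  ifelse(n == 0, 0, K * n / (1 + K * n) * theta_inf)
}

#' Steady-state RSA isotherm
#'
#' Solves the fixed-point condition \eqn{k_a n B(\theta) = k_d \theta} of
#' the kinetics ODE by bisection on \eqn{[0, \theta_\infty]}, for each
#' concentration.
#'
#' @param spec a \code{kinetics_spec} with \code{k_d > 0}.
#' @param blocking as in \code{\link{solve_kinetics}} (polynomial forms
#'   required so \eqn{\theta_\infty} is defined).
#' @param n bulk concentration(s) in mol/L.
#' @return Steady-state coverage(s), one per concentration.
#' @export
rsa_isotherm <- function(spec, blocking, n = spec$n) {
  stopifnot(inherits(spec, "kinetics_spec"))
  if (spec$k_d <= 0) stop("domain error: rsa_isotherm requires k_d > 0")
  bl <- blocking_as_function(blocking)
  if (is.na(bl$theta_inf))
    stop("root error: blocking function has no defined theta_inf")
  vapply(n, function(ni) {
    if (ni == 0) return(0)
    f <- function(th) spec$k_a * ni * bl$B(th) - spec$k_d * th
    if (f(0) <= 0) return(0)
    uniroot(f, c(0, bl$theta_inf), tol = .Machine$double.eps)$root
  }, numeric(1))
}

#' Diffusion timescale of protein supply to the surface
#'
#' The interaction length \eqn{h} follows from equating the protein number
#' needed to cover the surface, \eqn{A/\sigma}, with the number in the slab
#' of thickness \eqn{h} at bulk density \eqn{n}: \eqn{A/\sigma = n h A},
#' so \eqn{h = 1/(n\sigma)}.  The diffusion timescale is
#' \deqn{\tau_D = h^2 / D_{dif} = \frac{1}{n^2 \sigma^2 D_{dif}}}
#' with \eqn{n} in molecules per m^3 and \eqn{\sigma} in m^2.
#' Optionally the adsorption timescale \eqn{\tau_a} (time for the kinetics
#' ODE to reach 99\% of its plateau) is computed for comparison.
#'
#' @param protein a \code{protein_model}.
#' @param n bulk concentration in mol/L; must be positive.
#' @param spec,blocking optionally, kinetics parameters and a blocking
#'   description; when both are given \code{tau_a} is estimated.
#' @param t_end integration horizon for the \code{tau_a} estimate (s).
#' @return An object of class \code{timescale_estimate} with \code{h} (m),
#'   \code{tau_D} (s) and \code{tau_a} (s, or \code{NA}).
#' @examples
#' diffusion_timescale(protein_model(), n = 1.06e-5)  # tau_D ~ 0.77 s
#' @export
diffusion_timescale <- function(protein, n, spec = NULL, blocking = NULL,
                                t_end = 1e3) {
  stopifnot(inherits(protein, "protein_model"))
  if (n <= 0) stop("domain error: concentration must be > 0")
  avogadro <- 6.02214076e23
  n_m3 <- n * 1e3 * avogadro             # mol/L -> molecules per m^3
  sigma_m2 <- protein$sigma * 1e-18      # nm^2 -> m^2
  h <- 1 / (n_m3 * sigma_m2)
  tau_D <- h^2 / protein$D_dif
  tau_a <- NA_real_
  if (!is.null(spec) && !is.null(blocking)) {
    tr <- solve_kinetics(spec, blocking, t_end = t_end, n_out = 2000L)
    hit <- which(tr$trajectory$theta >= 0.99 * tr$plateau)
    if (length(hit)) tau_a <- tr$trajectory$t[hit[1]]
  }
  structure(list(h = h, tau_D = tau_D, tau_a = tau_a, n = n),
            class = "timescale_estimate")
}

#' @export
print.timescale_estimate <- function(x, ...) {
  cat(sprintf("<timescale_estimate: n = %.3g mol/L, h = %.3g m, tau_D = %.3g s",
              x$n, x$h, x$tau_D))
  if (!is.na(x$tau_a)) cat(sprintf(", tau_a = %.3g s", x$tau_a))
  cat(">\n")
  invisible(x)
}
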