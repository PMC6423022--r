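#' Specification of a synthetic black-silicon-like spike field
#'
#' Parameters of the random rough-surface generator that emulates an AFM
#' scan of a black-silicon (bSi) spike array: a Poisson field of spike
#' centres thinned to a minimum separation, truncated Gaussian profiles
#' with jittered height and width, and a morphological dilation by a
#' spherical AFM tip that reproduces the tip-convolution smoothing of real
#' scans.  Defaults mimic the nominal bSi spike dimensions (height around
#' 500 nm, width at half height around 60 nm, 10\% jitter).
#'
#' @param extent lateral extent of the square periodic field (nm).
#' @param density spike density (per square micrometre).
#' @param height_mean,height_sd spike height distribution (nm);
#'   \code{height_mean} is signed -- negative for a field of pits (deep
#'   valleys) instead of spikes.
#' @param width_mean,width_sd width-at-half-height distribution (nm).
#' @param min_separation minimum spike centre separation (nm).
#' @param tip_radius AFM tip radius for the dilation (nm); 0 disables.
#' @param dx grid spacing of the generated map (nm).
#' @param seed RNG seed; the field is reproducible from it.
#' @return An object of class \code{synthetic_bsi_spec}.
#' @export
synthetic_bsi_spec <- function(extent = 1000, density = 80,
                               height_mean = 500, height_sd = 50,
                               width_mean = 60, width_sd = 6,
                               min_separation = 60, tip_radius = 10,
                               dx = 5, seed = 1L) {
  vals <- c(extent = extent, width_mean = width_mean,
            min_separation = min_separation, dx = dx)
  if (any(vals <= 0)) stop("invalid specification: all scales must be positive")
  if (height_mean == 0) stop("invalid specification: height_mean must be nonzero (signed: negative for pits)")
  if (density < 0 || height_sd < 0 || width_sd < 0 || tip_radius < 0)
    stop("invalid specification: negative parameter")
  structure(list(extent = extent, density = density,
                 height_mean = height_mean, height_sd = height_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 min_separation = min_separation, tip_radius = tip_radius,
                 dx = dx, seed = as.integer(seed)),
            class = "synthetic_bsi_spec")
}

#' Generate a synthetic bSi-like height map
#'
#' Spike centres are Poisson-sampled over the periodic field and thinned to
#' the minimum separation; each centre carries a truncated Gaussian profile
#' with height and width drawn from the specified distributions; profiles
#' are superimposed additively; finally the field is dilated by a spherical
#' tip of the given radius (an upper envelope, \eqn{z'(x) = \max_o [z(x+o)
#' + \sqrt{R^2 - |o|^2}] - R}), emulating AFM tip smoothing.
#'
#' @param spec a \code{\link{synthetic_bsi_spec}}.
#' @return A \code{\link{height_field}} of extent \code{spec$extent}.
#' @export
generate_synthetic_bsi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bsi_spec"))
  set.seed(spec$seed)
  L <- spec$extent
  n_target <- rpois(1, spec$density * (L / 1000)^2)
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n_target) {
    tries <- tries + 1L
    if (tries > 200L * max(n_target, 1L))
      stop("generation error: spike density too high for the minimum separation")
    px <- runif(1, 0, L); py <- runif(1, 0, L)
    if (length(cx)) {
      ddx <- abs(px - cx); ddx <- pmin(ddx, L - ddx)
      ddy <- abs(py - cy); ddy <- pmin(ddy, L - ddy)
      if (min(ddx^2 + ddy^2) < spec$min_separation^2) next
    }
    cx <- c(cx, px); cy <- c(cy, py)
  }
  # signed heights: magnitudes jittered about |mean|, sign preserved
  # (negative height_mean gives a field of pits rather than spikes)
  H <- sign(spec$height_mean) *
    pmax(abs(rnorm(n_target, abs(spec$height_mean), spec$height_sd)),
         0.2 * abs(spec$height_mean))
  W <- pmax(abs(rnorm(n_target, spec$width_mean, spec$width_sd)),
            0.2 * spec$width_mean)

  n <- max(4L, as.integer(round(L / spec$dx)))
  dx <- L / n
  z <- matrix(0, n, n)
  xs <- (seq_len(n) - 1L) * dx
  for (k in seq_along(cx)) {
    v <- (W[k] / 2)^2 / (2 * log(2))
    r_cut <- 2.5 * sqrt(v)            # profile ~ 4% of H at the cut
    ddx <- abs(xs - cx[k]); ddx <- pmin(ddx, L - ddx)
    ddy <- abs(xs - cy[k]); ddy <- pmin(ddy, L - ddy)
    ii <- which(ddx <= r_cut); jj <- which(ddy <= r_cut)
    if (!length(ii) || !length(jj)) next
    r2 <- outer(ddx[ii]^2, ddy[jj]^2, "+")
    add <- H[k] * exp(-r2 / (2 * v))
    add[r2 > r_cut^2] <- 0
    z[ii, jj] <- z[ii, jj] + add
  }

  if (spec$tip_radius > 0 && length(cx)) {
    R <- spec$tip_radius
    m <- floor(R / dx)
    zd <- z
    for (oi in -m:m) for (oj in -m:m) {
      d2 <- (oi * dx)^2 + (oj * dx)^2
      if (d2 > R^2) next
      shifted <- z[(((seq_len(n) - 1L + oi) %% n) + 1L),
                   (((seq_len(n) - 1L + oj) %% n) + 1L)]
      zd <- pmax(zd, shifted + sqrt(R^2 - d2))
    }
    z <- zd - R
    z <- z - min(z)                   # keep the valley floor at z = 0
  }
  height_field(z, dx = dx, dy = dx)
}
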