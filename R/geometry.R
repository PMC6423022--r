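#' Specification of a periodic Gaussian nanostructure array
#'
#' Describes a square lattice of axisymmetric features with a truncated
#' Gaussian height profile
#' \deqn{f_i(x, y) = H \exp\!\left(-\frac{(x - x_i)^2 + (y - y_i)^2}{2 v}\right)}
#' for lateral distances up to \eqn{d_p/2} from the peak centre
#' \eqn{(x_i, y_i)} and zero beyond.  The variance is tied to the width at
#' half height, \eqn{v = (W/2)^2 / (2 \ln 2)}, so the profile at lateral
#' distance \eqn{W/2} is exactly \eqn{H/2}.  A negative \eqn{H} describes a
#' hole rather than a pillar or spike.
#'
#' @param H signed feature height in nm (negative for a hole).
#' @param W width at half height in nm; must be positive.
#' @param d_p peak-to-peak lattice spacing in nm; must be positive.
#' @return An object of class \code{gaussian_array_spec} with fields
#'   \code{H}, \code{W}, \code{d_p} and the derived variance \code{v} (nm^2).
#' @examples
#' sp <- gaussian_array_spec(H = 500, W = 60, d_p = 200)
#' sp$v  # (W/2)^2 / (2 log 2)
#' @export
gaussian_array_spec <- function(H, W, d_p) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H))
    stop("invalid specification: H must be a finite number (nm)")
  if (!is.numeric(W) || length(W) != 1L || !is.finite(W) || W <= 0)
    stop("invalid specification: width at half height W must be > 0")
  if (!is.numeric(d_p) || length(d_p) != 1L || !is.finite(d_p) || d_p <= 0)
    stop("invalid specification: peak spacing d_p must be > 0")
  structure(
    list(H = as.numeric(H), W = as.numeric(W), d_p = as.numeric(d_p),
         v = (W / 2)^2 / (2 * log(2))),
    class = "gaussian_array_spec"
  )
}

#' Gridded height map
#'
#' A rectangular grid of surface heights, as produced by an AFM scan.
#' Node \code{(i, j)} (1-based) sits at lateral position
#' \code{((i-1)*dx, (j-1)*dy)}; the map is treated as one periodic tile of
#' extent \code{nx*dx} by \code{ny*dy}.
#'
#' @param z numeric matrix of heights in nm, \code{nx} rows (x index) by
#'   \code{ny} columns (y index); all entries must be finite and both
#'   dimensions at least 4.
#' @param dx,dy grid spacings in nm; must be positive.
#' @return An object of class \code{height_field}.
#' @export
height_field <- function(z, dx, dy = dx) {
  z <- as.matrix(z)
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("invalid data: height map contains non-finite entries")
  if (nrow(z) < 4L || ncol(z) < 4L)
    stop("invalid data: height map must be at least 4 x 4")
  if (!is.numeric(dx) || dx <= 0 || !is.numeric(dy) || dy <= 0)
    stop("invalid data: grid spacings dx, dy must be > 0")
  structure(
    list(nx = nrow(z), ny = ncol(z), dx = as.numeric(dx), dy = as.numeric(dy),
         z = unname(z)),
    class = "height_field"
  )
}

## internal: build the list handed to the C++ evaluator
surface_cpp_spec <- function(surface) surface$cpp

## internal: assemble an rsa_surface object
new_surface <- function(type, Lx, Ly, cpp, w_max, spec = NULL, periodic = TRUE) {
  structure(
    list(type = type, Lx = Lx, Ly = Ly, spec = spec, w_max = w_max,
         periodic = periodic, cpp = cpp),
    class = "rsa_surface"
  )
}

#' Flat reference substrate
#'
#' @param Lx,Ly lateral cell extents in nm.
#' @return An \code{rsa_surface} with \eqn{f \equiv 0}.
#' @export
flat_surface <- function(Lx = 500, Ly = Lx) {
  if (Lx <= 0 || Ly <= 0) stop("invalid specification: cell extents must be > 0")
  cpp <- list(type_code = 0L, Lx = as.numeric(Lx), Ly = as.numeric(Ly))
  new_surface("flat", Lx, Ly, cpp, w_max = 1)
}

#' Build a periodic Gaussian-array substrate
#'
#' Tiles the truncated Gaussian profile of a \code{\link{gaussian_array_spec}}
#' on a square lattice, one peak per \code{d_p} by \code{d_p} cell.  The
#' analytic gradient of the Gaussian is used inside the truncation circle and
#' set to zero outside, where the profile is identically zero.  The surface is
#' periodic in x and y with period \code{cells * d_p}.
#'
#' @param spec a \code{\link{gaussian_array_spec}}.
#' @param cells integer pair (or scalar): number of lattice cells per side.
#' @return An \code{rsa_surface}.
#' @examples
#' s <- make_gaussian_surface(gaussian_array_spec(200, 80, 150), cells = 2)
#' surface_eval(s, 75, 75)  # peak centre: height 200, zero gradient
#' @export
make_gaussian_surface <- function(spec, cells = c(1L, 1L)) {
  stopifnot(inherits(spec, "gaussian_array_spec"))
  cells <- as.integer(rep(cells, length.out = 2L))
  if (any(cells < 1L)) stop("invalid specification: cells must be >= 1 x 1")
  Lx <- cells[1L] * spec$d_p
  Ly <- cells[2L] * spec$d_p
  cpp <- list(type_code = 1L, Lx = Lx, Ly = Ly,
              H = spec$H, v = spec$v, dp = spec$d_p)
  # |grad f| = |H| (r/v) exp(-r^2 / 2v) peaks at r = sqrt(v) (or at the
  # truncation radius if that is smaller), giving an exact bound on w
  rmax <- min(sqrt(spec$v), spec$d_p / 2)
  gmax <- abs(spec$H) * (rmax / spec$v) * exp(-rmax^2 / (2 * spec$v))
  new_surface("gaussian", Lx, Ly, cpp, w_max = sqrt(1 + gmax^2), spec = spec)
}

#' Build a substrate from a gridded height map
#'
#' Heights are interpolated bilinearly between grid nodes; gradients are
#' central differences at the nodes (periodic wrap), also interpolated
#' bilinearly.  The map is treated as one periodic tile so the deposition
#' box has no edges.
#'
#' @param hf a \code{\link{height_field}}.
#' @return An \code{rsa_surface}.
#' @export
make_heightfield_surface <- function(hf) {
  stopifnot(inherits(hf, "height_field"))
  z <- hf$z
  ip <- c(2:hf$nx, 1L); im <- c(hf$nx, 1:(hf$nx - 1L))
  jp <- c(2:hf$ny, 1L); jm <- c(hf$ny, 1:(hf$ny - 1L))
  gx <- (z[ip, , drop = FALSE] - z[im, , drop = FALSE]) / (2 * hf$dx)
  gy <- (z[, jp, drop = FALSE] - z[, jm, drop = FALSE]) / (2 * hf$dy)
  # w is convex in (fx, fy) and both gradient fields are bilinear within a
  # grid cell, so the nodal maximum bounds w everywhere
  w_max <- sqrt(1 + max(gx^2 + gy^2))
  cpp <- list(type_code = 2L, Lx = hf$nx * hf$dx, Ly = hf$ny * hf$dy,
              z = z, gx = gx, gy = gy, dx = hf$dx, dy = hf$dy)
  new_surface("heightfield", cpp$Lx, cpp$Ly, cpp, w_max = w_max, spec = hf)
}

#' Evaluate a substrate at lateral positions
#'
#' @param surface an \code{rsa_surface}.
#' @param x,y lateral coordinates in nm (recycled to a common length;
#'   wrapped periodically into the cell).
#' @return A data frame with height \code{z}, gradient components \code{fx},
#'   \code{fy}, area-element weight \code{w = sqrt(1 + fx^2 + fy^2)} and the
#'   unit outward normal \code{nx, ny, nz}.
#' @export
surface_eval <- function(surface, x, y) {
  stopifnot(inherits(surface, "rsa_surface"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  m <- surf_eval_cpp(surface_cpp_spec(surface), x, y)
  data.frame(x = x, y = y, z = m[, 1], fx = m[, 2], fy = m[, 3], w = m[, 4],
             nx = -m[, 2] / m[, 4], ny = -m[, 3] / m[, 4], nz = 1 / m[, 4])
}

#' Curved and projected surface area of a substrate cell
#'
#' Integrates the area element \eqn{w = \sqrt{1 + f_x^2 + f_y^2}} over the
#' periodic cell with the midpoint rule at the given lateral resolution.
#'
#' @param surface an \code{rsa_surface}.
#' @param resolution integration step in nm; defaults to 0.7 nm (one tenth
#'   of the 7 nm protein diameter).
#' @return A list with the curved area \code{A_s}, the projected (flat)
#'   area \code{A_f = Lx * Ly} and their \code{ratio} \eqn{A_s / A_f}.
#' @export
surface_area <- function(surface, resolution = 0.7) {
  stopifnot(inherits(surface, "rsa_surface"))
  if (resolution <= 0) stop("invalid specification: resolution must be > 0")
  A_f <- surface$Lx * surface$Ly
  A_s <- if (surface$type == "flat") A_f else
    surface_area_cpp(surface_cpp_spec(surface), resolution)
  list(A_s = A_s, A_f = A_f, ratio = A_s / A_f)
}

#' Calibrate the lattice spacing to a target area ratio
#'
#' The curved-to-projected area ratio \eqn{A_s / A_f} of a Gaussian array
#' decreases strictly as the peak spacing \eqn{d_p} grows (fixed feature,
#' more flat area around it).  Given a feature geometry \code{(H, W)} and a
#' target ratio, this finds the spacing that reproduces the ratio by
#' bisection on \eqn{d_p \in [W, 50W]}.
#'
#' @param H,W feature height and width at half height (nm).
#' @param target_ratio desired \eqn{A_s / A_f}; must exceed 1.
#' @param tol relative tolerance on the achieved ratio.
#' @param resolution integration resolution passed to
#'   \code{\link{surface_area}}.
#' @return The calibrated spacing \code{d_p} in nm.
#' @examples
#' d_p <- calibrate_dp(500, 60, 3.6)
#' s <- make_gaussian_surface(gaussian_array_spec(500, 60, d_p))
#' surface_area(s)$ratio  # 3.6 to within tol
#' @export
calibrate_dp <- function(H, W, target_ratio, tol = 1e-3, resolution = 0.7) {
  if (target_ratio <= 1)
    stop("invalid specification: target ratio must exceed 1")
  ratio_at <- function(dp)
    surface_area(make_gaussian_surface(gaussian_array_spec(H, W, dp)),
                 resolution)$ratio
  lo <- W; hi <- 50 * W
  r_lo <- ratio_at(lo); r_hi <- ratio_at(hi)
  if (target_ratio > r_lo || target_ratio < r_hi)
    stop(sprintf(
      "calibration failure: target ratio %.4g outside achievable range [%.4g, %.4g] for H=%g, W=%g",
      target_ratio, r_hi, r_lo, H, W))
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    r_mid <- ratio_at(mid)
    if (abs(r_mid - target_ratio) / target_ratio < tol) return(mid)
    if (r_mid > target_ratio) lo <- mid else hi <- mid
  }
  stop("calibration failure: bisection did not converge")
}

#' Draw area-weighted uniform random points on a substrate
#'
#' Lateral positions are proposed uniformly over the cell and accepted with
#' probability \eqn{w / w_{max}} (rejection sampling), so accepted points are
#' uniform with respect to the true curved area element \eqn{dA = w\,dx\,dy}.
#' Consumes R's random number stream; seed with \code{set.seed}.
#'
#' @param surface an \code{rsa_surface}.
#' @param n number of points.
#' @return A data frame of anchor points \code{x, y, z} and outward unit
#'   normals \code{nx, ny, nz}.
#' @export
sample_surface_point <- function(surface, n = 1L) {
  stopifnot(inherits(surface, "rsa_surface"))
  m <- sample_surface_cpp(surface_cpp_spec(surface), as.integer(n),
                          surface$w_max)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
             nx = m[, 4], ny = m[, 5], nz = m[, 6])
}

#' @export
print.rsa_surface <- function(x, ...) {
  cat(sprintf("<rsa_surface: %s, cell %.5g x %.5g nm, w_max = %.4g>\n",
              x$type, x$Lx, x$Ly, x$w_max))
  invisible(x)
}
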