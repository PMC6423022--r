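#' Hard-sphere protein model
#'
#' Globular proteins are modelled as hard spheres.  The defaults describe
#' human serum albumin: diameter 7 nm and bulk diffusion coefficient
#' 2.15e-11 m^2/s.
#'
#' @param D sphere diameter in nm.
#' @param D_dif bulk diffusion coefficient in m^2/s.
#' @return An object of class \code{protein_model} with the cross-section
#'   area \code{sigma} \eqn{= \pi D^2/4} (nm^2) derived.
#' @export
protein_model <- function(D = 7, D_dif = 2.15e-11) {
  if (!is.numeric(D) || D <= 0) stop("protein diameter D must be > 0")
  structure(list(D = as.numeric(D), sigma = pi * D^2 / 4,
                 D_dif = as.numeric(D_dif)),
            class = "protein_model")
}

#' Deposition run configuration
#'
#' @param repeats number of independent runs (independent RNG stream each,
#'   seeded \code{seed + repeat - 1}).
#' @param seed base RNG seed.
#' @param max_attempts attempt budget per run; runs that exhaust it before
#'   jamming are flagged \code{budget_limited}.
#' @param stop_after_failures consecutive rejected attempts that declare the
#'   run jammed; must be at least 1e4.
#' @param enforce_no_penetration reject trial spheres that dig into the
#'   substrate (sampled on a lateral grid of step D/10 under the sphere);
#'   disable to get pure pair-exclusion RSA.
#' @param theta_bin_width default coverage bin width for blocking-function
#'   estimation.
#' @return An object of class \code{adsorption_config}.
#' @export
adsorption_config <- function(repeats = 1000L, seed = 1L,
                              max_attempts = 1e8,
                              stop_after_failures = 2e5,
                              enforce_no_penetration = TRUE,
                              theta_bin_width = 0.01) {
  if (repeats < 1L) stop("repeats must be >= 1")
  if (stop_after_failures < 1e4)
    stop("stop_after_failures must be >= 1e4 for a meaningful jamming stop")
  structure(list(repeats = as.integer(repeats), seed = as.integer(seed),
                 max_attempts = as.numeric(max_attempts),
                 stop_after_failures = as.numeric(stop_after_failures),
                 enforce_no_penetration = isTRUE(enforce_no_penetration),
                 theta_bin_width = as.numeric(theta_bin_width)),
            class = "adsorption_config")
}

#' Attempt a single adsorption event
#'
#' One trial of the RSA acceptance rule, exposed for inspection and testing:
#' an anchor is drawn area-weighted on the surface (or supplied), the trial
#' sphere centre is placed at \code{anchor + (D/2) * nhat}, and the trial is
#' rejected on hard-sphere overlap with any existing centre (3D distance
#' below D under the lateral minimum-image convention) or, optionally, on
#' substrate penetration.
#'
#' @param state list with element \code{centers}, an N x 3 matrix of existing
#'   sphere centres (may have zero rows).
#' @param surface an \code{rsa_surface}.
#' @param protein a \code{protein_model}.
#' @param anchor optional \code{c(x, y)} lateral anchor position; when
#'   omitted one is drawn at random.
#' @param enforce_no_penetration as in \code{\link{adsorption_config}}.
#' @return A list with \code{accepted} (logical), \code{reason}
#'   (\code{NA}, \code{"overlap"} or \code{"penetration"}) and, when
#'   accepted, the \code{deposit} (anchor, centre, normal).
#' @export
attempt_adsorption <- function(state, surface, protein, anchor = NULL,
                               enforce_no_penetration = TRUE) {
  stopifnot(inherits(surface, "rsa_surface"), inherits(protein, "protein_model"))
  centers <- state$centers
  if (is.null(centers)) centers <- matrix(numeric(0), ncol = 3)
  if (is.null(anchor)) {
    p <- sample_surface_point(surface, 1L)
  } else {
    ev <- surface_eval(surface, anchor[1], anchor[2])
    p <- data.frame(x = anchor[1], y = anchor[2], z = ev$z,
                    nx = ev$nx, ny = ev$ny, nz = ev$nz)
  }
  D <- protein$D
  ctr <- c(p$x + D / 2 * p$nx, p$y + D / 2 * p$ny, p$z + D / 2 * p$nz)
  code <- placement_check_cpp(surface_cpp_spec(surface), D, centers,
                              ctr[1], ctr[2], ctr[3],
                              isTRUE(enforce_no_penetration))
  if (code == 0L) {
    list(accepted = TRUE, reason = NA_character_,
         deposit = list(anchor = c(p$x, p$y, p$z), center = ctr,
                        normal = c(p$nx, p$ny, p$nz)))
  } else {
    list(accepted = FALSE,
         reason = if (code == 1L) "overlap" else "penetration",
         deposit = NULL)
  }
}

#' Run random sequential adsorption to jamming
#'
#' Repeats the Monte Carlo deposition loop \code{config$repeats} times.
#' Each repeat draws area-weighted anchors, places tangent spheres
#' (centre at anchor + (D/2) * surface normal) and accepts them under
#' steric exclusion until \code{stop_after_failures} consecutive
#' rejections declare jamming.  Coverage is measured against the curved
#' surface area: \eqn{\theta = N \sigma / A_s}.
#'
#' @param surface an \code{rsa_surface}.
#' @param protein a \code{protein_model}.
#' @param config an \code{adsorption_config}.
#' @param engine \code{"grid"} (lateral cell list, default) or
#'   \code{"brute"} (all-pairs scan); both produce identical deposit
#'   sequences for the same seed.
#' @return An object of class \code{rsa_run_set}: a list of runs, each with
#'   the deposit table (anchor and centre coordinates, attempts used per
#'   deposit, coverage at adsorption), total attempts \code{n_att}, final
#'   coverage \code{theta_end} and the \code{budget_limited} flag; plus the
#'   shared surface metadata (\code{A_s}, \code{A_f}, \code{area_ratio}).
#' @examples
#' \donttest{
#' runs <- run_rsa(flat_surface(120, 120), protein_model(),
#'                 adsorption_config(repeats = 3, seed = 1,
#'                                   stop_after_failures = 1e4))
#' jamming_limit(runs)
#' }
#' @export
run_rsa <- function(surface, protein = protein_model(),
                    config = adsorption_config(), engine = c("grid", "brute")) {
  stopifnot(inherits(surface, "rsa_surface"), inherits(protein, "protein_model"),
            inherits(config, "adsorption_config"))
  engine <- match.arg(engine)
  ar <- surface_area(surface, resolution = protein$D / 10)
  runs <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    set.seed(config$seed + r - 1L)
    raw <- run_rsa_cpp(surface_cpp_spec(surface), protein$D, surface$w_max,
                       config$max_attempts, config$stop_after_failures,
                       config$enforce_no_penetration, engine == "brute")
    N <- nrow(raw$anchors)
    theta <- seq_len(N) * protein$sigma / ar$A_s
    runs[[r]] <- structure(
      list(anchors = raw$anchors, centers = raw$centers,
           attempts_used = as.numeric(raw$attempts_used),
           theta = theta,
           n_att = raw$n_att,
           theta_end = if (N > 0) theta[N] else 0,
           budget_limited = raw$budget_limited,
           seed = config$seed + r - 1L),
      class = "rsa_run")
  }
  structure(list(runs = runs, surface = surface, protein = protein,
                 config = config, engine = engine,
                 A_s = ar$A_s, A_f = ar$A_f, area_ratio = ar$ratio),
            class = "rsa_run_set")
}

#' @export
print.rsa_run_set <- function(x, ...) {
  te <- vapply(x$runs, function(r) r$theta_end, numeric(1))
  cat(sprintf(
    "<rsa_run_set: %d run(s) on %s surface, A_s/A_f = %.3f, mean theta_end = %.4f>\n",
    length(x$runs), x$surface$type, x$area_ratio, mean(te)))
  invisible(x)
}

#' Vertical distribution of adsorbed proteins
#'
#' Histogram of deposit anchor heights, pooled over the runs of a set.
#'
#' @param result an \code{rsa_run_set} or a single \code{rsa_run}.
#' @param bin_width height bin width in nm.
#' @return A data frame with bin limits \code{z_lo}, \code{z_hi}, midpoints
#'   \code{z_mid} and \code{count}; counts sum to the number of deposits.
#' @export
z_distribution <- function(result, bin_width = 10) {
  zs <- if (inherits(result, "rsa_run_set"))
    unlist(lapply(result$runs, function(r) r$anchors[, 3]))
  else result$anchors[, 3]
  if (length(zs) == 0L) stop("no deposits: empty result")
  idx <- floor(zs / bin_width)
  tab <- table(idx)
  lo <- as.numeric(names(tab)) * bin_width
  data.frame(z_lo = lo, z_hi = lo + bin_width, z_mid = lo + bin_width / 2,
             count = as.integer(tab))
}

#' Smallest pairwise centre distance in a run (exact brute force)
#'
#' Diagnostic for the hard-core exclusion invariant: after any run the
#' minimum-image distance between any two sphere centres is at least D.
#'
#' @param run an \code{rsa_run}.
#' @param surface the surface the run was produced on.
#' @return Minimum pairwise centre distance in nm (\code{Inf} for fewer
#'   than two deposits).
#' @export
min_pair_distance <- function(run, surface) {
  min_pair_distance_cpp(run$centers, surface$Lx, surface$Ly)
}
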