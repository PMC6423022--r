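#' Estimate the blocking function from deposition runs
#'
#' The blocking function \eqn{B(\theta)} is the probability that an
#' adsorption attempt succeeds at coverage \eqn{\theta}.  Two estimators are
#' provided:
#' \describe{
#'   \item{\code{binned-ratio}}{attempts are attributed to the coverage at
#'     which they were made; per coverage bin,
#'     \eqn{\hat B = N_{succ} / N_{att}} pooled over runs.}
#'   \item{\code{inverse-attempts}}{\eqn{\hat B(\theta_i) = 1 / \langle
#'     a_i \rangle}, the reciprocal of the mean number of attempts needed
#'     for the i-th deposit, averaged across runs, then binned.}
#' }
#' Standard errors come from the across-run variation.  Empty bins are
#' dropped, not interpolated.
#'
#' @param runs an \code{rsa_run_set}.
#' @param bin_width coverage bin width; defaults to the run configuration's
#'   \code{theta_bin_width}.
#' @param estimator which estimator to use.
#' @return An object of class \code{blocking_curve}: a data frame with bin
#'   centre \code{theta}, estimate \code{B}, standard error \code{se} and
#'   pooled attempt count \code{n_att}; the estimator tag and bin width are
#'   attached as attributes.
#' @export
estimate_blocking <- function(runs, bin_width = NULL,
                              estimator = c("binned-ratio", "inverse-attempts")) {
  stopifnot(inherits(runs, "rsa_run_set"))
  estimator <- match.arg(estimator)
  if (is.null(bin_width)) bin_width <- runs$config$theta_bin_width
  nr <- length(runs$runs)

  if (estimator == "binned-ratio") {
    per_run <- lapply(runs$runs, function(r) {
      N <- length(r$theta)
      th_prev <- c(0, r$theta[-N])          # coverage while attempting deposit i
      bin <- floor(th_prev / bin_width)
      att <- rowsum(r$attempts_used, bin)
      suc <- rowsum(rep(1, N), bin)
      trailing <- r$n_att - sum(r$attempts_used)
      if (trailing > 0) {                   # failures after the last success
        bend <- floor(r$theta_end / bin_width)
        i <- match(bend, as.numeric(rownames(att)))
        if (is.na(i)) {
          att <- rbind(att, trailing); rownames(att)[nrow(att)] <- bend
          suc <- rbind(suc, 0);        rownames(suc)[nrow(suc)] <- bend
        } else att[i] <- att[i] + trailing
      }
      data.frame(bin = as.numeric(rownames(att)), att = att[, 1], suc = suc[, 1])
    })
    all <- do.call(rbind, Map(cbind, per_run, run = seq_len(nr)))
    att_tot <- rowsum(all$att, all$bin)
    suc_tot <- rowsum(all$suc, all$bin)
    bins <- as.numeric(rownames(att_tot))
    B <- suc_tot[, 1] / att_tot[, 1]
    # across-run spread of the per-run ratios
    se <- vapply(bins, function(b) {
      ratios <- vapply(per_run, function(d) {
        i <- match(b, d$bin)
        if (is.na(i)) NA_real_ else d$suc[i] / d$att[i]
      }, numeric(1))
      ratios <- ratios[!is.na(ratios)]
      if (length(ratios) >= 2) sd(ratios) / sqrt(length(ratios)) else NA_real_
    }, numeric(1))
    out <- data.frame(theta = (bins + 0.5) * bin_width, B = B, se = se,
                      n_att = att_tot[, 1])
  } else {
    nmax <- max(vapply(runs$runs, function(r) length(r$attempts_used), integer(1)))
    amat <- matrix(NA_real_, nr, nmax)
    tmat <- matrix(NA_real_, nr, nmax)
    for (k in seq_len(nr)) {
      r <- runs$runs[[k]]
      N <- length(r$attempts_used)
      if (N > 0) {
        amat[k, seq_len(N)] <- r$attempts_used
        tmat[k, seq_len(N)] <- c(0, r$theta[-N])
      }
    }
    nk <- colSums(!is.na(amat))
    keep <- nk >= max(2L, nr %/% 2L)   # indices reached by most runs
    abar <- colMeans(amat[, keep, drop = FALSE], na.rm = TRUE)
    asd  <- apply(amat[, keep, drop = FALSE], 2, sd, na.rm = TRUE)
    th   <- colMeans(tmat[, keep, drop = FALSE], na.rm = TRUE)
    Bi   <- 1 / abar
    sei  <- asd / (abar^2 * sqrt(nk[keep]))   # delta method on 1/mean
    bin  <- floor(th / bin_width)
    grp  <- rowsum(cbind(Bi, sei^2, 1), bin)
    bins <- as.numeric(rownames(grp))
    out <- data.frame(theta = (bins + 0.5) * bin_width,
                      B = grp[, 1] / grp[, 3],
                      se = sqrt(grp[, 2]) / grp[, 3],
                      n_att = NA_real_)
  }
  out <- out[order(out$theta), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("blocking_curve", "data.frame"),
            estimator = estimator, bin_width = bin_width)
}

#' Third-order blocking function for hard disks on a flat surface
#'
#' The low-density series expansion
#' \deqn{B(\theta) = 1 - 4\theta + \frac{6\sqrt 3}{\pi}\theta^2 +
#'   \left(\frac{40}{\pi\sqrt 3} - \frac{176}{3\pi^2}\right)\theta^3}
#' clamped below at zero.
#'
#' @param theta coverage value(s) in \code{[0, 1)}.
#' @return The blocking probability.
#' @export
theoretical_flat_blocking <- function(theta) {
  if (any(theta < 0 | theta >= 1))
    stop("domain error: theta must lie in [0, 1)")
  c3 <- 40 / (pi * sqrt(3)) - 176 / (3 * pi^2)
  pmax(1 - 4 * theta + (6 * sqrt(3) / pi) * theta^2 + c3 * theta^3, 0)
}

#' Fit a constrained cubic to a blocking curve
#'
#' Least squares of \eqn{B(\theta)} on \eqn{(\theta, \theta^2, \theta^3)}
#' with the intercept fixed at the theoretical value \eqn{B(0) = 1}.  The
#' unconstrained fit (free intercept) is returned as a diagnostic.
#'
#' Two weighting schemes are available.  \code{"equal"} (default) treats
#' every bin alike, which keeps the fit representative of the whole curve.
#' \code{"inverse-variance"} weights by \eqn{1/se^2}; note that near
#' jamming the bins accumulate enormous attempt counts, so their tiny
#' standard errors let the saturated tail dominate and the fitted
#' coefficients then describe the tail rather than the curve.
#'
#' When \code{pin_root} is supplied (typically the empirical jamming limit
#' \eqn{\theta_\infty}), the cubic is additionally constrained to
#' \eqn{B(\theta_\infty) = 0} with its terminal slope matched to the
#' empirical descent of the curve, leaving one free parameter for the bulk
#' shape.  The resulting blocking function terminates exactly where the
#' simulation jams, which is what the kinetics ODE needs for its plateau
#' to reproduce the jamming limit.
#'
#' @param curve a \code{blocking_curve} with at least 8 populated bins.
#' @param order polynomial order; only 3 is supported.
#' @param pin_root optional coverage at which the fitted cubic is forced
#'   to zero (with slope matched to the data).
#' @param weights weighting scheme, see Details.
#' @return An object of class \code{blocking_fit}: coefficients
#'   \code{coef = c(1, c1, c2, c3)}, the first positive root
#'   \code{theta_inf} of the fitted cubic, coefficient standard errors
#'   (free parameters only), residual summary, and the unconstrained
#'   coefficients.
#' @export
fit_blocking_poly <- function(curve, order = 3, pin_root = NULL,
                              weights = c("equal", "inverse-variance")) {
  stopifnot(inherits(curve, "blocking_curve"))
  if (order != 3) stop("only third-order fits are supported")
  weights <- match.arg(weights)
  d <- curve[is.finite(curve$B), , drop = FALSE]
  if (nrow(d) < 8) stop("fit error: need at least 8 populated bins")
  w <- if (weights == "equal") rep(1, nrow(d)) else 1 / pmax(d$se, 1e-8)^2
  w[!is.finite(w)] <- 1

  if (is.null(pin_root)) {
    X <- cbind(d$theta, d$theta^2, d$theta^3)
    fit <- lm.wfit(X, d$B - 1, w)
    if (fit$qr$rank < 3) stop("fit error: rank-deficient design")
    cf <- c(1, unname(fit$coefficients))
    # classical coefficient covariance for the free parameters
    dof <- nrow(d) - 3
    s2 <- sum(w * fit$residuals^2) / dof
    XtWX <- crossprod(X * sqrt(w))
    cse <- sqrt(diag(s2 * solve(XtWX)))
    resid <- fit$residuals
  } else {
    a <- pin_root
    if (!is.numeric(a) || a <= 0) stop("fit error: pin_root must be > 0")
    # terminal slope from secants to the root over the resolvable descent
    tl <- d[d$B >= 1e-4 & d$B <= 2e-2 & d$theta < a, , drop = FALSE]
    s <- if (nrow(tl) >= 2) mean(tl$B / (a - tl$theta)) else {
      last <- d[d$B > 0 & d$theta < a, , drop = FALSE]
      last <- last[nrow(last), ]
      max(last$B / (a - last$theta), 1e-3)
    }
    # B = 1 + c1 t + c2 t^2 + c3 t^3 with B(a) = 0, B'(a) = -s is linear
    # in the single free parameter c1: B = g0 + c1 * g1
    g0 <- 1 + ((-3 + s * a) / a^2) * d$theta^2 + ((2 - s * a) / a^3) * d$theta^3
    g1 <- d$theta - 2 * d$theta^2 / a + d$theta^3 / a^2
    c1 <- sum(w * g1 * (d$B - g0)) / sum(w * g1^2)
    A <- -1 - c1 * a; Bq <- -s - c1
    cf <- c(1, c1, (3 * A - Bq * a) / a^2, (Bq * a - 2 * A) / a^3)
    resid <- d$B - (g0 + c1 * g1)
    dof <- nrow(d) - 1
    s2 <- sum(w * resid^2) / dof
    cse <- c(sqrt(s2 / sum(w * g1^2)), NA_real_, NA_real_)
  }
  diag_fit <- lm.wfit(cbind(1, d$theta, d$theta^2, d$theta^3), d$B, w)
  structure(
    list(coef = cf,
         theta_inf = first_positive_root(cf),
         coef_se = cse,
         residual_sd = sqrt(sum(w * resid^2) / dof / mean(w)),
         unconstrained_coef = c(unname(diag_fit$coefficients)),
         pinned = !is.null(pin_root),
         n_bins = nrow(d)),
    class = "blocking_fit")
}

## internal: smallest real positive root of a polynomial c0 + c1 x + ...
first_positive_root <- function(cf) {
  r <- polyroot(cf)
  re <- Re(r)[abs(Im(r)) < 1e-8 * pmax(1, abs(Re(r)))]
  re <- re[re > 0]
  if (length(re) == 0L) return(NA_real_)
  min(re)
}

#' @export
print.blocking_fit <- function(x, ...) {
  cat(sprintf(
    "<blocking_fit: B = 1 %+0.4g t %+0.4g t^2 %+0.4g t^3, theta_inf = %.4f>\n",
    x$coef[2], x$coef[3], x$coef[4], x$theta_inf))
  invisible(x)
}

#' Jamming limit of a deposition ensemble
#'
#' Mean and standard deviation of the final coverage across repeats
#' (budget-limited runs excluded).  Against a flat reference the relative
#' change \eqn{\Delta\theta_\infty = (\theta_{\infty,s} - \theta_{\infty,f})
#' / \theta_{\infty,f}} and the adsorbed-count ratio per unit projected
#' area \eqn{N_s / N_f = A_s \theta_{\infty,s} / (A_f \theta_{\infty,f})}
#' are also reported.
#'
#' @param runs an \code{rsa_run_set} (at least 2 non-budget-limited repeats
#'   for a standard deviation).
#' @param flat_reference optionally, a \code{jamming_estimate} from a flat
#'   surface.
#' @return An object of class \code{jamming_estimate} with
#'   \code{theta_inf}, \code{sd}, \code{n_runs}, \code{area_ratio} and --
#'   when a reference is supplied -- \code{delta_theta_inf} and
#'   \code{Ns_over_Nf}.
#' @export
jamming_limit <- function(runs, flat_reference = NULL) {
  stopifnot(inherits(runs, "rsa_run_set"))
  ok <- !vapply(runs$runs, function(r) r$budget_limited, logical(1))
  te <- vapply(runs$runs[ok], function(r) r$theta_end, numeric(1))
  if (length(te) == 0L) stop("no jammed (non-budget-limited) runs")
  est <- list(theta_inf = mean(te),
              sd = if (length(te) >= 2) sd(te) else NA_real_,
              n_runs = length(te),
              area_ratio = runs$area_ratio,
              delta_theta_inf = NA_real_, Ns_over_Nf = NA_real_)
  if (!is.null(flat_reference)) {
    stopifnot(inherits(flat_reference, "jamming_estimate"))
    tf <- flat_reference$theta_inf
    est$delta_theta_inf <- (est$theta_inf - tf) / tf
    est$Ns_over_Nf <- (est$area_ratio * est$theta_inf) /
      (flat_reference$area_ratio * tf)
  }
  structure(est, class = "jamming_estimate")
}

#' @export
print.jamming_estimate <- function(x, ...) {
  cat(sprintf("<jamming_estimate: theta_inf = %.4f +/- %.4f (%d runs)",
              x$theta_inf, x$sd, x$n_runs))
  if (!is.na(x$delta_theta_inf))
    cat(sprintf(", delta = %+.1f%%, Ns/Nf = %.2f",
                100 * x$delta_theta_inf, x$Ns_over_Nf))
  cat(">\n")
  invisible(x)
}

#' Jamming limit versus feature curvature
#'
#' Ordinary least squares of \eqn{\theta_\infty} on the curvature
#' \eqn{1/W} of the feature cross-section at half height, for a family of
#' geometries sharing height and class.
#'
#' @param W feature widths at half height (nm); at least 3.
#' @param theta_inf jamming limits at those widths.
#' @return A list with \code{slope} (nm), \code{intercept},
#'   \code{r_squared} and the fitted \code{lm} object.
#' @export
curvature_regression <- function(W, theta_inf) {
  if (length(W) < 3 || length(theta_inf) != length(W))
    stop("fit error: need at least 3 (W, theta_inf) pairs")
  d <- data.frame(inv_W = 1 / W, theta_inf = theta_inf)
  fit <- lm(theta_inf ~ inv_W, data = d)
  # summary.lm warns on an exactly collinear triple; the fit is still valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, fit = fit)
}
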