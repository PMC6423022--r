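#' Read and validate a run configuration file
#'
#' Configurations are YAML with up to four blocks -- \code{surface},
#' \code{protein}, \code{engine}, \code{kinetics} -- plus an optional
#' \code{output} block of file paths.  Unknown blocks or keys are rejected
#' outright (fail-fast), so a typo cannot silently fall back to a default.
#'
#' Recognised keys:
#' \describe{
#'   \item{surface}{\code{type} (flat | gaussian | heightfield),
#'     \code{H}, \code{W}, \code{d_p}, \code{target_ratio}, \code{cells},
#'     \code{Lx}, \code{Ly}, \code{path}, \code{dx}, \code{dy}}
#'   \item{protein}{\code{D}, \code{D_dif}}
#'   \item{engine}{\code{repeats}, \code{seed}, \code{max_attempts},
#'     \code{stop_after_failures}, \code{enforce_no_penetration},
#'     \code{theta_bin_width}}
#'   \item{kinetics}{\code{k_a}, \code{k_d}, \code{n}}
#'   \item{output}{\code{xyz}, \code{summary}, \code{blocking},
#'     \code{trajectory}}
#' }
#' A gaussian surface may give \code{d_p} directly or a
#' \code{target_ratio}, in which case the spacing is calibrated with
#' \code{\link{calibrate_dp}}.
#'
#' @param path YAML file.
#' @return A validated nested list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  schema <- list(
    surface = c("type", "H", "W", "d_p", "target_ratio", "cells",
                "Lx", "Ly", "path", "dx", "dy"),
    protein = c("D", "D_dif"),
    engine = c("repeats", "seed", "max_attempts", "stop_after_failures",
               "enforce_no_penetration", "theta_bin_width"),
    kinetics = c("k_a", "k_d", "n"),
    output = c("xyz", "summary", "blocking", "trajectory")
  )
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    stop(sprintf("invalid config: unknown block(s) %s",
                 paste(sQuote(bad), collapse = ", ")))
  for (blk in names(cfg)) {
    bad <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(bad))
      stop(sprintf("invalid config: unknown key(s) %s in block '%s'",
                   paste(sQuote(bad), collapse = ", "), blk))
  }
  structure(cfg, class = "run_config")
}

#' Build an \code{rsa_surface} from a config surface block
#'
#' @param sb the \code{surface} block of a \code{\link{read_run_config}}
#'   result.
#' @return An \code{rsa_surface}.
#' @export
surface_from_config <- function(sb) {
  type <- sb$type
  if (is.null(type)) stop("invalid config: surface block needs a 'type'")
  switch(type,
    flat = flat_surface(Lx = sb$Lx %||% 500, Ly = sb$Ly %||% sb$Lx %||% 500),
    gaussian = {
      if (is.null(sb$H) || is.null(sb$W))
        stop("invalid config: gaussian surface needs H and W")
      d_p <- sb$d_p
      if (is.null(d_p)) {
        if (is.null(sb$target_ratio))
          stop("invalid config: gaussian surface needs d_p or target_ratio")
        d_p <- calibrate_dp(sb$H, sb$W, sb$target_ratio)
      }
      cells <- sb$cells %||% max(1L, ceiling(500 / d_p))
      make_gaussian_surface(gaussian_array_spec(sb$H, sb$W, d_p), cells = cells)
    },
    heightfield = {
      if (is.null(sb$path))
        stop("invalid config: heightfield surface needs a 'path'")
      make_heightfield_surface(read_heightmap(sb$path, dx = sb$dx, dy = sb$dy))
    },
    stop(sprintf("invalid config: unknown surface type '%s'", type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
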