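#' Read a height map from disk
#'
#' Two plain-text layouts are accepted.  The native ASCII format has a
#' header line \code{"nx ny dx dy"} (spacings in nm) followed by \code{ny}
#' rows of \code{nx} whitespace-separated heights (each row is one y line).
#' Bare CSV (no header, comma-separated rows of heights) is also accepted,
#' in which case the grid spacings must be supplied.
#'
#' @param path file to read.
#' @param format \code{"auto"} (default: CSV when the name ends in
#'   \code{.csv}), \code{"ascii"} or \code{"csv"}.
#' @param dx,dy grid spacings in nm; required for CSV input.
#' @return A \code{\link{height_field}}.
#' @export
read_heightmap <- function(path, format = c("auto", "ascii", "csv"),
                           dx = NULL, dy = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "ascii"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "ascii") {
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(hdr) != 4)
      stop("parse error in header (line 1): expected 'nx ny dx dy'")
    nx <- as.integer(hdr[1]); ny <- as.integer(hdr[2])
    dx <- as.numeric(hdr[3]); dy <- as.numeric(hdr[4])
    if (anyNA(c(nx, ny, dx, dy)))
      stop("parse error in header (line 1): non-numeric field")
    body <- lines[-1]
    if (length(body) != ny)
      stop(sprintf("parse error: expected %d data rows, found %d", ny, length(body)))
    rows <- lapply(seq_along(body), function(j) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body[j]), "\\s+")[[1]]))
      if (length(vals) != nx || anyNA(vals))
        stop(sprintf("parse error in data row %d (line %d): expected %d numeric values",
                     j, j + 1L, nx))
      vals
    })
  } else {
    if (is.null(dx) || is.null(dy))
      stop("CSV height maps carry no spacing: supply dx and dy (nm)")
    rows <- lapply(seq_along(lines), function(j) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[j], ",")[[1]]))
      if (anyNA(vals))
        stop(sprintf("parse error in data row %d: non-numeric value", j))
      vals
    })
    nx <- length(rows[[1]])
    bad <- which(vapply(rows, length, integer(1)) != nx)
    if (length(bad))
      stop(sprintf("parse error in data row %d: expected %d values", bad[1], nx))
  }
  # rows are y lines: row j gives z[, j]
  z <- do.call(cbind, rows)
  height_field(z, dx = dx, dy = dy)
}

#' Write a height map to disk
#'
#' Inverse of \code{\link{read_heightmap}}; values are written with full
#' double precision so a write/read round trip is bit-identical.
#'
#' @param hf a \code{\link{height_field}}.
#' @param path output file.
#' @param format \code{"ascii"} (native, with header) or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_heightmap <- function(hf, path, format = c("ascii", "csv")) {
  stopifnot(inherits(hf, "height_field"))
  format <- match.arg(format)
  fmt_row <- function(j, sep)
    paste(sprintf("%.17g", hf$z[, j]), collapse = sep)
  if (format == "ascii") {
    out <- c(sprintf("%d %d %.17g %.17g", hf$nx, hf$ny, hf$dx, hf$dy),
             vapply(seq_len(hf$ny), fmt_row, character(1), sep = " "))
  } else {
    out <- vapply(seq_len(hf$ny), fmt_row, character(1), sep = ",")
  }
  writeLines(out, path)
  invisible(path)
}

#' Export deposited particles as XYZ
#'
#' One record per adsorbed sphere centre (species tag, x, y, z in nm),
#' preceded by the standard count and comment lines, suitable for generic
#' particle viewers.
#'
#' @param run an \code{rsa_run} (or an \code{rsa_run_set}, in which case
#'   the first run is written).
#' @param path output file.
#' @param species species tag.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(run, path, species = "HSA") {
  if (inherits(run, "rsa_run_set")) run <- run$runs[[1]]
  ctr <- run$centers
  out <- c(sprintf("%d", nrow(ctr)),
           sprintf("RSA deposits (nm); seed=%d theta_end=%.6f",
                   run$seed, run$theta_end),
           sprintf("%s %.6f %.6f %.6f", species, ctr[, 1], ctr[, 2], ctr[, 3]))
  writeLines(out, path)
  invisible(path)
}

#' Export a blocking curve (or any table) as annotated TSV
#'
#' Tab-separated values preceded by \code{#}-commented header lines that
#' record the provenance (estimator, bin width, seeds, free-form notes), so
#' a written curve is reproducible from its own header.
#'
#' @param curve a \code{blocking_curve} or plain data frame.
#' @param path output file.
#' @param notes named character vector of extra header fields.
#' @return \code{path}, invisibly.
#' @export
write_blocking_table <- function(curve, path, notes = character()) {
  hdr <- character()
  if (inherits(curve, "blocking_curve"))
    hdr <- c(sprintf("# estimator: %s", attr(curve, "estimator")),
             sprintf("# bin_width: %g", attr(curve, "bin_width")))
  if (length(notes))
    hdr <- c(hdr, sprintf("# %s: %s", names(notes), notes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a run summary sidecar
#'
#' Flat \code{key = value} lines recording the configuration, seed, surface
#' metadata and jamming outcome of a run set.
#'
#' @param runs an \code{rsa_run_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_run_summary <- function(runs, path) {
  stopifnot(inherits(runs, "rsa_run_set"))
  jam <- jamming_limit(runs)
  cfg <- runs$config
  kv <- c(surface = runs$surface$type,
          Lx_nm = runs$surface$Lx, Ly_nm = runs$surface$Ly,
          A_s_nm2 = runs$A_s, A_f_nm2 = runs$A_f, area_ratio = runs$area_ratio,
          protein_D_nm = runs$protein$D,
          repeats = cfg$repeats, seed = cfg$seed,
          stop_after_failures = cfg$stop_after_failures,
          max_attempts = cfg$max_attempts,
          enforce_no_penetration = cfg$enforce_no_penetration,
          engine = runs$engine,
          theta_inf = jam$theta_inf, theta_inf_sd = jam$sd)
  writeLines(sprintf("%s = %s", names(kv), as.character(kv)), path)
  invisible(path)
}
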