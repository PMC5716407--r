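#' Construct a depth curve
#'
#' A depth curve tabulates a normalized detector response against
#' water-equivalent depth.  Two kinds are distinguished: `"dose"` for
#' ionization-chamber depth-dose curves DD(z) and `"output"` for MOSFET
#' depth-output curves DO(z).
#'
#' @param depths water-equivalent depths in mm, strictly increasing.
#' @param values non-negative response values, same length as `depths`.
#' @param kind `"dose"` or `"output"`.
#' @param normalization_depth depth (mm) at which the curve is normalized to 1
#'   by [normalize_curve()]; default 0 (entrance).
#' @param range_mm nominal range of the beam the curve belongs to (mm); used
#'   to translate between curve depth and proton residual range.  If `NULL`
#'   it is inferred as the distal depth at which the curve falls to 80% of
#'   its maximum.
#' @return An object of class `depth_curve`.
#' @export
depth_curve <- function(depths, values, kind = c("dose", "output"),
                        normalization_depth = 0, range_mm = NULL) {
  kind <- match.arg(kind)
  if (length(depths) != length(values) || length(depths) < 2) {
    stop("depths and values must have equal length >= 2")
  }
  if (is.unsorted(depths, strictly = TRUE)) stop("depths must be strictly increasing")
  if (any(values < 0)) stop("curve values must be >= 0")
  structure(
    list(depths = as.numeric(depths), values = as.numeric(values), kind = kind,
         normalization_depth = normalization_depth, range_mm = range_mm),
    class = "depth_curve")
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf("<depth_curve> kind=%s, %d knots over [%.1f, %.1f] mm, range %.1f mm\n",
              x$kind, length(x$depths), min(x$depths), max(x$depths),
              curve_range(x)))
  invisible(x)
}

#' Evaluate a depth curve at arbitrary depths
#'
#' Linear interpolation between knots; the first tabulated value before the
#' first knot, and 0 beyond the last knot (the beam has stopped).
#'
#' @param curve a [depth_curve()].
#' @param depth_mm depths in mm; vectorized.
#' @return Interpolated values.
#' @export
lookup_curve <- function(curve, depth_mm) {
  stopifnot(inherits(curve, "depth_curve"))
  stats::approx(curve$depths, curve$values, xout = depth_mm,
                yleft = curve$values[1], yright = 0)$y
}

#' Normalize a depth curve at its normalization depth
#'
#' Rescales all values by a single constant so the value at
#' `normalization_depth` equals 1.
#'
#' @param curve a [depth_curve()].
#' @return The rescaled curve.
#' @export
normalize_curve <- function(curve) {
  v0 <- lookup_curve(curve, curve$normalization_depth)
  if (v0 <= 0) stop("curve value at the normalization depth is not positive")
  curve$values <- curve$values / v0
  curve
}

#' Nominal range of a depth curve
#'
#' Returns the stored `range_mm` when present, otherwise the distal depth at
#' which the curve falls to 80% of its maximum (the conventional clinical
#' range definition).
#'
#' @param curve a [depth_curve()].
#' @return Range in mm.
#' @export
curve_range <- function(curve) {
  if (!is.null(curve$range_mm)) return(curve$range_mm)
  distal_level_depth(curve, 0.8)
}

# Distal depth at which the curve crosses `level` x max, beyond the argmax.
distal_level_depth <- function(curve, level) {
  v <- curve$values
  z <- curve$depths
  imax <- which.max(v)
  target <- level * v[imax]
  distal <- seq(imax, length(v))
  below <- distal[v[distal] <= target]
  if (length(below) == 0) return(z[length(z)])
  j <- below[1]
  if (j == imax) return(z[imax])
  # linear interpolation between knots j-1 and j
  z[j - 1] + (z[j] - z[j - 1]) * (v[j - 1] - target) / (v[j - 1] - v[j])
}

#' Write a depth curve to CSV
#'
#' Format: one comment header line
#' `# depth_curve kind=<kind> normalization_depth=<mm> range_mm=<mm|NA>`
#' followed by a `depth_mm,value` two-column table at full double precision.
#' `write_curve()` followed by [read_curve()] reproduces the curve to 12
#' significant digits.
#'
#' @param curve a [depth_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "depth_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# depth_curve kind=%s normalization_depth=%.17g range_mm=%s",
                     curve$kind, curve$normalization_depth,
                     if (is.null(curve$range_mm)) "NA"
                     else sprintf("%.17g", curve$range_mm)), con)
  writeLines("depth_mm,value", con)
  writeLines(sprintf("%.17g,%.17g", curve$depths, curve$values), con)
  invisible(path)
}

#' Read a depth curve from CSV
#'
#' @param path file written by [write_curve()] (or hand-authored in the same
#'   format).  Malformed headers, non-increasing depths and negative values
#'   raise an error naming the offending line.
#' @return A [depth_curve()].
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("parse error in '", path, "': need header + >= 2 data lines")
  hdr <- lines[1]
  m <- regmatches(hdr, regexec(
    "^# depth_curve kind=(dose|output) normalization_depth=([-0-9.eE+]+) range_mm=([-0-9.eE+]+|NA)$",
    hdr))[[1]]
  if (length(m) != 4) stop("parse error in '", path, "' at line 1: bad header")
  if (lines[2] != "depth_mm,value") {
    stop("parse error in '", path, "' at line 2: expected 'depth_mm,value'")
  }
  fields <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) == 2 && !anyNA(suppressWarnings(as.numeric(f)))
    if (!ok) stop("parse error in '", path, "' at line ", i + 2)
  }
  depths <- vapply(fields, function(f) as.numeric(f[1]), 0)
  values <- vapply(fields, function(f) as.numeric(f[2]), 0)
  bad <- which(diff(depths) <= 0)
  if (length(bad) > 0) {
    stop("parse error in '", path, "' at line ", bad[1] + 3,
         ": depths not strictly increasing")
  }
  if (any(values < 0)) {
    stop("parse error in '", path, "' at line ", which(values < 0)[1] + 2,
         ": negative value")
  }
  depth_curve(depths, values, kind = m[2],
              normalization_depth = as.numeric(m[3]),
              range_mm = if (m[4] == "NA") NULL else as.numeric(m[4]))
}
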