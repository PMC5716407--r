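#' Construct a voxel phantom
#'
#' A 3-D raster of relative stopping power (RSP).  Positions are in mm, the
#' beam axis is +z, voxel `[1,1,1]`'s center sits at `origin`, and a voxel
#' owns the half-open cube centred on its center.
#'
#' @param rsp 3-D numeric array of RSP values (>= 0).
#' @param voxel_size length-3 vector of voxel dimensions in mm (> 0);
#'   default `c(0.586, 0.586, 3)`, a typical CT raster.
#' @param origin mm position of the center of voxel `[1,1,1]`; default
#'   centres the grid laterally with the entrance face at z = 0.
#' @return An object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(rsp, voxel_size = c(0.586, 0.586, 3), origin = NULL) {
  stopifnot(is.array(rsp), length(dim(rsp)) == 3)
  if (any(rsp < 0)) stop("rsp must be >= 0")
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  shape <- dim(rsp)
  if (is.null(origin)) {
    origin <- c(-(shape[1] - 1) / 2 * voxel_size[1],
                -(shape[2] - 1) / 2 * voxel_size[2],
                voxel_size[3] / 2)
  }
  structure(list(rsp = rsp, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$rsp)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels of %.3f x %.3f x %.1f mm; RSP in [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$rsp), max(x$rsp)))
  invisible(x)
}

# voxel-center coordinates along each axis
phantom_axes <- function(ph) {
  d <- dim(ph$rsp)
  lapply(1:3, function(k) ph$origin[k] + (seq_len(d[k]) - 1) * ph$voxel_size[k])
}

# physical bounds [lo, hi] of the raster (outer voxel faces)
phantom_bounds <- function(ph) {
  d <- dim(ph$rsp)
  lo <- ph$origin - ph$voxel_size / 2
  hi <- ph$origin + (d - 0.5) * ph$voxel_size
  rbind(lo = lo, hi = hi)
}

#' Homogeneous water tank phantom
#'
#' @param shape integer length-3 voxel counts.
#' @param voxel_size voxel dimensions in mm.
#' @return A [voxel_phantom()] with RSP = 1 everywhere.
#' @export
make_water_tank <- function(shape, voxel_size = c(0.586, 0.586, 3)) {
  stopifnot(all(shape >= 1))
  voxel_phantom(array(1, dim = shape), voxel_size = voxel_size)
}

#' Place axis-aligned material boxes into a phantom
#'
#' Voxels whose centers fall inside a box (half-open: `lo <= x < hi`) take
#' the insert material's RSP; later inserts override earlier ones.
#'
#' @param base a [voxel_phantom()] (typically [make_water_tank()]).
#' @param inserts list of inserts, each a list with `lo` and `hi` (length-3
#'   mm corners) and either `material` (name or [material()]) or `rsp`.
#' @return The modified [voxel_phantom()].
#' @export
make_slab_phantom <- function(base, inserts = list()) {
  stopifnot(inherits(base, "voxel_phantom"))
  ax <- phantom_axes(base)
  b <- phantom_bounds(base)
  for (ins in inserts) {
    lo <- as.numeric(ins$lo); hi <- as.numeric(ins$hi)
    stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo))
    if (any(lo < b["lo", ] - 1e-9) || any(hi > b["hi", ] + 1e-9)) {
      stop("insert box extends outside the phantom")
    }
    rsp_val <- if (!is.null(ins$rsp)) ins$rsp else {
      m <- ins$material
      if (is.character(m)) m <- pt_material(m)
      m$rsp
    }
    ix <- which(ax[[1]] >= lo[1] & ax[[1]] < hi[1])
    iy <- which(ax[[2]] >= lo[2] & ax[[2]] < hi[2])
    iz <- which(ax[[3]] >= lo[3] & ax[[3]] < hi[3])
    if (length(ix) && length(iy) && length(iz)) {
      base$rsp[ix, iy, iz] <- rsp_val
    }
  }
  base
}

#' Synthetic head-like heterogeneous phantom
#'
#' A desk-scale analogue of the head-and-neck region of an anthropomorphic
#' phantom: a soft-tissue block (RSP 1) holding a cortical-bone jaw arc
#' (RSP 1.6), an air oral cavity (RSP 0.001) and a lateral half-field
#' cortical-bone plate whose edge produces distal-dose perturbations under
#' irradiation along +z.  Insert positions are jittered deterministically by
#' `seed`, so the same seed always yields the identical voxel array.  It is
#' an analogue of the real (unpublished) phantom, not a reconstruction.
#'
#' @param seed integer seed controlling the jitter.
#' @param shape voxel counts; default `c(160, 160, 90)` at the default CT
#'   raster (93.8 x 93.8 x 270 mm).
#' @param voxel_size voxel dimensions in mm.
#' @return A [voxel_phantom()].
#' @export
make_head_like <- function(seed = 1, shape = c(160, 160, 90),
                           voxel_size = c(0.586, 0.586, 3)) {
  if (any(shape * voxel_size < c(72, 72, 130))) {
    stop("raster too small for the head-like inserts (needs >= 72 x 72 x 130 mm)")
  }
  ph <- make_water_tank(shape, voxel_size)
  jit <- local({
    set.seed(seed)
    stats::runif(6, -2, 2)   # mm jitter of insert centres
  })
  ax <- phantom_axes(ph)
  x <- ax[[1]]; y <- ax[[2]]; z <- ax[[3]]
  nx <- length(x); ny <- length(y); nz <- length(z)
  rsp_bone <- pt_material("cortical_bone")$rsp
  rsp_air <- pt_material("air")$rsp

  # jaw arc: partial bone annulus in a band of slices around z ~ 105 mm
  cx <- jit[1]; cy <- jit[2]
  zl <- 90 + jit[3]; zh <- 120 + jit[3]
  r2 <- outer((x - cx)^2, (y - cy)^2, "+")
  ang <- atan2(matrix(y - cy, nx, ny, byrow = TRUE), matrix(x - cx, nx, ny))
  in_arc <- r2 >= 25^2 & r2 <= 33^2 & (ang > -2.6 & ang < 2.6)
  iz <- which(z >= zl & z < zh)
  for (k in iz) ph$rsp[, , k][in_arc] <- rsp_bone

  # oral cavity: air sphere, radius 12 mm
  sc <- c(jit[4], 8 + jit[5], 105 + jit[6])
  for (k in seq_len(nz)) {
    dz2 <- (z[k] - sc[3])^2
    if (dz2 > 12^2) next
    in_sph <- outer((x - sc[1])^2, (y - sc[2])^2, "+") + dz2 <= 12^2
    ph$rsp[, , k][in_sph] <- rsp_air
  }

  # lateral bone plate: occupies x > 4 mm only, z in [60, 78) mm, so its
  # edge crosses the field and perturbs the distal dose
  ph <- make_slab_phantom(ph, list(
    list(lo = c(4 + jit[1], min(y), 60), hi = c(max(x), max(y), 78),
         material = "cortical_bone")))
  ph
}

#' Water-equivalent depth along a ray
#'
#' Midpoint-rule accumulation of RSP x step along a straight ray, the
#' water-equivalent model for path length.  Sampling stops when the sample
#' point leaves the phantom.
#'
#' @param phantom a [voxel_phantom()].
#' @param entry mm starting point (must lie inside the phantom).
#' @param direction unit vector (|v| = 1 within 1e-9).
#' @param step step length in mm (> 0), default 0.5.
#' @return A data.frame with columns `geometric_mm` (distance from entry to
#'   the end of each step) and `wed_mm` (cumulative water-equivalent depth,
#'   monotone non-decreasing).
#' @export
wed_along_ray <- function(phantom, entry, direction, step = 0.5) {
  stopifnot(inherits(phantom, "voxel_phantom"), step > 0)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) stop("direction must be a unit vector")
  b <- phantom_bounds(phantom)
  if (any(entry < b["lo", ]) || any(entry > b["hi", ])) {
    stop("entry point lies outside the phantom")
  }
  d <- dim(phantom$rsp)
  # generous upper bound on the number of steps across the raster
  nmax <- ceiling(sqrt(sum((b["hi", ] - b["lo", ])^2)) / step) + 2
  t_mid <- (seq_len(nmax) - 0.5) * step
  pts <- cbind(entry[1] + t_mid * direction[1],
               entry[2] + t_mid * direction[2],
               entry[3] + t_mid * direction[3])
  idx <- sapply(1:3, function(k) {
    as.integer(floor((pts[, k] - phantom$origin[k]) / phantom$voxel_size[k] + 0.5)) + 1L
  })
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
            idx[, 2] >= 1 & idx[, 2] <= d[2] &
            idx[, 3] >= 1 & idx[, 3] <= d[3]
  last <- if (all(inside)) nmax else which(!inside)[1] - 1L
  if (last < 1) return(data.frame(geometric_mm = numeric(0), wed_mm = numeric(0)))
  keep <- seq_len(last)
  rsp <- phantom$rsp[idx[keep, , drop = FALSE]]
  data.frame(geometric_mm = t_mid[keep] + step / 2,
             wed_mm = cumsum(rsp * step))
}

#' Persist a voxel phantom
#'
#' Writes `<path>.json` (shape, voxel size, origin, byte order) and
#' `<path>.bin` (raw little-endian doubles in R array order), a bit-exact
#' round trip.
#'
#' @param phantom a [voxel_phantom()].
#' @param path file stem (without extension).
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  meta <- list(format = "mosfetcf_phantom", version = 1L,
               shape = dim(phantom$rsp), voxel_size = phantom$voxel_size,
               origin = phantom$origin, dtype = "float64le")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(phantom$rsp), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a voxel phantom written by [write_phantom()]
#'
#' @param path file stem used in [write_phantom()].
#' @return A [voxel_phantom()].
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "mosfetcf_phantom")) stop("not a phantom file: ", path)
  n <- prod(meta$shape)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  voxel_phantom(array(vals, dim = meta$shape), voxel_size = meta$voxel_size,
                origin = meta$origin)
}
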