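# Unit-cell geometries and voxelization.
#
# Membership is center-in-shape (no partial volumes): a voxel belongs to the
# channel mask iff its center lies within R_w of a segment axis (capped
# cylinders, union), and to the cell iff its center satisfies the cell's
# half-space description. Channels along shared cell edges are clipped by the
# cell boundary, so each cell is charged exactly its own sector of a shared
# channel -- summing over the honeycomb recovers full cylinders.

#' Construct a honeycomb base-unit geometry
#'
#' Supported kinds: `"cuboid"` (channels along the 12 edges of a cube of edge
#' `size`), `"rhombic_dodecahedron"` (channels along the 24 edges of the
#' rhombic dodecahedron with edge length `size`, vertices at
#' (+-u,+-u,+-u) and (+-2u,0,0),(0,+-2u,0),(0,0,+-2u) with u = size/sqrt(3)),
#' `"long_channel"` (a square prism of cross-section edge `size` and length
#' `length` with a single axial channel through the centerline) and
#' `"sphere"` (a channel-free spherical compartment of diameter `size`).
#' All outer faces carry the symmetry (zero normal flux) contract, so a single
#' cell stands for the infinite honeycomb.
#'
#' @param kind Geometry kind (see above).
#' @param size Edge length (cuboid, rhombic_dodecahedron, long_channel) or
#'   diameter (sphere), in mm.
#' @param R_w Outer channel radius (mm); ignored for spheres.
#' @param length Axial length for `long_channel` (mm).
#' @return A `unit_cell` object with fields `kind`, `size`, `R_w`, `segments`
#'   (tibble of axis endpoints), `volume` (analytic cell volume, mm^3),
#'   `bbox_lo`/`bbox_hi` and a half-space membership function.
#' @export
#' @examples
#' cube <- make_unit_cell("cuboid", size = 0.5, R_w = 0.05)
#' cube$volume                       # 0.125
#' nrow(cube$segments)               # 12
make_unit_cell <- function(kind, size, R_w = NA_real_, length = NULL) {
  kind <- match.arg(kind, c("cuboid", "rhombic_dodecahedron",
                            "long_channel", "sphere", "cuboid_octant"))
  check_positive(size, "size")
  if (kind != "sphere") {
    check_positive(R_w, "R_w")
    if (size <= 2 * R_w) {
      abort("Cell size must exceed the channel diameter 2*R_w.",
            class = "perfunet_geometry_error")
    }
  }
  seg <- function(p1, p2) c(p1, p2)
  if (kind == "cuboid") {
    s <- size
    v <- expand.grid(x = c(0, s), y = c(0, s), z = c(0, s))
    segs <- rbind(
      # 4 edges along each axis
      t(sapply(1:4, function(i) {
        yz <- expand.grid(c(0, s), c(0, s))[i, ]
        seg(c(0, yz[[1]], yz[[2]]), c(s, yz[[1]], yz[[2]]))
      })),
      t(sapply(1:4, function(i) {
        xz <- expand.grid(c(0, s), c(0, s))[i, ]
        seg(c(xz[[1]], 0, xz[[2]]), c(xz[[1]], s, xz[[2]]))
      })),
      t(sapply(1:4, function(i) {
        xy <- expand.grid(c(0, s), c(0, s))[i, ]
        seg(c(xy[[1]], xy[[2]], 0), c(xy[[1]], xy[[2]], s))
      }))
    )
    inside <- function(x, y, z) {
      x >= 0 & x < s & y >= 0 & y < s & z >= 0 & z < s
    }
    bbox <- list(lo = c(0, 0, 0), hi = c(s, s, s))
    vol <- s^3
  } else if (kind == "cuboid_octant") {
    # one octant of the cuboid cell: domain [0, s/2]^3, quarter-channels along
    # the three coordinate axes; all six faces are symmetry planes
    s <- size
    segs <- rbind(seg(c(0, 0, 0), c(s / 2, 0, 0)),
                  seg(c(0, 0, 0), c(0, s / 2, 0)),
                  seg(c(0, 0, 0), c(0, 0, s / 2)))
    inside <- function(x, y, z) {
      x >= 0 & x < s / 2 & y >= 0 & y < s / 2 & z >= 0 & z < s / 2
    }
    bbox <- list(lo = c(0, 0, 0), hi = c(s / 2, s / 2, s / 2))
    vol <- (s / 2)^3
  } else if (kind == "rhombic_dodecahedron") {
    a <- size
    u <- a / sqrt(3)
    deg3 <- as.matrix(expand.grid(x = c(-u, u), y = c(-u, u), z = c(-u, u)))
    deg4 <- rbind(c(2 * u, 0, 0), c(-2 * u, 0, 0),
                  c(0, 2 * u, 0), c(0, -2 * u, 0),
                  c(0, 0, 2 * u), c(0, 0, -2 * u))
    segs <- do.call(rbind, lapply(seq_len(nrow(deg3)), function(i) {
      p <- deg3[i, ]
      rbind(seg(p, c(2 * u * sign(p[1]), 0, 0)),
            seg(p, c(0, 2 * u * sign(p[2]), 0)),
            seg(p, c(0, 0, 2 * u * sign(p[3]))))
    }))
    inside <- function(x, y, z) {
      lim <- 2 * u
      (abs(x + y) < lim) & (abs(x - y) < lim) &
        (abs(x + z) < lim) & (abs(x - z) < lim) &
        (abs(y + z) < lim) & (abs(y - z) < lim)
    }
    bbox <- list(lo = c(-2 * u, -2 * u, -2 * u), hi = c(2 * u, 2 * u, 2 * u))
    vol <- 16 / 9 * sqrt(3) * a^3
  } else if (kind == "long_channel") {
    s <- size
    Lz <- if (is.null(length)) 4 * size else length
    segs <- matrix(seg(c(s / 2, s / 2, 0), c(s / 2, s / 2, Lz)), nrow = 1)
    inside <- function(x, y, z) {
      x >= 0 & x < s & y >= 0 & y < s & z >= 0 & z < Lz
    }
    bbox <- list(lo = c(0, 0, 0), hi = c(s, s, Lz))
    vol <- s^2 * Lz
  } else { # sphere
    R <- size / 2
    segs <- matrix(numeric(0), nrow = 0, ncol = 6)
    inside <- function(x, y, z) x^2 + y^2 + z^2 < R^2
    bbox <- list(lo = c(-R, -R, -R), hi = c(R, R, R))
    vol <- 4 / 3 * pi * R^3
  }
  segments <- tibble(
    id = seq_len(nrow(segs)),
    x1 = segs[, 1], y1 = segs[, 2], z1 = segs[, 3],
    x2 = segs[, 4], y2 = segs[, 5], z2 = segs[, 6],
    R_w = if (nrow(segs)) R_w else numeric(0),
    blocked = logical(nrow(segs))
  )
  structure(list(kind = kind, size = size, R_w = R_w, segments = segments,
                 volume = vol, bbox_lo = bbox$lo, bbox_hi = bbox$hi,
                 inside = inside),
            class = "unit_cell")
}

#' Mark unit-cell channel segments as blocked
#'
#' Blocked segments keep their volume accounting but their surface is treated
#' as impermeable (no-flux) in tissue solves.
#'
#' @param cell A `unit_cell`.
#' @param segment_ids Segment ids to block.
#' @export
block_segment <- function(cell, segment_ids) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!all(segment_ids %in% cell$segments$id)) {
    abort("Unknown segment id(s).", class = "perfunet_validation_error")
  }
  cell$segments$blocked[cell$segments$id %in% segment_ids] <- TRUE
  cell
}

# squared distance from points (x,y,z vectors) to a capped segment p1-p2
point_segment_dist2 <- function(x, y, z, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d * d)
  t <- ((x - p1[1]) * d[1] + (y - p1[2]) * d[2] + (z - p1[3]) * d[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  (x - p1[1] - t * d[1])^2 + (y - p1[2] - t * d[2])^2 + (z - p1[3] - t * d[3])^2
}

#' Voxelize a unit cell
#'
#' Cell-centered isotropic voxels over the cell's bounding box, half-open
#' membership convention. Voxels whose centers fall within `R_w` of any
#' channel segment axis form the channel mask (lumen plus wall); the remaining
#' in-cell voxels are tissue.
#'
#' @param cell A `unit_cell`.
#' @param h Voxel spacing (mm). Resolution floor: errors above `R_w/2`,
#'   warns above `R_w/5` (staircase error grows).
#' @return A `voxel_grid`: origin, spacing `h`, `shape`, logical arrays
#'   `in_cell`, `channel`, `tissue` and integer array `seg_id` (nearest
#'   channel segment, 0 where none). All grid faces are symmetry faces.
#' @export
voxelize <- function(cell, h) {
  stopifnot(inherits(cell, "unit_cell"))
  check_positive(h, "h")
  has_channels <- nrow(cell$segments) > 0
  if (has_channels) {
    if (h > cell$R_w / 2) {
      abort(sprintf("Voxel spacing h = %g exceeds R_w/2 = %g: channels cannot be resolved.",
                    h, cell$R_w / 2), class = "perfunet_geometry_error")
    }
    if (h > cell$R_w / 5) {
      warn(sprintf("h = %g above R_w/5 = %g: channel staircase error may be large.",
                   h, cell$R_w / 5))
    }
  }
  ext <- cell$bbox_hi - cell$bbox_lo
  shape <- pmax(1L, as.integer(round(ext / h)))
  # keep spacing exactly h; tiny rounding mismatch is absorbed by membership
  cx <- cell$bbox_lo[1] + (seq_len(shape[1]) - 0.5) * h
  cy <- cell$bbox_lo[2] + (seq_len(shape[2]) - 0.5) * h
  cz <- cell$bbox_lo[3] + (seq_len(shape[3]) - 0.5) * h
  X <- array(cx, dim = shape)
  Y <- array(rep(cy, each = shape[1]), dim = shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), dim = shape)

  in_cell <- cell$inside(X, Y, Z)
  seg_id <- array(0L, dim = shape)
  if (has_channels) {
    best <- array(Inf, dim = shape)
    for (i in seq_len(nrow(cell$segments))) {
      sgm <- cell$segments[i, ]
      d2 <- point_segment_dist2(X, Y, Z,
                                c(sgm$x1, sgm$y1, sgm$z1),
                                c(sgm$x2, sgm$y2, sgm$z2))
      hit <- d2 < best & d2 < sgm$R_w^2
      seg_id[hit] <- sgm$id
      best[hit] <- d2[hit]
    }
  }
  channel <- in_cell & seg_id > 0L
  tissue <- in_cell & seg_id == 0L
  if (!any(tissue)) {
    abort("Tissue mask is empty: the channels fill the whole cell at this resolution.",
          class = "perfunet_geometry_error")
  }
  structure(list(origin = cell$bbox_lo, h = h, shape = shape,
                 in_cell = in_cell, channel = channel, tissue = tissue,
                 seg_id = seg_id, cell = cell),
            class = "voxel_grid")
}

#' Volume accounting of a voxelized unit cell
#'
#' Tissue compartment volume, network volume (lumen plus wall, since the
#' channel mask extends to the outer radius `R_w`) and their ratio -- the
#' design objective of supplied tissue per unit network volume.
#'
#' @param grid A `voxel_grid`.
#' @return A tibble with `omega_t`, `omega_net` (mm^3) and `ratio`.
#' @export
measure_volumes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$h^3
  omega_net <- sum(grid$channel) * v
  omega_t <- sum(grid$tissue) * v
  if (omega_net == 0) {
    abort("Network volume is zero (no channels): the volume ratio is undefined. Spherical compartments have no supply network.",
          class = "perfunet_degeneracy_error")
  }
  tibble(omega_t = omega_t, omega_net = omega_net, ratio = omega_t / omega_net)
}

#' Generate a spatially correlated cell-density field
#'
#' White noise on the voxel grid is smoothed with an isotropic Gaussian
#' kernel (periodic convolution via FFT) and affinely rescaled to the target
#' mean and coefficient of variation, then clipped at zero. The kernel
#' standard deviation is `ell / sqrt(2)` so that the autocorrelation of the
#' resulting field decays to `exp(-1/2)` at lag `ell` -- `ell` is the
#' correlation length of the field, not of the kernel.
#'
#' @param grid A `voxel_grid`.
#' @param mean Target mean density (cells mm^-3).
#' @param cv Coefficient of variation (>= 0); 0 yields a uniform field.
#' @param ell Correlation length (mm).
#' @param seed Integer seed; the field is reproducible given (grid, mean, cv,
#'   ell, seed).
#' @return A `density_field`: the `values` array (cells mm^-3, same shape as
#'   the grid) plus generation metadata including the clipping fraction
#'   (warns above 1%).
#' @export
correlated_density_field <- function(grid, mean, cv, ell, seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  check_positive(mean, "mean")
  check_positive(cv, "cv", strict = FALSE)
  check_positive(ell, "ell")
  shape <- grid$shape
  if (cv == 0) {
    values <- array(mean, dim = shape)
    clip_frac <- 0
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    noise <- array(rnorm(prod(shape)), dim = shape)
    sigma <- ell / sqrt(2)
    freq1 <- function(n) {
      k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
      k / (n * grid$h)
    }
    fx <- freq1(shape[1]); fy <- freq1(shape[2]); fz <- freq1(shape[3])
    F2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
    H <- exp(-2 * pi^2 * sigma^2 * F2)
    sm <- Re(fft(fft(noise) * H, inverse = TRUE)) / prod(shape)
    z <- (sm - base::mean(sm)) / stats::sd(as.numeric(sm))
    values <- mean * (1 + cv * z)
    clip_frac <- base::mean(values < 0)
    values[values < 0] <- 0
    if (clip_frac > 0.01) {
      warn(sprintf("%.1f%% of density voxels clipped at zero; the marginal distribution is noticeably truncated.",
                   100 * clip_frac))
    }
  }
  structure(list(values = values, mean = mean, cv = cv, ell = ell,
                 seed = seed, clip_fraction = clip_frac, h = grid$h,
                 shape = shape),
            class = "density_field")
}

#' Density field as a voxel-index tibble
#'
#' @param x A `density_field`.
#' @param ... Unused.
#' @method as_tibble density_field
#' @export
as_tibble.density_field <- function(x, ...) {
  idx <- arrayInd(seq_along(x$values), .dim = x$shape)
  tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
         density = as.numeric(x$values))
}

#' Write a density field as CSV (voxel indices + density)
#'
#' @param field A `density_field`.
#' @param path Output CSV path.
#' @export
write_density_csv <- function(field, path) {
  write.csv(as_tibble.density_field(field), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid %d x %d x %d, h = %g mm: %d channel, %d tissue voxels\n",
              x$shape[1], x$shape[2], x$shape[3], x$h,
              sum(x$channel), sum(x$tissue)))
  invisible(x)
}
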