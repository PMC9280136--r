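#' Construct a gridded velocity field
#'
#' A 3-component velocity sampled on a uniform rectilinear grid, with an
#' optional inside-domain mask.  Grid node `(i, j, k)` sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param velocity numeric array of dimension `c(nx, ny, nz, 3)`, m/s.
#' @param spacing grid spacing per axis, length-3 positive numeric, m.
#' @param origin coordinates of node (1,1,1), length-3 numeric, m.
#' @param mask optional logical array `c(nx, ny, nz)`; `TRUE` marks nodes
#'   inside the flow domain.  Velocity must be finite wherever the mask
#'   is `TRUE` (and everywhere when no mask is given).
#' @param time sample time, s.
#' @return A list of class `"grid_velocity_field"` with elements `dims`,
#'   `spacing`, `origin`, `velocity`, `mask`, `time`.
#' @export
grid_velocity_field <- function(velocity, spacing, origin = c(0, 0, 0),
                                mask = NULL, time = 0) {
  if (!is.array(velocity) || length(dim(velocity)) != 4L ||
      dim(velocity)[4] != 3L) {
    stop("velocity must be an array of dimension c(nx, ny, nz, 3)",
         call. = FALSE)
  }
  dims <- dim(velocity)[1:3]
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be three finite numbers", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dims) || anyNA(mask)) {
      stop("mask must be a logical array matching the grid, without NAs",
           call. = FALSE)
    }
    inside <- which(mask)
    n3 <- prod(dims)
    ok <- vapply(0:2, function(c3) all(is.finite(velocity[inside + c3 * n3])),
                 logical(1))
    if (!all(ok)) {
      stop("velocity has non-finite values inside the mask", call. = FALSE)
    }
  } else if (!all(is.finite(velocity))) {
    stop("velocity has non-finite values", call. = FALSE)
  }
  structure(list(dims = as.integer(dims), spacing = spacing, origin = origin,
                 velocity = velocity, mask = mask, time = as.numeric(time)),
            class = "grid_velocity_field")
}

# shift an (nx,ny,nz) array by one node along `axis` (+1 or -1),
# padding the vacated plane with `fill`
.shift3 <- function(a, axis, by, fill) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (by == 1L) {         # out[i] = a[i+1]
    idx_dst[[axis]] <- seq_len(n - 1L)
    idx_src[[axis]] <- 2:n
  } else {                # out[i] = a[i-1]
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- seq_len(n - 1L)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Finite-difference velocity gradient of a gridded field
#'
#' Second-order central differences at interior nodes give the velocity
#' gradient tensor `g[i, j] = du_i/dx_j` at every node.  On an unmasked
#' grid, boundary nodes use one-sided second-order differences.  When a
#' mask is present, a node is defined only if its full central stencil
#' (all six axis neighbours) lies inside the mask and the grid: no
#' one-sided fallback is used near walls, because low-order one-sided
#' stencils would bias the near-wall shear, exactly the quantity of
#' interest.  Undefined nodes carry `NA`.
#'
#' @param field a [grid_velocity_field()].
#' @return A list of class `"gradient_field"`: `gradient` (array
#'   `c(nx, ny, nz, 3, 3)`, 1/s; `NA` at undefined nodes), `defined`
#'   (logical array), plus the grid geometry and `time`.
#' @export
compute_gradient <- function(field) {
  stopifnot(inherits(field, "grid_velocity_field"))
  d <- field$dims
  if (any(d < 3L)) {
    stop("grid must have at least 3 nodes along every axis", call. = FALSE)
  }
  v <- field$velocity
  h <- field$spacing
  grad <- array(NA_real_, c(d, 3L, 3L))
  masked <- !is.null(field$mask)

  if (masked) {
    defined <- field$mask
    for (ax in 1:3) {
      defined <- defined & .shift3(field$mask, ax, 1L, FALSE) &
        .shift3(field$mask, ax, -1L, FALSE)
    }
  } else {
    defined <- array(TRUE, d)
  }

  idx_all <- lapply(d, seq_len)
  for (comp in 1:3) {
    u <- array(v[, , , comp], d)
    if (masked) u[!field$mask] <- 0  # never read: stencil requires full mask
    for (ax in 1:3) {
      du <- (.shift3(u, ax, 1L, NA_real_) - .shift3(u, ax, -1L, NA_real_)) /
        (2 * h[ax])
      if (!masked) {
        # one-sided second-order at the two grid boundary planes
        n <- d[ax]
        lo <- idx_all; lo[[ax]] <- 1L
        l1 <- idx_all; l1[[ax]] <- 2L
        l2 <- idx_all; l2[[ax]] <- 3L
        hi <- idx_all; hi[[ax]] <- n
        h1 <- idx_all; h1[[ax]] <- n - 1L
        h2 <- idx_all; h2[[ax]] <- n - 2L
        du[lo[[1]], lo[[2]], lo[[3]]] <-
          (-3 * u[lo[[1]], lo[[2]], lo[[3]]] + 4 * u[l1[[1]], l1[[2]], l1[[3]]] -
             u[l2[[1]], l2[[2]], l2[[3]]]) / (2 * h[ax])
        du[hi[[1]], hi[[2]], hi[[3]]] <-
          (3 * u[hi[[1]], hi[[2]], hi[[3]]] - 4 * u[h1[[1]], h1[[2]], h1[[3]]] +
             u[h2[[1]], h2[[2]], h2[[3]]]) / (2 * h[ax])
      }
      grad[, , , comp, ax] <- du
    }
  }
  und <- !defined
  if (any(und)) {
    n3 <- prod(d)
    iu <- which(und)
    for (k in 0:8) grad[iu + k * n3] <- NA_real_
  }
  structure(list(gradient = grad, defined = defined, dims = d,
                 spacing = field$spacing, origin = field$origin,
                 time = field$time),
            class = "gradient_field")
}

#' Modality-magnitude fields of a gridded velocity field
#'
#' Applies the triple decomposition and the von Mises-like SSS at every
#' node where the finite-difference gradient is defined, yielding four
#' non-negative scalar fields: irrotational strain, rigid rotation, pure
#' shear, and SSS (all 1/s).  Undefined nodes carry `NA` and are
#' excluded from all downstream statistics.
#'
#' @param field a [grid_velocity_field()], or a precomputed
#'   `"gradient_field"` from [compute_gradient()].
#' @return A list of class `"modality_fields"`: arrays `strain`,
#'   `rotation`, `shear`, `sss` of dimension `dims`, the `defined`
#'   logical array, grid geometry and `time`.
#' @export
decompose_field <- function(field) {
  gf <- if (inherits(field, "gradient_field")) field else compute_gradient(field)
  d <- gf$dims
  idx <- which(gf$defined)
  n3 <- prod(d)
  gmat <- matrix(0, length(idx), 9L)
  for (k in 0:8) gmat[, k + 1L] <- gf$gradient[idx + k * n3]
  mags <- triple_magnitudes(gmat)
  mk <- function(col) {
    a <- array(NA_real_, d)
    a[idx] <- mags[, col]
    a
  }
  structure(list(strain = mk("strain"), rotation = mk("rotation"),
                 shear = mk("shear"), sss = mk("sss"),
                 defined = gf$defined, dims = d, spacing = gf$spacing,
                 origin = gf$origin, time = gf$time),
            class = "modality_fields")
}

# node quadrature weights: trapezoid-type, half weight on grid boundary
# planes (quarter on edges, eighth at corners), times the cell volume
.node_weights <- function(dims, spacing) {
  w1 <- function(n) c(0.5, rep(1, max(0L, n - 2L)), 0.5)[seq_len(n)]
  w <- outer(outer(w1(dims[1]), w1(dims[2])), w1(dims[3]))
  array(w, dims) * prod(spacing)
}

#' Volume-weighted spatial average of modality fields
#'
#' Averages each modality over the defined nodes, weighting each node by
#' its share of cell volume (uniform grid: product of spacings, halved
#' on grid boundary planes), and normalizing by the total represented
#' volume — the gridded analogue of integrating over the ventricle
#' volume and dividing by it.
#'
#' @param m a `"modality_fields"` object from [decompose_field()].
#' @return A one-row data frame: `time`, `mean_rotation`, `mean_shear`,
#'   `mean_strain`, `mean_sss` (1/s).
#' @export
spatial_average <- function(m) {
  stopifnot(inherits(m, "modality_fields"))
  idx <- which(m$defined)
  if (length(idx) == 0L) {
    stop("no defined nodes to average over", call. = FALSE)
  }
  w <- .node_weights(m$dims, m$spacing)[idx]
  wm <- function(a) sum(a[idx] * w) / sum(w)
  data.frame(time = m$time,
             mean_rotation = wm(m$rotation),
             mean_shear = wm(m$shear),
             mean_strain = wm(m$strain),
             mean_sss = wm(m$sss))
}

#' Extract thresholded 3D structures from a modality field
#'
#' Binarizes one modality at `value > threshold` (strict) and labels the
#' resulting voxel set into connected components using 26-connectivity,
#' the convention recorded in the result.  Undefined nodes never exceed
#' the threshold.
#'
#' @param m a `"modality_fields"` object.
#' @param modality one of `"rotation"`, `"shear"`, `"strain"`, `"sss"`.
#' @param threshold non-negative scalar, 1/s.
#' @return A data frame with one row per component, sorted by voxel
#'   count (descending): `label`, `voxels`, `centroid_x`, `centroid_y`,
#'   `centroid_z` (physical coordinates, m).  Attribute `connectivity`
#'   is 26.
#' @export
extract_structures <- function(m, modality, threshold) {
  stopifnot(inherits(m, "modality_fields"))
  if (!is.character(modality) || length(modality) != 1L ||
      !modality %in% c("rotation", "shear", "strain", "sss")) {
    stop("unknown modality name: ", paste(modality, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  a <- m[[modality]]
  bin <- !is.na(a) & a > threshold
  labels <- .label_components_cpp(as.logical(bin), m$dims)
  comp <- data.frame(label = integer(0), voxels = integer(0),
                     centroid_x = numeric(0), centroid_y = numeric(0),
                     centroid_z = numeric(0))
  if (any(labels > 0L)) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    co <- arrayInd(idx, m$dims)
    xyz <- sweep(sweep(co - 1, 2, m$spacing, `*`), 2, m$origin, `+`)
    voxels <- tabulate(lab)
    cx <- vapply(split(xyz[, 1], lab), mean, numeric(1))
    cy <- vapply(split(xyz[, 2], lab), mean, numeric(1))
    cz <- vapply(split(xyz[, 3], lab), mean, numeric(1))
    ord <- order(voxels, decreasing = TRUE)
    comp <- data.frame(label = seq_along(ord), voxels = voxels[ord],
                       centroid_x = unname(cx[ord]), centroid_y = unname(cy[ord]),
                       centroid_z = unname(cz[ord]))
  }
  attr(comp, "connectivity") <- 26L
  attr(comp, "modality") <- modality
  attr(comp, "threshold") <- threshold
  comp
}

#' Modality time series over a sequence of velocity frames
#'
#' Decomposes each frame and assembles the volume-averaged modality
#' magnitudes against time, the per-frame analogue of plotting mean
#' rotation, shear and strain over the heartbeat.
#'
#' @param fields a list of [grid_velocity_field()] objects with
#'   identical grid geometry and strictly increasing times.
#' @return A data frame with columns `time`, `mean_rotation`,
#'   `mean_shear`, `mean_strain`, `mean_sss`, one row per frame in time
#'   order.
#' @export
time_series <- function(fields) {
  if (!is.list(fields) || length(fields) == 0L ||
      !all(vapply(fields, inherits, logical(1), "grid_velocity_field"))) {
    stop("fields must be a non-empty list of grid velocity fields",
         call. = FALSE)
  }
  times <- vapply(fields, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  ref <- fields[[1]]
  for (f in fields[-1]) {
    if (!identical(f$dims, ref$dims) ||
        !isTRUE(all.equal(f$spacing, ref$spacing)) ||
        !isTRUE(all.equal(f$origin, ref$origin))) {
      stop("inconsistent grid geometry across frames", call. = FALSE)
    }
  }
  rows <- lapply(fields, function(f) spatial_average(decompose_field(f)))
  do.call(rbind, rows)
}
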