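#' @useDynLib triflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.check_gradient_tensor <- function(g) {
  if (!is.matrix(g) || !identical(dim(g), c(3L, 3L)) || !is.numeric(g)) {
    stop("velocity gradient must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (!all(is.finite(g))) {
    stop("velocity gradient contains non-finite entries", call. = FALSE)
  }
  storage.mode(g) <- "double"
  g
}

#' Double decomposition of a velocity gradient tensor
#'
#' Splits a 3x3 velocity gradient `g` (convention `g[i, j] = du_i/dx_j`,
#' units 1/s) into its symmetric part, the strain-rate tensor
#' `S = (g + t(g))/2`, and its skew-symmetric part, the spin tensor
#' `Omega = (g - t(g))/2`, so that `S + Omega` reconstructs `g` exactly.
#'
#' @param g numeric 3x3 matrix, finite entries, units 1/s.
#' @return A list of class `"double_decomposition"` with elements
#'   `strain_rate` (symmetric 3x3) and `spin` (skew-symmetric 3x3).
#' @examples
#' d <- double_decompose(matrix(c(0, 100, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE))
#' d$strain_rate + d$spin
#' @export
double_decompose <- function(g) {
  g <- .check_gradient_tensor(g)
  structure(list(strain_rate = (g + t(g)) / 2, spin = (g - t(g)) / 2),
            class = "double_decomposition")
}

#' Standardized real Schur form of a velocity gradient tensor
#'
#' Computes the real Schur factorization `g = q %*% t %*% t(q)` with `q`
#' orthogonal and `t` upper quasi-triangular, then applies fixed
#' standardization conventions so that the block entries are
#' deterministic: when a complex-conjugate eigenvalue pair exists, the
#' 1x1 block holding the real eigenvalue `lambda` is moved to position
#' (1,1) and the 2x2 block (equal diagonal entries `alpha`) to the lower
#' right; the block off-diagonals are swapped if needed so that
#' `|beta| >= |gamma|`; and column signs are flipped so that
#' `gamma >= 0`.  When all eigenvalues are real, `t` is upper triangular
#' and `gamma` is absent (no local rotation).
#'
#' @param g numeric 3x3 matrix, finite entries, units 1/s.
#' @return A list of class `"schur_form"`: `q`, `t`,
#'   `has_complex_pair`, and the named block entries `lam`, `alpha`,
#'   `beta`, `gamma` (NA when all eigenvalues are real), `eps`, `zeta`.
#' @seealso [triple_decompose()]
#' @export
schur_standardized <- function(g) {
  g <- .check_gradient_tensor(g)
  structure(.schur_standardized_cpp(g), class = "schur_form")
}

#' Triple decomposition of a velocity gradient tensor
#'
#' Decomposes `g` into irrotational strain (elongation/compression),
#' rigid-body rotation, and pure shear:
#' `g = q %*% (el + rr + sh) %*% t(q)`.  In the standardized Schur frame
#' the quasi-triangular form splits additively into a normal symmetric
#' part `el` (diagonal), a normal skew-symmetric part `rr` (the
#' rigid-rotation generator, entries `-gamma`/`gamma`), and the
#' non-normal remainder `sh` (strictly upper triangular), which carries
#' all of the shear.  The magnitude of each part is its Frobenius norm;
#' the three magnitudes are invariant under any orthogonal change of the
#' input frame.
#'
#' @param g numeric 3x3 matrix, finite entries, units 1/s.
#' @return A list of class `"triple_decomposition"` with the
#'   `schur` form, the parts `el`, `rr`, `sh` expressed in the Schur
#'   frame, and their Frobenius magnitudes `el_mag`, `rr_mag`, `sh_mag`
#'   (units 1/s).
#' @examples
#' # solid-body rotation at 3 rad/s: pure rotation, magnitude 3*sqrt(2)
#' g <- matrix(c(0, -3, 0, 3, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
#' triple_decompose(g)[c("el_mag", "rr_mag", "sh_mag")]
#' @export
triple_decompose <- function(g) {
  sf <- schur_standardized(g)
  tt <- sf$t
  el <- matrix(0, 3, 3)
  rr <- matrix(0, 3, 3)
  sh <- matrix(0, 3, 3)
  if (sf$has_complex_pair) {
    diag(el) <- c(sf$lam, sf$alpha, sf$alpha)
    rr[2, 3] <- -sf$gamma
    rr[3, 2] <- sf$gamma
    sh[1, 2] <- sf$eps
    sh[1, 3] <- sf$zeta
    sh[2, 3] <- sf$beta + sf$gamma
  } else {
    diag(el) <- diag(tt)
    sh[upper.tri(sh)] <- tt[upper.tri(tt)]
  }
  fro <- function(m) sqrt(sum(m^2))
  structure(list(schur = sf, el = el, rr = rr, sh = sh,
                 el_mag = fro(el), rr_mag = fro(rr), sh_mag = fro(sh)),
            class = "triple_decomposition")
}

#' Rotate triple-decomposition parts back to the original frame
#'
#' Applies the similarity `q %*% part %*% t(q)` to each part of a
#' [triple_decompose()] result, returning the strain, rotation and shear
#' tensors in the frame of the original velocity gradient.  Their sum
#' reconstructs the input tensor; Frobenius norms are unchanged.
#'
#' @param d a `"triple_decomposition"` object.
#' @return A list with 3x3 matrices `el`, `rr`, `sh` in the original frame.
#' @export
rotate_to_original_frame <- function(d) {
  stopifnot(inherits(d, "triple_decomposition"))
  q <- d$schur$q
  list(el = q %*% d$el %*% t(q),
       rr = q %*% d$rr %*% t(q),
       sh = q %*% d$sh %*% t(q))
}

#' Von Mises-like scalar shear stress (SSS)
#'
#' The scalar conventionally used in shear-induced platelet-activation
#' models, built from the shear-rate tensor
#' `gdot[i, j] = g[i, j] + g[j, i]` (viscosity deliberately omitted so
#' units stay 1/s, commensurate with the triple-decomposition
#' magnitudes):
#' \deqn{\tau = \sqrt{\tfrac16\left[(\tau_{xx}-\tau_{yy})^2 +
#'   (\tau_{yy}-\tau_{zz})^2 + (\tau_{xx}-\tau_{zz})^2\right] +
#'   \tau_{xy}^2 + \tau_{yz}^2 + \tau_{xz}^2}}
#' Because it is built from the symmetric strain-rate tensor, the SSS
#' conflates shear with irrotational strain: it equals the triple-
#' decomposition shear magnitude for single-plane pure shear, but is
#' strictly positive for trace-free diagonal (purely straining) tensors
#' whose shear magnitude is zero.
#'
#' @param g numeric 3x3 matrix, finite entries, units 1/s.
#' @return Non-negative scalar, units 1/s.
#' @examples
#' sss(diag(c(1, 2, -3)))          # sqrt(28): strain contaminates the SSS
#' triple_decompose(diag(c(1, 2, -3)))$sh_mag  # 0: no actual shear
#' @export
sss <- function(g) {
  g <- .check_gradient_tensor(g)
  tau <- g + t(g)
  sqrt(((tau[1, 1] - tau[2, 2])^2 + (tau[2, 2] - tau[3, 3])^2 +
          (tau[1, 1] - tau[3, 3])^2) / 6 +
         tau[1, 2]^2 + tau[2, 3]^2 + tau[1, 3]^2)
}

#' Triple-decomposition and SSS magnitudes for a batch of tensors
#'
#' Vectorized form of [triple_decompose()] and [sss()] for many tensors
#' at once (the per-voxel workhorse behind [decompose_field()]).
#'
#' @param gmat numeric matrix with 9 columns; each row is a 3x3 velocity
#'   gradient flattened column-major (as by `c(g)`).
#' @return A numeric matrix with columns `strain`, `rotation`, `shear`,
#'   `sss` (units 1/s), one row per input tensor.
#' @export
triple_magnitudes <- function(gmat) {
  if (is.numeric(gmat) && is.null(dim(gmat)) && length(gmat) == 9L) {
    gmat <- matrix(gmat, 1L, 9L)
  }
  if (!is.matrix(gmat) || ncol(gmat) != 9L) {
    stop("gmat must be an N x 9 matrix of flattened 3x3 tensors", call. = FALSE)
  }
  if (!all(is.finite(gmat))) {
    stop("gradient tensors contain non-finite entries", call. = FALSE)
  }
  storage.mode(gmat) <- "double"
  out <- .triple_magnitudes_cpp(gmat)
  colnames(out) <- c("strain", "rotation", "shear", "sss")
  out
}

#' Fluid properties for Reynolds-number estimates
#'
#' Density and dynamic viscosity of the working fluid.  Defaults are the
#' blood properties used throughout: density 1060 kg/m^3 and dynamic
#' viscosity 0.0027 Pa s.
#'
#' @param density fluid density, kg/m^3 (> 0).
#' @param dynamic_viscosity dynamic viscosity, Pa s (> 0).
#' @return A list of class `"fluid_properties"`.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.0027) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("density must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(dynamic_viscosity) || length(dynamic_viscosity) != 1L ||
      !is.finite(dynamic_viscosity) || dynamic_viscosity <= 0) {
    stop("dynamic_viscosity must be a single positive number", call. = FALSE)
  }
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}
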