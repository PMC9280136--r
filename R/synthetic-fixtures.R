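# Deterministic synthetic inputs: canonical velocity fields with
# closed-form gradients, LV volume curves with controlled landmarks, and
# seeded random gradient tensors.  These stand in for patient CFD data,
# which is not redistributable; they emulate the canonical local flow
# structures (uniform shear, solid-body rotation, irrotational strain,
# a trailing-line vortex, a round jet with a tanh shear layer).

# run expr with a private RNG state; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic velocity-field fixtures with closed-form gradients
#'
#' Generates a [grid_velocity_field()] on a cube of edge `extent`
#' centred at the origin, for one of the canonical cases:
#' \describe{
#'   \item{couette}{plane shear `u = (k y, 0, 0)`; `params$k` (1/s).}
#'   \item{solid_rotation}{rigid rotation `u = omega (-y, x, 0)`;
#'     `params$omega` (1/s).}
#'   \item{extensional}{trace-free irrotational strain
#'     `u = (a x, b y, -(a + b) z)`; `params$a`, `params$b` (1/s).}
#'   \item{lamb_oseen}{Lamb–Oseen vortex, tangential velocity
#'     `u_theta(r) = Gamma / (2 pi r) (1 - exp(-r^2 / r_c^2))`;
#'     `params$gamma` (m^2/s), `params$r_c` (m).  The core rotates
#'     rigidly at rate `Gamma / (2 pi r_c^2)`.}
#'   \item{round_jet}{axial jet with a tanh shear layer,
#'     `u_z(r) = U/2 (1 - tanh((r - R) / delta))`; `params$u` (m/s),
#'     `params$r_jet`, `params$delta` (m).  On the axis the closed-form
#'     gradient is taken as the flat-profile limit (the true radial
#'     derivative there is O(exp(-2 R / delta)), negligible for
#'     `R >> delta`).}
#'   \item{superposition}{pointwise sum of named cases;
#'     `params$cases` is a list of `list(case =, params =)` entries.}
#' }
#' Each case also returns the exact gradient field (element
#' `exact_gradient`, array `c(dims, 3, 3)`) for oracle tests.
#'
#' @param case fixture name (see above).
#' @param n nodes per axis (cubic grid).
#' @param extent cube edge length, m.
#' @param params named list of case parameters (defaults above are used
#'   for omitted entries).
#' @param time frame time, s.
#' @return A `"grid_velocity_field"` with an extra `exact_gradient`
#'   element.
#' @export
make_field <- function(case, n = 64, extent = 0.04, params = list(), time = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 3) {
    stop("n must be at least 3", call. = FALSE)
  }
  if (!is.numeric(extent) || extent <= 0) {
    stop("extent must be positive", call. = FALSE)
  }
  n <- as.integer(n)
  spacing <- rep(extent / (n - 1), 3)
  origin <- rep(-extent / 2, 3)
  x <- origin[1] + (seq_len(n) - 1) * spacing[1]
  dims <- c(n, n, n)
  X <- array(rep(x, times = n * n), dims)
  Y <- array(rep(rep(x, each = n), times = n), dims)
  Z <- array(rep(x, each = n * n), dims)

  vel <- array(0, c(dims, 3L))
  grad <- array(0, c(dims, 3L, 3L))
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default

  switch(case,
    couette = {
      k <- p("k", 100)
      vel[, , , 1] <- k * Y
      grad[, , , 1, 2] <- k
    },
    solid_rotation = {
      om <- p("omega", 50)
      vel[, , , 1] <- -om * Y
      vel[, , , 2] <- om * X
      grad[, , , 1, 2] <- -om
      grad[, , , 2, 1] <- om
    },
    extensional = {
      a <- p("a", 50); b <- p("b", 30)
      vel[, , , 1] <- a * X
      vel[, , , 2] <- b * Y
      vel[, , , 3] <- -(a + b) * Z
      grad[, , , 1, 1] <- a
      grad[, , , 2, 2] <- b
      grad[, , , 3, 3] <- -(a + b)
    },
    lamb_oseen = {
      gam <- p("gamma", 0.0157); rc <- p("r_c", 0.005)
      if (rc <= 0) stop("r_c must be positive", call. = FALSE)
      m <- rc^2
      rho <- X^2 + Y^2
      s <- rho / m
      small <- s < 1e-6
      # h = u_theta / r and its derivative w.r.t. rho = r^2 (smooth at 0)
      h <- ifelse(small,
                  gam / (2 * pi * m) * (1 - s / 2 + s^2 / 6),
                  gam / (2 * pi) * (1 - exp(-s)) / rho)
      hp <- ifelse(small,
                   gam / (2 * pi * m^2) * (-1 / 2 + s / 3 - s^2 / 8),
                   gam / (2 * pi) * (exp(-s) * (1 + s) - 1) / rho^2)
      vel[, , , 1] <- -Y * h
      vel[, , , 2] <- X * h
      grad[, , , 1, 1] <- -2 * X * Y * hp
      grad[, , , 1, 2] <- -h - 2 * Y^2 * hp
      grad[, , , 2, 1] <- h + 2 * X^2 * hp
      grad[, , , 2, 2] <- 2 * X * Y * hp
    },
    round_jet = {
      U <- p("u", 1); R <- p("r_jet", 0.01); del <- p("delta", 0.002)
      if (R <= 0 || del <= 0) stop("r_jet and delta must be positive",
                                   call. = FALSE)
      r <- sqrt(X^2 + Y^2)
      vel[, , , 3] <- U / 2 * (1 - tanh((r - R) / del))
      up <- -U / (2 * del) / cosh((r - R) / del)^2
      rr <- r
      rr[rr == 0] <- Inf  # axis: flat-profile limit, gradient 0
      grad[, , , 3, 1] <- up * X / rr
      grad[, , , 3, 2] <- up * Y / rr
    },
    superposition = {
      cases <- params$cases
      if (!is.list(cases) || length(cases) == 0L) {
        stop("superposition needs params$cases, a list of sub-specs",
             call. = FALSE)
      }
      for (cs in cases) {
        f <- make_field(cs$case, n = n, extent = extent,
                        params = if (is.null(cs$params)) list() else cs$params,
                        time = time)
        vel <- vel + f$velocity
        grad <- grad + f$exact_gradient
      }
    },
    stop("unknown fixture case: ", case, call. = FALSE)
  )
  field <- grid_velocity_field(vel, spacing, origin, mask = NULL, time = time)
  field$exact_gradient <- grad
  field
}

#' Seeded random velocity-gradient tensors
#'
#' Independent Gaussian entries, for exercising the tensor algebra over
#' generic (non-normal, non-symmetric) inputs.
#'
#' @param n number of tensors.
#' @param seed RNG seed (required; the global RNG state is preserved).
#' @param scale entry standard deviation, 1/s.
#' @return An `n x 9` matrix; each row a 3x3 tensor flattened
#'   column-major, as consumed by [triple_magnitudes()].
#' @export
random_gradient_tensors <- function(n, seed, scale = 100) {
  stopifnot(is.numeric(n), n >= 1, is.numeric(seed), is.numeric(scale),
            scale > 0)
  .with_seed(seed, matrix(stats::rnorm(as.integer(n) * 9L, sd = scale),
                          as.integer(n), 9L))
}

#' Synthetic LV volume curve with controlled landmarks
#'
#' Builds a smooth volume trace over one heartbeat starting in systole.
#' The volume rate dV/dt is modelled as a sum of three Gaussian waves —
#' one negative ejection wave in systole and two positive filling waves
#' (E and A) in diastole — so the trace is infinitely differentiable,
#' as a low-pass representation of echo-derived volumes should be.  The
#' wave centres and the E-wave width are calibrated by a damped fixed
#' point iteration so that the analytic curve places its landmarks
#' exactly at the requested times: the negative-to-positive zero
#' crossing of dV/dt at `t_diastole_start`, the two dV/dt maxima at
#' `t_e_peak` and `t_a_peak`, and the diastasis trough (the dV/dt
#' minimum between them) at `t_diastasis`; the wave amplitudes are
#' solved simultaneously so that the volume drops from exactly `edv` to
#' exactly `edv * (1 - ef)` at `t_diastole_start` and returns to `edv`
#' at `t_diastole_end`.  Defaults mirror the study subject: EDV 117 ml,
#' EF 0.64, 25 frames, and the default [scaling_schedule()] timings.
#'
#' @param edv end-diastolic volume, ml.
#' @param ef ejection fraction, strictly between 0 and 1.
#' @param frames number of evenly spaced samples over the cycle (>= 8).
#' @param t_diastole_start,t_e_peak,t_diastasis,t_a_peak,t_diastole_end
#'   landmark times, s, strictly increasing in this order.
#' @param ea_ratio ratio of E-wave to A-wave peak dV/dt (> 1 so the E
#'   wave is the higher peak).
#' @param noise Gaussian sampling noise standard deviation as a fraction
#'   of `edv` (e.g. 0.02 for 2%).
#' @param seed RNG seed, required when `noise > 0`.
#' @return A list: `curve` (a [volume_curve()] of the sampled, possibly
#'   noisy volumes), `truth` (the generating landmarks as a
#'   `"phase_timings"` object, with diastasis bounds resolved to the
#'   frame times bracketing `t_diastasis`), and the generating functions
#'   `V(t)` and `dV(t)` (noise-free).
#' @export
make_volume_curve <- function(edv = 117, ef = 0.64, frames = 25,
                              t_diastole_start = 0.420, t_e_peak = 0.525,
                              t_diastasis = 0.6775, t_a_peak = 0.779,
                              t_diastole_end = 0.830, ea_ratio = 2,
                              noise = 0, seed = NULL) {
  if (!is.numeric(ef) || ef <= 0 || ef >= 1) {
    stop("ef must be strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(edv) || edv <= 0) stop("edv must be positive", call. = FALSE)
  tl <- c(t_diastole_start, t_e_peak, t_diastasis, t_a_peak, t_diastole_end)
  if (any(!is.finite(tl)) || t_diastole_start <= 0 || any(diff(tl) <= 0)) {
    stop("landmark times must be positive and strictly increasing",
         call. = FALSE)
  }
  if (!is.numeric(ea_ratio) || ea_ratio <= 1) {
    stop("ea_ratio must exceed 1 (E wave is the higher dV/dt peak)",
         call. = FALSE)
  }
  if (frames < 8L) stop("need at least 8 frames", call. = FALSE)
  if (noise < 0) stop("noise must be non-negative", call. = FALSE)
  if (noise > 0 && is.null(seed)) {
    stop("a seed is required for a noisy curve", call. = FALSE)
  }
  esv <- edv * (1 - ef)
  sv <- edv - esv

  # wave widths: ejection spans systole; E width starts from the E-wave
  # rise time and is then calibrated against the diastasis trough;
  # the A wave must decay by end diastole
  s_sys <- t_diastole_start / 4
  s_e <- (t_e_peak - t_diastole_start) / 2.5
  s_a <- (t_diastole_end - t_a_peak) / 1.6
  mu <- c(0.62 * t_diastole_start, t_e_peak, t_a_peak)
  amp <- c(1, 1, 1)
  dV <- function(t) {
    -amp[1] * stats::dnorm(t, mu[1], s_sys) +
      amp[2] * stats::dnorm(t, mu[2], s_e) +
      amp[3] * stats::dnorm(t, mu[3], s_a)
  }
  cum <- function(t, m, s) stats::pnorm(t, m, s) - stats::pnorm(0, m, s)

  res <- Inf
  for (it in 1:400) {
    # amplitudes: net filling 0 over the cycle, stroke volume ejected by
    # diastole start; A-wave peak height = E-wave peak height / ea_ratio
    k_a <- s_a / (s_e * ea_ratio)
    cyc <- c(cum(t_diastole_end, mu[1], s_sys), cum(t_diastole_end, mu[2], s_e),
             cum(t_diastole_end, mu[3], s_a))
    sys <- c(cum(t_diastole_start, mu[1], s_sys),
             cum(t_diastole_start, mu[2], s_e),
             cum(t_diastole_start, mu[3], s_a))
    sol <- solve(rbind(c(-cyc[1], cyc[2] + k_a * cyc[3]),
                       c(-sys[1], sys[2] + k_a * sys[3])),
                 c(0, -sv))
    amp <- c(sol[1], sol[2], k_a * sol[2])
    if (any(amp <= 0)) {
      stop("volume-curve calibration failed: inconsistent landmark/EF ",
           "combination", call. = FALSE)
    }
    cross <- tryCatch(
      stats::uniroot(dV, c(mu[1], t_e_peak), tol = 1e-12)$root,
      error = function(e) NA_real_)
    if (is.na(cross)) {
      stop("volume-curve calibration failed: no systole-diastole crossing",
           call. = FALSE)
    }
    pk_e <- stats::optimize(dV, c(t_diastole_start, t_diastasis),
                            maximum = TRUE, tol = 1e-12)$maximum
    pk_a <- stats::optimize(dV, c(t_diastasis, t_diastole_end),
                            maximum = TRUE, tol = 1e-12)$maximum
    trough <- stats::optimize(dV, c(pk_e, pk_a), tol = 1e-12)$minimum
    step <- c(t_diastole_start - cross, t_e_peak - pk_e, t_a_peak - pk_a)
    res <- max(abs(c(step, t_diastasis - trough)))
    if (res < 1e-9) break
    mu <- mu + 0.9 * step
    s_e <- s_e + 0.4 * (t_diastasis - trough)
    if (s_e <= 0) {
      stop("volume-curve calibration failed: inconsistent landmark times",
           call. = FALSE)
    }
  }
  if (res >= 1e-6) {
    stop("volume-curve calibration did not converge for these landmarks",
         call. = FALSE)
  }

  Vfun <- function(t) {
    edv - amp[1] * cum(t, mu[1], s_sys) + amp[2] * cum(t, mu[2], s_e) +
      amp[3] * cum(t, mu[3], s_a)
  }

  times <- seq(0, t_diastole_end, length.out = as.integer(frames))
  vols <- Vfun(times)
  if (noise > 0) {
    vols <- vols + .with_seed(seed, stats::rnorm(length(vols),
                                                 sd = noise * edv))
    vols <- pmax(vols, 1e-6)
  }
  below <- times[times <= t_diastasis]
  above <- times[times >= t_diastasis]
  truth <- structure(list(
    diastole_start = t_diastole_start, e_peak = t_e_peak,
    diastasis_start = if (length(below)) max(below) else NA_real_,
    diastasis_end = if (length(above)) min(above) else NA_real_,
    a_peak = t_a_peak, diastole_end = t_diastole_end,
    diastasis_trough = t_diastasis,
    complete = TRUE, missing = character(0)), class = "phase_timings")
  list(curve = volume_curve(times, vols), truth = truth, V = Vfun, dV = dV)
}
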