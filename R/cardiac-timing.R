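#' Sampled left-ventricular volume curve
#'
#' @param times sample times, s, strictly increasing, at least 8 samples.
#' @param volumes LV volumes, ml, strictly positive and finite.
#' @return A list of class `"volume_curve"`.
#' @export
volume_curve <- function(times, volumes) {
  times <- as.numeric(times)
  volumes <- as.numeric(volumes)
  if (length(times) < 8L || length(volumes) != length(times)) {
    stop("need at least 8 (time, volume) samples of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("volumes must be finite and positive (ml)", call. = FALSE)
  }
  structure(list(times = times, volumes = volumes), class = "volume_curve")
}

#' Fit a smooth volume curve V(t)
#'
#' Cubic smoothing-spline fit to the sampled volumes, returning the
#' smooth function and its first derivative (the volume rate, dV/dt,
#' whose landmarks anchor the cardiac phases).  `smoothing = "gcv"`
#' (default) picks the penalty by generalized cross-validation;
#' a positive number is used directly as the spline's `lambda`;
#' `smoothing = 0` gives an interpolating cubic spline through all
#' samples (exact for cubic polynomials).
#'
#' @param curve a [volume_curve()].
#' @param smoothing `"gcv"`, or a non-negative number.
#' @return A list of class `"volume_spline"` with functions `V(t)` and
#'   `dV(t)`, the input `curve` and the `smoothing` used.
#' @export
fit_volume_spline <- function(curve, smoothing = "gcv") {
  stopifnot(inherits(curve, "volume_curve"))
  if (identical(smoothing, 0) || identical(smoothing, 0L)) {
    f <- stats::splinefun(curve$times, curve$volumes, method = "fmm")
    V <- function(t) f(t)
    dV <- function(t) f(t, deriv = 1)
  } else if (identical(smoothing, "gcv")) {
    fit <- stats::smooth.spline(curve$times, curve$volumes, cv = FALSE,
                                all.knots = TRUE)
    V <- function(t) stats::predict(fit, t)$y
    dV <- function(t) stats::predict(fit, t, deriv = 1)$y
  } else if (is.numeric(smoothing) && length(smoothing) == 1L &&
             is.finite(smoothing) && smoothing > 0) {
    fit <- stats::smooth.spline(curve$times, curve$volumes,
                                lambda = smoothing, all.knots = TRUE)
    V <- function(t) stats::predict(fit, t)$y
    dV <- function(t) stats::predict(fit, t, deriv = 1)$y
  } else {
    stop('smoothing must be "gcv" or a non-negative number', call. = FALSE)
  }
  structure(list(V = V, dV = dV, curve = curve, smoothing = smoothing),
            class = "volume_spline")
}

# locate local maxima of f on a dense grid, refined by golden-section
.refine_max <- function(f, lo, hi, tol = 1e-6) {
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

#' Detect cardiac phase landmarks from a smooth volume curve
#'
#' Six landmarks are extracted from dV/dt (isovolumetric phases are not
#' modelled).  The E-wave peak anchors the detection: it is the global
#' maximum of dV/dt after end systole (the E wave is by definition the
#' highest filling wave).  `diastole_start` is the zero crossing of
#' dV/dt from negative (contraction) to positive (expansion) nearest
#' before the E peak — anchoring on the dominant wave rather than on the
#' first sign change after the volume minimum keeps the crossing stable
#' when noise makes dV/dt wiggle around zero at end systole.  `a_peak`
#' is the most prominent later local maximum of dV/dt: among local
#' maxima after the E peak, candidates qualify only if the intervening
#' dV/dt valley drops below half the candidate's height (a genuine
#' atrial wave is separated from the E wave by a pronounced diastasis
#' trough; noise twins of the E peak are not), and the highest
#' qualifying candidate wins.  The diastasis bounds are the two original
#' acquisition frame times bracketing the dV/dt minimum between the two
#' peaks; `diastole_end` is the last frame time.  Zero crossings and
#' extrema are refined to 1e-6 s.  If no A wave is found, a partial
#' result is returned with the missing landmarks `NA` and listed in
#' `missing`.
#'
#' @param vs a `"volume_spline"` from [fit_volume_spline()], covering a
#'   full cycle that starts in systole.
#' @param frame_times the original acquisition frame times, s (defaults
#'   to the fitted curve's sample times).
#' @return A list of class `"phase_timings"`: `diastole_start`,
#'   `e_peak`, `diastasis_start`, `diastasis_end`, `a_peak`,
#'   `diastole_end` (s), `complete` flag and `missing` character vector.
#' @export
detect_phases <- function(vs, frame_times = vs$curve$times) {
  stopifnot(inherits(vs, "volume_spline"))
  frame_times <- sort(as.numeric(frame_times))
  t0 <- frame_times[1]
  t1 <- frame_times[length(frame_times)]
  grid <- seq(t0, t1, length.out = 2001L)
  dv <- vs$dV(grid)

  # end systole: global minimum of the fitted volume
  imin <- which.min(vs$V(grid))
  # E peak: global maximum of dV/dt after end systole
  after <- seq(max(imin, 2L), length(grid) - 1L)
  ie <- after[which.max(dv[after])]
  e_peak <- .refine_max(vs$dV, grid[ie - 1L], grid[ie + 1L])
  if (vs$dV(e_peak) <= 0) {
    stop("no filling wave found: dV/dt never becomes positive after end systole",
         call. = FALSE)
  }
  # diastole start: nearest negative -> positive crossing before the E peak
  pre <- which(grid[-1] <= e_peak & dv[-length(dv)] < 0 & dv[-1] >= 0)
  if (length(pre) == 0L) {
    stop("no systole-to-diastole transition found in dV/dt", call. = FALSE)
  }
  i <- pre[length(pre)]
  diastole_start <- stats::uniroot(vs$dV, c(grid[i], grid[i + 1]),
                                   tol = 1e-6)$root

  # candidate local maxima of dV/dt after the E peak
  dia <- which(grid > e_peak)
  g <- grid[dia]
  d <- dv[dia]
  n <- length(d)
  miss <- character(0)
  a_peak <- diastasis_start <- diastasis_end <- NA_real_
  peaks <- numeric(0)
  if (n > 2L) {
    ipk <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
    peaks <- vapply(ipk, function(j) .refine_max(vs$dV, g[j - 1L], g[j + 1L]),
                    numeric(1))
    pv <- vs$dV(peaks)
    # prominence: the valley between the E peak and the candidate must
    # drop below half the candidate height
    keep <- vapply(seq_along(peaks), function(k) {
      valley <- stats::optimize(vs$dV, c(e_peak, peaks[k]), tol = 1e-6)$objective
      pv[k] > 0 && valley < 0.5 * pv[k]
    }, logical(1))
    peaks <- peaks[keep]
    pv <- pv[keep]
  }
  if (length(peaks) == 0L) {
    miss <- c("a_peak", "diastasis_start", "diastasis_end")
  } else {
    a_peak <- peaks[which.max(pv)]
    trough <- stats::optimize(vs$dV, c(e_peak, a_peak), tol = 1e-6)$minimum
    below <- frame_times[frame_times <= trough]
    above <- frame_times[frame_times >= trough]
    if (length(below) && length(above)) {
      diastasis_start <- max(below)
      diastasis_end <- min(above)
    } else {
      miss <- c("diastasis_start", "diastasis_end")
    }
  }
  out <- list(diastole_start = diastole_start, e_peak = e_peak,
              diastasis_start = diastasis_start, diastasis_end = diastasis_end,
              a_peak = a_peak, diastole_end = t1,
              complete = length(miss) == 0L, missing = miss)
  structure(out, class = "phase_timings")
}

#' End-diastolic/end-systolic volume and ejection fraction
#'
#' `edv` is the maximum sampled volume, `esv` the minimum, and
#' `ef = (edv - esv) / edv`.
#'
#' @param curve a [volume_curve()].
#' @return A list with `edv` (ml), `esv` (ml) and `ef` (fraction).
#' @export
ejection_fraction <- function(curve) {
  stopifnot(inherits(curve, "volume_curve"))
  edv <- max(curve$volumes)
  esv <- min(curve$volumes)
  list(edv = edv, esv = esv, ef = (edv - esv) / edv)
}
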