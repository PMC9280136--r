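#' Mitral annulus axes
#'
#' Semi-axes of the planar two-half-ellipse orifice model: the two half
#' ellipses share the long (intercommissural) axis and have separate
#' anterior and posterior short axes.  Defaults are the study valve:
#' semi-long axis 12.8 mm, anterior short axis 8.1 mm, posterior short
#' axis 11.6 mm.
#'
#' @param l semi-long axis (half the intercommissural diameter), mm.
#' @param saa anterior short axis, mm.
#' @param sap posterior short axis, mm.
#' @return A list of class `"valve_axes"`.
#' @export
valve_axes <- function(l = 12.8, saa = 8.1, sap = 11.6) {
  vals <- c(l = l, saa = saa, sap = sap)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("valve axes must all be strictly positive", call. = FALSE)
  }
  structure(list(l = l, saa = saa, sap = sap), class = "valve_axes")
}

#' Leaflet short-axis scaling schedule
#'
#' Time knots over diastole with the scale factors applied to the
#' anterior (SAA) and posterior (SAP) short axes.  Scales of 1 mean the
#' fully open half-ellipse; a negative SAP scale folds the posterior
#' leaflet edge past the long axis so the projected edges overlap and
#' the orifice is closed.  Evaluation between knots is by monotone
#' piecewise-cubic Hermite interpolation (zero tangents at local extrema
#' and across plateaus, so interpolants never overshoot the physical
#' maximum of 1).  The default schedule is the idealized valve used in
#' the study: diastole start 0.420 s (0.40, -0.57), E-wave peak 0.525 s
#' (1.00, 1.00), diastasis 0.644-0.711 s (0.50, 0.70), A-wave peak
#' 0.779 s (0.85, 0.85), diastole end 0.830 s (0.40, -0.57).
#'
#' @param times knot times, s, strictly increasing.
#' @param saa_scale,sap_scale scale factors at the knots.
#' @return A list of class `"scaling_schedule"`.
#' @export
scaling_schedule <- function(times = c(0.420, 0.525, 0.644, 0.711, 0.779, 0.830),
                             saa_scale = c(0.40, 1.00, 0.50, 0.50, 0.85, 0.40),
                             sap_scale = c(-0.57, 1.00, 0.70, 0.70, 0.85, -0.57)) {
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("knot times must be strictly increasing", call. = FALSE)
  }
  if (length(saa_scale) != length(times) || length(sap_scale) != length(times)) {
    stop("scale vectors must match the knot times in length", call. = FALSE)
  }
  if (!all(is.finite(c(times, saa_scale, sap_scale)))) {
    stop("schedule entries must be finite", call. = FALSE)
  }
  structure(list(times = as.numeric(times), saa_scale = as.numeric(saa_scale),
                 sap_scale = as.numeric(sap_scale)),
            class = "scaling_schedule")
}

#' Clip (edge-to-edge repair) specification
#'
#' Position and width of a mitral valve clip along the coaptation line.
#' The clip centre sits at `s * l` from the valve centre (s in (-1, 1);
#' negative values anterolateral, positive posteromedial) and occludes a
#' segment of length `width` of the long axis, splitting the orifice
#' into two sub-openings.  The device width is a required model
#' parameter (default 5 mm, the arm span of common edge-to-edge clips).
#'
#' @param s dimensionless position scale, -1 < s < 1.
#' @param width clip width along the long axis, mm, >= 0.
#' @return A list of class `"clip_spec"`.
#' @export
clip_spec <- function(s, width = 5) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || abs(s) >= 1) {
    stop("clip position s must satisfy -1 < s < 1", call. = FALSE)
  }
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width < 0) {
    stop("clip width must be a non-negative length in mm", call. = FALSE)
  }
  structure(list(s = s, width = width), class = "clip_spec")
}

#' Assemble a time-resolved valve model
#'
#' Binds annulus axes, a scaling schedule and an optional clip into one
#' model object, checking that the schedule's first and last knots close
#' the valve (zero opening area) and, when a clip is present, that both
#' unclipped segments have positive length.
#'
#' @param axes a [valve_axes()].
#' @param schedule a [scaling_schedule()].
#' @param clip a [clip_spec()], or `NULL` for the untreated valve.
#' @return A list of class `"valve_model"`.
#' @export
valve_model <- function(axes = valve_axes(), schedule = scaling_schedule(),
                        clip = NULL) {
  stopifnot(inherits(axes, "valve_axes"), inherits(schedule, "scaling_schedule"))
  nk <- length(schedule$times)
  for (i in c(1L, nk)) {
    if (schedule$saa_scale[i] * axes$saa + schedule$sap_scale[i] * axes$sap > 0) {
      stop("schedule must close the valve at its first and last knots",
           call. = FALSE)
    }
  }
  geom <- NULL
  if (!is.null(clip)) {
    stopifnot(inherits(clip, "clip_spec"))
    if (axes$l * (1 - abs(clip$s)) - clip$width / 2 <= 0) {
      stop("clip leaves a non-positive unclipped segment", call. = FALSE)
    }
    geom <- size_clipped_valve(axes, clip)
  }
  structure(list(axes = axes, schedule = schedule, clip = clip,
                 clipped_geometry = geom),
            class = "valve_model")
}

#' Interpolate leaflet scalings at a time in diastole
#'
#' Monotone piecewise-cubic Hermite evaluation of the SAA and SAP scale
#' factors; knots are reproduced exactly and plateaus stay constant.
#' The valve is closed outside the schedule's time span (systole), so
#' times outside it are an error here; [area_at_time()] maps them to
#' zero area instead.
#'
#' @param sched a [scaling_schedule()].
#' @param t time, s (vectorized), within the schedule span.
#' @return A list with numeric vectors `saa_scale` and `sap_scale`.
#' @export
interpolate_scalings <- function(sched, t) {
  stopifnot(inherits(sched, "scaling_schedule"))
  rng <- range(sched$times)
  if (any(!is.finite(t)) || any(t < rng[1]) || any(t > rng[2])) {
    stop("t outside the diastole span of the schedule (valve closed in systole)",
         call. = FALSE)
  }
  list(saa_scale = pracma::pchip(sched$times, sched$saa_scale, t),
       sap_scale = pracma::pchip(sched$times, sched$sap_scale, t))
}

#' Orifice opening area of the two-half-ellipse model
#'
#' The open orifice is bounded by the anterior half ellipse with short
#' axis `saa_scale * saa` and the posterior one with `sap_scale * sap`,
#' sharing the long axis `2 l`, so the enclosed area is
#' `(pi/2) l (saa_scale * saa + sap_scale * sap)`, clamped at zero when
#' the projected leaflet edges overlap (negative sum: closed valve).
#'
#' @param axes a [valve_axes()] (lengths in mm).
#' @param saa_scale,sap_scale scale factors (vectorized).
#' @return Opening area in cm^2.
#' @export
opening_area <- function(axes, saa_scale, sap_scale) {
  stopifnot(inherits(axes, "valve_axes"))
  (pi / 2) * axes$l * pmax(0, saa_scale * axes$saa + sap_scale * axes$sap) / 100
}

#' Orifice area over the cardiac cycle
#'
#' Composes [interpolate_scalings()] and the opening-area formula
#' ([opening_area()] for the untreated valve, the two-sub-opening sum
#' for a clipped one).  Outside the schedule span the valve is closed
#' and the area is zero, making the area continuous over the full cycle.
#'
#' @param model a [valve_model()].
#' @param t time, s (vectorized).
#' @return Opening area in cm^2.
#' @export
area_at_time <- function(model, t) {
  stopifnot(inherits(model, "valve_model"))
  out <- numeric(length(t))
  rng <- range(model$schedule$times)
  open <- is.finite(t) & t >= rng[1] & t <= rng[2]
  if (any(open)) {
    sc <- interpolate_scalings(model$schedule, t[open])
    out[open] <- if (is.null(model$clip)) {
      opening_area(model$axes, sc$saa_scale, sc$sap_scale)
    } else {
      g <- model$clipped_geometry
      a1 <- (pi / 2) * g$a[1] *
        pmax(0, sc$saa_scale * g$b_a[1] + sc$sap_scale * g$b_p[1]) / 100
      a2 <- (pi / 2) * g$a[2] *
        pmax(0, sc$saa_scale * g$b_a[2] + sc$sap_scale * g$b_p[2]) / 100
      a1 + a2
    }
  }
  out
}

#' Arc length of a half ellipse
#'
#' Length of the half-ellipse arc with semi-axes `a` (along the cut) and
#' `b`, by adaptive quadrature of the exact integrand
#' `sqrt(a^2 sin^2 + b^2 cos^2)` over half a period, to relative
#' tolerance 1e-10.  Degenerate axes (`b = 0`) give `2 a`.
#'
#' @param a,b semi-axes (same units; returned length in those units).
#' @return The arc length.
#' @export
half_ellipse_arc <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b), a >= 0, b >= 0)
  if (a == 0 && b == 0) return(0)
  stats::integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                   0, pi, rel.tol = 1e-10, abs.tol = 0)$value
}

# total leaflet free-edge length at full opening (scales 1): the two
# half-ellipse arcs, excluding the straight long-axis chord
.edge_length <- function(a, b_a, b_p) {
  half_ellipse_arc(a, b_a) + half_ellipse_arc(a, b_p)
}

#' Size the double-orifice geometry after clip placement
#'
#' The clip converts the orifice into two sub-openings, each again two
#' half ellipses.  Their semi-long axes follow from the unclipped
#' segments of the coaptation line:
#' `a1 = (l (1 + s) - width/2) / 2`, `a2 = (l (1 - s) - width/2) / 2`.
#' Short axes keep the untreated anterior/posterior ratio and are
#' proportional to their opening's long axis, leaving one free common
#' multiplier `k`: `b_a[i] = k a[i] saa / l`, `b_p[i] = k a[i] sap / l`.
#' `k` is determined by conserving the total leaflet free-edge length at
#' E-wave peak: the two sub-openings' half-ellipse arcs must sum to the
#' untreated orifice's arcs.  The resulting scalar equation is solved by
#' root bracketing to 1e-10 (arc lengths by adaptive quadrature,
#' relative tolerance 1e-10).
#'
#' @param axes a [valve_axes()].
#' @param clip a [clip_spec()].
#' @return A list of class `"clipped_geometry"`: vectors `a`, `b_a`,
#'   `b_p` (mm, one entry per sub-opening), centres `center_x` (mm along
#'   the long axis), and the multiplier `k`.
#' @export
size_clipped_valve <- function(axes, clip) {
  stopifnot(inherits(axes, "valve_axes"), inherits(clip, "clip_spec"))
  l <- axes$l
  w <- clip$width
  s <- clip$s
  a1 <- (l * (1 + s) - w / 2) / 2
  a2 <- (l * (1 - s) - w / 2) / 2
  if (min(a1, a2) <= 0) {
    stop("clip leaves a non-positive unclipped segment", call. = FALSE)
  }
  target <- .edge_length(l, axes$saa, axes$sap)
  edge_k <- function(k) {
    .edge_length(a1, k * a1 * axes$saa / l, k * a1 * axes$sap / l) +
      .edge_length(a2, k * a2 * axes$saa / l, k * a2 * axes$sap / l) - target
  }
  k <- if (abs(edge_k(1)) < 1e-12 * target) {
    1
  } else {
    k_hi <- 2
    while (edge_k(k_hi) < 0 && k_hi < 1e3) k_hi <- k_hi * 2
    if (edge_k(k_hi) < 0) {
      stop("no edge-length-conserving multiplier in bracket (degenerate clip)",
           call. = FALSE)
    }
    stats::uniroot(edge_k, c(1, k_hi), tol = 1e-10)$root
  }
  center1 <- (-l + (s * l - w / 2)) / 2
  center2 <- (l + (s * l + w / 2)) / 2
  structure(list(a = c(a1, a2),
                 b_a = k * c(a1, a2) * axes$saa / l,
                 b_p = k * c(a1, a2) * axes$sap / l,
                 center_x = c(center1, center2),
                 k = k),
            class = "clipped_geometry")
}

#' Clipped-orifice area over the cardiac cycle
#'
#' Convenience wrapper: sizes the double-orifice geometry for the given
#' clip and evaluates the total opening area at `t`.  Both sub-openings
#' follow the untreated valve's scaling schedule.
#'
#' @param axes a [valve_axes()].
#' @param sched a [scaling_schedule()].
#' @param clip a [clip_spec()].
#' @param t time, s (vectorized).
#' @return Total opening area in cm^2.
#' @export
clipped_area_at_time <- function(axes, sched, clip, t) {
  area_at_time(valve_model(axes, sched, clip), t)
}

#' Point-in-orifice indicator
#'
#' Tests whether a point in the valve plane lies inside the open orifice
#' at time `t`.  Coordinates: origin at the annulus centre, `x` along
#' the long (intercommissural) axis, `y` positive toward the anterior
#' side, lengths in mm.  A point is inside a (sub-)opening when `x` lies
#' in its long-axis extent and
#' `-sap_scale * b_p * sqrt(1 - (dx/a)^2) < y <
#'   saa_scale * b_a * sqrt(1 - (dx/a)^2)`.
#' Everything is outside when the valve is closed (including all of
#' systole).
#'
#' @param model a [valve_model()].
#' @param point numeric length-2, `(x, y)` in mm.
#' @param t time, s.
#' @return Logical scalar.
#' @export
point_in_orifice <- function(model, point, t) {
  stopifnot(inherits(model, "valve_model"), length(point) == 2L,
            all(is.finite(point)), length(t) == 1L, is.finite(t))
  rng <- range(model$schedule$times)
  if (t < rng[1] || t > rng[2]) return(FALSE)
  sc <- interpolate_scalings(model$schedule, t)
  inside_opening <- function(cx, a, b_a, b_p) {
    dx <- (point[1] - cx) / a
    if (abs(dx) >= 1) return(FALSE)
    half <- sqrt(1 - dx^2)
    y <- point[2]
    (y < sc$saa_scale * b_a * half) && (y > -sc$sap_scale * b_p * half)
  }
  if (is.null(model$clip)) {
    inside_opening(0, model$axes$l, model$axes$saa, model$axes$sap)
  } else {
    g <- model$clipped_geometry
    inside_opening(g$center_x[1], g$a[1], g$b_a[1], g$b_p[1]) ||
      inside_opening(g$center_x[2], g$a[2], g$b_a[2], g$b_p[2])
  }
}

#' Reynolds number of the inflow jet
#'
#' `Re = rho U D / mu` with the length scale `D` taken as the diameter
#' of the circle whose area equals the valve opening area.
#'
#' @param fluid a [fluid_properties()].
#' @param peak_velocity jet velocity `U`, m/s, > 0.
#' @param opening_area_cm2 orifice area, cm^2, > 0.
#' @return Dimensionless Reynolds number.
#' @examples
#' jet_reynolds_number(fluid_properties(), 1.86, 4.0)  # about 1.6e4
#' @export
jet_reynolds_number <- function(fluid, peak_velocity, opening_area_cm2) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(peak_velocity) || peak_velocity <= 0 ||
      !is.finite(peak_velocity)) {
    stop("peak_velocity must be positive", call. = FALSE)
  }
  if (!is.numeric(opening_area_cm2) || opening_area_cm2 <= 0 ||
      !is.finite(opening_area_cm2)) {
    stop("opening area must be positive", call. = FALSE)
  }
  area_m2 <- opening_area_cm2 * 1e-4
  d <- 2 * sqrt(area_m2 / pi)
  fluid$density * peak_velocity * d / fluid$dynamic_viscosity
}
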