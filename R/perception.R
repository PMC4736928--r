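# Visual perception geometry: projection of stimuli onto the unit sphere
# centred on a focal fish and solid angles of spherical polygons.
#
# Conventions used throughout the package:
#   * azimuth: body-frame angle in [-pi, pi), 0 = straight ahead,
#     positive = leftward (counter-clockwise seen from above);
#   * elevation: angle from the horizontal swimming plane in [-pi/2, pi/2],
#     positive = upward;
#   * agents swim in the plane z = 0; spots float at z = +height.

#' Fish body model
#'
#' The simulated fish is a three-dimensional polygon with six vertices: a
#' nose vertex at the head position, four corner vertices (at +/- width/2
#' laterally and +/- height/2 vertically) located at 40% of the body length
#' behind the nose, and a tail vertex on the midline at the full body length
#' behind the nose. The bounding dimensions default to an adult zebrafish
#' (3.5 cm x 1 cm x 1 cm).
#'
#' @param length body length in metres.
#' @param width body width in metres.
#' @param height body height in metres.
#' @return an object of class `body_model`.
#' @export
body_model <- function(length = 0.035, width = 0.01, height = 0.01) {
  stopifnot(.is_number(length), .is_number(width), .is_number(height),
            length > 0, width > 0, height > 0)
  structure(list(length = length, width = width, height = height),
            class = "body_model")
}

#' World-frame coordinates of the six body vertices
#'
#' @param position numeric `(x, y)` head position in metres.
#' @param heading world-frame heading in radians.
#' @param body a [body_model()].
#' @return a 6 x 3 matrix of vertex coordinates (x, y, z), one row per
#'   vertex: nose, four mid-body corners, tail.
#' @export
body_vertices <- function(position, heading, body = body_model()) {
  stopifnot(length(position) >= 2)
  fx <- cos(heading); fy <- sin(heading)   # forward
  lx <- -sin(heading); ly <- cos(heading)  # left
  hw <- body$width / 2
  hh <- body$height / 2
  mid <- -0.4 * body$length                # corners 40% of length behind nose
  # body-frame (forward, left, up) offsets
  local <- rbind(
    c(0,    0,  0),    # nose
    c(mid,  hw,  hh),  # mid left top
    c(mid, -hw,  hh),  # mid right top
    c(mid,  hw, -hh),  # mid left bottom
    c(mid, -hw, -hh),  # mid right bottom
    c(-body$length, 0, 0)  # tail
  )
  cbind(position[1] + local[, 1] * fx + local[, 2] * lx,
        position[2] + local[, 1] * fy + local[, 2] * ly,
        local[, 3])
}

#' Project points onto the unit sphere centred on an observer
#'
#' Returns body-frame spherical coordinates (azimuth, elevation) of the
#' direction from the observer to each point. Azimuth 0 is straight ahead,
#' positive azimuth is to the left; elevation 0 is the horizontal plane,
#' positive is up. A point directly above or below the observer has
#' undefined azimuth, returned as 0 by convention.
#'
#' @param points a 3-vector `(x, y, z)` or an n x 3 matrix of points, metres.
#' @param observer_position `(x, y)` or `(x, y, z)` position of the observer;
#'   a missing z coordinate is taken as 0 (the swimming plane).
#' @param observer_heading world-frame heading of the observer in radians.
#' @return an n x 2 matrix with columns `azimuth` and `elevation` (radians).
#' @export
project_to_unit_sphere <- function(points, observer_position, observer_heading) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  oz <- if (length(observer_position) >= 3) observer_position[3] else 0
  dx <- points[, 1] - observer_position[1]
  dy <- points[, 2] - observer_position[2]
  dz <- points[, 3] - oz
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r < 1e-12)) {
    stop("degenerate geometry: point coincides with the observer position")
  }
  fx <- cos(observer_heading); fy <- sin(observer_heading)
  bx <- dx * fx + dy * fy    # forward component
  by <- -dx * fy + dy * fx   # leftward component
  rh <- sqrt(bx^2 + by^2)
  az <- ifelse(rh < 1e-15, 0, atan2(by, bx))
  el <- atan2(dz, rh)
  cbind(azimuth = wrap_angle(az), elevation = el)
}

#' Great-circle arc length between two points on the unit sphere
#'
#' @param p1,p2 sphere points as `(azimuth, elevation)` pairs in radians.
#' @return arc length in radians, in \[0, pi\].
#' @export
great_circle_arc <- function(p1, p2) {
  ca <- sin(p1[2]) * sin(p2[2]) +
    cos(p1[2]) * cos(p2[2]) * cos(p1[1] - p2[1])
  acos(.clamp(ca, -1, 1))
}

#' Solid angle of a spherical triangle from its side arcs
#'
#' Computes the spherical excess E via L'Huilier's theorem,
#' tan(E/4) = sqrt(tan(s/2) tan((s-a)/2) tan((s-b)/2) tan((s-c)/2)),
#' with s = (a + b + c) / 2 the semi-perimeter. The excess equals the
#' triangle's solid angle in steradians.
#'
#' @param a,b,c side arcs in radians. Each side must not exceed the sum of
#'   the other two and the perimeter must be below 2 pi.
#' @return the spherical excess in steradians (non-negative).
#' @export
spherical_triangle_solid_angle <- function(a, b, c) {
  .spherical_triangle_excess(a, b, c, strict = TRUE)
}

# Shared L'Huilier kernel. strict = TRUE errors on violated triangle
# inequalities; strict = FALSE treats small violations (rounding of
# near-degenerate triangles) as flat triangles with zero excess.
.spherical_triangle_excess <- function(a, b, c, strict = TRUE, tol = 1e-9) {
  stopifnot(.is_number(a), .is_number(b), .is_number(c))
  if (min(a, b, c) < 0) stop("invalid triangle: negative side arc")
  s <- (a + b + c) / 2
  excessive <- max(a, b, c) - (2 * s - max(a, b, c))
  if (excessive > tol || 2 * s >= 2 * pi) {
    if (strict) stop("invalid triangle: side arcs violate the spherical triangle inequality")
    return(0)
  }
  prod <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - c) / 2)
  4 * atan(sqrt(max(prod, 0)))
}

#' Solid angle of a spherical quadrilateral
#'
#' The quadrilateral, given as four ordered boundary points, is split along
#' the (v1, v3) diagonal into two spherical triangles whose excesses are
#' summed. For a convex quad the result is independent of the choice of
#' diagonal (within 1e-9).
#'
#' @param quad a 4 x 2 matrix of sphere points (azimuth, elevation), ordered
#'   along the boundary (no self-intersection).
#' @return solid angle in steradians.
#' @export
quad_solid_angle <- function(quad) {
  quad <- as.matrix(quad)
  stopifnot(nrow(quad) == 4, ncol(quad) == 2)
  # coincident vertices -> degenerate quad
  for (i in 1:3) for (j in (i + 1):4) {
    if (great_circle_arc(quad[i, ], quad[j, ]) < 1e-12) {
      warning("degenerate quadrilateral: coincident vertices; solid angle 0")
      return(0)
    }
  }
  d13 <- great_circle_arc(quad[1, ], quad[3, ])
  t1 <- .spherical_triangle_excess(
    great_circle_arc(quad[1, ], quad[2, ]),
    great_circle_arc(quad[2, ], quad[3, ]),
    d13, strict = FALSE)
  t2 <- .spherical_triangle_excess(
    d13,
    great_circle_arc(quad[3, ], quad[4, ]),
    great_circle_arc(quad[4, ], quad[1, ]),
    strict = FALSE)
  t1 + t2
}

#' Extremal-projection quadrilateral of a perceived fish
#'
#' Builds the target's six body vertices in world space, projects them on
#' the observer's unit sphere, and returns the four extremal projections
#' (minimum/maximum azimuth, minimum/maximum elevation) as an ordered
#' quadrilateral. Azimuth extremes are taken relative to the direction of
#' the target centroid, so a target near the rear of the visual field is
#' handled correctly across the +/-pi seam.
#'
#' @param observer,target [agent_state()] objects (position, heading).
#' @param body a [body_model()] describing the target.
#' @return a 4 x 2 matrix of sphere points ordered (min az, max el, max az,
#'   min el), suitable for [quad_solid_angle()].
#' @export
fish_extremal_quad <- function(observer, target, body = body_model()) {
  op <- observer$position
  # reject an observer inside the target's body volume
  dxy <- op[1:2] - target$position[1:2]
  f <- .heading_vec(target$heading)
  bx <- dxy[1] * f[1] + dxy[2] * f[2]
  by <- -dxy[1] * f[2] + dxy[2] * f[1]
  if (bx <= 1e-12 && bx >= -body$length - 1e-12 && abs(by) <= body$width / 2 + 1e-12) {
    stop("degenerate geometry: observer lies inside the target body volume")
  }
  verts <- body_vertices(target$position, target$heading, body)
  sp <- project_to_unit_sphere(verts, op, observer$heading)
  .extremal_quad(sp)
}

# Pick the 4 extremal points (min/max azimuth relative to the circular
# mean azimuth, min/max elevation) of a set of projections, ordered
# right -> top -> left -> bottom along the boundary. Views that collapse
# two extremes onto one vertex (e.g. tail-on) yield a repeated vertex; the
# quad then degenerates to a triangle.
.extremal_quad <- function(sp) {
  az0 <- atan2(mean(sin(sp[, 1])), mean(cos(sp[, 1])))
  rel <- wrap_angle(sp[, 1] - az0)
  rbind(sp[which.min(rel), ],   # rightmost
        sp[which.max(sp[, 2]), ],  # top
        sp[which.max(rel), ],   # leftmost
        sp[which.min(sp[, 2]), ])  # bottom
}

#' Extremal-projection quadrilateral of a floating spot
#'
#' The disc rim is reduced to its four extremal points as seen from the
#' observer: nearest, leftmost, farthest, and rightmost rim points (the
#' left/right axis is perpendicular to the horizontal observer-to-centre
#' direction). For an observer directly beneath the centre the axis is
#' taken along the observer's heading.
#'
#' @param observer an [agent_state()].
#' @param spot a [spot()] (centre, radius, height above the plane).
#' @return a 4 x 2 matrix of ordered sphere points.
#' @export
spot_extremal_quad <- function(observer, spot) {
  op <- observer$position
  dx <- spot$centre[1] - op[1]
  dy <- spot$centre[2] - op[2]
  dh <- sqrt(dx^2 + dy^2)
  if (dh < 1e-12) {
    u <- .heading_vec(observer$heading)
  } else {
    u <- c(dx, dy) / dh
  }
  v <- c(-u[2], u[1])  # leftward perpendicular (as seen looking along u)
  R <- spot$radius
  rim <- rbind(
    c(spot$centre - R * u, spot$height),  # nearest
    c(spot$centre + R * v, spot$height),  # leftmost
    c(spot$centre + R * u, spot$height),  # farthest
    c(spot$centre - R * v, spot$height))  # rightmost
  project_to_unit_sphere(rim, op, observer$heading)
}

# --- fast internal path used by the simulation loop -------------------------
# Same geometry as the public functions above, without class/attribute
# bookkeeping: scalar arcs, no names, degenerate triangles collapse to 0.

.arc_fast <- function(az1, el1, az2, el2) {
  ca <- sin(el1) * sin(el2) + cos(el1) * cos(el2) * cos(az1 - az2)
  acos(min(max(ca, -1), 1))
}

.excess_fast <- function(a, b, c) {
  s <- (a + b + c) / 2
  if (2 * s >= 2 * pi || max(a, b, c) > s + 1e-9) return(0)
  prod <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - c) / 2)
  4 * atan(sqrt(max(prod, 0)))
}

# solid angle of the quad through 4 (az, el) points, ordered on the boundary
.quad_omega_fast <- function(az, el) {
  d13 <- .arc_fast(az[1], el[1], az[3], el[3])
  .excess_fast(.arc_fast(az[1], el[1], az[2], el[2]),
               .arc_fast(az[2], el[2], az[3], el[3]), d13) +
    .excess_fast(d13, .arc_fast(az[3], el[3], az[4], el[4]),
                 .arc_fast(az[4], el[4], az[1], el[1]))
}

# project points (matrix n x 3) on the unit sphere of an observer at
# (ox, oy, 0) with the given heading; returns list(az, el) without names
.project_fast <- function(pts, ox, oy, heading) {
  dx <- pts[, 1] - ox
  dy <- pts[, 2] - oy
  dz <- pts[, 3]
  fx <- cos(heading); fy <- sin(heading)
  bx <- dx * fx + dy * fy
  by <- -dx * fy + dy * fx
  list(az = atan2(by, bx), el = atan2(dz, sqrt(bx^2 + by^2)))
}

# extremal-quad solid angle of a projected vertex set, with azimuth
# extremes taken relative to the reference bearing az0
.extremal_omega_fast <- function(az, el, az0) {
  rel <- wrap_angle(az - az0)
  i <- c(which.min(rel), which.max(el), which.max(rel), which.min(el))
  .quad_omega_fast(az[i], el[i])
}

#' Percept constructor
#'
#' One perceived stimulus: its kind, the body-frame bearing of its centroid,
#' and the solid angle it captures in the observer's visual field.
#'
#' @param kind `"fish"` or `"spot"`.
#' @param bearing body-frame bearing in radians, wrapped to \[-pi, pi).
#' @param solid_angle captured solid angle in steradians (>= 0, < 2 pi).
#' @param source_id identifier of the stimulus.
#' @return an object of class `percept`.
#' @export
percept <- function(kind, bearing, solid_angle, source_id = NA_integer_) {
  kind <- match.arg(kind, c("fish", "spot"))
  stopifnot(solid_angle >= 0, solid_angle < 2 * pi)
  structure(list(kind = kind, bearing = wrap_angle(bearing),
                 solid_angle = solid_angle, source_id = source_id),
            class = "percept")
}

#' Perceive congeners and spots from a focal agent
#'
#' Projects every other agent and every spot onto the focal agent's visual
#' sphere and returns one [percept()] per stimulus whose centroid bearing
#' falls within the field of view (default 270 degrees, i.e. bearings within
#' +/- 135 degrees of the heading, boundary inclusive). Stimuli in the rear
#' blind zone are omitted entirely; there is no occlusion and no distance
#' cut-off.
#'
#' @param focal an [agent_state()].
#' @param others list of [agent_state()] objects (excluding the focal).
#' @param spots list of [spot()] objects.
#' @param params a [behaviour_params()] (supplies the field of view and the
#'   body model).
#' @return a list of [percept()] objects (possibly empty).
#' @export
perceive <- function(focal, others = list(), spots = list(),
                     params = behaviour_params()) {
  half_fov <- params$fov / 2
  out <- list()
  body <- params$body
  for (i in seq_along(others)) {
    verts <- body_vertices(others[[i]]$position, others[[i]]$heading, body)
    centroid <- colMeans(verts)
    sp <- project_to_unit_sphere(centroid, focal$position, focal$heading)
    if (abs(sp[1]) > half_fov) next
    quad <- fish_extremal_quad(focal, others[[i]], body)
    # a collapsed extremal quad (tail-on or head-on view) degenerates to a
    # triangle whose excess still measures the captured area
    omega <- .quad_omega_fast(quad[, 1], quad[, 2])
    out[[length(out) + 1L]] <- percept("fish", sp[1], omega, source_id = i)
  }
  for (j in seq_along(spots)) {
    sp <- project_to_unit_sphere(c(spots[[j]]$centre, spots[[j]]$height),
                                 focal$position, focal$heading)
    if (abs(sp[1]) > half_fov) next
    quad <- spot_extremal_quad(focal, spots[[j]])
    omega <- .quad_omega_fast(quad[, 1], quad[, 2])
    out[[length(out) + 1L]] <- percept("spot", sp[1], omega, source_id = j)
  }
  out
}
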