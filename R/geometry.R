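#' Ellipse annotation
#'
#' One drawn ellipse in image-pixel coordinates. The image uses the raster
#' convention: origin at the top-left corner, x increasing rightward, y
#' increasing downward, so the "top right" of the image is large x, small y.
#'
#' @param cx,cy Center, in pixels.
#' @param a,b Semi-axes, in pixels; both must be strictly positive.
#' @param rotation Rotation of the a-axis, in radians. Normalized to
#'   `[0, pi)` on construction (an ellipse is invariant under rotation by pi).
#' @return An object of class `ellipse`: a named list with fields
#'   `cx`, `cy`, `a`, `b`, `rotation`.
#' @examples
#' e <- ellipse(250, 250, 40, 30, pi / 6)
#' ellipse_area(e)
#' @export
ellipse <- function(cx, cy, a, b, rotation = 0) {
  if (!all(is.finite(c(cx, cy, a, b, rotation)))) {
    stop("ellipse parameters must be finite numbers", call. = FALSE)
  }
  if (a <= 0 || b <= 0) {
    stop("invalid geometry: semi-axes must be strictly positive", call. = FALSE)
  }
  structure(
    list(cx = cx, cy = cy, a = a, b = b,
         rotation = normalize_rotation(rotation)),
    class = "ellipse"
  )
}

#' Normalize an ellipse rotation angle to `[0, pi)`
#'
#' @param theta Angle(s) in radians.
#' @return Angle(s) reduced modulo pi into `[0, pi)`.
#' @export
normalize_rotation <- function(theta) {
  theta %% pi
}

#' Image frame of the annotation interface
#'
#' The annotation canvas: airway slices are upsampled to a fixed pixel frame,
#' and the physical scale of one pixel follows from the CT voxel size divided
#' by the upsampling factor (0.5508 mm voxels shown at 10x give 0.05508
#' mm/pixel).
#'
#' @param width,height Frame size in pixels.
#' @param mm_per_pixel Physical size of one pixel, in mm.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(width = 500, height = 500, mm_per_pixel = 0.05508) {
  if (width <= 0 || height <= 0 || mm_per_pixel <= 0) {
    stop("frame dimensions and mm_per_pixel must be positive", call. = FALSE)
  }
  structure(list(width = width, height = height, mm_per_pixel = mm_per_pixel),
            class = "image_frame")
}

#' Area of an ellipse
#'
#' @param e An [ellipse()], or a numeric semi-axis length `a` when `b` is
#'   given (vectorized over `a` and `b`).
#' @param b Optional second semi-axis for the numeric form.
#' @return Area in squared pixels (`pi * a * b`); rotation- and
#'   translation-invariant.
#' @export
ellipse_area <- function(e, b = NULL) {
  if (inherits(e, "ellipse")) {
    return(pi * e$a * e$b)
  }
  if (is.null(b)) stop("supply an ellipse or both semi-axes", call. = FALSE)
  if (any(e <= 0) || any(b <= 0)) {
    stop("invalid geometry: semi-axes must be strictly positive", call. = FALSE)
  }
  pi * e * b
}

#' Equivalent-circle diameter of an area
#'
#' The diameter of the circle with the same area, `2 * sqrt(area / pi)`.
#' Used to place worker ellipses and area-only expert references on the same
#' footing: both annotators outline near-circular airway cross-sections, and
#' the experts record areas only, so all diameters are circular-equivalent.
#'
#' @param area Area(s), in any squared length unit; must be non-negative.
#' @return Diameter(s) in the corresponding length unit.
#' @export
equivalent_diameter <- function(area) {
  if (any(area < 0)) {
    stop("invalid measure: area must be non-negative", call. = FALSE)
  }
  2 * sqrt(area / pi)
}

# Is each point (x, y) strictly inside ellipse (cx, cy, a, b, rot)?
# Vectorized over points; the ellipse is scalar.
point_in_ellipse <- function(x, y, cx, cy, a, b, rotation) {
  dx <- x - cx
  dy <- y - cy
  co <- cos(rotation)
  si <- sin(rotation)
  u <- co * dx + si * dy
  v <- -si * dx + co * dy
  (u / a)^2 + (v / b)^2 < 1
}

# Boundary points of an ellipse at n parameter values (matrix n x 2).
ellipse_boundary <- function(cx, cy, a, b, rotation, n = 256L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  co <- cos(rotation)
  si <- sin(rotation)
  px <- a * cos(t)
  py <- b * sin(t)
  cbind(x = cx + co * px - si * py,
        y = cy + si * px + co * py)
}

#' Do two ellipses overlap?
#'
#' True iff the interiors intersect with positive area; containment of one
#' ellipse in the other counts as overlap. The test discretizes each boundary
#' to `n_vertices` points and checks (a) mutual center containment and (b)
#' boundary points of one ellipse falling inside the other. This is exact up
#' to discretization: sliver intersections thinner than the boundary spacing
#' can be missed, which is inconsequential for hand-drawn annotations that
#' are far from tangency.
#'
#' @param e1,e2 [ellipse()] objects.
#' @param n_vertices Number of boundary points per ellipse.
#' @return Logical scalar; symmetric in its arguments.
#' @export
ellipses_overlap <- function(e1, e2, n_vertices = 256L) {
  stopifnot(inherits(e1, "ellipse"), inherits(e2, "ellipse"))
  overlap_vec(
    cx1 = e1$cx, cy1 = e1$cy, a1 = e1$a, b1 = e1$b, r1 = e1$rotation,
    cx2 = e2$cx, cy2 = e2$cy, a2 = e2$a, b2 = e2$b, r2 = e2$rotation,
    n_vertices = n_vertices
  )
}

# Vectorized overlap over m ellipse pairs (all arguments length m).
# Returns a logical vector of length m.
overlap_vec <- function(cx1, cy1, a1, b1, r1, cx2, cy2, a2, b2, r2,
                        n_vertices = 256L) {
  m <- length(cx1)
  if (m == 0L) return(logical(0))
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cost <- cos(t)
  sint <- sin(t)

  inside_other <- function(cx, cy, a, b, r, ox, oy, oa, ob, orr) {
    # boundary of ellipse 1 (m x n), tested against ellipse 2 (per row)
    co <- cos(r); si <- sin(r)
    px <- outer(a, cost)            # m x n
    py <- outer(b, sint)
    bx <- cx + co * px - si * py
    by <- cy + si * px + co * py
    dx <- bx - ox
    dy <- by - oy
    co2 <- cos(orr); si2 <- sin(orr)
    u <- co2 * dx + si2 * dy
    v <- -si2 * dx + co2 * dy
    rowSums((u / oa)^2 + (v / ob)^2 < 1) > 0L
  }

  point_in <- function(x, y, cx, cy, a, b, r) {
    dx <- x - cx; dy <- y - cy
    co <- cos(r); si <- sin(r)
    u <- co * dx + si * dy
    v <- -si * dx + co * dy
    (u / a)^2 + (v / b)^2 < 1
  }

  # quick reject: bounding circles disjoint
  rad1 <- pmax(a1, b1)
  rad2 <- pmax(a2, b2)
  close_enough <- (cx1 - cx2)^2 + (cy1 - cy2)^2 < (rad1 + rad2)^2
  out <- logical(m)
  idx <- which(close_enough)
  if (length(idx) > 0L) {
    hit <- point_in(cx1[idx], cy1[idx], cx2[idx], cy2[idx],
                    a2[idx], b2[idx], r2[idx]) |
      point_in(cx2[idx], cy2[idx], cx1[idx], cy1[idx],
               a1[idx], b1[idx], r1[idx])
    todo <- idx[!hit]
    out[idx[hit]] <- TRUE
    if (length(todo) > 0L) {
      out[todo] <-
        inside_other(cx1[todo], cy1[todo], a1[todo], b1[todo], r1[todo],
                     cx2[todo], cy2[todo], a2[todo], b2[todo], r2[todo]) |
        inside_other(cx2[todo], cy2[todo], a2[todo], b2[todo], r2[todo],
                     cx1[todo], cy1[todo], a1[todo], b1[todo], r1[todo])
    }
  }
  out
}

#' Is an ellipse a "no airway" corner marker?
#'
#' Workers who see no airway are instructed to place a small circle in the
#' top right corner of the image. The predicate is true when the ellipse
#' center lies in the top-right corner region of the frame (the top-right
#' `corner_fraction` x `corner_fraction` of the canvas) and the mean
#' semi-axis is below `size_fraction` of the frame width. The interface
#' never specified these regions numerically, so both are configuration.
#'
#' @param e An [ellipse()].
#' @param frame An [image_frame()].
#' @param corner_fraction Corner region size as a fraction of each dimension.
#' @param size_fraction Maximum mean semi-axis as a fraction of frame width.
#' @return Logical scalar.
#' @export
is_corner_marker <- function(e, frame = image_frame(),
                             corner_fraction = 0.2, size_fraction = 0.1) {
  stopifnot(inherits(e, "ellipse"), inherits(frame, "image_frame"))
  corner_marker_vec(e$cx, e$cy, e$a, e$b, frame, corner_fraction, size_fraction)
}

# Vectorized corner-marker predicate over parallel coordinate vectors.
corner_marker_vec <- function(cx, cy, a, b, frame,
                              corner_fraction = 0.2, size_fraction = 0.1) {
  in_corner <- cx >= frame$width * (1 - corner_fraction) &
    cy <= frame$height * corner_fraction
  small <- (a + b) / 2 <= size_fraction * frame$width
  in_corner & small
}
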