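#' Construct an ellipse from geometric parameters
#'
#' @param center [point2d] center in pixels.
#' @param semi_major_px,semi_minor_px Semi-axis lengths a >= b > 0, pixels.
#' @param orientation_deg Angle of the major axis from the +x image axis,
#'   in degrees, normalized to (-90, 90]. The angle is measured in the
#'   (x, y) coordinate algebra directly; because image y points down, a
#'   positive angle appears clockwise on screen.
#' @param orientation_indeterminate Logical; TRUE when a == b (circle), where
#'   the major-axis direction carries no information.
#' @return An object of class `ellipse`.
#' @export
ellipse <- function(center, semi_major_px, semi_minor_px, orientation_deg,
                    orientation_indeterminate = FALSE) {
  stopifnot(inherits(center, "point2d"))
  a <- as.numeric(semi_major_px)
  b <- as.numeric(semi_minor_px)
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b) {
    stop("ellipse: requires semi_major_px >= semi_minor_px > 0", call. = FALSE)
  }
  structure(
    list(center = center, semi_major_px = a, semi_minor_px = b,
         orientation_deg = fold_axis_angle(as.numeric(orientation_deg)),
         orientation_indeterminate = isTRUE(orientation_indeterminate)),
    class = "ellipse"
  )
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf(
    "<ellipse center (%.4g, %.4g), a = %.6g px, b = %.6g px, psi = %.4g deg%s>\n",
    x$center$x, x$center$y, x$semi_major_px, x$semi_minor_px,
    x$orientation_deg,
    if (x$orientation_indeterminate) " (circle: orientation indeterminate)" else ""))
  invisible(x)
}

#' Pixel-to-millimetre scale from a calibration marker
#'
#' The scale is the marker's known physical diameter divided by its apparent
#' diameter in pixels (distance between the two annotated edge points).
#'
#' @param marker A [calibration_marker].
#' @return An object of class `calibration`: list with `scale_mm_per_px`.
#' @examples
#' m <- calibration_marker("scaling_ball", 25, point2d(0, 0), point2d(50, 0))
#' compute_scale(m)$scale_mm_per_px   # 0.5 mm per pixel
#' @export
compute_scale <- function(marker) {
  stopifnot(inherits(marker, "calibration_marker"))
  d_px <- euclid(marker$edge_point_a, marker$edge_point_b)
  if (d_px == 0) {
    stop("degenerate calibration marker: edge points coincide", call. = FALSE)
  }
  structure(list(scale_mm_per_px = marker$known_diameter_mm / d_px),
            class = "calibration")
}

#' Fit an ellipse to annotated rim points
#'
#' Direct least-squares conic fit: minimizes the algebraic residual of
#' \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F} over the rim points subject to the
#' ellipse constraint \eqn{4AC - B^2 = 1}, using the numerically stable
#' block decomposition of the constrained eigenproblem. The fit is closed
#' form and deterministic: no iteration, no starting value. Data are
#' centered and scaled internally for conditioning, so points lying exactly
#' on an ellipse are recovered to near machine precision.
#'
#' @param points List of [point2d] (or an n x 2 matrix), n >= 5, not all
#'   collinear.
#' @return An [ellipse]. When the fitted conic is a circle (a == b within
#'   1e-9 relative), `orientation_deg` is reported as 0 and
#'   `orientation_indeterminate` is TRUE.
#' @section Errors: Fewer than 5 points, collinear points, or a best conic
#'   that is not an ellipse (hyperbolic/parabolic) raise an error.
#' @references Halir R., Flusser J. (1998) Numerically stable direct least
#'   squares fitting of ellipses; Fitzgibbon A., Pilu M., Fisher R. (1999)
#'   Direct least square fitting of ellipses.
#' @export
fit_ellipse <- function(points) {
  xy <- as_point_matrix(points)
  if (nrow(xy) < 5L) {
    stop(sprintf("fit_ellipse: %d points given; at least 5 required", nrow(xy)),
         call. = FALSE)
  }
  if (!all(is.finite(xy))) {
    stop("fit_ellipse: non-finite coordinates", call. = FALSE)
  }
  if (points_collinear(xy)) {
    stop("fit_ellipse: points are collinear; no ellipse fits them",
         call. = FALSE)
  }
  ctr <- colMeans(xy)
  sc <- sqrt(mean((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
  u <- (xy[, 1] - ctr[1]) / sc
  v <- (xy[, 2] - ctr[2]) / sc

  D1 <- cbind(u * u, u * v, v * v)
  D2 <- cbind(u, v, 1)

  # The constraint below forces an ellipse even through hyperbolic data, so
  # first ask the unconstrained best conic (smallest singular direction of
  # the design matrix) what the points really describe.
  free <- eigen(crossprod(cbind(D1, D2)), symmetric = TRUE)$vectors[, 6L]
  if (4 * free[1] * free[3] - free[2]^2 <= 0) {
    stop("fit_ellipse: best-fitting conic is not an ellipse", call. = FALSE)
  }

  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) {
    stop("fit_ellipse: best-fitting conic is not an ellipse", call. = FALSE)
  }
  a1 <- vec[, ok[1]]
  coef <- c(a1, as.vector(Tm %*% a1))   # (A, B, C, D, E, F) in scaled frame
  if (coef[1] < 0) coef <- -coef        # fix sign so the quadratic part is PD

  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  ctr_s <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  mu <- A * ctr_s[1]^2 + B * ctr_s[1] * ctr_s[2] + C * ctr_s[2]^2 +
    D * ctr_s[1] + E * ctr_s[2] + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)      # eigenvalues decreasing
  ax2 <- -mu / eq$values                # squared semi-axes
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) {
    stop("fit_ellipse: best-fitting conic is not an ellipse", call. = FALSE)
  }
  # smaller eigenvalue -> larger axis
  a_s <- sqrt(ax2[2]); b_s <- sqrt(ax2[1])
  major_vec <- eq$vectors[, 2]
  psi <- fold_axis_angle(rad2deg(atan2(major_vec[2], major_vec[1])))

  a_px <- a_s * sc
  b_px <- b_s * sc
  circle <- (a_px - b_px) <= 1e-9 * a_px
  ellipse(center = point2d(ctr_s[1] * sc + ctr[1], ctr_s[2] * sc + ctr[2]),
          semi_major_px = a_px, semi_minor_px = b_px,
          orientation_deg = if (circle) 0 else psi,
          orientation_indeterminate = circle)
}

#' Radiographic cup anteversion from the fitted ellipse
#'
#' On an AP radiograph the circular cup opening projects to an ellipse; the
#' radiographic version is \eqn{V = \arcsin(b/a)} where `b` and `a` are the
#' semi-minor and semi-major axes. A single AP view cannot distinguish ante-
#' from retroversion, so the returned angle is the non-negative magnitude in
#' \[0, 90\] degrees (90 corresponds to a circular projection).
#'
#' @param e An [ellipse].
#' @return Anteversion in degrees.
#' @examples
#' e <- ellipse(point2d(0, 0), 10, 5, 0)
#' anteversion(e)   # 30
#' @export
anteversion <- function(e) {
  stopifnot(inherits(e, "ellipse"))
  rad2deg(asin(min(1, e$semi_minor_px / e$semi_major_px)))
}

#' Reference line through two landmarks
#'
#' @param point_a,point_b Distinct [point2d]. For the inter-ischial line these
#'   are the inferior-most points of the two ischial tuberosities.
#' @return An object of class `reference_line`.
#' @export
reference_line <- function(point_a, point_b) {
  stopifnot(inherits(point_a, "point2d"), inherits(point_b, "point2d"))
  if (euclid(point_a, point_b) == 0) {
    stop("reference_line: points coincide; line is undefined", call. = FALSE)
  }
  structure(list(point_a = point_a, point_b = point_b),
            class = "reference_line")
}

line_direction <- function(ref) {
  d <- c(ref$point_b$x - ref$point_a$x, ref$point_b$y - ref$point_a$y)
  d / sqrt(sum(d^2))
}

#' Cup inclination relative to a reference line
#'
#' The acute angle between the line along the ellipse's major axis (through
#' the medial and lateral apexes of the cup face) and the transverse
#' reference line. Computed from direction vectors, so vertical reference
#' lines are legal.
#'
#' @param e An [ellipse]; if its orientation is indeterminate (circular
#'   projection) the inclination is undefined and `NA` is returned.
#' @param ref A [reference_line].
#' @return Inclination in degrees, in \[0, 90\], or `NA_real_` for a circle.
#' @export
inclination <- function(e, ref) {
  stopifnot(inherits(e, "ellipse"), inherits(ref, "reference_line"))
  if (e$orientation_indeterminate) return(NA_real_)
  u <- c(cos(deg2rad(e$orientation_deg)), sin(deg2rad(e$orientation_deg)))
  v <- line_direction(ref)
  rad2deg(acos(min(1, abs(sum(u * v)))))
}

#' Calibrated signed leg length relative to a reference line
#'
#' Perpendicular distance in pixels from the trochanter landmark to the
#' inter-ischial (reference) line, converted to millimetres with the
#' calibration scale. The sign is positive when the landmark lies on the
#' inferior (larger image `y`) side of the line; for an exactly vertical
#' reference line, where "inferior" is undefined, the positive side is
#' taken as larger `x`.
#'
#' @param ref A [reference_line].
#' @param trochanter [point2d] trochanter landmark.
#' @param cal A `calibration` from [compute_scale()].
#' @return Signed leg length in millimetres.
#' @examples
#' ref <- reference_line(point2d(0, 0), point2d(100, 0))
#' cal <- structure(list(scale_mm_per_px = 0.5), class = "calibration")
#' leg_length(ref, point2d(30, 40), cal)   # +20
#' @export
leg_length <- function(ref, trochanter, cal) {
  stopifnot(inherits(ref, "reference_line"), inherits(trochanter, "point2d"),
            inherits(cal, "calibration"))
  d <- line_direction(ref)
  n <- c(-d[2], d[1])                       # unit normal
  if (n[2] < 0 || (n[2] == 0 && n[1] < 0)) n <- -n  # point toward inferior
  w <- c(trochanter$x - ref$point_a$x, trochanter$y - ref$point_a$y)
  sum(w * n) * cal$scale_mm_per_px
}

#' Leg length discrepancy
#'
#' Difference of the two per-leg radiographic leg lengths measured on the
#' same image: positive when the left leg is longer.
#'
#' @param left_mm,right_mm Signed per-leg lengths in mm.
#' @return `left_mm - right_mm`, in mm.
#' @export
leg_length_discrepancy <- function(left_mm, right_mm) left_mm - right_mm

#' Measure one annotated radiograph
#'
#' Runs the full per-image measurement: calibration scale from the marker,
#' inter-ischial reference line from the pelvis landmarks, and per hip the
#' ellipse fit to the rim points, anteversion, inclination and signed leg
#' length. The inter-ischial line serves as the reference for both
#' inclination and leg length.
#'
#' @param rec A [radiograph_annotation] that passes [validate_annotation()].
#' @return A list of class `radiograph_measurement` with elements
#'   `measurements` (data frame: one row per hip with columns `side`,
#'   `anteversion_deg`, `inclination_deg`, `leg_length_mm`,
#'   `trochanter_kind`, `inclination_indeterminate`), `scale_mm_per_px`,
#'   and the identifying fields of the record.
#' @export
measure_radiograph <- function(rec) {
  stopifnot(inherits(rec, "radiograph_annotation"))
  iss <- blocking_issues(validate_annotation(rec))
  if (nrow(iss) > 0L) {
    stop(sprintf("cannot measure image '%s': %s (%s)", rec$image_id,
                 iss$code[1], iss$message[1]), call. = FALSE)
  }
  cal <- compute_scale(rec$calibration)
  ref <- reference_line(rec$pelvis$left_ischial, rec$pelvis$right_ischial)
  rows <- lapply(rec$hips, function(h) {
    e <- tryCatch(fit_ellipse(h$rim_points), error = function(err) {
      stop(sprintf("image '%s', %s hip: %s", rec$image_id, h$side,
                   conditionMessage(err)), call. = FALSE)
    })
    data.frame(
      side = h$side,
      anteversion_deg = anteversion(e),
      inclination_deg = inclination(e, ref),
      leg_length_mm = leg_length(ref, h$trochanter_point, cal),
      trochanter_kind = h$trochanter_kind,
      inclination_indeterminate = e$orientation_indeterminate,
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(image_id = rec$image_id, program_id = rec$program_id,
         reviewer_id = rec$reviewer_id, replicate_index = rec$replicate_index,
         scale_mm_per_px = cal$scale_mm_per_px,
         measurements = do.call(rbind, rows)),
    class = "radiograph_measurement"
  )
}

#' Measure every record of an annotation set
#'
#' Records that fail validation or whose ellipse fit degenerates are skipped
#' (not fatal); their identities and error messages are returned in the
#' `errors` attribute so batch runs can report them.
#'
#' @param set An [annotation_set].
#' @return A data frame with one row per (record, hip): columns `image_id`,
#'   `program_id`, `reviewer_id`, `replicate_index`, `side`,
#'   `anteversion_deg`, `inclination_deg`, `leg_length_mm`,
#'   `scale_mm_per_px`. Attribute `errors` is a data frame of skipped
#'   records (`image_id`, `program_id`, `reviewer_id`, `replicate_index`,
#'   `error`).
#' @export
measure_annotation_set <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  rows <- list()
  errs <- list()
  for (rec in set$records) {
    m <- tryCatch(measure_radiograph(rec), error = function(e) e)
    if (inherits(m, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        image_id = rec$image_id, program_id = rec$program_id,
        reviewer_id = rec$reviewer_id, replicate_index = rec$replicate_index,
        error = conditionMessage(m), stringsAsFactors = FALSE)
      next
    }
    df <- m$measurements
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = m$image_id, program_id = m$program_id,
      reviewer_id = m$reviewer_id, replicate_index = m$replicate_index,
      side = df$side, anteversion_deg = df$anteversion_deg,
      inclination_deg = df$inclination_deg, leg_length_mm = df$leg_length_mm,
      scale_mm_per_px = m$scale_mm_per_px, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    image_id = character(), program_id = character(), reviewer_id = character(),
    replicate_index = integer(), side = character(),
    anteversion_deg = numeric(), inclination_deg = numeric(),
    leg_length_mm = numeric(), scale_mm_per_px = numeric(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else data.frame(
    image_id = character(), program_id = character(), reviewer_id = character(),
    replicate_index = integer(), error = character(), stringsAsFactors = FALSE)
  out
}

#' Convert wide per-hip measurements to the long measurement table
#'
#' Reshapes the output of [measure_annotation_set()] into the long format
#' used by the agreement statistics: one row per (record, hip, parameter)
#' with `parameter` in `anteversion`, `inclination`, `leg_length`.
#' Indeterminate inclinations (`NA`) are dropped.
#'
#' @param wide Data frame from [measure_annotation_set()].
#' @return A long-format measurement table data frame with columns
#'   `image_id`, `side`, `program_id`, `reviewer_id`, `replicate_index`,
#'   `parameter`, `value`.
#' @export
measurements_to_table <- function(wide) {
  cols <- c(anteversion = "anteversion_deg", inclination = "inclination_deg",
            leg_length = "leg_length_mm")
  pieces <- lapply(names(cols), function(p) {
    data.frame(image_id = wide$image_id, side = wide$side,
               program_id = wide$program_id, reviewer_id = wide$reviewer_id,
               replicate_index = wide$replicate_index,
               parameter = p, value = wide[[cols[[p]]]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[!is.na(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
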