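#' Create a 2D image point
#'
#' Points use image conventions: the origin is the top-left corner of the
#' radiograph, `x` increases to the right (image columns) and `y` increases
#' downward, i.e. toward the patient's feet (inferior) on an AP pelvic view.
#' All coordinates are in pixels.
#'
#' @param x,y Finite numeric scalars, pixel coordinates.
#' @return An object of class `point2d`: a list with elements `x` and `y`.
#' @examples
#' point2d(512, 384)
#' @export
point2d <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != 1L || length(y) != 1L || !is.finite(x) || !is.finite(y)) {
    stop("point2d: x and y must be finite numeric scalars", call. = FALSE)
  }
  structure(list(x = x, y = y), class = "point2d")
}

#' @export
print.point2d <- function(x, ...) {
  cat(sprintf("<point2d (%.6g, %.6g) px>\n", x$x, x$y))
  invisible(x)
}

# Internal: list of point2d -> n x 2 matrix
as_point_matrix <- function(points) {
  if (inherits(points, "point2d")) points <- list(points)
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2L)
    return(points)
  }
  do.call(rbind, lapply(points, function(p) c(p$x, p$y)))
}

#' Create a calibration marker annotation
#'
#' A marker of known physical diameter visible on the image (a 25 mm scaling
#' ball, or the femoral head implant itself when no ball was placed), stored
#' as its two diametrically opposite edge points so the pixel-to-millimetre
#' scale is computed, not assumed.
#'
#' @param marker_kind `"scaling_ball"` or `"femoral_head"`.
#' @param known_diameter_mm True physical diameter of the marker in mm, > 0.
#' @param edge_point_a,edge_point_b [point2d] edge points across the marker.
#' @return An object of class `calibration_marker`.
#' @seealso [compute_scale()]
#' @export
calibration_marker <- function(marker_kind = c("scaling_ball", "femoral_head"),
                               known_diameter_mm,
                               edge_point_a, edge_point_b) {
  marker_kind <- match.arg(marker_kind)
  known_diameter_mm <- as.numeric(known_diameter_mm)
  if (!is.finite(known_diameter_mm) || known_diameter_mm <= 0) {
    stop("calibration_marker: known_diameter_mm must be > 0", call. = FALSE)
  }
  stopifnot(inherits(edge_point_a, "point2d"), inherits(edge_point_b, "point2d"))
  structure(
    list(marker_kind = marker_kind,
         known_diameter_mm = known_diameter_mm,
         edge_point_a = edge_point_a,
         edge_point_b = edge_point_b),
    class = "calibration_marker"
  )
}

#' Create a per-hip annotation
#'
#' @param side `"left"` or `"right"` (patient side).
#' @param rim_points List of at least 5 [point2d] on the projected rim of the
#'   acetabular cup face; they must not be collinear.
#' @param trochanter_point [point2d]: the most prominent medial point of the
#'   lesser trochanter, or the most lateral point of the greater trochanter
#'   when the lesser is not visible.
#' @param trochanter_kind `"lesser_medial"` or `"greater_lateral"`.
#' @return An object of class `hip_annotation`.
#' @export
hip_annotation <- function(side = c("left", "right"), rim_points,
                           trochanter_point,
                           trochanter_kind = c("lesser_medial", "greater_lateral")) {
  side <- match.arg(side)
  trochanter_kind <- match.arg(trochanter_kind)
  stopifnot(is.list(rim_points), inherits(trochanter_point, "point2d"))
  for (p in rim_points) stopifnot(inherits(p, "point2d"))
  structure(
    list(side = side, rim_points = rim_points,
         trochanter_point = trochanter_point,
         trochanter_kind = trochanter_kind),
    class = "hip_annotation"
  )
}

#' Create a pelvis annotation
#'
#' The inferior-most points of the two ischial tuberosities; the line through
#' them (the inter-ischial line) is the transverse reference used for both
#' inclination and leg length.
#'
#' @param left_ischial,right_ischial [point2d] landmarks; must be distinct.
#' @return An object of class `pelvis_annotation`.
#' @export
pelvis_annotation <- function(left_ischial, right_ischial) {
  stopifnot(inherits(left_ischial, "point2d"), inherits(right_ischial, "point2d"))
  structure(list(left_ischial = left_ischial, right_ischial = right_ischial),
            class = "pelvis_annotation")
}

#' Create a full radiograph annotation record
#'
#' One annotation session of one image by one reviewer in one program:
#' calibration marker, pelvis landmarks, and one or two hips (two for
#' bilateral arthroplasty). Replicates of the same session differ only in
#' `replicate_index`.
#'
#' @param image_id,program_id,reviewer_id Non-empty identifier strings.
#' @param replicate_index Integer >= 1; 1..3 for the triplicate protocol.
#' @param calibration A [calibration_marker].
#' @param pelvis A [pelvis_annotation].
#' @param hips List of 1 or 2 [hip_annotation] with distinct sides.
#' @return An object of class `radiograph_annotation`.
#' @export
radiograph_annotation <- function(image_id, program_id, reviewer_id,
                                  replicate_index, calibration, pelvis, hips) {
  stopifnot(is.character(image_id), nzchar(image_id),
            is.character(program_id), nzchar(program_id),
            is.character(reviewer_id), nzchar(reviewer_id))
  replicate_index <- as.integer(replicate_index)
  if (is.na(replicate_index) || replicate_index < 1L) {
    stop("radiograph_annotation: replicate_index must be an integer >= 1",
         call. = FALSE)
  }
  stopifnot(inherits(calibration, "calibration_marker"),
            inherits(pelvis, "pelvis_annotation"), is.list(hips))
  for (h in hips) stopifnot(inherits(h, "hip_annotation"))
  structure(
    list(image_id = image_id, program_id = program_id,
         reviewer_id = reviewer_id, replicate_index = replicate_index,
         calibration = calibration, pelvis = pelvis, hips = hips),
    class = "radiograph_annotation"
  )
}

#' Create an annotation set
#'
#' The tool's sole raw input: every landmark annotation across images,
#' programs, reviewers and replicates. Record keys
#' (image_id, program_id, reviewer_id, replicate_index) must be unique.
#'
#' @param records List of [radiograph_annotation].
#' @param schema_version Schema version string.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(records = list(), schema_version = "1.0") {
  stopifnot(is.list(records), is.character(schema_version))
  for (r in records) stopifnot(inherits(r, "radiograph_annotation"))
  keys <- vapply(records, record_key, character(1))
  dup <- duplicated(keys)
  if (any(dup)) {
    stop("annotation_set: duplicate record key(s): ",
         paste(unique(keys[dup]), collapse = ", "), call. = FALSE)
  }
  structure(list(schema_version = schema_version, records = records),
            class = "annotation_set")
}

record_key <- function(rec) {
  paste(rec$image_id, rec$program_id, rec$reviewer_id, rec$replicate_index,
        sep = "|")
}

#' @export
print.annotation_set <- function(x, ...) {
  n_hips <- sum(vapply(x$records, function(r) length(r$hips), integer(1)))
  cat(sprintf("<annotation_set v%s: %d records, %d hip annotations>\n",
              x$schema_version, length(x$records), n_hips))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$records)
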