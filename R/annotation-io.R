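#' Validate a radiograph annotation record
#'
#' Checks every schema invariant and returns the problems found instead of
#' raising, so whole sets can be screened before measurement. A record is
#' measurable iff the returned list is empty.
#'
#' Issue codes:
#' \describe{
#'   \item{NONFINITE_COORDINATE}{a landmark coordinate is not a finite number}
#'   \item{RIM_POINTS_TOO_FEW}{fewer than 5 cup rim points on a hip}
#'   \item{RIM_POINTS_COLLINEAR}{rim points do not determine an ellipse}
#'   \item{DUPLICATE_SIDE}{two hips annotated with the same side}
#'   \item{NO_HIPS}{record contains no hip annotation}
#'   \item{DEGENERATE_REFERENCE_LINE}{ischial landmarks coincide}
#'   \item{DEGENERATE_MARKER}{calibration edge points coincide}
#'   \item{NONPOSITIVE_DIAMETER}{marker diameter is not > 0}
#'   \item{REPLICATE_INDEX_UNUSUAL}{replicate_index > 3 (allowed, flagged)}
#' }
#'
#' @param rec A [radiograph_annotation].
#' @return A data frame with columns `code`, `field`, `message`; zero rows
#'   when the record is valid. `REPLICATE_INDEX_UNUSUAL` is a warning-level
#'   flag and does not block measurement.
#' @examples
#' rec <- demo_annotation()
#' validate_annotation(rec)   # zero rows
#' @export
validate_annotation <- function(rec) {
  stopifnot(inherits(rec, "radiograph_annotation"))
  issues <- list()
  add <- function(code, field, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  finite_pt <- function(p) is.finite(p$x) && is.finite(p$y)

  cal <- rec$calibration
  if (!finite_pt(cal$edge_point_a) || !finite_pt(cal$edge_point_b)) {
    add("NONFINITE_COORDINATE", "calibration",
        "calibration edge point has non-finite coordinates")
  } else if (euclid(cal$edge_point_a, cal$edge_point_b) == 0) {
    add("DEGENERATE_MARKER", "calibration",
        "calibration edge points coincide; scale is undefined")
  }
  if (!is.finite(cal$known_diameter_mm) || cal$known_diameter_mm <= 0) {
    add("NONPOSITIVE_DIAMETER", "calibration.known_diameter_mm",
        "marker diameter must be a positive length in mm")
  }

  pel <- rec$pelvis
  if (!finite_pt(pel$left_ischial) || !finite_pt(pel$right_ischial)) {
    add("NONFINITE_COORDINATE", "pelvis",
        "ischial landmark has non-finite coordinates")
  } else if (euclid(pel$left_ischial, pel$right_ischial) == 0) {
    add("DEGENERATE_REFERENCE_LINE", "pelvis",
        "ischial landmarks coincide; inter-ischial line is undefined")
  }

  if (length(rec$hips) == 0L) {
    add("NO_HIPS", "hips", "record annotates no hip")
  }
  sides <- vapply(rec$hips, function(h) h$side, character(1))
  if (anyDuplicated(sides)) {
    add("DUPLICATE_SIDE", "hips",
        sprintf("hip side '%s' annotated more than once",
                sides[duplicated(sides)][1]))
  }
  for (h in rec$hips) {
    fld <- sprintf("hips[side=%s].rim_points", h$side)
    if (!all(vapply(h$rim_points, finite_pt, logical(1))) ||
        !finite_pt(h$trochanter_point)) {
      add("NONFINITE_COORDINATE", fld,
          "hip landmark has non-finite coordinates")
      next
    }
    if (length(h$rim_points) < 5L) {
      add("RIM_POINTS_TOO_FEW", fld,
          sprintf("%d rim points; at least 5 are required to fit an ellipse",
                  length(h$rim_points)))
    } else if (points_collinear(as_point_matrix(h$rim_points))) {
      add("RIM_POINTS_COLLINEAR", fld,
          "rim points are collinear; no ellipse passes through them")
    }
  }
  if (rec$replicate_index > 3L) {
    add("REPLICATE_INDEX_UNUSUAL", "replicate_index",
        sprintf("replicate_index %d exceeds the triplicate protocol",
                rec$replicate_index))
  }
  if (length(issues) == 0L) {
    data.frame(code = character(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

# Issues that block measurement (REPLICATE_INDEX_UNUSUAL is advisory only).
blocking_issues <- function(issues) {
  issues[issues$code != "REPLICATE_INDEX_UNUSUAL", , drop = FALSE]
}

pt_to_list <- function(p) list(x = p$x, y = p$y)

pt_from_list <- function(obj, where) {
  if (is.null(obj$x) || is.null(obj$y)) {
    stop(sprintf("annotation schema violation at %s: expected {x, y} point",
                 where), call. = FALSE)
  }
  point2d(obj$x, obj$y)
}

rec_to_list <- function(rec) {
  list(
    image_id = rec$image_id,
    program_id = rec$program_id,
    reviewer_id = rec$reviewer_id,
    replicate_index = rec$replicate_index,
    calibration = list(
      marker_kind = rec$calibration$marker_kind,
      known_diameter_mm = rec$calibration$known_diameter_mm,
      edge_point_a = pt_to_list(rec$calibration$edge_point_a),
      edge_point_b = pt_to_list(rec$calibration$edge_point_b)
    ),
    pelvis = list(
      left_ischial = pt_to_list(rec$pelvis$left_ischial),
      right_ischial = pt_to_list(rec$pelvis$right_ischial)
    ),
    hips = lapply(rec$hips, function(h) list(
      side = h$side,
      trochanter_kind = h$trochanter_kind,
      trochanter_point = pt_to_list(h$trochanter_point),
      rim_points = lapply(h$rim_points, pt_to_list)
    ))
  )
}

rec_from_list <- function(obj, idx) {
  where <- function(f) sprintf("record %d (image_id=%s): %s", idx,
                               if (is.null(obj$image_id)) "?" else obj$image_id, f)
  need <- function(field) {
    if (is.null(obj[[field]])) {
      stop("annotation schema violation at ", where(field), ": missing field",
           call. = FALSE)
    }
    obj[[field]]
  }
  cal <- need("calibration")
  pel <- need("pelvis")
  hips <- need("hips")
  if (length(hips) < 1L) {
    stop("annotation schema violation at ", where("hips"),
         ": at least one hip required", call. = FALSE)
  }
  hip_objs <- lapply(hips, function(h) {
    if (is.null(h$rim_points) || length(h$rim_points) < 5L) {
      stop("annotation schema violation at ",
           where(sprintf("hips[side=%s].rim_points",
                         if (is.null(h$side)) "?" else h$side)),
           ": at least 5 rim points required", call. = FALSE)
    }
    hip_annotation(
      side = h$side,
      rim_points = lapply(seq_along(h$rim_points), function(i)
        pt_from_list(h$rim_points[[i]],
                     where(sprintf("hips[side=%s].rim_points[%d]", h$side, i)))),
      trochanter_point = pt_from_list(h$trochanter_point,
                                      where("trochanter_point")),
      trochanter_kind = h$trochanter_kind
    )
  })
  radiograph_annotation(
    image_id = need("image_id"),
    program_id = need("program_id"),
    reviewer_id = need("reviewer_id"),
    replicate_index = need("replicate_index"),
    calibration = calibration_marker(
      marker_kind = cal$marker_kind,
      known_diameter_mm = cal$known_diameter_mm,
      edge_point_a = pt_from_list(cal$edge_point_a, where("calibration.edge_point_a")),
      edge_point_b = pt_from_list(cal$edge_point_b, where("calibration.edge_point_b"))
    ),
    pelvis = pelvis_annotation(
      left_ischial = pt_from_list(pel$left_ischial, where("pelvis.left_ischial")),
      right_ischial = pt_from_list(pel$right_ischial, where("pelvis.right_ischial"))
    ),
    hips = hip_objs
  )
}

#' Write an annotation set to a JSON file
#'
#' Numeric fields are serialized at full double precision, so
#' [read_annotations()] restores the set exactly and repeated write-read-write
#' cycles are byte-identical.
#'
#' @param set An [annotation_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  doc <- list(schema_version = set$schema_version,
              records = lapply(set$records, rec_to_list))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an annotation set from a JSON file
#'
#' Parses and fully validates the documented annotation schema; any invariant
#' breach is reported as an error naming the offending record and field.
#'
#' @param path Path to a JSON file produced by [write_annotations()] (or
#'   conforming to the same schema).
#' @return A validated [annotation_set].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$records)) {
    stop("annotation schema violation: missing top-level 'records' array",
         call. = FALSE)
  }
  records <- lapply(seq_along(doc$records),
                    function(i) rec_from_list(doc$records[[i]], i))
  set <- annotation_set(records,
                        schema_version = if (is.null(doc$schema_version)) "1.0"
                                         else doc$schema_version)
  for (i in seq_along(set$records)) {
    iss <- blocking_issues(validate_annotation(set$records[[i]]))
    if (nrow(iss) > 0L) {
      stop(sprintf("annotation schema violation at record %d (image_id=%s): %s: %s",
                   i, set$records[[i]]$image_id, iss$field[1], iss$message[1]),
           call. = FALSE)
    }
  }
  set
}
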