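# Synthetic annotation generator. The forward model is the orthographic
# (parallel-beam) projection that the arcsin(b/a) version formula inverts:
# a circular cup opening of radius r at true version V projects to an
# ellipse with semi-major axis a = r/scale pixels and semi-minor axis
# b = a sin(V); the major axis makes the true inclination angle with the
# inter-ischial reference line. Perspective/beam-divergence effects are
# deliberately excluded so the measurement inverts the projection exactly
# at zero noise.

#' Simulation configuration
#'
#' Defaults emulate the validation-study conditions: 135 standing AP pelvic
#' radiographs read in triplicate, roughly 6% of images bilateral, a 25 mm
#' scaling ball, cup radius 25 mm at a scale of 0.125 mm/px (projected
#' semi-major axis about 200 px), anteversion drawn uniformly on 10-45
#' degrees, inclination on 30-55 degrees, per-leg length on -15 to 35 mm,
#' with 16 rim points at 0.5 px noise and 1 px landmark noise.
#'
#' @param n_images Number of radiographs.
#' @param n_rim_points Rim points per cup, >= 5.
#' @param rim_noise_sd_px Isotropic Gaussian noise SD on rim points, px.
#' @param landmark_noise_sd_px Noise SD on ischial, trochanter and marker
#'   edge landmarks, px.
#' @param anteversion_range_deg,inclination_range_deg True-angle ranges
#'   (uniform), degrees.
#' @param leg_length_range_mm True per-leg length range (uniform), mm.
#' @param cup_radius_mm Physical cup-opening radius, mm.
#' @param scale_mm_per_px True image scale.
#' @param bilateral_prob Probability an image carries two implants.
#' @param replicates Replicate annotations per reviewer per image.
#' @param n_reviewers Reviewers annotating every image.
#' @param program_id Program identifier stamped on the records.
#' @param seed Master seed; every output is a pure function of the config
#'   including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_images = 135L,
                       n_rim_points = 16L,
                       rim_noise_sd_px = 0.5,
                       landmark_noise_sd_px = 1,
                       anteversion_range_deg = c(10, 45),
                       inclination_range_deg = c(30, 55),
                       leg_length_range_mm = c(-15, 35),
                       cup_radius_mm = 25,
                       scale_mm_per_px = 0.125,
                       bilateral_prob = 8 / 135,
                       replicates = 3L,
                       n_reviewers = 1L,
                       program_id = "sim",
                       seed = 1L) {
  cfg <- list(n_images = as.integer(n_images),
              n_rim_points = as.integer(n_rim_points),
              rim_noise_sd_px = rim_noise_sd_px,
              landmark_noise_sd_px = landmark_noise_sd_px,
              anteversion_range_deg = anteversion_range_deg,
              inclination_range_deg = inclination_range_deg,
              leg_length_range_mm = leg_length_range_mm,
              cup_radius_mm = cup_radius_mm,
              scale_mm_per_px = scale_mm_per_px,
              bilateral_prob = bilateral_prob,
              replicates = as.integer(replicates),
              n_reviewers = as.integer(n_reviewers),
              program_id = program_id,
              seed = as.integer(seed))
  stopifnot(cfg$n_images >= 1L, cfg$replicates >= 1L, cfg$n_reviewers >= 1L,
            cfg$rim_noise_sd_px >= 0, cfg$landmark_noise_sd_px >= 0,
            cfg$cup_radius_mm > 0, cfg$scale_mm_per_px > 0,
            cfg$bilateral_prob >= 0, cfg$bilateral_prob <= 1)
  if (cfg$n_rim_points < 5L) {
    stop("sim_config: n_rim_points must be >= 5 (an ellipse needs 5 points)",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' True cup state for one hip
#'
#' @param side `"left"` or `"right"`.
#' @param true_anteversion_deg,true_inclination_deg True angles, in
#'   (0, 90) degrees.
#' @param cup_radius_mm Cup-opening radius, mm.
#' @param cup_center [point2d] projected cup center, px.
#' @return A list of class `cup_truth`.
#' @export
cup_truth <- function(side, true_anteversion_deg, true_inclination_deg,
                      cup_radius_mm, cup_center) {
  stopifnot(side %in% c("left", "right"),
            true_anteversion_deg > 0, true_anteversion_deg < 90,
            true_inclination_deg > 0, true_inclination_deg < 90,
            cup_radius_mm > 0, inherits(cup_center, "point2d"))
  structure(list(side = side,
                 true_anteversion_deg = true_anteversion_deg,
                 true_inclination_deg = true_inclination_deg,
                 cup_radius_mm = cup_radius_mm,
                 cup_center = cup_center),
            class = "cup_truth")
}

#' Forward-project a cup onto the radiograph
#'
#' Orthographic projection of the circular cup opening: the projected
#' ellipse has semi-major axis `a = r / scale` pixels, semi-minor axis
#' `b = a sin(V)`, and its major axis makes the true inclination angle with
#' the reference line, so measuring the returned ellipse recovers the true
#' angles exactly.
#'
#' @param truth A [cup_truth].
#' @param scale_mm_per_px Image scale.
#' @param ref [reference_line] (the inter-ischial line of the scene).
#' @return An [ellipse].
#' @examples
#' tr <- cup_truth("left", 30, 45, 25, point2d(0, 0))
#' ref <- reference_line(point2d(0, 0), point2d(1, 0))
#' project_cup(tr, 1, ref)   # a = 25, b = 12.5, psi = 45
#' @export
project_cup <- function(truth, scale_mm_per_px, ref) {
  stopifnot(inherits(truth, "cup_truth"), scale_mm_per_px > 0,
            inherits(ref, "reference_line"))
  a <- truth$cup_radius_mm / scale_mm_per_px
  b <- a * sin(deg2rad(truth$true_anteversion_deg))
  d <- line_direction(ref)
  theta_ref <- rad2deg(atan2(d[2], d[1]))
  ellipse(center = truth$cup_center, semi_major_px = a, semi_minor_px = b,
          orientation_deg = fold_axis_angle(theta_ref + truth$true_inclination_deg))
}

#' Sample (optionally noisy) rim points on an ellipse
#'
#' `n` points at uniformly spaced parametric angles, plus isotropic Gaussian
#' pixel noise. Deterministic given `seed`; the caller's RNG state is left
#' untouched when a seed is supplied.
#'
#' @param e An [ellipse].
#' @param n Number of points, >= 5.
#' @param noise_sd_px Noise SD in pixels (0 = exact points).
#' @param seed Optional integer seed.
#' @return List of `n` [point2d].
#' @export
sample_rim_points <- function(e, n, noise_sd_px = 0, seed = NULL) {
  stopifnot(inherits(e, "ellipse"), noise_sd_px >= 0)
  n <- as.integer(n)
  if (n < 5L) stop("sample_rim_points: n must be >= 5", call. = FALSE)
  with_local_seed(seed, {
    tt <- 2 * pi * (seq_len(n) - 1L) / n
    psi <- deg2rad(e$orientation_deg)
    x <- e$center$x + e$semi_major_px * cos(tt) * cos(psi) -
      e$semi_minor_px * sin(tt) * sin(psi)
    y <- e$center$y + e$semi_major_px * cos(tt) * sin(psi) +
      e$semi_minor_px * sin(tt) * cos(psi)
    if (noise_sd_px > 0) {
      x <- x + stats::rnorm(n, 0, noise_sd_px)
      y <- y + stats::rnorm(n, 0, noise_sd_px)
    }
    lapply(seq_len(n), function(i) point2d(x[i], y[i]))
  })
}

# Pelvis layout template, in mm relative to the pelvis midline at the
# inter-ischial level. Converted to pixels through the scene scale.
PELVIS_TEMPLATE <- list(
  midline_px = c(x = 1200, y = 1400),   # ischial level in image coords
  ischial_half_span_mm = 60,
  cup_offset_mm = c(x = 35, y = -80),   # lateral and superior of midline
  trochanter_x_mm = 45,
  marker_offset_mm = c(x = 0, y = 120),
  marker_diameter_mm = 25
)

jitter_pt <- function(p, sd) {
  if (sd <= 0) return(p)
  point2d(p$x + stats::rnorm(1, 0, sd), p$y + stats::rnorm(1, 0, sd))
}

#' Generate one synthetic annotated radiograph with its ground truth
#'
#' Draws true angles and leg lengths from the configured ranges, lays out
#' ischial, trochanter and calibration-marker landmarks on a fixed pelvis
#' template, forward-projects each cup and samples its rim points. Each
#' reviewer/replicate re-noises all landmarks independently, emulating
#' independent annotation sessions of the same image.
#'
#' @param cfg A [sim_config].
#' @param image_index 1-based image index; the RNG substream is a stable
#'   hash of `(seed, image_index)`, so adding images never perturbs
#'   earlier ones.
#' @return List with `records` (list of [radiograph_annotation], one per
#'   reviewer x replicate) and `truth` (data frame: one row per hip with
#'   `image_id`, `side`, `true_anteversion_deg`, `true_inclination_deg`,
#'   `true_leg_length_mm`, `scale_mm_per_px`).
#' @export
generate_scene <- function(cfg, image_index) {
  stopifnot(inherits(cfg, "sim_config"))
  image_id <- sprintf("img_%04d", image_index)
  tpl <- PELVIS_TEMPLATE
  sc <- cfg$scale_mm_per_px
  mid <- tpl$midline_px
  with_local_seed(substream_seed(cfg$seed, image_index), {
    bilateral <- stats::runif(1) < cfg$bilateral_prob
    sides <- if (bilateral) c("right", "left") else
      sample(c("right", "left"), 1L)

    # patient right appears on image left
    side_sign <- function(side) if (side == "right") -1 else 1

    ischial_l <- point2d(mid["x"] + tpl$ischial_half_span_mm / sc, mid["y"])
    ischial_r <- point2d(mid["x"] - tpl$ischial_half_span_mm / sc, mid["y"])
    ref <- reference_line(ischial_l, ischial_r)

    truths <- list()
    for (side in sides) {
      v <- stats::runif(1, cfg$anteversion_range_deg[1], cfg$anteversion_range_deg[2])
      inc <- stats::runif(1, cfg$inclination_range_deg[1], cfg$inclination_range_deg[2])
      ll <- stats::runif(1, cfg$leg_length_range_mm[1], cfg$leg_length_range_mm[2])
      ctr <- point2d(mid["x"] + side_sign(side) * tpl$cup_offset_mm["x"] / sc,
                     mid["y"] + tpl$cup_offset_mm["y"] / sc)
      truths[[side]] <- list(
        cup = cup_truth(side, v, inc, cfg$cup_radius_mm, ctr),
        leg_length_mm = ll,
        trochanter = point2d(mid["x"] + side_sign(side) * tpl$trochanter_x_mm / sc,
                             mid["y"] + ll / sc))
    }
    marker_a <- point2d(mid["x"] + tpl$marker_offset_mm["x"] / sc -
                          tpl$marker_diameter_mm / (2 * sc),
                        mid["y"] + tpl$marker_offset_mm["y"] / sc)
    marker_b <- point2d(marker_a$x + tpl$marker_diameter_mm / sc, marker_a$y)

    records <- list()
    for (rv in seq_len(cfg$n_reviewers)) {
      for (rep_i in seq_len(cfg$replicates)) {
        lsd <- cfg$landmark_noise_sd_px
        hips <- lapply(truths, function(tr) {
          e <- project_cup(tr$cup, sc, ref)
          hip_annotation(
            side = tr$cup$side,
            rim_points = sample_rim_points(e, cfg$n_rim_points,
                                           cfg$rim_noise_sd_px),
            trochanter_point = jitter_pt(tr$trochanter, lsd),
            trochanter_kind = "lesser_medial")
        })
        names(hips) <- NULL
        records[[length(records) + 1L]] <- radiograph_annotation(
          image_id = image_id, program_id = cfg$program_id,
          reviewer_id = sprintf("rev%02d", rv), replicate_index = rep_i,
          calibration = calibration_marker(
            "scaling_ball", tpl$marker_diameter_mm,
            jitter_pt(marker_a, lsd), jitter_pt(marker_b, lsd)),
          pelvis = pelvis_annotation(jitter_pt(ischial_l, lsd),
                                     jitter_pt(ischial_r, lsd)),
          hips = hips)
      }
    }
    truth_df <- do.call(rbind, lapply(truths, function(tr) data.frame(
      image_id = image_id, side = tr$cup$side,
      true_anteversion_deg = tr$cup$true_anteversion_deg,
      true_inclination_deg = tr$cup$true_inclination_deg,
      true_leg_length_mm = tr$leg_length_mm,
      scale_mm_per_px = sc, stringsAsFactors = FALSE)))
    rownames(truth_df) <- NULL
    list(records = records, truth = truth_df)
  })
}

#' Generate a full synthetic annotation set with its truth table
#'
#' Maps [generate_scene()] over `cfg$n_images` independent per-image RNG
#' substreams. Deterministic: the same config (including seed) always
#' produces the identical set, and [write_annotations()] of it is
#' byte-identical across runs.
#'
#' @param cfg A [sim_config].
#' @return List with `annotations` (an [annotation_set]) and `truth`
#'   (data frame, one row per hip).
#' @export
generate_annotation_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  scenes <- lapply(seq_len(cfg$n_images), function(i) generate_scene(cfg, i))
  records <- do.call(c, lapply(scenes, `[[`, "records"))
  truth <- do.call(rbind, lapply(scenes, `[[`, "truth"))
  rownames(truth) <- NULL
  list(annotations = annotation_set(records), truth = truth)
}

#' Variance-components rater model
#'
#' Additive two-way model for simulated measurement tables:
#' `value = truth + subject + program_bias + rater + residual`, every
#' random effect Gaussian with the configured variance. With
#' `sigma2_rater = 0` and no bias the analytic ICC of replicates is
#' `sigma2_subject / (sigma2_subject + sigma2_error)`.
#'
#' @param sigma2_subject,sigma2_rater,sigma2_error Variance components
#'   (squared measurement units), >= 0.
#' @param program_bias Named numeric vector of additive per-program biases;
#'   programs not named get bias 0.
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(sigma2_subject = 0, sigma2_rater = 0,
                        sigma2_error = 0, program_bias = numeric(0)) {
  stopifnot(sigma2_subject >= 0, sigma2_rater >= 0, sigma2_error >= 0)
  structure(list(sigma2_subject = sigma2_subject,
                 sigma2_rater = sigma2_rater,
                 sigma2_error = sigma2_error,
                 program_bias = program_bias),
            class = "rater_model")
}

#' Simulate a long-format measurement table from known truths
#'
#' For each truth row, parameter, program, reviewer and replicate, draws
#' `value = truth + s_unit + bias_program + r_reviewer + e` with the
#' variance components of the [rater_model()]. Subject effects are shared
#' across programs, reviewers and replicates of a unit; reviewer effects
#' are shared across that reviewer's replicates and units of a parameter.
#' Deterministic given `seed`.
#'
#' @param truths Truth data frame as produced by
#'   [generate_annotation_set()] (columns `image_id`, `side`,
#'   `true_anteversion_deg`, `true_inclination_deg`, `true_leg_length_mm`).
#' @param model A [rater_model()].
#' @param programs Character vector of program ids.
#' @param reviewers Character vector of reviewer ids.
#' @param replicates Replicates per reviewer.
#' @param seed Integer seed.
#' @return Long-format measurement table data frame.
#' @export
simulate_measurement_table <- function(truths, model, programs, reviewers,
                                       replicates, seed) {
  stopifnot(inherits(model, "rater_model"), length(programs) >= 1L,
            length(reviewers) >= 1L, replicates >= 1L)
  truth_cols <- c(anteversion = "true_anteversion_deg",
                  inclination = "true_inclination_deg",
                  leg_length = "true_leg_length_mm")
  with_local_seed(seed, {
    out <- list()
    for (param in names(truth_cols)) {
      if (!truth_cols[[param]] %in% names(truths)) next
      n_units <- nrow(truths)
      subj <- stats::rnorm(n_units, 0, sqrt(model$sigma2_subject))
      rater <- stats::rnorm(length(reviewers), 0, sqrt(model$sigma2_rater))
      names(rater) <- reviewers
      for (prog in programs) {
        bias <- if (prog %in% names(model$program_bias))
          model$program_bias[[prog]] else 0
        for (rv in reviewers) {
          for (rep_i in seq_len(replicates)) {
            e <- stats::rnorm(n_units, 0, sqrt(model$sigma2_error))
            out[[length(out) + 1L]] <- data.frame(
              image_id = truths$image_id, side = truths$side,
              program_id = prog, reviewer_id = rv,
              replicate_index = rep_i, parameter = param,
              value = truths[[truth_cols[[param]]]] + subj + bias +
                rater[[rv]] + e,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    tbl <- do.call(rbind, out)
    rownames(tbl) <- NULL
    tbl
  })
}

#' A small valid demonstration annotation record
#'
#' One zero-noise synthetic radiograph annotation (single left hip, true
#' anteversion 30 degrees, inclination 45 degrees, leg length +12 mm),
#' handy for examples and quick checks.
#'
#' @return A [radiograph_annotation].
#' @export
demo_annotation <- function() {
  cfg <- sim_config(n_images = 1L, rim_noise_sd_px = 0,
                    landmark_noise_sd_px = 0, bilateral_prob = 0,
                    replicates = 1L, seed = 42L)
  tpl <- PELVIS_TEMPLATE
  sc <- cfg$scale_mm_per_px
  mid <- tpl$midline_px
  ischial_l <- point2d(mid["x"] + tpl$ischial_half_span_mm / sc, mid["y"])
  ischial_r <- point2d(mid["x"] - tpl$ischial_half_span_mm / sc, mid["y"])
  ref <- reference_line(ischial_l, ischial_r)
  tr <- cup_truth("left", 30, 45, cfg$cup_radius_mm,
                  point2d(mid["x"] + tpl$cup_offset_mm["x"] / sc,
                          mid["y"] + tpl$cup_offset_mm["y"] / sc))
  e <- project_cup(tr, sc, ref)
  radiograph_annotation(
    image_id = "demo_001", program_id = "demo", reviewer_id = "rev01",
    replicate_index = 1L,
    calibration = calibration_marker(
      "scaling_ball", tpl$marker_diameter_mm,
      point2d(mid["x"] - tpl$marker_diameter_mm / (2 * sc),
              mid["y"] + tpl$marker_offset_mm["y"] / sc),
      point2d(mid["x"] + tpl$marker_diameter_mm / (2 * sc),
              mid["y"] + tpl$marker_offset_mm["y"] / sc)),
    pelvis = pelvis_annotation(ischial_l, ischial_r),
    hips = list(hip_annotation(
      side = "left",
      rim_points = sample_rim_points(e, 12L, 0),
      trochanter_point = point2d(mid["x"] + tpl$trochanter_x_mm / sc,
                                 mid["y"] + 12 / sc),
      trochanter_kind = "lesser_medial")))
}
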