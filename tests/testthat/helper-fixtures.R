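# Programmatic fixtures: everything is built in code at test time.

# Smallest absolute difference between two undirected axis angles (degrees).
fold_diff <- function(a, b) {
  d <- (a - b) %% 180
  min(d, 180 - d)
}

as_mat <- function(points) do.call(rbind, lapply(points, function(p) c(p$x, p$y)))

# A valid single-hip record with controllable truth, zero noise.
make_record <- function(image_id = "img_t", program_id = "p", reviewer_id = "r",
                        replicate_index = 1L, side = "left",
                        v_deg = 30, i_deg = 45, ll_mm = 12,
                        scale = 0.5, n_rim = 12L, rim_noise = 0,
                        rim_seed = NULL) {
  ischial_l <- point2d(1000 + 60 / scale, 800)
  ischial_r <- point2d(1000 - 60 / scale, 800)
  ref <- reference_line(ischial_l, ischial_r)
  tr <- cup_truth(side, v_deg, i_deg, 25, point2d(1000 + 35 / scale, 800 - 80 / scale))
  e <- project_cup(tr, scale, ref)
  radiograph_annotation(
    image_id = image_id, program_id = program_id, reviewer_id = reviewer_id,
    replicate_index = replicate_index,
    calibration = calibration_marker("scaling_ball", 25,
                                     point2d(900, 1000),
                                     point2d(900 + 25 / scale, 1000)),
    pelvis = pelvis_annotation(ischial_l, ischial_r),
    hips = list(hip_annotation(
      side = side,
      rim_points = sample_rim_points(e, n_rim, rim_noise, seed = rim_seed),
      trochanter_point = point2d(1000 + 45 / scale, 800 + ll_mm / scale),
      trochanter_kind = "lesser_medial")))
}

# Long-format measurement table from parallel vectors.
make_table <- function(image_id, value, parameter = "anteversion",
                       side = "left", program_id = "p", reviewer_id = "r",
                       replicate_index = 1L) {
  data.frame(image_id = image_id, side = side, program_id = program_id,
             reviewer_id = reviewer_id, replicate_index = replicate_index,
             parameter = parameter, value = value, stringsAsFactors = FALSE)
}

# Paired two-program table on common units.
make_paired_table <- function(a, b, parameter = "anteversion",
                              prog_a = "A", prog_b = "B") {
  ids <- sprintf("img_%03d", seq_along(a))
  rbind(make_table(ids, a, parameter, program_id = prog_a),
        make_table(ids, b, parameter, program_id = prog_b))
}

# All 2x2 tables with total N <= nmax (including zero margins).
all_tables_upto <- function(nmax) {
  g <- expand.grid(a = 0:nmax, b = 0:nmax, c = 0:nmax)
  g <- g[g$a + g$b + g$c <= nmax, ]
  out <- do.call(rbind, lapply(1:nmax, function(n) {
    keep <- g[g$a + g$b + g$c <= n, ]
    cbind(keep$a, keep$b, keep$c, n - keep$a - keep$b - keep$c)
  }))
  unname(out)
}
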