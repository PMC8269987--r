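# The comparison report: the full agreement protocol applied to one
# measurement table, with a fixed serializable shape.

PARAMETERS <- c("anteversion", "inclination", "leg_length")
param_unit <- function(parameter) {
  if (parameter == "leg_length") "mm" else "deg"
}

#' Build a full comparison report
#'
#' Runs the whole agreement protocol for every parameter present: replicate
#' averaging, test-vs-reference difference summaries, Pearson correlations,
#' paired t-tests, within-threshold proportions, an omnibus test across
#' programs (one-way ANOVA when at least three programs measure the
#' parameter, the paired t when exactly two do), and pooled per-program
#' ICCs from the unaveraged replicates. A reference that records no values
#' for a parameter (e.g. a program without an ellipse tool records no
#' anteversion) is silently omitted from that parameter's comparisons.
#'
#' @param t Long-format measurement table (unaveraged; averaging happens
#'   internally where required).
#' @param reference_programs Character vector of reference program ids.
#' @param test_program Program id under evaluation.
#' @param thresholds Strictly increasing positive thresholds for the
#'   within-threshold proportions, in parameter units. Default `c(1, 5)`:
#'   1 and 5 degrees for angles, 1 and 5 mm for leg length.
#' @return An object of class `comparison_report`.
#' @export
build_report <- function(t, reference_programs, test_program,
                         thresholds = c(1, 5)) {
  check_table(t)
  stopifnot(length(reference_programs) >= 1L, length(test_program) == 1L)
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be positive and strictly increasing", call. = FALSE)
  }
  all_progs <- c(test_program, reference_programs)
  missing <- setdiff(all_progs, unique(t$program_id))
  if (length(missing)) {
    stop("programs absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- intersect(PARAMETERS, unique(t$parameter))
  per_param <- list()
  for (param in params) {
    with_param <- all_progs[vapply(all_progs, function(p)
      nrow(t[t$program_id == p & t$parameter == param, ]) > 0, logical(1))]
    refs <- intersect(reference_programs, with_param)
    comparisons <- list()
    if (test_program %in% with_param) {
      for (ref in refs) {
        ds <- difference_summary(t, test_program, ref, param)
        pr <- pearson(t, test_program, ref, param)
        tt <- paired_t(t, test_program, ref, param)
        props <- lapply(thresholds, function(th)
          within_threshold(t, test_program, ref, param, th))
        names(props) <- paste0("within_", thresholds)
        ds$pearson_r <- pr$r
        ds$paired_t <- tt
        ds$prop_within <- props
        comparisons[[ref]] <- ds
      }
    }
    omnibus <- NULL
    if (length(with_param) >= 3L) {
      omnibus <- c(list(test = "one_way_anova", programs = with_param),
                   one_way_anova(t, with_param, param))
    } else if (length(with_param) == 2L) {
      omnibus <- c(list(test = "paired_t", programs = with_param),
                   paired_t(t, with_param[1], with_param[2], param))
    }
    iccs <- list()
    has_reps <- !all(is.na(t$replicate_index))
    if (has_reps) {
      for (p in with_param) {
        res <- tryCatch(pooled_icc(t, p, param), error = function(e) NULL)
        if (!is.null(res)) iccs[[p]] <- res
      }
    }
    per_param[[param]] <- list(parameter = param, unit = param_unit(param),
                               programs = with_param,
                               comparisons = comparisons,
                               omnibus = omnibus, iccs = iccs)
  }
  structure(list(test_program = test_program,
                 reference_programs = reference_programs,
                 thresholds = thresholds, parameters = per_param),
            class = "comparison_report")
}

#' Flatten a comparison report to a table-shaped data frame
#'
#' One row per (parameter, reference program) pair, with the difference
#' summary, Pearson r, paired-t p-value, within-threshold proportions, the
#' omnibus p-value for the parameter, and the two programs' pooled ICCs.
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.comparison_report <- function(x, ...) {
  rows <- list()
  for (pp in x$parameters) {
    for (ref in names(pp$comparisons)) {
      cmp <- pp$comparisons[[ref]]
      row <- data.frame(
        parameter = pp$parameter, unit = pp$unit,
        program_test = cmp$program_a, program_ref = cmp$program_b,
        n = cmp$n,
        mean_test = cmp$mean_a, sd_test = cmp$sd_a,
        mean_ref = cmp$mean_b, sd_ref = cmp$sd_b,
        mean_diff = cmp$mean_diff, sd_diff = cmp$sd_diff,
        abs_mean_diff = cmp$abs_mean_diff, abs_sd_diff = cmp$abs_sd_diff,
        pearson_r = cmp$pearson_r,
        paired_t_p = cmp$paired_t$p_value,
        omnibus_p = if (is.null(pp$omnibus)) NA_real_ else pp$omnibus$p_value,
        icc_test = if (is.null(pp$iccs[[cmp$program_a]])) NA_real_
                   else pp$iccs[[cmp$program_a]]$icc_value,
        icc_ref = if (is.null(pp$iccs[[ref]])) NA_real_
                  else pp$iccs[[ref]]$icc_value,
        stringsAsFactors = FALSE)
      for (nm in names(cmp$prop_within)) {
        row[[paste0("prop_", nm)]] <- cmp$prop_within[[nm]]$proportion
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a comparison report as JSON
#'
#' @param report A `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  json <- jsonlite::toJSON(unclass_deep(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Write a comparison report as a flat CSV
#'
#' @param report A `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_to_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report: test program '%s' vs reference(s) %s\n",
              x$test_program,
              paste(sprintf("'%s'", x$reference_programs), collapse = ", ")))
  df <- as.data.frame(x)
  if (nrow(df) == 0L) {
    cat("  (no comparisons)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cat(sprintf(
      "  %-11s vs %-4s n=%3d  mean diff %+.3f +/- %.3f %s  |diff| %.3f  r=%.3f  p=%.3g\n",
      r$parameter, r$program_ref, r$n, r$mean_diff, r$sd_diff, r$unit,
      r$abs_mean_diff, r$pearson_r, r$paired_t_p))
  }
  invisible(x)
}
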