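# Method-comparison and reliability statistics on long-format measurement
# tables. A "unit" throughout is one hip on one image, keyed (image_id, side),
# so bilateral arthroplasties contribute two units.

MEAS_COLS <- c("image_id", "side", "program_id", "reviewer_id",
               "replicate_index", "parameter", "value")

check_table <- function(t) {
  stopifnot(is.data.frame(t))
  missing <- setdiff(MEAS_COLS, names(t))
  if (length(missing)) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- do.call(paste, c(t[MEAS_COLS[MEAS_COLS != "value"]], sep = "|"))
  if (anyDuplicated(key)) {
    stop("measurement table has duplicate (image, side, program, reviewer, ",
         "replicate, parameter) keys", call. = FALSE)
  }
  invisible(t)
}

#' Average replicate measurements
#'
#' Collapses the triplicate protocol: one value per
#' (image, side, program, reviewer, parameter) group, equal to the
#' arithmetic mean of its replicates. Groups with a replicate count other
#' than 3 are reported via `message()` but averaged all the same.
#'
#' @param t Long-format measurement table (see [measurements_to_table()]).
#' @return A table of the same shape with `replicate_index = NA` and one row
#'   per group.
#' @export
average_replicates <- function(t) {
  check_table(t)
  if (nrow(t) == 0L) return(t)
  grp <- interaction(t$image_id, t$side, t$program_id, t$reviewer_id,
                     t$parameter, drop = TRUE, lex.order = TRUE)
  counts <- tabulate(grp)
  odd <- sum(counts != 3L)
  if (odd > 0L) {
    message(sprintf("average_replicates: %d group(s) without triplicates", odd))
  }
  first <- !duplicated(grp)
  out <- t[first, , drop = FALSE]
  out$replicate_index <- NA_integer_
  out$value <- as.numeric(tapply(t$value, grp, mean))[as.integer(grp[first])]
  rownames(out) <- NULL
  out
}

# Unit-level values of one program for one parameter: replicate-averaged,
# then averaged across reviewers. Returns data.frame(unit, value).
unit_values <- function(t, program, parameter) {
  s <- t[t$program_id == program & t$parameter == parameter, , drop = FALSE]
  if (nrow(s) == 0L) return(data.frame(unit = character(), value = numeric()))
  s <- average_replicates(s)
  unit <- paste(s$image_id, s$side, sep = "|")
  v <- tapply(s$value, unit, mean)
  data.frame(unit = names(v), value = as.numeric(v), stringsAsFactors = FALSE)
}

paired_units <- function(t, prog_a, prog_b, parameter) {
  a <- unit_values(t, prog_a, parameter)
  b <- unit_values(t, prog_b, parameter)
  common <- sort(intersect(a$unit, b$unit))
  data.frame(unit = common,
             value_a = a$value[match(common, a$unit)],
             value_b = b$value[match(common, b$unit)],
             stringsAsFactors = FALSE)
}

#' Paired difference summary between two programs
#'
#' Per-unit differences `d = value_b - value_a` (program B minus program A;
#' pass the test program as `prog_a` and the reference as `prog_b` to match
#' the reporting convention where a positive mean difference means the
#' reference reads higher). Returns signed and absolute summaries.
#'
#' @param t Long-format measurement table.
#' @param prog_a,prog_b Program identifiers present in `t`.
#' @param parameter One of `"anteversion"`, `"inclination"`, `"leg_length"`.
#' @return A list of class `comparison_result`: `parameter`, `program_a`,
#'   `program_b`, `n`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `mean_diff`,
#'   `sd_diff`, `abs_mean_diff`, `abs_sd_diff`.
#' @export
difference_summary <- function(t, prog_a, prog_b, parameter) {
  p <- paired_units(t, prog_a, prog_b, parameter)
  if (nrow(p) < 2L) {
    stop(sprintf("difference_summary: fewer than 2 common units for %s vs %s (%s)",
                 prog_a, prog_b, parameter), call. = FALSE)
  }
  d <- p$value_b - p$value_a
  structure(list(
    parameter = parameter, program_a = prog_a, program_b = prog_b,
    n = nrow(p),
    mean_a = mean(p$value_a), sd_a = stats::sd(p$value_a),
    mean_b = mean(p$value_b), sd_b = stats::sd(p$value_b),
    mean_diff = mean(d), sd_diff = stats::sd(d),
    abs_mean_diff = mean(abs(d)), abs_sd_diff = stats::sd(abs(d))
  ), class = "comparison_result")
}

#' Paired t-test between two programs
#'
#' Two-sided paired t-test on unit-level differences. When every difference
#' is identical (zero variance) the measurements are indistinguishable and
#' the result is reported as `t = 0, p = 1` with `degenerate = TRUE` rather
#' than an error.
#'
#' @inheritParams difference_summary
#' @return List with `statistic`, `df`, `p_value`, `n`, `degenerate`.
#' @export
paired_t <- function(t, prog_a, prog_b, parameter) {
  p <- paired_units(t, prog_a, prog_b, parameter)
  if (nrow(p) < 2L) {
    stop("paired_t: fewer than 2 paired units", call. = FALSE)
  }
  d <- p$value_b - p$value_a
  if (stats::sd(d) == 0) {
    return(list(statistic = 0, df = length(d) - 1L, p_value = 1,
                n = length(d), degenerate = TRUE))
  }
  ht <- stats::t.test(p$value_b, p$value_a, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = nrow(p), degenerate = FALSE)
}

#' One-way ANOVA across programs
#'
#' Classic (equal-variance) one-way analysis of variance of the unit-level
#' averaged values across program groups, treating programs as independent
#' groups. Identical groups with zero residual variance are reported as
#' `F = 0, p = 1` with a degeneracy flag.
#'
#' @param t Long-format measurement table.
#' @param programs Character vector of >= 2 program identifiers.
#' @param parameter Parameter name.
#' @return List with `statistic` (F), `df1`, `df2`, `p_value`, `n`,
#'   `degenerate`.
#' @export
one_way_anova <- function(t, programs, parameter) {
  stopifnot(length(programs) >= 2L)
  groups <- lapply(programs, function(p) unit_values(t, p, parameter)$value)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("one_way_anova: every program needs >= 2 values", call. = FALSE)
  }
  value <- unlist(groups)
  program <- factor(rep(programs, sizes), levels = programs)
  if (stats::sd(value) == 0) {
    return(list(statistic = 0, df1 = length(programs) - 1L,
                df2 = length(value) - length(programs), p_value = 1,
                n = length(value), degenerate = TRUE))
  }
  ht <- stats::oneway.test(value ~ program, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p_value = ht$p.value,
       n = length(value), degenerate = FALSE)
}

#' Pearson correlation between two programs
#'
#' Sample Pearson correlation of the paired unit-level values.
#'
#' @inheritParams difference_summary
#' @return List with `r` and `n`.
#' @export
pearson <- function(t, prog_a, prog_b, parameter) {
  p <- paired_units(t, prog_a, prog_b, parameter)
  if (nrow(p) < 3L) stop("pearson: fewer than 3 paired units", call. = FALSE)
  if (stats::sd(p$value_a) == 0 || stats::sd(p$value_b) == 0) {
    stop("pearson: constant input; correlation undefined", call. = FALSE)
  }
  list(r = stats::cor(p$value_a, p$value_b), n = nrow(p))
}

#' Proportion of paired measurements within a threshold
#'
#' Fraction of units whose absolute between-program difference is at most
#' `threshold` (degrees for angles, millimetres for leg length).
#'
#' @inheritParams difference_summary
#' @param threshold Positive scalar in the parameter's units.
#' @return List with `proportion`, `n_within`, `n_total`, `threshold`.
#' @export
within_threshold <- function(t, prog_a, prog_b, parameter, threshold) {
  stopifnot(is.numeric(threshold), threshold > 0)
  p <- paired_units(t, prog_a, prog_b, parameter)
  if (nrow(p) == 0L) stop("within_threshold: no paired units", call. = FALSE)
  d <- abs(p$value_b - p$value_a)
  list(proportion = mean(d <= threshold), n_within = sum(d <= threshold),
       n_total = nrow(p), threshold = threshold)
}

# Two-sided Fisher exact p for a 2x2 table from the hypergeometric mass:
# the sum of probabilities of all tables with the observed margins that are
# no more probable than the observed one (the convention of fisher.test).
fisher2x2_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  k <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(k, r1, r2, c1)
  pobs <- stats::dhyper(m[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Chi-square or Fisher's exact test on a 2x2 proportion table
#'
#' Pearson chi-square without continuity correction when every expected
#' count is at least 5; otherwise Fisher's exact test (two-sided, computed
#' by exact hypergeometric enumeration over all tables with the observed
#' margins). The result records which test ran.
#'
#' @param counts 2x2 matrix of non-negative integer counts (rows: groups,
#'   columns: within / beyond threshold).
#' @return List with `p_value`, `test_used` (`"chi_square"` or
#'   `"fisher_exact"`), `statistic` (chi-square statistic, `NA` for Fisher),
#'   `expected` (matrix of expected counts).
#' @export
proportion_test <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2L, 2L))) {
    stop("proportion_test: counts must be a 2x2 matrix", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m)) || any(!is.finite(m))) {
    stop("proportion_test: counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(m)
  if (n == 0) stop("proportion_test: all-zero table", call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / n
  if (any(expected < 5)) {
    list(p_value = fisher2x2_p(m), test_used = "fisher_exact",
         statistic = NA_real_, expected = expected)
  } else {
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(p_value = ht$p.value, test_used = "chi_square",
         statistic = unname(ht$statistic), expected = expected)
  }
}

#' Intraclass correlation coefficient (two-way, absolute agreement, single)
#'
#' ICC for a complete subjects-by-replicates matrix, computed from the
#' two-way ANOVA mean squares (McGraw & Wong form A-1, i.e. two-way model,
#' absolute agreement, single measure):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-replicate
#' (column) and \eqn{MS_E} the residual mean square.
#'
#' @param values Numeric matrix, `n >= 2` subjects (rows) by `k >= 2`
#'   replicates (columns), no missing values (no imputation is attempted).
#' @return List of class `icc_result`: `icc_value`, `form_id`, `n_subjects`,
#'   `n_replicates`, `degenerate` (TRUE with `icc_value = NA` when every
#'   value in the matrix is identical, so no variance exists to partition).
#' @export
icc <- function(values) {
  m <- as.matrix(values)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("icc: need >= 2 subjects and >= 2 replicates", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("icc: matrix has missing or non-finite values; no imputation",
         call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - msr * (n - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  form <- "ICC(A,1): two-way mixed effects, absolute agreement, single measure"
  if (sst == 0 || denom <= 0) {
    return(structure(list(icc_value = NA_real_, form_id = form,
                          n_subjects = n, n_replicates = k,
                          degenerate = TRUE), class = "icc_result"))
  }
  structure(list(icc_value = (msr - mse) / denom, form_id = form,
                 n_subjects = n, n_replicates = k, degenerate = FALSE),
            class = "icc_result")
}

#' Pooled ICC across reviewers
#'
#' Computes one replicate-reliability ICC per reviewer (subjects = units,
#' columns = replicates) and pools them by averaging Fisher-z transforms and
#' back-transforming. ICCs at the +1/-1 boundary are clamped by 1e-12 before
#' the transform so a set of perfect reviewers pools to 1.
#'
#' @param t Long-format measurement table with replicate_index filled in.
#' @param program_id Program whose replicates are assessed.
#' @param parameter Parameter name.
#' @return List of class `icc_result` with pooled `icc_value`, `form_id`,
#'   `n_subjects` (total units), `n_replicates`, and `component_iccs`
#'   (named by reviewer).
#' @export
pooled_icc <- function(t, program_id, parameter) {
  s <- t[t$program_id == program_id & t$parameter == parameter, , drop = FALSE]
  if (nrow(s) == 0L) {
    stop(sprintf("pooled_icc: no records for program '%s', parameter '%s'",
                 program_id, parameter), call. = FALSE)
  }
  reviewers <- sort(unique(s$reviewer_id))
  comp <- numeric(0)
  n_subj <- 0L
  n_rep <- NA_integer_
  for (rv in reviewers) {
    sr <- s[s$reviewer_id == rv, , drop = FALSE]
    mat <- stats::xtabs(value ~ paste(image_id, side, sep = "|") + replicate_index,
                        data = sr)
    cnt <- stats::xtabs(~ paste(image_id, side, sep = "|") + replicate_index,
                        data = sr)
    if (any(cnt != 1L)) {
      stop(sprintf("pooled_icc: reviewer '%s' has an incomplete replicate matrix",
                   rv), call. = FALSE)
    }
    res <- icc(unclass(mat))
    if (res$degenerate) {
      stop(sprintf("pooled_icc: degenerate ICC for reviewer '%s'", rv),
           call. = FALSE)
    }
    comp[rv] <- res$icc_value
    n_subj <- n_subj + res$n_subjects
    n_rep <- res$n_replicates
  }
  z <- atanh(pmax(pmin(comp, 1 - 1e-12), -1 + 1e-12))
  pooled <- tanh(mean(z))
  if (all(comp == 1)) pooled <- 1
  structure(list(icc_value = pooled,
                 form_id = paste("pooled Fisher-z mean of",
                                 "ICC(A,1) two-way mixed, absolute agreement,",
                                 "single measure"),
                 n_subjects = n_subj, n_replicates = n_rep,
                 component_iccs = comp, degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f  [%s]  (%d subjects x %d replicates)\n",
              x$icc_value, x$form_id, x$n_subjects, x$n_replicates))
  invisible(x)
}
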