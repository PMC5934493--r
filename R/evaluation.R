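#' Root-mean-square error between two angle series
#'
#' `sqrt(sum((x - y)^2) / n)`, capturing shape and offset differences
#' between an estimate and the ground truth.
#'
#' @param x,y numeric vectors of equal length (degrees); `x` is the
#'   ground-truth series, `y` the estimate.
#' @return RMSE in degrees.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y) || length(x) == 0L)
    stop("x and y must be non-empty and of equal length", call. = FALSE)
  sqrt(mean((x - y)^2))
}

#' Range-of-motion error between two angle series
#'
#' `(max(x) - min(x)) - (max(y) - min(y))`: the difference in movement
#' amplitude between ground truth and estimate. Signed; invariant to
#' constant offsets in either series. Aggregation uses the magnitude.
#'
#' @inheritParams rmse
#' @return Signed ROME in degrees.
#' @export
rome <- function(x, y) {
  if (length(x) != length(y) || length(x) == 0L)
    stop("x and y must be non-empty and of equal length", call. = FALSE)
  (max(x) - min(x)) - (max(y) - min(y))
}

#' Error-reduction percentage of one estimator over another
#'
#' `100 * (e_rigid - e_eikpe) / e_rigid`: the reduction in error achieved
#' by the constraint-closure estimate relative to the rigid baseline.
#' Report tables round to the nearest integer; the computation itself is
#' exact.
#'
#' @param e_rigid baseline error (> 0), degrees.
#' @param e_eikpe comparison error (>= 0), degrees.
#' @return Improvement in percent (unrounded).
#' @export
improvement_pct <- function(e_rigid, e_eikpe) {
  if (any(e_rigid <= 0))
    stop("undefined improvement: baseline error must be > 0", call. = FALSE)
  if (any(e_eikpe < 0))
    stop("comparison error must be >= 0", call. = FALSE)
  100 * (e_rigid - e_eikpe) / e_rigid
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided two-sample rank-sum test with mid-ranks for ties. For
#' combined sample sizes up to `exact_limit` the p-value is exact, by full
#' enumeration of all `choose(n+m, n)` assignments of the pooled
#' mid-ranks (valid under ties, unlike the classical exact tables);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric error samples (non-empty).
#' @param exact_limit maximum `length(a) + length(b)` for the exact path
#'   (default 16, covering 7-vs-7 comparisons).
#' @return List with `statistic` (rank sum of `a`), `p.value` and
#'   `method`.
#' @export
ranksum_test <- function(a, b, exact_limit = 16L) {
  if (!length(a) || !length(b))
    stop("samples must be non-empty", call. = FALSE)
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))  # mid-ranks
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  if (n + m <= exact_limit) {
    idx <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[idx], nrow = n))
    d_obs <- abs(w_obs - mu)
    p <- mean(abs(w_all - mu) >= d_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * m / 12 * ((n + m + 1) -
      sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = w_obs, p.value = p, method = method)
}

#' Build an evaluation report comparing estimators against ground truth
#'
#' For every subject and sagittal joint, computes RMSE and |ROME| of the
#' rigid baseline and of the constraint-closure (EIKPE) estimate against
#' the ground-truth angles; aggregates mean and standard deviation across
#' subjects; derives per-joint/per-metric improvement percentages from the
#' unrounded mean errors (rounding happens only at print time); and runs
#' a rank-sum test per joint/metric comparing the two methods' per-subject
#' error samples.
#'
#' @param gt named list subject -> ground-truth [joint_trajectory()].
#' @param rigid,eikpe named lists with the same subject keys holding each
#'   method's estimated trajectories.
#' @return An object of class `eval_report`: `per_subject` (long
#'   data.frame of per-trial errors) and `table` (aggregated
#'   Table-1-style data.frame with columns joint, metric, rigid_mean,
#'   rigid_sd, eikpe_mean, eikpe_sd, improvement_pct, p_value).
#' @export
build_report <- function(gt, rigid, eikpe) {
  keys <- names(gt)
  if (is.null(keys) || !setequal(keys, names(rigid)) ||
      !setequal(keys, names(eikpe)))
    stop("schema error: gt, rigid and eikpe must share subject keys",
         call. = FALSE)
  joints <- c("hip_flexion", "knee_flexion", "ankle_flexion")
  rows <- list()
  for (s in keys) {
    for (j in joints) {
      x <- gt[[s]]$channels[[j]]
      for (method in c("rigid", "eikpe")) {
        est <- (if (method == "rigid") rigid else eikpe)[[s]]$channels[[j]]
        if (length(est) != length(x))
          stop("schema error: trajectory lengths differ for subject ", s,
               call. = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, joint = j, method = method,
                     rmse = rmse(x, est), rome = rome(x, est))
      }
    }
  }
  per_subject <- do.call(rbind, rows)
  tab <- list()
  for (j in joints) {
    for (metric in c("rmse", "rome")) {
      er <- per_subject[per_subject$joint == j &
                          per_subject$method == "rigid", metric]
      ee <- per_subject[per_subject$joint == j &
                          per_subject$method == "eikpe", metric]
      er <- abs(er); ee <- abs(ee)  # |ROME| aggregation; RMSE already >= 0
      imp <- if (mean(er) > 0) improvement_pct(mean(er), mean(ee)) else NA_real_
      p <- ranksum_test(er, ee)$p.value
      tab[[length(tab) + 1L]] <-
        data.frame(joint = sub("_flexion", "", j), metric = toupper(metric),
                   rigid_mean = mean(er), rigid_sd = stats::sd(er),
                   eikpe_mean = mean(ee), eikpe_sd = stats::sd(ee),
                   improvement_pct = imp, p_value = p)
    }
  }
  structure(list(per_subject = per_subject, table = do.call(rbind, tab),
                 n_subjects = length(keys)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("joint angle estimation errors (", x$n_subjects,
      " subjects, mean ± sd, degrees)\n\n", sep = "")
  t <- x$table
  out <- data.frame(
    joint = t$joint, metric = t$metric,
    rigid = sprintf("%.1f ± %.1f", t$rigid_mean, t$rigid_sd),
    eikpe = sprintf("%.1f ± %.1f", t$eikpe_mean, t$eikpe_sd),
    improvement = ifelse(is.na(t$improvement_pct), "-",
                         sprintf("%d%%", round(t$improvement_pct))),
    p = sprintf("%.3f", t$p_value))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  ps <- x$per_subject
  for (metric in c("rmse", "rome")) {
    vals <- abs(ps[[metric]])
    grp <- interaction(sub("_flexion", "", ps$joint), ps$method, sep = "\n")
    graphics::boxplot(vals ~ grp, ylab = paste(toupper(metric), "(deg)"),
                      xlab = "", las = 2, col = c("lightsteelblue", "sandybrown"),
                      ...)
  }
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report an `eval_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(table = report$table,
                              per_subject = report$per_subject,
                              n_subjects = report$n_subjects),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
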