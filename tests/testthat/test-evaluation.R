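test_that("rmse follows its closed form and basic invariances", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(3, 4, 5)), 2)
  expect_equal(rmse(c(0, 3, 4), c(0, 0, 0)), sqrt(25 / 3))
  # invariant to a common reordering of paired samples
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50); o <- sample(50)
  expect_equal(rmse(x, y), rmse(x[o], y[o]))
  expect_gt(rmse(x, y), 0)
  expect_error(rmse(1:3, 1:4), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("rome is the signed range difference, offset-invariant", {
  x <- c(0, 30, 60); y <- c(5, 30, 55)
  expect_equal(rome(x, y), 10)
  expect_equal(rome(x, x), 0)
  expect_equal(rome(x, y + 10), 10)
  expect_equal(rome(x + 7, y), 10)
  expect_equal(rome(y, x), -10)  # signed
})

test_that("improvement percentage matches the reference error-reduction arithmetic", {
  expect_equal(round(improvement_pct(2.2, 1.6)), 27)
  expect_equal(round(improvement_pct(2.9, 1.0)), 66)
  expect_equal(round(improvement_pct(4.1, 2.3)), 44)
  expect_equal(improvement_pct(3, 3), 0)
  expect_equal(improvement_pct(5, 0), 100)
  expect_error(improvement_pct(0, 1), "undefined")
  expect_error(improvement_pct(2, -1), ">= 0")
})

test_that("exact rank-sum p-values: identical samples, full separation, symmetry", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(ranksum_test(a, a)$p.value, 1)
  # fully separated 7-vs-7: only the two extreme rank splits are as extreme
  sep <- ranksum_test(1:7, 8:14)
  expect_equal(sep$p.value, 2 / choose(14, 7))
  expect_equal(sep$method, "exact enumeration")
  # symmetric in its arguments
  set.seed(31)
  x <- rnorm(6); y <- rnorm(5) + 1
  expect_equal(ranksum_test(x, y)$p.value, ranksum_test(y, x)$p.value)
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact enumeration agrees with the classical exact distribution without ties", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    a <- rnorm(n); b <- rnorm(m, mean = runif(1, -1, 1))
    p_pkg <- ranksum_test(a, b)$p.value
    p_ref <- stats::wilcox.test(a, b, exact = TRUE,
                                alternative = "two.sided")$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("exact enumeration with ties agrees with a permutation oracle", {
  set.seed(55)
  perm_p <- function(a, b, B = 1e5) {
    n <- length(a); r <- rank(c(a, b)); mu <- n * (n + length(b) + 1) / 2
    obs <- abs(sum(r[seq_len(n)]) - mu)
    hits <- replicate(B, abs(sum(sample(r, n)) - mu) >= obs - 1e-9)
    mean(hits)
  }
  for (rep in 1:3) {
    a <- sample(0:3, 5, replace = TRUE)   # heavy ties
    b <- sample(1:4, 5, replace = TRUE)
    expect_equal(ranksum_test(a, b)$p.value, perm_p(a, b), tolerance = 0.005)
  }
})

test_that("large samples fall back to a tie-corrected normal approximation", {
  set.seed(42)
  a <- rnorm(12); b <- rnorm(12, 1)
  res <- ranksum_test(a, b)
  expect_match(res$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(res$p.value, ref, tolerance = 1e-6)
})

test_that("evaluation reports aggregate per-subject errors into the standard table layout", {
  v <- generate_gait_profile(gait_profile_params(duration = 2))
  subjects <- paste0("S", 1:4)
  gt <- rigid <- est <- list()
  set.seed(9)
  for (s in subjects) {
    noise <- rnorm(n_frames(v), sd = 0.2)
    gt[[s]] <- v
    rigid[[s]] <- joint_trajectory(v$time, lapply(v$channels, function(x)
      x + 2 + noise))
    est[[s]] <- joint_trajectory(v$time, lapply(v$channels, function(x)
      x + 0.5 * noise))
  }
  rep <- build_report(gt, rigid, est)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$table), 6L)
  expect_true(all(rep$table$eikpe_mean < rep$table$rigid_mean))
  expect_true(all(rep$table$p_value >= 0 & rep$table$p_value <= 1))
  expect_output(print(rep), "Improvement|improvement|%")
  # estimator identical to ground truth: zero error, 100% improvement
  rep2 <- build_report(gt["S1"], rigid["S1"], gt["S1"])
  expect_equal(rep2$table$eikpe_mean, rep(0, 6))
  expect_equal(rep2$table$improvement_pct[rep2$table$metric == "RMSE"],
               rep(100, 3))
  # both methods identical: zero improvement, exact p = 1
  rep3 <- build_report(gt, rigid, rigid)
  expect_equal(rep3$table$improvement_pct, rep(0, 6))
  expect_equal(rep3$table$p_value, rep(1, 6))
  expect_error(build_report(gt, rigid[1:2], est), "schema error")
  # injected reference means reproduce the printed improvement cell
  expect_equal(round(improvement_pct(mean(c(2.2, 2.2)), mean(c(1.6, 1.6)))), 27)
})

test_that("reports serialize to CSV and JSON and render box plots", {
  v <- generate_gait_profile(gait_profile_params(duration = 0.5))
  gt <- list(S1 = v, S2 = v)
  shift <- joint_trajectory(v$time, lapply(v$channels, `+`, 1))
  rep <- build_report(gt, list(S1 = shift, S2 = shift), gt)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_report(rep, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), 6L)
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(rep))
})
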