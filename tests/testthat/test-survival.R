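test_that("report times convert to frame durations with final censoring", {
  ds <- structure(list(
    reports = data.frame(subject = 1, block = 1, T_frame_ms = 300,
                         report_time_ms = c(1200, 2400),
                         block_duration_ms = 3000),
    blocks = data.frame(block = 1, T_frame_ms = 300,
                        block_duration_ms = 3000),
    provenance = "synthetic"), class = "report_dataset")
  rec <- records_from_reports(ds)
  expect_equal(rec$T_D, c(4, 4, 2))
  expect_equal(rec$censored, c(FALSE, FALSE, TRUE))
  expect_equal(rec$epoch, 1:3)
  # a block without reports becomes one fully censored record
  ds$reports$report_time_ms <- NA
  ds$reports <- ds$reports[1, ]
  rec0 <- records_from_reports(ds)
  expect_equal(rec0$T_D, 10)
  expect_true(rec0$censored)
  # already-encoded records pass through unchanged
  expect_identical(records_from_reports(rec0), rec0)
})

test_that("durations conserve the block length up to rounding", {
  ds <- synth_reports(n_subjects = 4, seed = 11)
  rec <- records_from_reports(ds)
  for (key in split(rec, interaction(rec$subject, rec$block))) {
    block_frames <- ds$blocks$block_duration_ms[key$block[1]] /
      ds$blocks$T_frame_ms[key$block[1]]
    expect_lt(abs(sum(key$T_D) - block_frames), nrow(key) * 0.5 + 1)
  }
})

test_that("screening drops inadequate blocks and subjects", {
  ds <- synth_reports(n_subjects = 16, seed = 2)
  rec <- records_from_reports(ds)
  # construct one subject with fewer than two switches in every block
  rec <- rec[!(rec$subject == 16 & !rec$censored) |
               (rec$subject == 16 & rec$epoch <= 1), ]
  rec$censored[rec$subject == 16] <- TRUE
  sc <- screen_subjects(rec)
  expect_equal(attr(sc, "n_subjects"), 15L)
  expect_false(16 %in% sc$subject)
  expect_gt(nrow(attr(sc, "exclusions")), 0)
  # all-pass data returns identically
  sc2 <- screen_subjects(records_from_reports(ds))
  expect_equal(nrow(sc2), nrow(records_from_reports(ds)))
  # screening everything away is an error
  lone <- rec[rec$subject == 16, ]
  expect_error(screen_subjects(lone), "removed all")
})

test_that("synthetic reports are seed-deterministic and exponential under the null", {
  d1 <- synth_reports(n_subjects = 3, seed = 99)
  d2 <- synth_reports(n_subjects = 3, seed = 99)
  expect_identical(d1$reports, d2$reports)
  # zero effects, zero frailty: pooled inter-report gaps are exponential
  ds <- synth_reports(n_subjects = 10, T_frame_ms = 300,
                      block_duration_ms = 1.6e6, beta_T_frame = 0,
                      beta_epoch = 0, frailty_var = 0,
                      baseline_hazard = 1 / 5, epoch_cap = Inf, seed = 7)
  gaps <- unlist(lapply(split(ds$reports, ds$reports$subject), function(r)
    diff(c(0, r$report_time_ms)) / 300))
  expect_gt(length(gaps), 5000)
  ks <- stats::ks.test(gaps, "pexp", rate = 1 / 5)
  expect_gt(ks$p.value, 0.01)
})

test_that("the mixed Cox fit recovers known effects and validates its inputs", {
  ds <- synth_reports(n_subjects = 8, block_duration_ms = 60000 * rep(2, 4),
                      beta_T_frame = log(0.996), beta_epoch = 0,
                      frailty_var = 0.1, epoch_cap = Inf, seed = 21)
  rec <- screen_subjects(records_from_reports(ds))
  fit <- fit_cox_mixed(rec, fixed = "T_frame")
  expect_lt(abs(fit$coef - log(0.996)), 2 * fit$se)
  expect_equal(fit$hazard_ratio, exp(fit$coef))
  expect_gt(fit$hazard_ratio, 0)
  expect_lte(fit$n_events, fit$n)
  expect_equal(unname(coef(fit)), fit$coef)
  # no events -> explicit failure
  rec_cens <- rec; rec_cens$censored <- TRUE
  expect_error(fit_cox_mixed(rec_cens, "T_frame"), "no uncensored")
  # a single covariate value is unfittable
  one <- rec[rec$T_frame_ms == 300, ]
  expect_error(fit_cox_mixed(one, "T_frame"), "distinct")
})

test_that("proportionality check flags a strongly time-varying effect", {
  # hazard effect of the covariate reverses midway: piecewise-exponential
  # sampling by inversion of the cumulative hazard
  set.seed(5)
  n <- 400
  x <- rep(c(0, 1), each = n / 2)
  b <- 1.2; brk <- 3
  h1 <- 0.2 * exp(b * x); h2 <- 0.2 * exp(-b * x)
  E <- stats::rexp(n)
  t_obs <- ifelse(E < h1 * brk, E / h1, brk + (E - h1 * brk) / h2)
  rec <- data.frame(subject = rep(1:8, length.out = n),
                    T_frame_ms = 300 + 100 * x, epoch = 1,
                    T_D = t_obs, censored = FALSE)
  fit <- fit_cox_mixed(rec, fixed = "T_frame")
  p <- proportionality_check(fit)
  expect_lt(p[["x"]], 0.05)
  # single covariate value: untestable
  fit$data$x <- 1
  expect_error(proportionality_check(fit), "untestable")
})

test_that("report CSV round trips through the column-mapped reader", {
  ds <- synth_reports(n_subjects = 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(ds, f)
  back <- read_report_csv(f, provenance = "synthetic")
  expect_equal(back$reports$report_time_ms, ds$reports$report_time_ms)
  expect_equal(records_from_reports(back), records_from_reports(ds))
  # mapping errors are explicit
  expect_error(read_report_csv(f, column_map = c(subject = "nope")),
               "lacks")
})
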