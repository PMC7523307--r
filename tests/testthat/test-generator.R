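test_that("build_schedule reproduces the 5-a-day, 14-day design", {
  times <- build_schedule(ema_schedule(14, 5, 180, 0))
  expect_length(times, 70)
  expect_true(all(diff(times) > 0))

  single <- build_schedule(ema_schedule(1, 1, 180, 0))
  expect_equal(single, 0)

  two_days <- build_schedule(ema_schedule(2, 5, 180, 0))
  expect_equal(two_days[6] - two_days[5], 1440 - 4 * 180)  # 720-min night

  expect_error(ema_schedule(2, 9, 180, 0), "infeasible")
})

test_that("schedule jitter keeps prompts ordered and near-nominal", {
  sch <- ema_schedule(14, 5, 180, jitter_sd_min = 10)
  for (seed in 1:10) {
    times <- build_schedule(sch, seed = seed)
    expect_length(times, 70)
    expect_true(all(diff(times) > 0))
    expect_true(all(times >= 0))
    within_day <- diff(times)[rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 14)[-70]]
    expect_true(all(abs(within_day - 180) <= 120))
  }
})

test_that("person parameter draws respect the random-effect structure", {
  base <- default_generator_config()
  g <- base$group_specs[[1]]

  exact <- draw_person_params(g, re_sd_phi = 0, re_sd_mu = 0, seed = 5)
  expect_equal(exact$phi, g$phi_mean)
  expect_equal(exact$mu, g$mu_mean)
  expect_equal(exact$retries, 0L)

  a <- draw_person_params(g, 0.1, 0.5, seed = 42)
  b <- draw_person_params(g, 0.1, 0.5, seed = 42)
  expect_identical(a, b)

  # near-unit-root group mean forces redraws, but results stay stationary
  risky <- group_spec("edge", diag(0.85, 7), g$mu_mean, 1)
  retries <- 0L
  for (seed in 1:25) {
    p <- draw_person_params(risky, 0.08, 0, seed = seed)
    expect_lt(spectral_radius(p$phi), 1)
    retries <- retries + p$retries
  }
  expect_gt(retries, 0)

  # an explosive group mean with no person variation can never succeed
  doomed <- structure(list(name = "doomed", phi_mean = diag(1.2, 7),
                           mu_mean = g$mu_mean, n_persons = 1L),
                      class = "group_spec")
  expect_error(draw_person_params(doomed, 0, 0, seed = 1, max_retries = 5),
               "doomed")
})

test_that("simulate_person matches closed-form VAR(1) moments", {
  mu4 <- rep(4, 7)
  times <- build_schedule(ema_schedule(4, 5, 180, 0))
  quiet <- simulate_person(matrix(0, 7, 7), mu4, diag(1e-20, 7), times, 180,
                           seed = 1)
  expect_true(all(abs(as.matrix(quiet[, -(1:2)]) - 4) < 1e-6))

  # phi = 0, Sigma = I: per-item variance of emitted values ~ 1
  long <- build_schedule(ema_schedule(400, 8, 180, 0))
  white <- simulate_person(matrix(0, 7, 7), mu4, diag(7), long, 180, seed = 2)
  v <- apply(as.matrix(white[, -(1:2)]), 2, var)
  expect_true(all(abs(v - 1) < 0.12))

  # phi = 0.5 I: lag-1 autocorrelation at the lattice spacing ~ 0.5
  ar <- simulate_person(diag(0.5, 7), mu4, diag(7), long, 180, seed = 3)
  y <- as.matrix(ar[, -(1:2)])
  r1 <- vapply(seq_len(7), function(j) cor(y[-nrow(y), j], y[-1, j]), 1.0)
  expect_true(all(abs(r1 - 0.5) < 0.06))

  expect_error(simulate_person(diag(1.01, 7), mu4, diag(7), times, 180),
               "non-stationary")
})

test_that("likert emission rounds and clips to the 1-7 scale", {
  times <- build_schedule(ema_schedule(4, 5, 180, 0))
  rec <- simulate_person(diag(0.2, 7), rep(6.5, 7), diag(2, 7), times, 180,
                         likert = TRUE, seed = 4)
  y <- as.matrix(rec[, -(1:2)])
  expect_true(all(y == round(y)))
  expect_true(all(y >= 1 & y <= 7))
})

test_that("simulate_panel reproduces the study's group sizes and missingness", {
  cfg <- default_generator_config(seed = 3)
  panel <- simulate_panel(cfg)
  expect_equal(length(unique(panel$person_id)), 220)
  sizes <- table(unique(as.data.frame(panel)[, c("person_id", "group")])$group)
  expect_equal(as.integer(sizes[c("comorbid", "depression_only", "anxiety_only")]),
               c(143L, 40L, 37L))
  expect_equal(nrow(panel), 220 * 70)

  # binomial expectation for answered records
  n_ans <- sum(panel$answered)
  expval <- 220 * 70 * (1 - cfg$miss_prob)
  expect_lt(abs(n_ans - expval), 4 * sqrt(220 * 70 * 0.08 * 0.92))

  meta <- attr(panel, "metadata")
  expect_equal(nrow(meta), 220)
  expect_true(all(c("severity", "recency_class") %in% names(meta)))
})

test_that("no-missingness config answers every scheduled prompt", {
  cfg <- single_group_config(3, days = 2, prompts_per_day = 5, seed = 8)
  panel <- simulate_panel(cfg)
  expect_true(all(panel$answered))
  expect_equal(as.integer(table(panel$person_id)), rep(10L, 3))
})

test_that("identical seeds give byte-identical panels", {
  cfg <- single_group_config(4, days = 3, seed = 77)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_ema_csv(p1, f1); write_ema_csv(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2, paste0(c(f1, f2), ".json")))
})

test_that("panel CSV round-trips through write/read", {
  cfg <- single_group_config(3, days = 2, miss_prob = 0.2, seed = 12)
  panel <- simulate_panel(cfg)
  f <- tempfile(fileext = ".csv")
  write_ema_csv(panel, f)
  back <- read_ema_csv(f)
  strip <- function(d) {
    d <- as.data.frame(d)
    data.frame(d, stringsAsFactors = FALSE)
  }
  expect_equal(strip(back), strip(panel), tolerance = 1e-12)
  expect_false(isTRUE(attr(back, "reverse_coded")))
  expect_equal(nrow(attr(back, "metadata")), 3)
  unlink(c(f, paste0(f, ".json")))
})

test_that("long-series lag regressions converge to the generating matrix", {
  base <- default_generator_config()
  phi <- base$group_specs[[1]]$phi_mean
  long <- single_group_config(3, days = 250, phi = phi, seed = 21)
  gridded <- gridded_from_config(long)
  # every person's own T = 2000 regression sits near the truth ...
  for (p in gridded) {
    expect_gte(nrow(p$y), 2000)
    expect_lt(max(abs(pooled_ols(list(p))$phi - phi)), 0.08)
  }
  # ... and the error keeps shrinking with more information
  expect_lt(max(abs(pooled_ols(gridded)$phi - phi)), 0.03)
  short <- single_group_config(3, days = 25, phi = phi, seed = 21)
  err_short <- max(abs(pooled_ols(gridded_from_config(short))$phi - phi))
  expect_lt(max(abs(pooled_ols(gridded)$phi - phi)), err_short)
})
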