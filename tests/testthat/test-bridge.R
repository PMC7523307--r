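test_that("path counts match the 7-item catalog exactly", {
  expected <- c(WOR = 22L, IRR = 22L, NER = 24L, REL = 24L,
                LIS = 26L, CHE = 26L, DOW = 26L)
  for (b in names(expected)) {
    ps <- enumerate_bridge_paths(b)
    expect_equal(ps$count, expected[[b]], info = b)
    expect_equal(nrow(ps$pairs), ps$count)
    expect_false(any(ps$pairs$from == b | ps$pairs$to == b))
    expect_false(any(ps$pairs$from == ps$pairs$to))
    expect_false(anyDuplicated(paste(ps$pairs$from, ps$pairs$to)) > 0)
  }
  expect_error(enumerate_bridge_paths("XXX"), "unknown bridge")
})

test_that("enumerator agrees with the brute-force membership rule on random catalogs", {
  set.seed(2024)
  for (rep_ in 1:100) {
    cat_r <- random_catalog(sample(4:9, 1))
    b <- sample(cat_r$code, 1)
    expect_equal(enumerate_bridge_paths(b, cat_r)$count,
                 brute_force_path_count(b, cat_r),
                 info = sprintf("rep %d bridge %s", rep_, b))
  }
})

test_that("bridge effect sums lag-2 cross-products over the path set", {
  codes <- item_catalog()$code
  ps <- enumerate_bridge_paths("WOR")

  zero <- array(0, dim = c(10, 7, 7), dimnames = list(NULL, codes, codes))
  expect_equal(bridge_effect_draws(zero, ps), rep(0, 10))

  # single surviving path: DOW -> WOR -> NER
  one <- zero
  one[, "WOR", "DOW"] <- 0.2
  one[, "NER", "WOR"] <- 0.1
  expect_equal(bridge_effect_draws(one, ps), rep(0.2 * 0.1, 10))

  # bilinearity: doubling every coefficient quadruples the effect
  arr <- fixed_phi_draws()
  base <- bridge_effect_draws(arr, ps)
  expect_equal(bridge_effect_draws(2 * arr, ps), 4 * base, tolerance = 1e-12)
})

test_that("bridge effect equals the sum of per-pair terms", {
  arr <- fixed_phi_draws()
  for (b in c("WOR", "DOW", "NER")) {
    ps <- enumerate_bridge_paths(b)
    total <- bridge_effect_draws(arr, ps)
    by_pair <- rowSums(vapply(seq_len(ps$count), function(k) {
      arr[, b, ps$pairs$from[k]] * arr[, ps$pairs$to[k], b]
    }, numeric(dim(arr)[1])))
    expect_equal(total, by_pair, tolerance = 1e-14)
  }
})

test_that("summaries are functionals of the draws, not of plug-in means", {
  arr <- fixed_phi_draws(n_draw = 400)
  ps <- enumerate_bridge_paths("WOR")
  draws <- bridge_effect_draws(arr, ps)
  s <- summarize_effect(draws, ps$count)
  expect_equal(s$mean, mean(draws))
  expect_equal(s$ci, quantile(draws, c(0.025, 0.975), names = FALSE))
  expect_equal(s$mean_draws, draws / ps$count)

  # plug-in of posterior-mean coefficients differs from the drawwise mean
  pm <- apply(arr, c(2, 3), mean)
  plug <- sum(pm["WOR", ps$pairs$from] *
                pm[cbind(ps$pairs$to, rep("WOR", ps$count))])
  expect_false(isTRUE(all.equal(plug, s$mean, tolerance = 1e-6)))
})

test_that("summarize_effect handles degenerate and symmetric draws", {
  s <- summarize_effect(rep(0.5, 200), count = 22)
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci, c(0.5, 0.5))
  expect_equal(s$p_one_tailed, 0)
  expect_true(s$significant)
  expect_equal(s$mean_effect, 0.5 / 22)

  sym <- summarize_effect(c(seq(-1, -0.01, length = 100),
                            seq(0.01, 1, length = 100)), 1)
  expect_equal(sym$p_one_tailed, 0.5)
  expect_false(sym$significant)

  expect_error(summarize_effect(numeric(0)), "empty")
})

test_that("summarize_effect matches the normal quantile oracle", {
  set.seed(31)
  draws <- rnorm(1e4, 0.02, 0.005)
  s <- summarize_effect(draws, 1)
  expect_equal(s$ci[1], qnorm(0.025, 0.02, 0.005), tolerance = 0.02)
  expect_equal(s$ci[2], qnorm(0.975, 0.02, 0.005), tolerance = 0.02)
})

test_that("group comparisons subtract drawwise", {
  a <- summarize_effect(rep(0.3, 100), 22, "WOR", "comorbid")
  b <- summarize_effect(rep(0.3, 100), 22, "WOR", "anxiety_only")
  d0 <- compare_groups(a, b)
  expect_equal(d0$mean, 0)
  expect_equal(d0$ci, c(0, 0))

  shift <- summarize_effect(rep(0.3, 100) - 0.019, 22, "WOR", "anxiety_only")
  d1 <- compare_groups(a, shift)
  expect_equal(d1$mean, 0.019)

  set.seed(5)
  x <- rnorm(5000, 0, 0.01); y <- rnorm(5000, 0, 0.02)
  dv <- compare_groups(summarize_effect(x, 1), summarize_effect(y, 1))
  expect_equal(var(dv$draws), 0.01^2 + 0.02^2, tolerance = 0.1)

  expect_error(compare_groups(a, summarize_effect(rep(0, 50), 22)),
               "not aligned")
})

test_that("scale equivariance: c * draws scales summaries by c^2", {
  arr <- fixed_phi_draws(n_draw = 200)
  for (b in c("WOR", "LIS")) {
    ps <- enumerate_bridge_paths(b)
    s1 <- summarize_effect(bridge_effect_draws(arr, ps), ps$count)
    s3 <- summarize_effect(bridge_effect_draws(3 * arr, ps), ps$count)
    expect_equal(s3$mean, 9 * s1$mean, tolerance = 1e-12)
    expect_equal(s3$ci, 9 * s1$ci, tolerance = 1e-12)
    expect_equal(s3$mean_effect, 9 * s1$mean_effect, tolerance = 1e-12)
  }
})

test_that("rank_bridges orders by mean bridge effect and flags differences", {
  codes <- item_catalog()$code
  n <- 500
  set.seed(8)
  # construct posteriors with a known ordering and one clear winner
  summaries <- lapply(seq_along(codes), function(k) {
    ps <- enumerate_bridge_paths(codes[k])
    draws <- rnorm(n, 0.002 * k, 0.0005) * ps$count
    summarize_effect(draws, ps$count, bridge = codes[k], group = "comorbid")
  })
  r <- rank_bridges(summaries)
  expect_equal(r$bridge[1], codes[7])
  expect_true(r$is_best[1])
  expect_equal(r$mean_effect, sort(r$mean_effect, decreasing = TRUE))
  expect_true(all(r$differs_from_best[r$rank >= 3]))

  # identical draws: no flags, tie broken by catalog order with a warning
  same <- lapply(codes, function(b) {
    ps <- enumerate_bridge_paths(b)
    summarize_effect(rep(0.001, n) * ps$count, ps$count, bridge = b,
                     group = "comorbid")
  })
  expect_warning(r2 <- rank_bridges(same), "tie")
  expect_equal(r2$bridge[r2$is_best], "REL")
  expect_false(any(r2$differs_from_best))

  # drawwise dominance by a constant margin flags everyone else
  dom <- lapply(seq_along(codes), function(k) {
    ps <- enumerate_bridge_paths(codes[k])
    base <- rnorm(n, 0, 0.0005)
    margin <- if (k == 1) 0.005 else 0
    summarize_effect((base + margin) * ps$count, ps$count,
                     bridge = codes[k], group = "comorbid")
  })
  r3 <- rank_bridges(dom)
  expect_equal(r3$bridge[1], codes[1])
  expect_true(all(r3$differs_from_best[-1]))
})
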