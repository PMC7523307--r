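# one small complete-data fit reused by several blocks
small_fit <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      cfg <- single_group_config(12, days = 6, seed = 7)
      gridded <- gridded_from_config(cfg)
      cached <<- list(
        gridded = gridded,
        fit = fit_mlvar(gridded, mlvar_spec(chains = 2, iterations = 3000,
                                            seed = 3)))
    }
    cached
  }
})

test_that("group composition rule reconstructs every group at every draw", {
  fx <- make_fixtures("tiny")
  gridded <- align_to_grid(reverse_code(fx$panel), 180)
  fit <- fit_mlvar(gridded, mlvar_spec(chains = 2, iterations = 300,
                                       min_obs = 5, seed = 11))
  expect_equal(fit$groups[1], "comorbid")
  ref <- group_phi_draws(fit, "comorbid")
  for (g in fit$groups[-1]) {
    phi_g <- group_phi_draws(fit, g)
    gi <- match(g, fit$groups)
    off <- fit$gamma[, gi, 1:49]
    recon <- array(as.vector(ref) + as.vector(off), dim = dim(ref))
    expect_equal(as.vector(phi_g), as.vector(recon), tolerance = 1e-12)
  }
  expect_error(group_phi_draws(fit, "nope"), "unknown group")
})

test_that("reference-group draws are the intercept draws unchanged", {
  fit <- small_fit()$fit
  phi <- group_phi_draws(fit, "comorbid")
  expect_equal(as.vector(phi), as.vector(fit$gamma[, 1, 1:49]))
})

test_that("imputation bookkeeping equals the count of missing grid cells", {
  cfg <- single_group_config(4, days = 4, prompts_per_day = 5,
                             miss_prob = 0.15, seed = 19)
  gridded <- gridded_from_config(cfg)
  n_missing <- sum(vapply(gridded, function(p) sum(is.na(p$y)), 1L))
  fit <- fit_mlvar(gridded, mlvar_spec(chains = 2, iterations = 200,
                                       min_obs = 5, seed = 2))
  expect_equal(fit$n_imputed_cells, n_missing)
  expect_gt(n_missing, 0)
})

test_that("fit_mlvar validates its inputs", {
  fx <- small_fit()
  g2 <- fx$gridded
  g2[[1]]$delta_min <- 90
  class(g2) <- "gridded_panel"
  expect_error(fit_mlvar(g2, mlvar_spec()), "equally spaced")

  g3 <- fx$gridded
  g3[[1]]$y <- g3[[1]]$y[1:1, , drop = FALSE]
  class(g3) <- "gridded_panel"
  expect_error(fit_mlvar(g3, mlvar_spec(min_obs = 10)), "fewer than")

  expect_error(mlvar_spec(chains = 1), "chains")
})

test_that("edge summaries cover all 49 ordered pairs per group", {
  fit <- small_fit()$fit
  edges <- edge_summaries(fit)
  expect_equal(nrow(edges), 49)
  expect_equal(nrow(unique(edges[, c("from", "to")])), 49)
  expect_true(all(edges$lo <= edges$mean & edges$mean <= edges$hi))
  expect_true(all(edges$significant == (edges$lo > 0 | edges$hi < 0)))
  dens <- attr(edges, "density")
  expect_true(dens >= 0 && dens <= 1)
})

test_that("psr diagnostic detects shifted chains and passes identical ones", {
  # hand-built draws object: two chains of well-mixed draws
  set.seed(55)
  n_per <- 400
  codes <- item_catalog()$code
  pn <- c(as.vector(outer(codes, codes, function(to, from)
    paste0("phi_", to, "_", from))), paste0("mu_", codes))
  g1 <- array(rnorm(n_per * 2 * 56), dim = c(n_per, 2, 56),
              dimnames = list(NULL, c("(ref:comorbid)", "depression_only"), pn))
  mk <- function(gamma2) {
    g_all <- array(NA_real_, dim = c(2 * n_per, 2, 56),
                   dimnames = dimnames(g1))
    g_all[seq_len(n_per), , ] <- g1
    g_all[n_per + seq_len(n_per), , ] <- gamma2
    structure(list(gamma = g_all,
                   chain = rep(1:2, each = n_per),
                   iteration = rep(seq_len(n_per), 2),
                   groups = c("comorbid", "depression_only"),
                   param_names = pn,
                   spec = mlvar_spec()), class = "mlvar_draws")
  }
  twin <- mk(g1)  # chain 2 identical to chain 1
  expect_lt(max(psr_diagnostic(twin)$psr), 1.05)

  shifted <- mk(g1 + 2)  # chain 2 displaced by a constant
  expect_warning(res2 <- psr_diagnostic(shifted), "PSR above")
  expect_false(attr(res2, "pass"))
  expect_gt(max(res2$psr), 1.5)

  solo <- twin
  keep <- solo$chain == 1
  solo$gamma <- solo$gamma[keep, , , drop = FALSE]
  solo$chain <- solo$chain[keep]
  expect_error(psr_diagnostic(solo), "two chains")
})

test_that("well-behaved fits converge by the split-chain criterion", {
  fit <- small_fit()$fit
  res <- psr_diagnostic(fit)
  expect_true(attr(res, "pass"))
})

test_that("credible intervals contract as persons and time grow", {
  width <- function(n, days, seed) {
    cfg <- single_group_config(n, days = days, seed = seed)
    fit <- fit_mlvar(gridded_from_config(cfg),
                     mlvar_spec(chains = 2, iterations = 500, seed = 13))
    edges <- edge_summaries(fit)
    mean(edges$hi - edges$lo)
  }
  w_small <- width(5, 3, seed = 41)
  w_large <- width(15, 9, seed = 42)
  expect_lt(w_large, w_small)
})

test_that("95% intervals for a cross-lagged entry attain nominal coverage", {
  base <- default_generator_config()
  phi <- base$group_specs[[1]]$phi_mean
  truth <- phi["WOR", "DOW"]
  n_sim <- 100
  covered <- 0L
  for (s in seq_len(n_sim)) {
    cfg <- single_group_config(8, days = 5, phi = phi, seed = 1000 + s)
    fit <- fit_mlvar(gridded_from_config(cfg),
                     mlvar_spec(chains = 2, iterations = 400, seed = s))
    draws <- group_phi_draws(fit, "comorbid")[, "WOR", "DOW"]
    ci <- quantile(draws, c(0.025, 0.975))
    covered <- covered + (ci[1] <= truth && truth <= ci[2])
  }
  expect_gte(covered / n_sim, 0.90)
  expect_lte(covered / n_sim, 1.00)
})
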