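# Shared fixtures and independent oracles for the test suite.

# Brute-force path counter: triple loop applying the cluster-membership
# rule directly, independent of enumerate_bridge_paths().
brute_force_path_count <- function(bridge, catalog) {
  mem <- function(code) {
    k <- match(code, catalog$code)
    c("DEP", "ANX")[c(catalog$dep[k], catalog$anx[k])]
  }
  count <- 0L
  for (i in catalog$code) {
    for (j in catalog$code) {
      if (i == j || i == bridge || j == bridge) next
      qualifies <- FALSE
      for (ci in mem(i)) {
        for (cj in mem(j)) {
          if (ci != cj) qualifies <- TRUE
        }
      }
      if (qualifies) count <- count + 1L
    }
  }
  count
}

# random item/cluster configuration (every item in at least one cluster)
random_catalog <- function(n_items) {
  repeat {
    dep <- sample(c(TRUE, FALSE), n_items, replace = TRUE)
    anx <- sample(c(TRUE, FALSE), n_items, replace = TRUE)
    none <- !dep & !anx
    dep[none] <- sample(c(TRUE, FALSE), sum(none), replace = TRUE)
    anx[none] <- !dep[none]
    if (all(dep | anx)) break
  }
  new_item_catalog(data.frame(
    code = sprintf("I%02d", seq_len(n_items)),
    label = sprintf("item %d", seq_len(n_items)),
    dep = dep, anx = anx,
    reverse_coded = rep(FALSE, n_items), stringsAsFactors = FALSE))
}

# Pooled person-centered least squares on a complete gridded panel:
# each person's series is centered at its observed mean, lag pairs are
# stacked across persons, and each equation is fitted by OLS.
pooled_ols <- function(gridded) {
  Ys <- lapply(gridded, function(p) scale(p$y, scale = FALSE))
  X <- do.call(rbind, lapply(Ys, function(y) y[-nrow(y), , drop = FALSE]))
  Z <- do.call(rbind, lapply(Ys, function(y) y[-1, , drop = FALSE]))
  xtx <- crossprod(X)
  phi <- t(solve(xtx, crossprod(X, Z)))      # phi[to, from]
  resid <- Z - X %*% t(phi)
  d <- ncol(X)
  sigma2 <- colSums(resid^2) / (nrow(X) - d)
  se <- sqrt(outer(sigma2, diag(solve(xtx))))  # se[to, from]
  dimnames(phi) <- dimnames(se) <- list(colnames(X), colnames(X))
  list(phi = phi, se = se, n = nrow(X))
}

# single-group generator on a gap-free lattice (8 prompts/day x 180 min
# leaves exactly one 180-min step overnight, so no latent night cells)
single_group_config <- function(n_persons, days, prompts_per_day = 8,
                                phi = NULL, re_sd_phi = 0, re_sd_mu = 0,
                                miss_prob = 0, seed = 1) {
  base <- default_generator_config()
  phi <- phi %||% base$group_specs[[1]]$phi_mean
  gs <- group_spec("comorbid", phi, base$group_specs[[1]]$mu_mean, n_persons)
  generator_config(list(gs), re_sd_phi = re_sd_phi, re_sd_mu = re_sd_mu,
                   innovation_cov = base$innovation_cov,
                   schedule = ema_schedule(days, prompts_per_day, 180, 0),
                   miss_prob = miss_prob, likert = FALSE, seed = seed)
}

gridded_from_config <- function(cfg) {
  align_to_grid(reverse_code(simulate_panel(cfg)), 180)
}

# a tiny deterministic draws array (draw, to, from) for bridge fixtures
fixed_phi_draws <- function(n_draw = 50, seed = 99) {
  set.seed(seed)
  codes <- item_catalog()$code
  arr <- array(stats::rnorm(n_draw * 49, 0.05, 0.05),
               dim = c(n_draw, 7, 7),
               dimnames = list(NULL, to = codes, from = codes))
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
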