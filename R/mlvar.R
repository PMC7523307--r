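#' Specification of the hierarchical Bayesian VAR(1) fit
#'
#' Within persons the model is the latent-mean-centered first-order vector
#' autoregression
#' \deqn{y_{it} - \mu_i = \Phi_i (y_{i,t-1} - \mu_i) + \varepsilon_{it},
#'       \quad \varepsilon_{it} \sim N(0, \Sigma),}
#' with all 49 lagged coefficients and all 7 means varying over persons.
#' At the between level every person parameter gets a Gaussian random
#' effect whose mean is a linear function of group dummies (reference
#' group first), so each group has its own average coefficient matrix.
#'
#' @param chains Number of independent MCMC chains (>= 2).
#' @param iterations Iterations per chain.
#' @param burn_in Fraction of each chain discarded.
#' @param thinning Keep every \code{thinning}-th post-burn-in draw.
#' @param prior_var_fixed Prior variance of the between-level regression
#'   coefficients (Normal(0, .)); a proper stand-in for flat priors.
#' @param tau_prior Inverse-Gamma (shape, rate) prior for the 56
#'   random-effect variances.
#' @param sigma_prior_df,sigma_prior_scale Inverse-Wishart prior for the
#'   innovation covariance.
#' @param psr_threshold Potential-scale-reduction warning threshold.
#' @param min_obs Minimum observed grid cells required per person.
#' @param reference_group Group absorbed into the intercept.
#' @param seed Integer seed; chain c uses \code{seed + c - 1}.
#' @return List of class \code{mlvar_spec}.
#' @export
mlvar_spec <- function(chains = 2L, iterations = 4000L, burn_in = 0.5,
                       thinning = 1L, prior_var_fixed = 100,
                       tau_prior = c(0.001, 0.001), sigma_prior_df = 9,
                       sigma_prior_scale = NULL, psr_threshold = 1.1,
                       min_obs = 10L, reference_group = "comorbid",
                       seed = 1L) {
  stopifnot(chains >= 2, iterations > 10, burn_in > 0, burn_in < 1,
            thinning >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations), burn_in = burn_in,
                 thinning = as.integer(thinning),
                 prior_var_fixed = prior_var_fixed, tau_prior = tau_prior,
                 sigma_prior_df = sigma_prior_df,
                 sigma_prior_scale = sigma_prior_scale,
                 psr_threshold = psr_threshold, min_obs = as.integer(min_obs),
                 reference_group = reference_group, seed = as.integer(seed)),
            class = "mlvar_spec")
}

#' Fit the hierarchical Bayesian VAR(1) by Gibbs sampling
#'
#' Runs \code{spec$chains} independent chains of a Gibbs sampler that
#' cycles over (1) forward-filter backward-sample imputation of missing
#' grid cells, (2) conjugate updates of each person's coefficient matrix
#' and latent mean, (3) the between-level group regression and
#' random-effect variances, and (4) the innovation covariance. Missing
#' cells are re-imputed at every iteration, so missingness propagates
#' into posterior uncertainty rather than being deleted.
#'
#' @param gridded A \code{gridded_panel} from [align_to_grid()].
#' @param spec An [mlvar_spec()].
#' @return Object of class \code{mlvar_draws} holding the retained
#'   between-level draws: \code{gamma} (draws x groups x 56 array),
#'   \code{sigma} (draws x 49), chain/iteration indices, group and
#'   parameter labels, and bookkeeping (number of imputed cells, which is
#'   constant over iterations).
#' @export
fit_mlvar <- function(gridded, spec = mlvar_spec()) {
  stopifnot(inherits(gridded, "gridded_panel"), inherits(spec, "mlvar_spec"))
  deltas <- vapply(gridded, function(p) p$delta_min, 1.0)
  if (length(unique(deltas)) != 1) {
    stop("fit_mlvar requires a single equally spaced lattice for all persons")
  }
  catalog <- attr(gridded, "catalog") %||% item_catalog()
  codes <- catalog$code
  d <- length(codes)

  n_obs <- vapply(gridded, function(p) sum(!is.na(p$y)), 1L)
  if (any(n_obs < spec$min_obs)) {
    bad <- vapply(gridded, function(p) p$person_id, "")[n_obs < spec$min_obs]
    stop(sprintf("persons with fewer than %d observed cells: %s",
                 spec$min_obs, paste(bad, collapse = ", ")))
  }

  groups_present <- unique(vapply(gridded, function(p) p$group, ""))
  ref <- spec$reference_group
  if (!ref %in% groups_present) ref <- groups_present[1]
  groups <- c(ref, setdiff(groups_present, ref))
  gidx <- match(vapply(gridded, function(p) p$group, ""), groups)
  X <- cbind(1, outer(gidx, seq_along(groups)[-1], `==`) + 0)
  colnames(X) <- c(paste0("(ref:", ref, ")"),
                   if (length(groups) > 1) groups[-1])

  Y_list <- lapply(gridded, function(p) unname(p$y))
  n_burn <- as.integer(floor(spec$iterations * spec$burn_in))
  s0 <- spec$sigma_prior_scale %||% diag(d)

  param_names <- c(as.vector(outer(codes, codes,
                                   function(to, from) paste0("phi_", to, "_", from))),
                   paste0("mu_", codes))
  p <- ncol(X); q <- d * d + d
  chains_out <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch - 1L)
    chains_out[[ch]] <- mlvar_gibbs_cpp(
      Y_list, X, spec$iterations, n_burn, spec$thinning,
      spec$prior_var_fixed, spec$tau_prior[1], spec$tau_prior[2],
      spec$sigma_prior_df, s0)
  }
  n_keep <- chains_out[[1]]$n_kept
  gamma <- do.call(rbind, lapply(chains_out, `[[`, "gamma"))
  sigma <- do.call(rbind, lapply(chains_out, `[[`, "sigma"))
  # gamma rows are vec(Gamma) with the p group coefficients fastest
  gamma <- array(gamma, dim = c(nrow(gamma), p, q),
                 dimnames = list(NULL, colnames(X), param_names))
  structure(list(gamma = gamma, sigma = sigma,
                 chain = rep(seq_len(spec$chains), each = n_keep),
                 iteration = rep(seq_len(n_keep), spec$chains),
                 groups = groups, reference_group = ref,
                 param_names = param_names, items = codes,
                 n_imputed_cells = chains_out[[1]]$n_missing,
                 n_persons = length(gridded), spec = spec),
            class = "mlvar_draws")
}

#' @export
print.mlvar_draws <- function(x, ...) {
  cat(sprintf("mlvar_draws: %d retained draws (%d chains), %d persons, groups: %s\n",
              dim(x$gamma)[1], max(x$chain), x$n_persons,
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  imputed cells per iteration: %d\n", x$n_imputed_cells))
  invisible(x)
}

#' Per-draw group-average coefficient matrices
#'
#' Applies the reference + offset composition: the reference group's
#' matrix is the between-level intercept; every other group adds its dummy
#' coefficient, entrywise, at every retained draw.
#'
#' @param draws An \code{mlvar_draws}.
#' @param group Group label.
#' @return Array \code{draws x 7 x 7} with dims (draw, to, from).
#' @export
group_phi_draws <- function(draws, group) {
  stopifnot(inherits(draws, "mlvar_draws"))
  gi <- match(group, draws$groups)
  if (is.na(gi)) {
    stop(sprintf("unknown group '%s' (have: %s)", group,
                 paste(draws$groups, collapse = ", ")))
  }
  d <- length(draws$items)
  phi_cols <- seq_len(d * d)
  m <- draws$gamma[, 1, phi_cols, drop = FALSE]
  dim(m) <- c(dim(draws$gamma)[1], d * d)
  if (gi > 1) {
    off <- draws$gamma[, gi, phi_cols, drop = FALSE]
    dim(off) <- dim(m)
    m <- m + off
  }
  array(m, dim = c(nrow(m), d, d),
        dimnames = list(NULL, to = draws$items, from = draws$items))
}

#' Summarize every lagged edge of every group network
#'
#' One row per group and ordered item pair (from -> to, self-loops
#' included): posterior mean, central 95\% credible interval, and a
#' significance flag (interval excludes zero), the criterion used to draw
#' or omit edges in group network figures.
#'
#' @param draws An \code{mlvar_draws}.
#' @param level Credible level.
#' @return Data frame of 49 rows per group, with per-group edge densities
#'   (significant edges / 49) in attribute \code{density}.
#' @export
edge_summaries <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "mlvar_draws"))
  out <- list()
  dens <- numeric(0)
  for (g in draws$groups) {
    phi <- group_phi_draws(draws, g)
    for (from in draws$items) {
      for (to in draws$items) {
        v <- phi[, to, from]
        ci <- quantile_ci(v, level)
        out[[length(out) + 1L]] <- data.frame(
          group = g, from = from, to = to, mean = mean(v),
          lo = ci[1], hi = ci[2],
          significant = ci[1] > 0 || ci[2] < 0, stringsAsFactors = FALSE)
      }
    }
    last <- (length(out) - 48):length(out)
    dens[g] <- sum(vapply(out[last], function(r) r$significant, TRUE)) /
      length(draws$items)^2
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "density") <- dens
  res
}

#' Split-chain potential scale reduction diagnostic
#'
#' Splits each chain in half and computes the potential scale reduction
#' factor (R-hat) for every stored between-level parameter. Failures are
#' reported with a warning listing the worst parameters; the pipeline
#' continues, mirroring common practice of inspecting rather than
#' aborting on borderline convergence.
#'
#' @param draws An \code{mlvar_draws} with at least two chains.
#' @param threshold Pass/fail threshold.
#' @return Data frame (parameter, group coefficient, psr, pass) with
#'   attribute \code{pass} (all parameters below threshold).
#' @export
psr_diagnostic <- function(draws, threshold = NULL) {
  stopifnot(inherits(draws, "mlvar_draws"))
  threshold <- threshold %||% draws$spec$psr_threshold
  n_chain <- max(draws$chain)
  if (n_chain < 2) stop("psr_diagnostic requires at least two chains")
  rows <- list()
  dims <- dim(draws$gamma)
  coef_names <- dimnames(draws$gamma)[[2]]
  for (gi in seq_len(dims[2])) {
    for (qi in seq_len(dims[3])) {
      v <- draws$gamma[, gi, qi]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = draws$param_names[qi], coefficient = coef_names[gi],
        psr = split_psr(v, draws$chain), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$pass <- res$psr < threshold
  if (!all(res$pass)) {
    worst <- res[order(-res$psr), ][seq_len(min(5, sum(!res$pass))), ]
    warning(sprintf("PSR above %g for %d parameters; worst: %s",
                    threshold, sum(!res$pass),
                    paste(sprintf("%s[%s]=%.3f", worst$parameter,
                                  worst$coefficient, worst$psr),
                          collapse = ", ")))
  }
  attr(res, "pass") <- all(res$pass)
  res
}

# split-chain R-hat of one parameter vector given its chain index
split_psr <- function(v, chain) {
  seqs <- list()
  for (ch in unique(chain)) {
    x <- v[chain == ch]
    h <- floor(length(x) / 2)
    seqs[[length(seqs) + 1L]] <- x[seq_len(h)]
    seqs[[length(seqs) + 1L]] <- x[(h + 1):(2 * h)]
  }
  m <- length(seqs)
  nn <- length(seqs[[1]])
  means <- vapply(seqs, mean, 1.0)
  vars <- vapply(seqs, stats::var, 1.0)
  w <- mean(vars)
  b <- nn * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Export group networks as an edge list
#'
#' @param edges Result of [edge_summaries()].
#' @param path Optional CSV path; when given the edge list is written
#'   there as well.
#' @param significant_only Keep only edges whose interval excludes zero.
#' @return Data frame (from, to, group, mean, lo, hi, significant).
#' @export
edge_list <- function(edges, path = NULL, significant_only = FALSE) {
  out <- edges[, c("from", "to", "group", "mean", "lo", "hi", "significant")]
  if (significant_only) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
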