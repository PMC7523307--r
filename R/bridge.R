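#' Enumerate the indirect-effect paths through a candidate bridge node
#'
#' A lag-2 indirect effect \code{i -> bridge -> j} qualifies when it starts
#' and ends at different non-bridge nodes and crosses between the
#' depression and anxiety clusters: there must exist a cluster-role
#' assignment with \code{i} acting for one cluster and \code{j} for the
#' other. Equivalently, a pair is excluded exactly when both endpoints are
#' single-cluster items of the same cluster. Each qualifying ordered
#' (from, to) pair enters once, even when (as for two overlapping
#' endpoints) it qualifies under both role assignments. For the 7-item
#' catalog this yields 22 paths for an overlapping bridge, 24 for a pure
#' anxiety bridge and 26 for a pure depression bridge.
#'
#' @param bridge Item code of the candidate bridge node.
#' @param catalog Item catalog.
#' @return List of class \code{bridge_path_set}: \code{bridge},
#'   \code{pairs} (data frame \code{from}, \code{to}), \code{count}.
#' @examples
#' enumerate_bridge_paths("WOR")$count  # 22
#' enumerate_bridge_paths("NER")$count  # 24
#' enumerate_bridge_paths("DOW")$count  # 26
#' @export
enumerate_bridge_paths <- function(bridge, catalog = item_catalog()) {
  if (!bridge %in% catalog$code) {
    stop(sprintf("unknown bridge code '%s'", bridge))
  }
  others <- setdiff(catalog$code, bridge)
  from <- character(0); to <- character(0)
  for (i in others) {
    mi <- item_membership(catalog, i)
    for (j in others) {
      if (i == j) next
      mj <- item_membership(catalog, j)
      # qualifies iff some cross-cluster role assignment exists
      cross <- any(outer(mi, mj, `!=`))
      if (cross) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  structure(list(bridge = bridge,
                 pairs = data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE),
                 count = length(from)),
            class = "bridge_path_set")
}

#' @export
print.bridge_path_set <- function(x, ...) {
  cat(sprintf("Bridge '%s': %d indirect-effect paths\n", x$bridge, x$count))
  invisible(x)
}

#' Per-draw bridge effect
#'
#' For every retained posterior draw of a group's coefficient matrix,
#' sums the products of the lagged coefficient into the bridge node and
#' the lagged coefficient out of it over all qualifying paths:
#' \deqn{B = \sum_{(i,j)} \phi_{bridge \leftarrow i} \,
#'       \phi_{j \leftarrow bridge}.}
#' Computing the sum at every draw (rather than plugging in posterior
#' means) yields the full posterior distribution of the statistic.
#'
#' @param phi_draws Array \code{draws x 7 x 7} (draw, to, from), e.g. from
#'   [group_phi_draws()].
#' @param path_set A [enumerate_bridge_paths()] result.
#' @return Numeric vector of per-draw bridge effects.
#' @export
bridge_effect_draws <- function(phi_draws, path_set) {
  stopifnot(inherits(path_set, "bridge_path_set"))
  items <- dimnames(phi_draws)[[2]]
  if (is.null(items) || !path_set$bridge %in% items ||
      !all(unlist(path_set$pairs) %in% items)) {
    stop("phi_draws dimnames do not cover the path set's items")
  }
  b <- path_set$bridge
  total <- numeric(dim(phi_draws)[1])
  for (k in seq_len(path_set$count)) {
    i <- path_set$pairs$from[k]
    j <- path_set$pairs$to[k]
    total <- total + phi_draws[, b, i] * phi_draws[, j, b]
  }
  total
}

#' Summarize a posterior draw vector of a bridge effect
#'
#' @param draws Per-draw values of the statistic.
#' @param count Number of contributing paths (divides the draws for the
#'   mean bridge effect, enabling comparison across bridges with unequal
#'   path counts).
#' @param bridge,group Optional labels carried into the result.
#' @param level Credible level.
#' @return List of class \code{bridge_summary}: \code{draws},
#'   \code{mean}, \code{ci} (central interval), \code{p_one_tailed}
#'   (smaller tail probability of 0), \code{significant} (interval
#'   excludes 0), and the same fields on the mean-bridge-effect scale
#'   (\code{mean_draws}, \code{mean_effect}, \code{mean_ci}).
#' @export
summarize_effect <- function(draws, count = 1L, bridge = NA_character_,
                             group = NA_character_, level = 0.95) {
  if (length(draws) == 0) stop("empty draw vector")
  ci <- quantile_ci(draws, level)
  p1 <- min(mean(draws <= 0), mean(draws >= 0))
  md <- draws / count
  mci <- quantile_ci(md, level)
  structure(list(bridge = bridge, group = group, count = as.integer(count),
                 draws = draws, mean = mean(draws), ci = ci,
                 p_one_tailed = p1,
                 significant = ci[1] > 0 || ci[2] < 0,
                 mean_draws = md, mean_effect = mean(md), mean_ci = mci),
            class = "bridge_summary")
}

#' @export
print.bridge_summary <- function(x, ...) {
  cat(sprintf(
    "bridge %s%s: %.4f [%.4f, %.4f], one-tailed p = %.3f%s (paths = %d)\n",
    x$bridge, if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
    x$mean, x$ci[1], x$ci[2], x$p_one_tailed,
    if (x$significant) " *" else "", x$count))
  invisible(x)
}

#' Posterior difference between two groups' bridge effects
#'
#' Subtracts drawwise on aligned (chain, iteration) indices — group
#' matrices derive from shared between-level draws, so alignment is
#' automatic — and summarizes the difference like any other effect. Both
#' the one-tailed posterior probability and its two-tailed double are
#' reported.
#'
#' @param summary_a,summary_b Two [summarize_effect()] results with equal
#'   draw counts (difference = a - b).
#' @param level Credible level.
#' @return List of class \code{bridge_difference}.
#' @export
compare_groups <- function(summary_a, summary_b, level = 0.95) {
  stopifnot(inherits(summary_a, "bridge_summary"),
            inherits(summary_b, "bridge_summary"))
  if (length(summary_a$draws) != length(summary_b$draws)) {
    stop("draw vectors are not aligned (unequal lengths)")
  }
  delta <- summary_a$draws - summary_b$draws
  ci <- quantile_ci(delta, level)
  p1 <- min(mean(delta <= 0), mean(delta >= 0))
  structure(list(bridge = summary_a$bridge,
                 group_a = summary_a$group, group_b = summary_b$group,
                 draws = delta, mean = mean(delta), ci = ci,
                 p_one_tailed = p1, p_two_tailed = min(1, 2 * p1),
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "bridge_difference")
}

#' @export
print.bridge_difference <- function(x, ...) {
  cat(sprintf("delta(%s) %s - %s: %.4f [%.4f, %.4f], p1 = %.3f%s\n",
              x$bridge, x$group_a, x$group_b, x$mean, x$ci[1], x$ci[2],
              x$p_one_tailed, if (x$significant) " *" else ""))
  invisible(x)
}

#' Rank candidate bridges within a group
#'
#' Orders the items of one group by posterior mean of the mean bridge
#' effect (descending), identifies the top node by point estimate, and
#' for every other node tests whether it differs from the best via the
#' drawwise difference (top - node) on the mean-bridge-effect scale: a
#' node is flagged when that difference's central credible interval
#' excludes zero. Ties in the top point estimate are broken by catalog
#' order with a warning.
#'
#' @param summaries List of [summarize_effect()] results, one per item,
#'   all from the same group.
#' @param level Credible level for the comparison-to-best intervals.
#' @return Data frame ordered by rank: bridge, count, mean_effect, CI,
#'   one-tailed p, \code{is_best}, \code{differs_from_best}.
#' @export
rank_bridges <- function(summaries, level = 0.95) {
  stopifnot(length(summaries) >= 2,
            all(vapply(summaries, inherits, TRUE, "bridge_summary")))
  means <- vapply(summaries, function(s) s$mean_effect, 1.0)
  top <- which(means == max(means))
  if (length(top) > 1) {
    warning("tie for the highest mean bridge effect; broken by catalog order")
    top <- top[1]
  }
  ord <- order(means, decreasing = TRUE)
  rows <- lapply(seq_along(summaries), function(k) {
    s <- summaries[[k]]
    if (k == top) {
      differs <- FALSE
    } else {
      dd <- summaries[[top]]$mean_draws - s$mean_draws
      ci <- quantile_ci(dd, level)
      differs <- ci[1] > 0 || ci[2] < 0
    }
    data.frame(bridge = s$bridge, group = s$group, count = s$count,
               mean_effect = s$mean_effect,
               lo = s$mean_ci[1], hi = s$mean_ci[2],
               p_one_tailed = min(mean(s$mean_draws <= 0),
                                  mean(s$mean_draws >= 0)),
               is_best = k == top, differs_from_best = differs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Bridge-effect analysis of a fitted model
#'
#' Convenience wrapper: for each candidate bridge and each group, builds
#' the path set, computes the per-draw bridge effect from that group's
#' coefficient draws and summarizes it.
#'
#' @param draws An \code{mlvar_draws}.
#' @param bridges Item codes to treat as candidate bridges (default: all).
#' @param catalog Item catalog.
#' @return Nested list \code{result[[bridge]][[group]]} of
#'   \code{bridge_summary} objects, with the path sets in attribute
#'   \code{path_sets}.
#' @export
bridge_effects <- function(draws, bridges = NULL, catalog = item_catalog()) {
  stopifnot(inherits(draws, "mlvar_draws"))
  bridges <- bridges %||% catalog$code
  path_sets <- lapply(bridges, enumerate_bridge_paths, catalog = catalog)
  names(path_sets) <- bridges
  phi <- lapply(draws$groups, function(g) group_phi_draws(draws, g))
  names(phi) <- draws$groups
  out <- lapply(bridges, function(b) {
    ps <- path_sets[[b]]
    res <- lapply(draws$groups, function(g) {
      summarize_effect(bridge_effect_draws(phi[[g]], ps), ps$count,
                       bridge = b, group = g)
    })
    names(res) <- draws$groups
    res
  })
  names(out) <- bridges
  attr(out, "path_sets") <- path_sets
  out
}

#' Tidy table of bridge-effect summaries
#'
#' @param effects Result of [bridge_effects()].
#' @return Data frame (bridge, group, statistic scale, mean, lo, hi, p,
#'   count, significant).
#' @export
bridge_effect_table <- function(effects) {
  rows <- list()
  for (b in names(effects)) {
    for (g in names(effects[[b]])) {
      s <- effects[[b]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        bridge = b, group = g, statistic = "bridge_effect",
        mean = s$mean, lo = s$ci[1], hi = s$ci[2], p = s$p_one_tailed,
        count = s$count, significant = s$significant,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bridge = b, group = g, statistic = "mean_bridge_effect",
        mean = s$mean_effect, lo = s$mean_ci[1], hi = s$mean_ci[2],
        p = min(mean(s$mean_draws <= 0), mean(s$mean_draws >= 0)),
        count = s$count,
        significant = s$mean_ci[1] > 0 || s$mean_ci[2] < 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
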