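#' KPSS level-stationarity statistic
#'
#' Kwiatkowski-Phillips-Schmidt-Shin test statistic for the null of level
#' stationarity: partial sums of demeaned values scaled by a Bartlett-kernel
#' long-run variance estimate,
#' \deqn{\hat\eta = n^{-2} \sum_t S_t^2 / \hat\sigma^2_l ,}
#' with \eqn{S_t} the cumulative demeaned series and
#' \eqn{\hat\sigma^2_l} the Newey-West estimator at lag truncation l. The
#' default truncation is the deterministic rule
#' \code{ceiling(12 * (n/100)^(1/4))}. An exactly constant series has zero
#' partial-sum variance and zero long-run variance; its statistic is
#' defined as 0 (stationary).
#'
#' @param x Numeric series (NAs removed).
#' @param lags Lag truncation; \code{NULL} for the default rule.
#' @return List with \code{statistic}, \code{lags}, \code{n}.
#' @export
kpss_stat <- function(x, lags = NULL) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 2) stop("kpss_stat needs at least 2 observations")
  if (is.null(lags)) lags <- as.integer(ceiling(12 * (n / 100)^0.25))
  lags <- min(as.integer(lags), n - 1L)
  e <- x - mean(x)
  if (all(e == 0)) {
    return(list(statistic = 0, lags = lags, n = n))
  }
  s <- cumsum(e)
  eta <- sum(s^2) / n^2
  s2 <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      s2 <- s2 + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  list(statistic = eta / s2, lags = lags, n = n)
}

# asymptotic critical values for the level-stationary KPSS null
kpss_critical <- function(alpha) {
  cv <- c("0.10" = 0.347, "0.05" = 0.463, "0.025" = 0.574, "0.01" = 0.739)
  key <- sprintf("%g", alpha)
  hit <- match(key, sprintf("%g", c(0.10, 0.05, 0.025, 0.01)))
  if (is.na(hit)) stop("alpha must be one of 0.10, 0.05, 0.025, 0.01")
  unname(cv[hit])
}

#' Per-person KPSS stationarity screening
#'
#' Runs the level KPSS test on every person x item series of a gridded
#' panel (missing cells dropped, so the test sees the observed
#' subsequence). A series is called stationary when its statistic stays
#' below the critical value at \code{alpha}; series shorter than
#' \code{min_obs} are marked untestable and excluded from the per-item
#' stationary fraction's denominator.
#'
#' @param gridded A \code{gridded_panel}.
#' @param alpha Test level (0.10, 0.05, 0.025 or 0.01).
#' @param min_obs Minimum observed points for a testable series.
#' @param lags Lag truncation passed to [kpss_stat()].
#' @return List of class \code{stationarity_report}: \code{per_series}
#'   (data frame person x item with statistic and decision) and
#'   \code{per_item} (fraction of testable persons judged stationary).
#' @export
kpss_screen <- function(gridded, alpha = 0.05, min_obs = 20, lags = NULL) {
  stopifnot(inherits(gridded, "gridded_panel"))
  cv <- kpss_critical(alpha)
  codes <- colnames(gridded[[1]]$y)
  rows <- list()
  for (p in gridded) {
    for (code in codes) {
      x <- p$y[, code]
      x <- x[!is.na(x)]
      if (length(x) < min_obs) {
        rows[[length(rows) + 1L]] <- data.frame(
          person_id = p$person_id, item = code, n = length(x),
          statistic = NA_real_, stationary = NA, testable = FALSE,
          stringsAsFactors = FALSE)
      } else {
        st <- kpss_stat(x, lags)
        rows[[length(rows) + 1L]] <- data.frame(
          person_id = p$person_id, item = code, n = st$n,
          statistic = st$statistic, stationary = st$statistic < cv,
          testable = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  per_series <- do.call(rbind, rows)
  per_item <- do.call(rbind, lapply(split(per_series, per_series$item),
                                    function(d) {
    t <- d[d$testable, , drop = FALSE]
    data.frame(item = d$item[1], n_testable = nrow(t),
               frac_stationary = if (nrow(t)) mean(t$stationary) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_item) <- NULL
  structure(list(per_series = per_series, per_item = per_item,
                 alpha = alpha, critical_value = cv),
            class = "stationarity_report")
}

#' @export
print.stationarity_report <- function(x, ...) {
  cat(sprintf("KPSS level-stationarity screen (alpha = %g, cv = %g)\n",
              x$alpha, x$critical_value))
  print(x$per_item, row.names = FALSE)
  invisible(x)
}
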