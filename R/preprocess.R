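#' Reverse-code positively worded items
#'
#' Items flagged \code{reverse_coded} in the catalog (not cheerful, not
#' relaxed) are recorded from positively worded prompts; on the 1-7 response
#' scale the analysis value is \code{8 - score}. The panel carries a state
#' flag so coding is applied exactly once; calling this on an already coded
#' panel is an error (use \code{force = TRUE} to flip back deliberately).
#'
#' @param panel An \code{ema_panel}.
#' @param catalog Item catalog.
#' @param force Apply even if the panel is already marked coded.
#' @param likert Declare the panel as 1-7 Likert data, enforcing the score
#'   range; defaults to the panel's own \code{likert} attribute. Continuous
#'   panels may legitimately fall outside [1, 7] and are flipped as-is.
#' @return The panel with flipped scores and \code{reverse_coded = TRUE}.
#' @export
reverse_code <- function(panel, catalog = attr(panel, "catalog"), force = FALSE,
                         likert = isTRUE(attr(panel, "likert"))) {
  catalog <- catalog %||% item_catalog()
  if (isTRUE(attr(panel, "reverse_coded")) && !force) {
    stop("panel is already reverse-coded; pass force = TRUE to flip again")
  }
  if (likert) {
    for (code in catalog$code) {
      x <- panel[[code]]
      ok <- is.na(x) | (x >= 1 & x <= 7)
      if (!all(ok)) {
        stop(sprintf("item %s has scores outside [1, 7]; cannot reverse-code",
                     code))
      }
    }
  }
  for (code in catalog$code[catalog$reverse_coded]) {
    panel[[code]] <- 8 - panel[[code]]
  }
  attr(panel, "reverse_coded") <- !isTRUE(attr(panel, "reverse_coded"))
  panel
}

#' Align unequally spaced records to an equally spaced lattice
#'
#' Places each person's answered records on a \code{delta_min}-minute
#' lattice anchored at that person's first answered prompt: record at time
#' t goes to slot \code{round((t - t0) / delta_min)} (ties rounded half
#' away from zero). Slots between the first and last assigned slot that
#' receive no record become explicit missing cells — this is how lagged
#' coefficients come to refer to a fixed ~\code{delta_min} interval even
#' though real prompts drift and nights go unobserved. When two records
#' fall into one slot the earlier record is kept and the later one logged.
#'
#' @param panel An \code{ema_panel} (reverse-coded or not; values are
#'   carried as-is).
#' @param delta_min Lattice spacing in minutes.
#' @return A \code{gridded_panel}: list with per-person elements
#'   \code{person_id}, \code{group}, \code{y} (T_i x 7 matrix, NA =
#'   missing), \code{delta_min}, \code{t0_min}, plus attributes
#'   \code{collisions} (data frame of dropped records) and \code{catalog}.
#' @export
align_to_grid <- function(panel, delta_min = 180) {
  stopifnot(delta_min > 0)
  catalog <- attr(panel, "catalog") %||% item_catalog()
  codes <- catalog$code
  df <- as.data.frame(panel)
  persons <- unique(df$person_id)
  out <- vector("list", length(persons))
  collisions <- list()
  for (i in seq_along(persons)) {
    p <- df[df$person_id == persons[i] & df$answered, , drop = FALSE]
    if (nrow(p) == 0) {
      stop(sprintf("person %s has no answered records", persons[i]))
    }
    if (is.unsorted(p$t_min, strictly = TRUE)) {
      stop(sprintf("person %s: t_min must be strictly increasing", persons[i]))
    }
    t0 <- p$t_min[1]
    slot <- floor((p$t_min - t0) / delta_min + 0.5)  # half away from zero (x >= 0)
    keep <- !duplicated(slot)                        # earlier record wins
    if (any(!keep)) {
      collisions[[length(collisions) + 1L]] <- data.frame(
        person_id = persons[i], t_min = p$t_min[!keep], slot = slot[!keep],
        stringsAsFactors = FALSE)
    }
    p <- p[keep, , drop = FALSE]
    slot <- slot[keep]
    y <- matrix(NA_real_, max(slot) + 1L, length(codes),
                dimnames = list(NULL, codes))
    y[slot + 1L, ] <- as.matrix(p[, codes])
    out[[i]] <- list(person_id = persons[i], group = p$group[1], y = y,
                     delta_min = delta_min, t0_min = t0)
  }
  structure(out,
            collisions = if (length(collisions)) do.call(rbind, collisions)
                         else data.frame(person_id = character(),
                                         t_min = numeric(), slot = numeric()),
            catalog = catalog,
            reverse_coded = isTRUE(attr(panel, "reverse_coded")),
            class = "gridded_panel")
}

#' @export
print.gridded_panel <- function(x, ...) {
  n_obs <- vapply(x, function(p) sum(rowSums(!is.na(p$y)) > 0), 1L)
  t_len <- vapply(x, function(p) nrow(p$y), 1L)
  cat(sprintf("Gridded panel: %d persons, delta = %g min\n",
              length(x), x[[1]]$delta_min))
  cat(sprintf("  slots per person: median %g (range %d-%d)\n",
              stats::median(t_len), min(t_len), max(t_len)))
  cat(sprintf("  observed slots: %d, collisions dropped: %d\n",
              sum(n_obs), nrow(attr(x, "collisions"))))
  invisible(x)
}

#' Per-group item descriptives
#'
#' For each group and item: the group mean of within-person endorsement
#' (proportion of a person's answered scores that are 2 or higher, as a
#' percentage), the mean and SD over persons of within-person means, and
#' the mean and SD over persons of within-person SDs. Person-level
#' aggregation first, then group summary, so each person counts equally
#' regardless of compliance. Persons with fewer than two answered records
#' contribute no within-person SD.
#'
#' @param panel A reverse-coded \code{ema_panel}.
#' @param catalog Item catalog.
#' @return Data frame with one row per group x item.
#' @export
descriptives <- function(panel, catalog = attr(panel, "catalog")) {
  catalog <- catalog %||% item_catalog()
  if (!isTRUE(attr(panel, "reverse_coded"))) {
    stop("descriptives expects a reverse-coded panel; run reverse_code() first")
  }
  df <- as.data.frame(panel)[as.data.frame(panel)$answered, , drop = FALSE]
  out <- list()
  for (g in unique(df$group)) {
    dg <- df[df$group == g, , drop = FALSE]
    if (nrow(dg) == 0) stop(sprintf("group '%s' has no answered records", g))
    for (code in catalog$code) {
      per <- split(dg[[code]], dg$person_id)
      per <- lapply(per, function(x) x[!is.na(x)])
      per <- per[vapply(per, length, 1L) > 0]
      endorsed <- vapply(per, function(x) 100 * mean(x >= 2), 1.0)
      pmeans <- vapply(per, mean, 1.0)
      psds <- vapply(per, function(x) if (length(x) >= 2) stats::sd(x)
                     else NA_real_, 1.0)
      out[[length(out) + 1L]] <- data.frame(
        group = g, item = code,
        percent_endorsed = mean(endorsed),
        person_mean = mean(pmeans), person_mean_sd = stats::sd(pmeans),
        within_sd = mean(psds, na.rm = TRUE),
        within_sd_sd = stats::sd(psds, na.rm = TRUE),
        n_persons = length(per), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pooled within-person collinearity check
#'
#' Person-mean-centers every item (answered records only), pools across
#' persons, and reports the Pearson correlation matrix of the centered
#' scores together with a flag when any off-diagonal |r| exceeds the
#' threshold. High collinearity among lagged predictors would make the
#' cross-lagged coefficients of the VAR uninterpretable.
#'
#' @param panel An \code{ema_panel} or \code{gridded_panel}.
#' @param threshold Flag threshold on |r|.
#' @return List with \code{correlation} (7x7), \code{max_abs_r},
#'   \code{flagged}, \code{threshold}.
#' @export
collinearity_check <- function(panel, threshold = 0.9) {
  catalog <- attr(panel, "catalog") %||% item_catalog()
  codes <- catalog$code
  if (inherits(panel, "gridded_panel")) {
    blocks <- lapply(panel, function(p) p$y)
    ids <- rep(vapply(panel, function(p) p$person_id, ""),
               vapply(blocks, nrow, 1L))
    m <- do.call(rbind, blocks)
  } else {
    df <- as.data.frame(panel)
    df <- df[df$answered, , drop = FALSE]
    m <- as.matrix(df[, codes])
    ids <- df$person_id
  }
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]; ids <- ids[keep]
  centered <- m - apply(m, 2, function(col) ave(col, ids))
  r <- stats::cor(centered)
  off <- abs(r); diag(off) <- 0
  list(correlation = r, max_abs_r = max(off),
       flagged = max(off) > threshold, threshold = threshold)
}
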