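#' Sampling-scheme description for an EMA study
#'
#' @param days Number of study days.
#' @param prompts_per_day Prompts issued per day.
#' @param interval_min Nominal within-day spacing between prompts, minutes.
#' @param jitter_sd_min SD of Gaussian jitter added to each prompt time
#'   (clipped at a third of the interval so prompts can never cross).
#' @return A list of class \code{ema_schedule}.
#' @export
ema_schedule <- function(days = 14, prompts_per_day = 5, interval_min = 180,
                         jitter_sd_min = 0) {
  stopifnot(days >= 1, prompts_per_day >= 1, interval_min > 0,
            jitter_sd_min >= 0)
  if (prompts_per_day > 1 && (prompts_per_day - 1) * interval_min >= 1440) {
    stop("schedule infeasible: within-day prompts span a full day or more")
  }
  structure(list(days = days, prompts_per_day = prompts_per_day,
                 interval_min = interval_min, jitter_sd_min = jitter_sd_min),
            class = "ema_schedule")
}

#' Build the prompt times of one person
#'
#' Lays out \code{days * prompts_per_day} prompt times in minutes since the
#' first scheduled prompt. Consecutive within-day prompts are
#' \code{interval_min} apart (plus jitter); the overnight gap between the
#' last prompt of a day and the first of the next is
#' \code{1440 - (prompts_per_day - 1) * interval_min} minutes (plus jitter),
#' i.e. the latent process runs through the night unobserved.
#'
#' @param schedule An [ema_schedule()].
#' @param seed Optional integer seed; \code{NULL} uses the current RNG state.
#' @return Numeric vector of strictly increasing, nonnegative prompt times.
#' @examples
#' length(build_schedule(ema_schedule(14, 5, 180)))  # 70
#' @export
build_schedule <- function(schedule, seed = NULL) {
  stopifnot(inherits(schedule, "ema_schedule"))
  if (!is.null(seed)) set.seed(seed)
  d <- schedule$days
  p <- schedule$prompts_per_day
  nominal <- as.vector(outer(seq_len(p) - 1L, seq_len(d) - 1L,
                             function(k, day) day * 1440 + k * schedule$interval_min))
  if (schedule$jitter_sd_min > 0) {
    lim <- schedule$interval_min / 3
    jit <- pmin(pmax(stats::rnorm(length(nominal), 0, schedule$jitter_sd_min),
                     -lim), lim)
    jit[1] <- max(jit[1], 0)   # first prompt defines t = 0, keep times nonnegative
    times <- nominal + jit
  } else {
    times <- nominal
  }
  stopifnot(all(diff(times) > 0), all(times >= 0))
  times
}

#' Group-level generating truth
#'
#' @param name Group label.
#' @param phi_mean 7x7 matrix of group-average lagged coefficients, entry
#'   \code{[to, from]}, per grid step.
#' @param mu_mean Length-7 vector of group-average person means on the
#'   analysis (reverse-coded) 1-7 scale.
#' @param n_persons Number of persons to simulate in the group.
#' @return List of class \code{group_spec}.
#' @export
group_spec <- function(name, phi_mean, mu_mean, n_persons) {
  phi_mean <- as.matrix(phi_mean)
  stopifnot(nrow(phi_mean) == ncol(phi_mean), length(mu_mean) == nrow(phi_mean),
            n_persons >= 1)
  if (spectral_radius(phi_mean) >= 1) {
    stop(sprintf("group '%s': phi_mean is non-stationary (spectral radius >= 1)",
                 name))
  }
  structure(list(name = name, phi_mean = phi_mean, mu_mean = as.numeric(mu_mean),
                 n_persons = as.integer(n_persons)),
            class = "group_spec")
}

#' Full configuration of the synthetic-panel generator
#'
#' @param group_specs List of [group_spec()] objects.
#' @param re_sd_phi SD of person-level deviations of each lagged coefficient.
#' @param re_sd_mu SD of person-level deviations of each item mean.
#' @param innovation_cov 7x7 positive-definite innovation covariance, shared
#'   across persons and groups.
#' @param schedule An [ema_schedule()].
#' @param miss_prob Probability that any one prompt goes unanswered.
#' @param likert If \code{TRUE}, emitted scores are rounded and clipped to
#'   1..7; the default emits the continuous values the analysis model assumes.
#' @param seed Integer master seed.
#' @param catalog Item catalog; defaults to [item_catalog()].
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(group_specs, re_sd_phi = 0.05, re_sd_mu = 0.8,
                             innovation_cov, schedule = ema_schedule(),
                             miss_prob = 0.08, likert = FALSE, seed = 1L,
                             catalog = item_catalog()) {
  stopifnot(length(group_specs) >= 1, re_sd_phi >= 0, re_sd_mu >= 0,
            miss_prob >= 0, miss_prob < 1)
  innovation_cov <- as.matrix(innovation_cov)
  ev <- eigen(innovation_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("innovation_cov must be positive definite")
  structure(list(group_specs = group_specs, re_sd_phi = re_sd_phi,
                 re_sd_mu = re_sd_mu, innovation_cov = innovation_cov,
                 schedule = schedule, miss_prob = miss_prob, likert = likert,
                 seed = as.integer(seed), catalog = catalog),
            class = "generator_config")
}

# Fig. 3-shaped group coefficient matrices: dense positive comorbid network,
# sparse depression-only network (nothing through IRR), intermediate
# anxiety-only network with the strongest worry autocorrelation. Values are
# illustrative, not estimates.
default_phi_matrices <- function(codes = item_catalog()$code) {
  mk <- function(diag_vals, edges) {
    m <- diag(diag_vals)
    dimnames(m) <- list(to = codes, from = codes)
    for (e in edges) m[e[[2]], e[[1]]] <- as.numeric(e[[3]])
    m
  }
  e <- function(from, to, b) list(from, to, b)
  comorbid <- mk(
    c(REL = 0.25, CHE = 0.24, IRR = 0.22, LIS = 0.26, DOW = 0.28,
      NER = 0.24, WOR = 0.30)[codes],
    list(# depression -> worry -> anxiety and back, plus intra-cluster spill
      e("DOW", "WOR", 0.10), e("LIS", "WOR", 0.06), e("CHE", "WOR", 0.07),
      e("WOR", "NER", 0.09), e("WOR", "REL", 0.07),
      e("NER", "WOR", 0.08), e("REL", "WOR", 0.06),
      e("WOR", "DOW", 0.08), e("WOR", "CHE", 0.05),
      e("DOW", "CHE", 0.08), e("CHE", "DOW", 0.07), e("DOW", "LIS", 0.06),
      e("LIS", "DOW", 0.06), e("NER", "REL", 0.08), e("REL", "NER", 0.07),
      e("IRR", "NER", 0.05), e("DOW", "IRR", 0.05), e("CHE", "REL", 0.06),
      e("NER", "DOW", 0.05)))
  depression_only <- mk(
    c(REL = 0.22, CHE = 0.22, IRR = 0.18, LIS = 0.24, DOW = 0.26,
      NER = 0.20, WOR = 0.28)[codes],
    list(# one-directional depression -> worry -> anxiety chain only
      e("DOW", "WOR", 0.09), e("CHE", "WOR", 0.06), e("WOR", "NER", 0.07),
      e("DOW", "CHE", 0.07), e("LIS", "DOW", 0.06), e("NER", "REL", 0.06),
      e("CHE", "DOW", 0.06)))
  anxiety_only <- mk(
    c(REL = 0.24, CHE = 0.22, IRR = 0.20, LIS = 0.22, DOW = 0.30,
      NER = 0.26, WOR = 0.36)[codes],
    list(
      e("CHE", "REL", 0.13), e("NER", "REL", 0.08), e("REL", "NER", 0.07),
      e("WOR", "NER", 0.07), e("NER", "WOR", 0.06), e("DOW", "WOR", 0.07),
      e("WOR", "DOW", 0.08), e("CHE", "DOW", 0.08), e("DOW", "CHE", 0.07),
      e("LIS", "DOW", 0.05), e("DOW", "NER", 0.06), e("CHE", "WOR", 0.05),
      e("REL", "WOR", 0.05)))
  list(comorbid = comorbid, depression_only = depression_only,
       anxiety_only = anxiety_only)
}

#' Default generator configuration
#'
#' Ships the study conditions the package emulates: three diagnostic groups
#' (comorbid n = 143, depression-only n = 40, anxiety-only n = 37), 5
#' prompts/day at 180-minute intervals for 14 days (70 prompts max), mild
#' prompt-time jitter, ~8\% missed prompts, group person-mean targets and
#' innovation scales matching published descriptives, and lag-coefficient
#' matrices qualitatively shaped like the published group networks. The
#' dynamics are illustrative ground truth for testing, not estimates.
#'
#' @param seed Master seed.
#' @param n_persons Optional named vector overriding group sizes.
#' @return A [generator_config()].
#' @export
default_generator_config <- function(seed = 1L, n_persons = NULL) {
  catalog <- item_catalog()
  codes <- catalog$code
  phis <- default_phi_matrices(codes)
  mus <- list(
    comorbid = c(REL = 3.52, CHE = 3.66, IRR = 2.09, LIS = 2.48,
                 DOW = 2.43, NER = 2.22, WOR = 3.02),
    depression_only = c(REL = 2.84, CHE = 3.03, IRR = 1.48, LIS = 1.75,
                        DOW = 1.50, NER = 1.37, WOR = 1.76),
    anxiety_only = c(REL = 3.09, CHE = 3.01, IRR = 1.70, LIS = 1.72,
                     DOW = 1.47, NER = 1.77, WOR = 2.19))
  sizes <- c(comorbid = 143L, depression_only = 40L, anxiety_only = 37L)
  if (!is.null(n_persons)) sizes[names(n_persons)] <- n_persons
  groups <- lapply(names(sizes), function(g) {
    group_spec(g, phis[[g]], mus[[g]][codes], sizes[[g]])
  })
  # innovation scale chosen so stationary within-person SDs sit near the
  # published within-person SDs (~0.9-1.1); mild positive cross-correlation
  # because momentary negative states co-fluctuate
  sds <- c(REL = 1.10, CHE = 0.97, IRR = 1.07, LIS = 1.04, DOW = 0.94,
           NER = 0.96, WOR = 0.94)[codes] * 0.95
  r <- matrix(0.3, 7, 7); diag(r) <- 1
  sig <- diag(sds) %*% r %*% diag(sds)
  dimnames(sig) <- list(codes, codes)
  generator_config(groups, re_sd_phi = 0.05, re_sd_mu = 0.8,
                   innovation_cov = sig,
                   schedule = ema_schedule(14, 5, 180, jitter_sd_min = 10),
                   miss_prob = 0.08, likert = FALSE, seed = seed,
                   catalog = catalog)
}

#' Draw one person's parameters from the group distribution
#'
#' Every lagged coefficient and item mean receives an independent Gaussian
#' person deviation. Draws whose coefficient matrix is non-stationary
#' (spectral radius >= 1) are redrawn, up to \code{max_retries} times.
#'
#' @param group A [group_spec()].
#' @param re_sd_phi,re_sd_mu Person-deviation SDs.
#' @param seed Optional seed (\code{NULL}: current RNG state).
#' @param max_retries Redraw limit before failing.
#' @return List with \code{phi} (7x7), \code{mu} (7-vector) and
#'   \code{retries} (number of rejected draws).
#' @export
draw_person_params <- function(group, re_sd_phi, re_sd_mu, seed = NULL,
                               max_retries = 100L) {
  stopifnot(inherits(group, "group_spec"))
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(group$phi_mean)
  retries <- 0L
  repeat {
    phi <- group$phi_mean +
      matrix(stats::rnorm(d * d, 0, re_sd_phi), d, d)
    dimnames(phi) <- dimnames(group$phi_mean)
    if (spectral_radius(phi) < 1) break
    retries <- retries + 1L
    if (retries > max_retries) {
      stop(sprintf(
        "group '%s': could not draw a stationary coefficient matrix in %d retries",
        group$name, max_retries))
    }
  }
  mu <- group$mu_mean + stats::rnorm(d, 0, re_sd_mu)
  list(phi = phi, mu = mu, retries = retries)
}

#' Simulate one person's EMA records
#'
#' The latent continuous process evolves on the equally spaced
#' \code{interval_min} lattice as
#' \code{y_t = mu + Phi (y_{t-1} - mu) + eps_t}, \code{eps_t ~ MVN(0, Sigma)},
#' initialized from its stationary distribution, and keeps running through
#' lattice points with no prompt (nights, missed prompts). Each prompt is
#' read off at its nearest lattice point; each prompt is independently
#' unanswered with probability \code{miss_prob}.
#'
#' @param phi Stationary 7x7 coefficient matrix.
#' @param mu Person mean vector.
#' @param innovation_cov Innovation covariance.
#' @param prompt_times Strictly increasing prompt times in minutes.
#' @param interval_min Lattice spacing in minutes.
#' @param miss_prob Per-prompt nonresponse probability.
#' @param likert Round and clip emitted scores to 1..7.
#' @param seed Optional seed.
#' @return Data frame with \code{t_min}, \code{answered} and one column per
#'   item (NA when unanswered), on the analysis (reverse-coded) scale.
#' @export
simulate_person <- function(phi, mu, innovation_cov, prompt_times,
                            interval_min, miss_prob = 0, likert = FALSE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spectral_radius(phi) >= 1) {
    stop("simulate_person: non-stationary coefficient matrix")
  }
  d <- length(mu)
  n_steps <- floor(max(prompt_times) / interval_min + 0.5) + 1L
  p0 <- stationary_cov(phi, innovation_cov)
  ch <- chol((innovation_cov + t(innovation_cov)) / 2)
  y <- matrix(NA_real_, n_steps, d)
  y[1, ] <- rmvn1(mu, p0)
  if (n_steps > 1) {
    eps <- matrix(stats::rnorm((n_steps - 1) * d), n_steps - 1, d) %*% ch
    for (t in 2:n_steps) {
      y[t, ] <- mu + as.vector(phi %*% (y[t - 1, ] - mu)) + eps[t - 1, ]
    }
  }
  slot <- floor(prompt_times / interval_min + 0.5) + 1L
  answered <- stats::runif(length(prompt_times)) >= miss_prob
  scores <- y[slot, , drop = FALSE]
  if (likert) scores <- pmin(pmax(round(scores), 1), 7)
  scores[!answered, ] <- NA_real_
  out <- data.frame(t_min = prompt_times, answered = answered)
  colnames(scores) <- colnames(phi) %||% paste0("V", seq_len(d))
  cbind(out, as.data.frame(scores))
}

#' Simulate a full multi-group EMA panel
#'
#' Concatenates per-person simulations across all configured groups and
#' attaches person metadata: a synthetic severity score (a monotone
#' function of the person's mean across items, plus noise — used only to
#' exercise subgroup filters) and a diagnosis-recency class drawn with
#' group-specific frequencies. Items flagged reverse-coded in the catalog
#' are emitted on the raw response scale (\code{8 - value}), as a
#' questionnaire platform would record them.
#'
#' @param config A [generator_config()].
#' @return An \code{ema_panel}: long data frame (\code{person_id},
#'   \code{group}, \code{t_min}, \code{answered}, one column per item) with
#'   attributes \code{metadata} (person-level data frame), \code{catalog},
#'   \code{config_summary} and \code{reverse_coded = FALSE}.
#' @examples
#' cfg <- default_generator_config(seed = 42)
#' \donttest{panel <- simulate_panel(cfg)}
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  codes <- config$catalog$code
  rev_codes <- codes[config$catalog$reverse_coded]
  recency_levels <- c("<2w", "2w-1m", "1-6m", "6-12m", ">1y")
  recency_counts <- list(comorbid = c(54, 11, 10, 7, 61),
                         depression_only = c(1, 0, 6, 2, 31),
                         anxiety_only = c(8, 1, 3, 1, 24))
  rows <- list(); meta <- list(); pid <- 0L
  for (g in config$group_specs) {
    for (k in seq_len(g$n_persons)) {
      pid <- pid + 1L
      person_id <- sprintf("P%03d", pid)
      pars <- tryCatch(
        draw_person_params(g, config$re_sd_phi, config$re_sd_mu),
        error = function(e) stop(sprintf("person %s (group %s): %s",
                                         person_id, g$name, conditionMessage(e))))
      times <- build_schedule(config$schedule)
      rec <- simulate_person(pars$phi, pars$mu, config$innovation_cov, times,
                             config$schedule$interval_min, config$miss_prob,
                             config$likert)
      for (rc in rev_codes) rec[[rc]] <- 8 - rec[[rc]]
      rows[[pid]] <- cbind(data.frame(person_id = person_id, group = g$name,
                                      stringsAsFactors = FALSE), rec)
      sev <- max(0, 8 * (mean(pars$mu) - 1) + stats::rnorm(1, 0, 2))
      pr <- recency_counts[[g$name]] %||% rep(1, 5)
      meta[[pid]] <- data.frame(
        person_id = person_id, group = g$name, severity = sev,
        recency_class = sample(recency_levels, 1, prob = pr / sum(pr)),
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  panel <- panel[, c("person_id", "group", "t_min", "answered", codes)]
  rownames(panel) <- NULL
  structure(panel,
            metadata = do.call(rbind, meta),
            catalog = config$catalog,
            reverse_coded = FALSE,
            likert = config$likert,
            config_summary = list(
              seed = config$seed, miss_prob = config$miss_prob,
              likert = config$likert,
              schedule = unclass(config$schedule),
              groups = vapply(config$group_specs, function(g) g$n_persons, 1L),
              re_sd_phi = config$re_sd_phi, re_sd_mu = config$re_sd_mu),
            class = c("ema_panel", "data.frame"))
}

#' Write / read an EMA panel as long-format CSV
#'
#' The CSV has header \code{person_id, group, t_min, answered, REL, CHE,
#' IRR, LIS, DOW, NER, WOR}; unanswered rows have empty score cells. A JSON
#' sidecar (\code{<path>.json}) records the generating configuration and
#' person metadata so a written panel round-trips.
#'
#' @param panel An \code{ema_panel}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ema_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  side <- list(config = attr(panel, "config_summary"),
               reverse_coded = isTRUE(attr(panel, "reverse_coded")),
               likert = isTRUE(attr(panel, "likert")),
               metadata = attr(panel, "metadata"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ema_csv
#' @param catalog Item catalog for the columns expected in the file.
#' @export
read_ema_csv <- function(path, catalog = item_catalog()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "group", "t_min", "answered", catalog$code)
  if (!all(need %in% names(df))) {
    stop("panel CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$answered <- as.logical(df$answered)
  meta <- NULL; revd <- FALSE; lik <- FALSE
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$metadata) && length(side$metadata)) {
      meta <- as.data.frame(side$metadata, stringsAsFactors = FALSE)
    }
    revd <- isTRUE(side$reverse_coded)
    lik <- isTRUE(side$likert)
  }
  structure(df[, need], metadata = meta, catalog = catalog,
            reverse_coded = revd, likert = lik,
            class = c("ema_panel", "data.frame"))
}
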