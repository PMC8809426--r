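#' Simulation scenario for the full pipeline
#'
#' Bundles every parameter of the synthetic world. The defaults mirror the
#' scale of a two-year puma camera-trap survey: 61 sites totalling 13,375
#' camera-days, roughly half the sites carrying an attention-caller device
#' (ACD), ~200 detection events, and a 16-event / 5-rater pairwise
#' photo-ID rating exercise in which 10 of 16 events are monochrome, 8
#' occur at night, 6 show pinnae damage, and face resolutions are
#' log-normal around a median of ~39,216 pixels.
#'
#' @param n_sites,total_days camera-site count and total site-days of
#'   effort (days are split as evenly as possible across sites).
#' @param acd_fraction,scrape_fraction fraction of sites with an ACD /
#'   at a community scrape.
#' @param start_date,tz study start and timezone.
#' @param lure_refresh_days scent-lure refresh interval.
#' @param beta named fixed-effect truth on the scaled-covariate scale
#'   (names: `(Intercept)`, `has_acd`, `is_scrape`, `days_since_deploy`,
#'   `days_since_lure`, `has_acd:days_since_deploy`).
#' @param sigma named random-intercept SDs for `site`, `season`, `year`.
#' @param n_events,n_individuals size of the identity-rating exercise.
#' @param monochrome_fraction,night_given_monochrome,night_given_color,
#'   pinnae_fraction attribute distribution of the rated events.
#' @param resolution_meanlog,resolution_sdlog log-normal face-resolution
#'   distribution (pixel area of the face bounding box).
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_sites = 61, total_days = 13375,
                         acd_fraction = 0.5, scrape_fraction = 0.5,
                         start_date = "2017-07-01", tz = "US/Mountain",
                         lure_refresh_days = 30,
                         beta = c("(Intercept)" = -4.2, has_acd = -0.2,
                                  is_scrape = 0.6, days_since_deploy = -0.1,
                                  days_since_lure = 0,
                                  "has_acd:days_since_deploy" = -0.4),
                         sigma = c(site = 0.5, season = 0.2, year = 0.2),
                         n_events = 16, n_individuals = 7,
                         monochrome_fraction = 10 / 16,
                         night_given_monochrome = 0.8,
                         night_given_color = 0.05,
                         pinnae_fraction = 6 / 16,
                         resolution_meanlog = log(39216),
                         resolution_sdlog = 0.55) {
  sc <- as.list(environment())
  stopifnot(n_sites >= 1, total_days >= n_sites,
            acd_fraction >= 0, acd_fraction <= 1,
            scrape_fraction >= 0, scrape_fraction <= 1,
            n_events >= n_individuals, n_individuals >= 1,
            monochrome_fraction >= 0, monochrome_fraction <= 1,
            pinnae_fraction >= 0, pinnae_fraction <= 1,
            all(sigma >= 0), resolution_sdlog > 0)
  class(sc) <- "sim_scenario"
  sc
}

#' Simulate a site-day detection history with known truth
#'
#' Site-day counts are Poisson with
#' log-mean = beta.x + site + season + year random intercepts, where the
#' day covariates enter z-scaled (the same standardization the fitting
#' routine applies). Deployment dates are staggered over the first 18
#' months so that seasons and years vary across sites; scent lure is
#' refreshed every `lure_refresh_days`.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed; the output is fully reproducible.
#' @return list with `data` (detection-history data.frame with raw
#'   covariates) and `truth` (beta, sigma, the drawn intercepts, and the
#'   day-covariate SDs needed to interpret scaled slopes).
#' @export
simulate_detection_history <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  ns <- scenario$n_sites
  base <- scenario$total_days %/% ns
  extra <- scenario$total_days - base * ns
  days <- rep(base, ns) + rep(c(1L, 0L), c(extra, ns - extra))
  site_ids <- sprintf("S%02d", seq_len(ns))
  has_acd <- sample(rep(c(TRUE, FALSE), length.out = ns))
  is_scrape <- sample(rep(c(TRUE, FALSE),
                          c(round(ns * scenario$scrape_fraction),
                            ns - round(ns * scenario$scrape_fraction))))
  start <- as.Date(scenario$start_date)
  deploy <- start + sample(0:540, ns, replace = TRUE)

  site <- rep(seq_len(ns), times = days)
  dsd <- unlist(lapply(days, function(k) seq_len(k) - 1L))
  date <- deploy[site] + dsd
  dsl <- dsd %% scenario$lure_refresh_days
  season <- meteorological_season(date)
  year <- format(date, "%Y")

  dsd_s <- (dsd - mean(dsd)) / stats::sd(dsd)
  dsl_s <- (dsl - mean(dsl)) / stats::sd(dsl)
  acd <- has_acd[site]; scr <- is_scrape[site]
  b <- scenario$beta
  u_site <- stats::rnorm(ns, 0, scenario$sigma["site"])
  season_lev <- sort(unique(season)); year_lev <- sort(unique(year))
  u_season <- stats::setNames(stats::rnorm(length(season_lev), 0,
                                           scenario$sigma["season"]), season_lev)
  u_year <- stats::setNames(stats::rnorm(length(year_lev), 0,
                                         scenario$sigma["year"]), year_lev)
  eta <- b[["(Intercept)"]] + b[["has_acd"]] * acd + b[["is_scrape"]] * scr +
    b[["days_since_deploy"]] * dsd_s + b[["days_since_lure"]] * dsl_s +
    b[["has_acd:days_since_deploy"]] * acd * dsd_s +
    u_site[site] + u_season[season] + u_year[year]
  count <- stats::rpois(length(eta), exp(eta))

  data <- data.frame(site_id = site_ids[site], date = date, count = count,
                     days_since_deploy = dsd, days_since_lure = dsl,
                     has_acd = acd, is_scrape = scr,
                     season = season, year = year,
                     stringsAsFactors = FALSE)
  truth <- list(beta = b, sigma = scenario$sigma,
                u_site = stats::setNames(u_site, site_ids),
                u_season = u_season, u_year = u_year,
                sd_days_since_deploy = stats::sd(dsd),
                sd_days_since_lure = stats::sd(dsl))
  list(data = data, truth = truth)
}

meteorological_season <- function(date) {
  m <- as.integer(format(date, "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

#' Simulate rated events with latent individual identities
#'
#' Assigns each of `n_events` events to one of `n_individuals` latent
#' pumas (every individual appears at least once; remaining events are
#' allocated with a mild skew so some individuals recur more than others)
#' and draws the binary attributes the subset-agreement analysis uses.
#' Pinnae damage is an individual-level trait inherited by all of that
#' individual's events; monochrome imagery implies the IR flash fired, and
#' night-time is strongly associated with monochrome imagery.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return events data.frame with `event_id`, `individual`, `monochrome`,
#'   `flash_fired`, `is_night`, `pinnae_damage`, `face_resolution_px`,
#'   `resolution_class` (median split, computed on this event set).
#' @export
simulate_identities <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  n <- scenario$n_events; k <- scenario$n_individuals
  if (n < k) stop_input("simulate_identities: more individuals than events")
  ind <- c(seq_len(k),
           sample(seq_len(k), n - k, replace = TRUE,
                  prob = 0.7^seq_len(k)))
  ind <- sample(ind)  # shuffle which event slots hold which individual
  mono <- stats::runif(n) < scenario$monochrome_fraction
  night <- stats::runif(n) < ifelse(mono, scenario$night_given_monochrome,
                                    scenario$night_given_color)
  pin_ind <- stats::runif(k) < scenario$pinnae_fraction
  px <- round(stats::rlnorm(n, scenario$resolution_meanlog,
                            scenario$resolution_sdlog))
  ev <- data.frame(
    event_id = sprintf("E%02d", seq_len(n)),
    individual = sprintf("I%02d", ind),
    monochrome = mono, flash_fired = mono, is_night = night,
    pinnae_damage = pin_ind[ind],
    face_resolution_px = px, resolution_class = "unset",
    stringsAsFactors = FALSE)
  assign_resolution_class(ev)
}

#' A rater's confusion model for pairwise verdicts
#'
#' @param rater_id identifier.
#' @param p_false_split probability a truly-same pairing is rated
#'   "different".
#' @param p_false_merge probability a truly-different pairing is rated
#'   "same".
#' @param pinnae_mixed_merge_factor multiplier on `p_false_merge` for
#'   pairings where exactly one event shows pinnae damage; the default 0
#'   encodes that such pairs are unmistakably different animals.
#' @param low_res_both_factor multiplier on both error probabilities when
#'   both events are in the low-resolution class.
#' @return list of class `rater_model`.
#' @export
rater_model <- function(rater_id, p_false_split = 0.22, p_false_merge = 0.035,
                        pinnae_mixed_merge_factor = 0,
                        low_res_both_factor = 1.5) {
  stopifnot(p_false_split >= 0, p_false_split <= 1,
            p_false_merge >= 0, p_false_merge <= 1,
            pinnae_mixed_merge_factor >= 0, low_res_both_factor >= 0)
  structure(as.list(environment()), class = "rater_model")
}

#' A panel of identical raters
#'
#' @param n_raters panel size.
#' @param ... passed to [rater_model()].
#' @export
rater_panel <- function(n_raters = 5, ...) {
  lapply(seq_len(n_raters), function(i) rater_model(sprintf("R%d", i), ...))
}

#' Simulate multi-rater pairwise verdicts from latent identities
#'
#' For every unordered event pairing and rater, the true verdict ("same"
#' iff the two events share a latent individual) is flipped with the
#' rater's applicable error probability after attribute modifiers:
#' mixed-pinnae pairings scale the false-merge rate (0 by default), and
#' both-low-resolution pairings inflate both error rates. Errors are
#' independent across raters and pairings given the truth.
#'
#' @param events events data.frame from [simulate_identities()] (needs
#'   `event_id`, `individual`, `pinnae_damage`, `resolution_class`).
#' @param raters list of [rater_model()]s.
#' @param seed integer seed.
#' @return list with `ratings` (a `pair_rating_set`), `truth` (logical
#'   vector: truly same, aligned with the canonical pair order) and
#'   `n_true_individuals`.
#' @export
simulate_ratings <- function(events, raters, seed = 1) {
  if (!length(raters)) stop_input("simulate_ratings: need at least one rater")
  set.seed(seed)
  pairs <- enumerate_pairs(events$event_id)
  ia <- match(pairs$event_a, events$event_id)
  ib <- match(pairs$event_b, events$event_id)
  true_same <- events$individual[ia] == events$individual[ib]
  pin_mixed <- xor(events$pinnae_damage[ia], events$pinnae_damage[ib])
  low_both <- events$resolution_class[ia] == "low" &
              events$resolution_class[ib] == "low"
  long <- do.call(rbind, lapply(raters, function(rm) {
    p_split <- rep(rm$p_false_split, nrow(pairs))
    p_merge <- rep(rm$p_false_merge, nrow(pairs))
    p_merge[pin_mixed] <- p_merge[pin_mixed] * rm$pinnae_mixed_merge_factor
    p_split[low_both] <- p_split[low_both] * rm$low_res_both_factor
    p_merge[low_both] <- p_merge[low_both] * rm$low_res_both_factor
    p_err <- pmin(1, ifelse(true_same, p_split, p_merge))
    flip <- stats::runif(nrow(pairs)) < p_err
    verdict <- ifelse(xor(true_same, flip), "same", "different")
    data.frame(event_a = pairs$event_a, event_b = pairs$event_b,
               rater = rm$rater_id, verdict = verdict,
               stringsAsFactors = FALSE)
  }))
  list(ratings = pair_rating_set(long),
       truth = true_same,
       n_true_individuals = length(unique(events$individual)))
}

#' Long-run Fleiss' kappa of the independent-error confusion model
#'
#' Closed form for the kappa that the pairing-level rating table converges
#' to as the number of pairings grows, when a fraction `p_true_same` of
#' pairings are truly "same" and every rater independently reports the
#' truth up to the two error probabilities: with
#' q_s = 1 - p_false_split, q_d = p_false_merge,
#' P-bar = E\[q^2 + (1-q)^2\] over the truth distribution and
#' Pe = m^2 + (1-m)^2 at the marginal m, kappa = (P-bar - Pe)/(1 - Pe).
#'
#' @param p_true_same fraction of truly-same pairings.
#' @param p_false_split,p_false_merge rater error probabilities.
#' @return the long-run kappa.
#' @export
longrun_fleiss_kappa <- function(p_true_same, p_false_split, p_false_merge) {
  q_s <- 1 - p_false_split
  q_d <- p_false_merge
  m <- p_true_same * q_s + (1 - p_true_same) * q_d
  P_e <- m^2 + (1 - m)^2
  P_bar <- p_true_same * (q_s^2 + (1 - q_s)^2) +
    (1 - p_true_same) * (q_d^2 + (1 - q_d)^2)
  (P_bar - P_e) / (1 - P_e)
}

#' Calibrate rater error rates to a target long-run kappa
#'
#' Scales a base (split, merge) error pair by a common factor so that
#' [longrun_fleiss_kappa()] hits `target_kappa`. Used to build fixed-kappa
#' generators for confidence-interval calibration studies.
#'
#' @param target_kappa desired long-run kappa in (0, 1).
#' @param p_true_same fraction of truly-same pairings.
#' @param base_split,base_merge error pair at scale 1.
#' @return named vector `c(p_false_split, p_false_merge)`.
#' @export
calibrate_rater_errors <- function(target_kappa, p_true_same,
                                   base_split = 0.25, base_merge = 0.04) {
  stopifnot(target_kappa > 0, target_kappa < 1)
  f <- function(s) {
    longrun_fleiss_kappa(p_true_same, min(1, s * base_split),
                         min(1, s * base_merge)) - target_kappa
  }
  s <- stats::uniroot(f, c(1e-6, 1 / max(base_split, base_merge)),
                      tol = 1e-10)$root
  c(p_false_split = s * base_split, p_false_merge = s * base_merge)
}

#' Simulate an event schedule respecting the independence gap
#'
#' Places `n_events` detection events on `n_sites` sites with within-site
#' spacing strictly greater than the independence gap, so regrouping the
#' derived photo stream must reproduce the schedule exactly.
#'
#' @param n_events,n_sites schedule size.
#' @param start_date,tz study start.
#' @param gap_minutes independence gap the schedule must exceed.
#' @param mean_sep_hours mean within-site separation beyond the gap
#'   (exponential).
#' @param seed integer seed.
#' @return data.frame with `event_id`, `site_id`, `start_time`.
#' @export
simulate_event_schedule <- function(n_events = 208, n_sites = 61,
                                    start_date = "2017-07-01",
                                    tz = "US/Mountain", gap_minutes = 30,
                                    mean_sep_hours = 36, seed = 1) {
  set.seed(seed)
  site <- sort(sample(seq_len(n_sites), n_events, replace = TRUE))
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = tz)
  start_time <- rep(t0, n_events)
  for (s in unique(site)) {
    idx <- which(site == s)
    seps <- (gap_minutes + 1) * 60 + stats::rexp(length(idx), 1 / (mean_sep_hours * 3600))
    start_time[idx] <- t0 + stats::runif(1, 0, 86400) + cumsum(seps)
  }
  out <- data.frame(event_id = sprintf("E%03d", seq_len(n_events)),
                    site_id = sprintf("S%02d", site),
                    start_time = start_time, stringsAsFactors = FALSE)
  out[order(out$start_time), ]
}

#' Expand events into a timestamped photo stream
#'
#' Emits `photos_per_event` photos per event, spaced by uniform gaps of at
#' most `intra_gap_minutes`, and checks that the schedule keeps distinct
#' events at one site separated by more than `independence_gap_minutes`
#' photo-to-photo, so that [group_events()] reproduces the input exactly
#' (round trip).
#'
#' @param events data.frame with `event_id`, `site_id`, `start_time`
#'   (POSIXct) and optionally `face_captured`, `face_resolution_px`,
#'   `monochrome`, `flash_fired`, `behavior`, `pinnae_damage`.
#' @param photos_per_event photos per event (scalar or per-event vector).
#' @param intra_gap_minutes maximum gap between photos within an event;
#'   must be below the independence gap.
#' @param independence_gap_minutes the gap used when regrouping.
#' @param seed integer seed.
#' @return photo-record data.frame suitable for [group_events()].
#' @export
simulate_photo_stream <- function(events, photos_per_event = 5,
                                  intra_gap_minutes = 2,
                                  independence_gap_minutes = 30, seed = 1) {
  if (intra_gap_minutes >= independence_gap_minutes) {
    stop_input("simulate_photo_stream: intra-event gap must be below the independence gap")
  }
  set.seed(seed)
  n <- nrow(events)
  k <- rep_len(photos_per_event, n)
  ev <- events
  if (is.null(ev$face_captured)) ev$face_captured <- FALSE
  if (is.null(ev$face_resolution_px)) {
    ev$face_resolution_px <- ifelse(ev$face_captured, 30000, 0)
  }
  if (is.null(ev$monochrome)) ev$monochrome <- FALSE
  if (is.null(ev$flash_fired)) ev$flash_fired <- ev$monochrome
  if (is.null(ev$behavior)) ev$behavior <- "none"
  if (is.null(ev$pinnae_damage)) ev$pinnae_damage <- FALSE

  rows <- lapply(seq_len(n), function(i) {
    gaps <- stats::runif(k[i] - 1, 0.2, 1) * intra_gap_minutes * 60
    ts <- ev$start_time[i] + c(0, cumsum(gaps))
    face_photo <- if (ev$face_captured[i] || ev$face_resolution_px[i] > 0) {
      sample.int(k[i], 1)
    } else 0L
    data.frame(
      site_id = ev$site_id[i], timestamp = ts,
      is_color = !ev$monochrome[i], flash_fired = ev$flash_fired[i],
      face_visible = seq_len(k[i]) == face_photo,
      face_bbox_pixels = ifelse(seq_len(k[i]) == face_photo,
                                ev$face_resolution_px[i], 0),
      behavior_code = ev$behavior[i], pinnae_damage = ev$pinnae_damage[i],
      species = "Puma concolor", stringsAsFactors = FALSE)
  })
  photos <- do.call(rbind, rows)
  # verify the schedule respects independence photo-to-photo
  ord <- order(photos$site_id, photos$timestamp)
  p <- photos[ord, ]
  same_site <- c(FALSE, p$site_id[-1] == p$site_id[-nrow(p)])
  dt <- c(Inf, diff(as.numeric(p$timestamp)))
  ev_of <- rep(ev$event_id, times = k)[ord]
  new_ev <- c(TRUE, ev_of[-1] != ev_of[-length(ev_of)])
  viol <- same_site & new_ev & dt <= independence_gap_minutes * 60
  if (any(viol)) {
    stop_input("simulate_photo_stream: schedule violates the independence gap between events")
  }
  photos[order(photos$timestamp), ]
}
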