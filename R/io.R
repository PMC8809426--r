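#' @name facetrap-io
#' @title Delimited-text readers and writers
#' @description All interchange is comma-separated UTF-8 text with a header
#'   row and ISO-8601 dates, the shape of a typical ecology data deposit.
#'   Files written by the pipeline carry a leading `#` comment naming the
#'   producing stage and the configuration hash; readers skip such comments.
NULL

#' Write a stage output table
#'
#' @param x data.frame.
#' @param path output file.
#' @param stage producing stage name (recorded in the header comment).
#' @param config_hash configuration hash (see [config_hash()]).
#' @export
write_stage_table <- function(x, path, stage = "facetrap", config_hash = "") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# facetrap stage=%s config=%s", stage, config_hash), con)
  df <- x
  for (cl in names(df)) {
    if (inherits(df[[cl]], "POSIXct")) df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%S")
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

read_csv_strict <- function(path, required, optional = character(),
                            strict = TRUE, what = "table") {
  if (!file.exists(path)) stop_input(paste(what, "file not found:", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_input(sprintf("%s %s: missing column(s): %s", what, path,
                       paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(names(df), c(required, optional))
  if (strict && length(unknown)) {
    stop_input(sprintf("%s %s: unknown column(s) in strict mode: %s", what, path,
                       paste(unknown, collapse = ", ")))
  }
  if (nrow(df) == 0) warning(sprintf("%s %s is empty", what, path), call. = FALSE)
  df
}

as_logical_col <- function(x, col, what) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("true", "t", "1", "yes"), TRUE,
                ifelse(v %in% c("false", "f", "0", "no"), FALSE, NA))
  if (anyNA(out) & !anyNA(x)) {
    stop_input(sprintf("%s: column %s is not interpretable as logical (row %d)",
                       what, col, which(is.na(out))[1]))
  }
  out
}

#' Read a photo-record table
#'
#' @param path CSV with columns `site_id`, `timestamp` and optionally
#'   `is_color`, `flash_fired`, `face_visible`, `face_bbox_pixels`,
#'   `behavior_code`, `pinnae_damage`, `species`.
#' @param tz timezone for timestamps without an explicit offset.
#' @param strict reject unknown columns.
#' @export
read_photo_records <- function(path, tz = "UTC", strict = TRUE) {
  opt <- c("is_color", "flash_fired", "face_visible", "face_bbox_pixels",
           "behavior_code", "pinnae_damage", "species")
  df <- read_csv_strict(path, c("site_id", "timestamp"), opt, strict,
                        "photo records")
  df$timestamp <- parse_timestamps(df$timestamp, tz = tz)
  for (cl in intersect(c("is_color", "flash_fired", "face_visible",
                         "pinnae_damage"), names(df))) {
    df[[cl]] <- as_logical_col(df[[cl]], cl, "photo records")
  }
  df
}

#' Read a site deployment table
#'
#' @param path CSV with columns `site_id`, `latitude`, `longitude`,
#'   `has_acd`, `is_scrape` (plus optional `deploy_date`).
#' @param strict reject unknown columns.
#' @export
read_site_deployments <- function(path, strict = TRUE) {
  df <- read_csv_strict(path, c("site_id", "latitude", "longitude"),
                        c("has_acd", "is_scrape", "deploy_date"), strict,
                        "site deployments")
  if (anyDuplicated(df$site_id)) {
    stop_input(paste("site deployments: duplicate site_id:",
                     df$site_id[duplicated(df$site_id)][1]))
  }
  if (any(abs(df$latitude) > 90, na.rm = TRUE) ||
      any(abs(df$longitude) > 180, na.rm = TRUE)) {
    stop_input("site deployments: coordinates out of range")
  }
  for (cl in intersect(c("has_acd", "is_scrape"), names(df))) {
    df[[cl]] <- as_logical_col(df[[cl]], cl, "site deployments")
  }
  df
}

#' Read a long-format pairwise rating table
#'
#' @param path CSV with columns `event_a`, `event_b`, `rater`, `verdict`.
#' @param strict when TRUE, verdicts must be exactly "same"/"different";
#'   lenient mode trims whitespace and lowercases first.
#' @return a validated `pair_rating_set`.
#' @export
read_pair_ratings <- function(path, strict = TRUE) {
  df <- read_csv_strict(path, c("event_a", "event_b", "rater", "verdict"),
                        character(), strict, "pair ratings")
  if (!strict) df$verdict <- tolower(trimws(df$verdict))
  pair_rating_set(df)
}

#' Read an events table (round trip of [write_stage_table()] output)
#'
#' @param path CSV of detection events.
#' @param tz timezone.
#' @export
read_events <- function(path, tz = "UTC") {
  df <- read_csv_strict(path, c("event_id", "site_id", "start_time"),
                        c("end_time", "n_photos", "face_captured", "behavior",
                          "is_night", "monochrome", "flash_fired",
                          "pinnae_damage", "face_resolution_px",
                          "resolution_class"), strict = FALSE, "events")
  for (cl in intersect(c("start_time", "end_time"), names(df))) {
    df[[cl]] <- parse_timestamps(df[[cl]], tz = tz)
  }
  for (cl in intersect(c("face_captured", "is_night", "monochrome",
                         "flash_fired", "pinnae_damage"), names(df))) {
    df[[cl]] <- as_logical_col(df[[cl]], cl, "events")
  }
  df
}

#' Read a detection-history table
#' @param path CSV with `site_id`, `date`, `count` plus covariates.
#' @export
read_detection_history <- function(path) {
  df <- read_csv_strict(path, c("site_id", "date", "count"),
                        c("days_since_deploy", "days_since_lure", "has_acd",
                          "is_scrape", "season", "year"), strict = FALSE,
                        "detection history")
  df$date <- as.Date(df$date)
  for (cl in intersect(c("has_acd", "is_scrape"), names(df))) {
    df[[cl]] <- as_logical_col(df[[cl]], cl, "detection history")
  }
  df$year <- as.character(df$year)
  df
}

#' Analysis run configuration
#'
#' @param photos,sites,ratings,history optional input paths; stages with a
#'   NULL input are fed from the synthetic generator.
#' @param out_dir output directory.
#' @param seed integer seed for any simulated stage.
#' @param tz timezone.
#' @param gap_minutes detection-event independence gap.
#' @param twilight_deg solar-elevation threshold for night.
#' @param kappa_level kappa confidence level.
#' @param alpha backward-selection significance level.
#' @param strict strict file reading.
#' @param scenario a [sim_scenario()] used for any synthetic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(photos = NULL, sites = NULL, ratings = NULL,
                       history = NULL, out_dir = "facetrap-out", seed = 1,
                       tz = "US/Mountain", gap_minutes = 30,
                       twilight_deg = -18, kappa_level = 0.95, alpha = 0.05,
                       strict = TRUE, scenario = sim_scenario()) {
  stopifnot(gap_minutes > 0, twilight_deg > -90, twilight_deg < 0,
            kappa_level > 0, kappa_level < 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Short stable hash of a configuration
#'
#' FNV-1a over the deparsed configuration; used to stamp output files so a
#' result can be traced to the exact settings that produced it.
#' @param config a [run_config()] (any R object works).
#' @export
config_hash <- function(config) {
  if (inherits(config, "run_config")) config$out_dir <- NULL # location-free
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  # polynomial rolling hash mod a Mersenne prime; every step stays well
  # inside double precision (2^31 * 31 << 2^53)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the two analyses end to end
#'
#' Orchestrates the full pipeline: detection events, face-capture and
#' behaviour contingency tables, the pairwise-agreement analysis (full,
#' singleton-adjusted, and attribute subsets), per-rater identity
#' partitions with contradictions, and the detection-rate GLMM with
#' backward selection -- writing one delimited file per result plus a JSON
#' manifest. Inputs not supplied in the configuration are generated by the
#' synthetic module under the configured seed.
#'
#' @param config a [run_config()].
#' @return invisibly, the list of written file paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  written <- character()
  emit <- function(x, name, stage) {
    p <- file.path(config$out_dir, name)
    write_stage_table(x, p, stage, hash)
    written <<- c(written, p)
  }
  stage <- "setup"
  tryCatch({
    set.seed(config$seed)
    stage <- "events"
    if (is.null(config$photos)) {
      sc <- config$scenario
      sched <- simulate_event_schedule(
        n_events = max(10L, round(0.0156 * sc$total_days)),
        n_sites = sc$n_sites, start_date = sc$start_date,
        seed = config$seed, gap_minutes = config$gap_minutes, tz = config$tz)
      sched$face_captured <- stats::runif(nrow(sched)) < 0.3
      sched$face_resolution_px <- ifelse(sched$face_captured,
                                         round(stats::rlnorm(nrow(sched),
                                                             log(39216), 0.55)), 0)
      photos <- simulate_photo_stream(sched, seed = config$seed,
                                      independence_gap_minutes = config$gap_minutes)
      ns <- length(unique(sched$site_id))
      sites <- data.frame(site_id = sort(unique(sched$site_id)),
                          latitude = 43.5 + stats::runif(ns, -0.3, 0.3),
                          longitude = -110.7 + stats::runif(ns, -0.3, 0.3),
                          has_acd = stats::runif(ns) < 0.5,
                          is_scrape = stats::runif(ns) < 0.5)
    } else {
      photos <- read_photo_records(config$photos, config$tz, config$strict)
      sites <- read_site_deployments(config$sites, config$strict)
    }
    events <- group_events(photos, config$gap_minutes, config$tz)
    events <- classify_night(events, sites, config$twilight_deg)
    emit(events, "events.csv", "events")

    stage <- "contingency"
    idx <- match(events$site_id, sites$site_id)
    face_tab <- table(factor(ifelse(sites$has_acd[idx], "acd", "conventional"),
                             c("acd", "conventional")),
                      factor(ifelse(events$face_captured, "face", "no_face"),
                             c("face", "no_face")))
    face_m <- as.data.frame.matrix(face_tab)
    chi <- tryCatch(pearson_chi2(unclass(as.matrix(face_tab))),
                    facetrap_degenerate_error = function(e) NULL)
    face_m$site_type <- rownames(face_m)
    if (!is.null(chi)) {
      face_m$chi2 <- chi$statistic
      face_m$p_value <- chi$p_value
    }
    emit(face_m, "face_contingency.csv", "contingency")
    beh <- as.data.frame.matrix(behavior_table(events, sites))
    beh$behavior <- rownames(beh)
    emit(beh, "behavior_contingency.csv", "contingency")

    stage <- "agreement"
    if (is.null(config$ratings)) {
      idents <- simulate_identities(config$scenario, seed = config$seed)
      sim <- simulate_ratings(idents, rater_panel(5), seed = config$seed)
      ratings <- sim$ratings
      rated_events <- idents
    } else {
      ratings <- read_pair_ratings(config$ratings, config$strict)
      rated_events <- events[match(ratings$event_ids, events$event_id), ]
      rated_events <- assign_resolution_class(rated_events)
    }
    kap_rows <- list()
    add_kappa <- function(label, tab) {
      row <- tryCatch({
        ci <- fleiss_kappa_ci(tab, config$kappa_level)
        data.frame(subset = label, n_pairings = nrow(tab),
                   kappa = attr(ci, "kappa"), lower = ci[["lower"]],
                   upper = ci[["upper"]], status = "ok")
      }, facetrap_degenerate_error = function(e) {
        data.frame(subset = label, n_pairings = nrow(tab), kappa = NA,
                   lower = NA, upper = NA, status = "degenerate")
      })
      kap_rows[[length(kap_rows) + 1L]] <<- row
    }
    add_kappa("full", rating_table(ratings))
    adj <- singleton_adjust(ratings)
    add_kappa("singleton_adjusted", rating_table(adj$adjusted))
    for (attribute in c("monochrome", "pinnae_damage", "resolution_high")) {
      for (mode in c("both", "neither", "mixed")) {
        sk <- subset_kappa(ratings, rated_events, attribute, mode,
                           config$kappa_level)
        kap_rows[[length(kap_rows) + 1L]] <-
          data.frame(subset = paste(attribute, mode, sep = ":"),
                     n_pairings = sk$n_pairings, kappa = sk$kappa,
                     lower = sk$lower, upper = sk$upper, status = sk$status)
      }
    }
    emit(do.call(rbind, kap_rows), "kappa.csv", "agreement")

    parts <- lapply(ratings$raters, function(r) {
      p <- partition_from_ratings(ratings, r)
      data.frame(rater = r,
                 event_id = unlist(p$components),
                 individual = rep(seq_along(p$components),
                                  lengths(p$components)))
    })
    emit(do.call(rbind, parts), "partitions.csv", "agreement")
    contra <- lapply(ratings$raters, function(r) {
      cc <- partition_from_ratings(ratings, r)$contradictions
      if (nrow(cc)) cbind(rater = r, cc) else NULL
    })
    contra <- do.call(rbind, contra)
    if (is.null(contra)) {
      contra <- data.frame(rater = character(), event_a = character(),
                           event_b = character())
    }
    emit(contra, "contradictions.csv", "agreement")

    stage <- "glmm"
    if (is.null(config$history)) {
      hist <- simulate_detection_history(config$scenario, seed = config$seed)$data
    } else {
      hist <- read_detection_history(config$history)
    }
    sel <- backward_select(hist, ~ has_acd * days_since_deploy +
                             has_acd * is_scrape + days_since_lure,
                           alpha = config$alpha)
    emit(sel$trail, "glmm_trail.csv", "glmm")
    an <- type3_anova(sel$fit)
    co <- sel$fit$coefficients
    co$chisq <- an$chisq[match(clean_term(co$term, an$term), an$term)]
    co$p_value <- an$p_value[match(clean_term(co$term, an$term), an$term)]
    emit(co, "glmm_coefficients.csv", "glmm")

    stage <- "manifest"
    manifest <- list(package = "facetrap",
                     version = as.character(utils::packageVersion("facetrap")),
                     config_hash = hash, seed = config$seed,
                     files = basename(written))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(c(written, file.path(config$out_dir, "manifest.json")))
  }, facetrap_error = function(e) {
    stop(errorCondition(sprintf("stage `%s` failed: %s", stage,
                                conditionMessage(e)),
                        class = class(e)))
  })
}

# map a coefficient name like "has_acdTRUE:days_since_deploy" onto its term
clean_term <- function(coef_names, term_labels) {
  vapply(coef_names, function(nm) {
    if (nm == "(Intercept)") return("(Intercept)")
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    hit <- vapply(term_labels, function(tl) {
      tparts <- strsplit(tl, ":", fixed = TRUE)[[1]]
      length(tparts) == length(parts) &&
        all(mapply(function(p, tp) startsWith(p, tp), sort(parts), sort(tparts)))
    }, logical(1))
    if (any(hit)) term_labels[which(hit)[1]] else NA_character_
  }, character(1))
}
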