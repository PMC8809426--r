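#' Group photo records into independent detection events
#'
#' Photos from the same site belong to the same detection event as long as
#' no more than `gap_minutes` pass between consecutive photos (chained rule:
#' each photo is compared with the previous photo at that site, not with the
#' event's first photo). A strictly larger gap starts a new, independent
#' event. The default 30-minute independence interval is the conventional
#' choice in camera-trap studies of large carnivores.
#'
#' Per-event attributes are aggregated from the constituent photos:
#' \itemize{
#'   \item `face_captured`: any photo has all facial features visible;
#'   \item `behavior`: the most "reactive" code present, with precedence
#'     retreat > curiosity > look_only > none > unknown;
#'   \item `monochrome`: any photo is monochrome (IR-flash imagery);
#'   \item `flash_fired`: any photo used the IR flash;
#'   \item `pinnae_damage`: any photo shows conspicuous ear damage;
#'   \item `face_resolution_px`: maximum face bounding-box pixel area.
#' }
#'
#' @param photos data.frame of photo records with columns `site_id`,
#'   `timestamp` (ISO-8601 character or POSIXct), `face_visible` (logical),
#'   `face_bbox_pixels` (integer, 0 when no face), and optionally
#'   `is_color`, `flash_fired`, `behavior_code`, `pinnae_damage`, `species`.
#' @param gap_minutes positive independence gap in minutes (default 30).
#' @param tz timezone applied to character timestamps.
#' @return data.frame of detection events, one row per event, sorted by
#'   `start_time`, with columns `event_id`, `site_id`, `start_time`,
#'   `end_time`, `n_photos`, `face_captured`, `behavior`, `is_night`
#'   (NA until [classify_night()]), `monochrome`, `flash_fired`,
#'   `pinnae_damage`, `face_resolution_px`, `resolution_class` ("unset"
#'   until [assign_resolution_class()]).
#' @seealso [classify_night()], [assign_resolution_class()]
#' @export
group_events <- function(photos, gap_minutes = 30, tz = "UTC") {
  stopifnot(is.numeric(gap_minutes), gap_minutes > 0)
  required <- c("site_id", "timestamp")
  missing_cols <- setdiff(required, names(photos))
  if (length(missing_cols)) {
    stop_input(paste("group_events: missing column(s):",
                     paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(photos)
  empty <- data.frame(
    event_id = character(), site_id = character(),
    start_time = as.POSIXct(character(), tz = tz),
    end_time = as.POSIXct(character(), tz = tz),
    n_photos = integer(), face_captured = logical(),
    behavior = character(), is_night = logical(),
    monochrome = logical(), flash_fired = logical(),
    pinnae_damage = logical(), face_resolution_px = numeric(),
    resolution_class = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  ph <- photos
  ph$timestamp <- parse_timestamps(ph$timestamp, tz = tz)
  if (is.null(ph$face_visible)) ph$face_visible <- FALSE
  if (is.null(ph$face_bbox_pixels)) ph$face_bbox_pixels <- 0
  if (is.null(ph$is_color)) ph$is_color <- TRUE
  if (is.null(ph$flash_fired)) ph$flash_fired <- FALSE
  if (is.null(ph$behavior_code)) ph$behavior_code <- "unknown"
  if (is.null(ph$pinnae_damage)) ph$pinnae_damage <- FALSE
  bad <- which(ph$face_bbox_pixels > 0 & !ph$face_visible)
  if (length(bad)) {
    stop_input(paste("group_events: face_bbox_pixels > 0 but face_visible is",
                     "FALSE in record(s)", paste(utils::head(bad, 5), collapse = ", ")))
  }
  ok_codes <- c("curiosity", "look_only", "none", "retreat", "unknown")
  if (!all(ph$behavior_code %in% ok_codes)) {
    stop_input(paste("group_events: unknown behavior_code value(s):",
                     paste(setdiff(unique(ph$behavior_code), ok_codes), collapse = ", ")))
  }

  ord <- order(ph$site_id, ph$timestamp)
  ph <- ph[ord, , drop = FALSE]
  gap_s <- gap_minutes * 60
  dt <- c(Inf, diff(as.numeric(ph$timestamp)))
  new_site <- c(TRUE, ph$site_id[-1] != ph$site_id[-n])
  new_event <- new_site | dt > gap_s        # strict ">": a gap of exactly
  grp <- cumsum(new_event)                  # gap_minutes stays in the event

  precedence <- c(retreat = 4, curiosity = 3, look_only = 2, none = 1, unknown = 0)
  behav <- vapply(split(ph$behavior_code, grp), function(b) {
    pres <- precedence[unique(b)]
    names(pres)[which.max(pres)]
  }, character(1))

  ev <- data.frame(
    event_id = NA_character_,
    site_id = vapply(split(ph$site_id, grp), function(s) as.character(s[1]), character(1)),
    start_time = as.POSIXct(vapply(split(as.numeric(ph$timestamp), grp), min, numeric(1)),
                            origin = "1970-01-01", tz = tz),
    end_time = as.POSIXct(vapply(split(as.numeric(ph$timestamp), grp), max, numeric(1)),
                          origin = "1970-01-01", tz = tz),
    n_photos = as.integer(tabulate(grp)),
    face_captured = vapply(split(ph$face_visible, grp), any, logical(1)),
    behavior = behav,
    is_night = NA,
    monochrome = vapply(split(!ph$is_color, grp), any, logical(1)),
    flash_fired = vapply(split(ph$flash_fired, grp), any, logical(1)),
    pinnae_damage = vapply(split(ph$pinnae_damage, grp), any, logical(1)),
    face_resolution_px = vapply(split(ph$face_bbox_pixels, grp),
                                function(x) as.numeric(max(x)), numeric(1)),
    resolution_class = "unset",
    stringsAsFactors = FALSE, row.names = NULL)
  ev <- ev[order(ev$start_time, ev$site_id), , drop = FALSE]
  ev$event_id <- sprintf(paste0("E%0", max(3L, nchar(nrow(ev))), "d"), seq_len(nrow(ev)))
  rownames(ev) <- NULL
  ev
}

#' Classify detection events as night or day
#'
#' An event is "night" when the solar elevation at the site, evaluated at
#' the event's start time (the triggering moment), is below the
#' astronomical-twilight threshold.
#'
#' @param events events data.frame from [group_events()].
#' @param sites site deployment data.frame with `site_id`, `latitude`,
#'   `longitude`.
#' @param threshold_deg solar elevation defining night (default -18).
#' @return `events` with `is_night` filled in.
#' @export
classify_night <- function(events, sites, threshold_deg = -18) {
  idx <- match(events$site_id, sites$site_id)
  if (anyNA(idx)) {
    stop_input(paste("classify_night: events reference unknown site(s):",
                     paste(unique(events$site_id[is.na(idx)]), collapse = ", ")))
  }
  lat <- sites$latitude[idx]
  lon <- sites$longitude[idx]
  if (anyNA(lat) || anyNA(lon)) {
    stop_config("classify_night: missing coordinates for some sites")
  }
  events$is_night <- is_astronomical_night(lat, lon, events$start_time, threshold_deg)
  events
}

#' Median-split face resolution into low/high classes
#'
#' Dichotomizes `face_resolution_px` at the sample median (standard midpoint
#' of the sorted values). Events at or below the median are "low", above it
#' "high"; ties with the median deterministically go to "low".
#'
#' @param events events data.frame; every row must have
#'   `face_resolution_px > 0` (i.e., a face was captured).
#' @return `events` with `resolution_class` set to "low"/"high".
#' @export
assign_resolution_class <- function(events) {
  px <- events$face_resolution_px
  bad <- which(!is.finite(px) | px <= 0)
  if (length(bad)) {
    stop_input(paste("assign_resolution_class: events without a face capture:",
                     paste(events$event_id[bad], collapse = ", ")))
  }
  med <- stats::median(px)
  events$resolution_class <- ifelse(px <= med, "low", "high")
  events
}
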