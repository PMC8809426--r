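# Shared fixtures and independent oracles for the test suite.

# Build a long-format rating table from a verdict matrix (pairs x raters).
# `partition` is a named character vector event_id -> individual.
ratings_from_partition <- function(partition, raters = paste0("R", 1:5),
                                   flips = NULL) {
  ids <- names(partition)
  pairs <- facetrap::enumerate_pairs(ids)
  truth <- partition[pairs$event_a] == partition[pairs$event_b]
  long <- do.call(rbind, lapply(raters, function(r) {
    data.frame(event_a = pairs$event_a, event_b = pairs$event_b, rater = r,
               verdict = ifelse(truth, "same", "different"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(flips)) {
    for (f in flips) { # f = c(event_a, event_b, rater)
      i <- which(long$event_a == min(f[1:2]) & long$event_b == max(f[1:2]) &
                   long$rater == f[3])
      long$verdict[i] <- ifelse(long$verdict[i] == "same", "different", "same")
    }
  }
  long
}

# Independent brute-force Fleiss kappa: recompute every ingredient from the
# definition, with no shared code with the implementation.
fleiss_oracle <- function(tab) {
  N <- nrow(tab)
  R <- sum(tab[1, ])
  p_j <- numeric(ncol(tab))
  for (j in seq_len(ncol(tab))) p_j[j] <- sum(tab[, j]) / (N * R)
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    agree <- 0
    for (j in seq_len(ncol(tab))) agree <- agree + tab[i, j] * (tab[i, j] - 1)
    P_i[i] <- agree / (R * (R - 1))
  }
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  (P_bar - P_e) / (1 - P_e)
}

# Brute-force reachability: repeated boolean matrix closure over "same" edges.
reachability_oracle <- function(ids, same_pairs) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(ids, ids)
  for (k in seq_len(nrow(same_pairs))) {
    adj[same_pairs$event_a[k], same_pairs$event_b[k]] <- TRUE
    adj[same_pairs$event_b[k], same_pairs$event_a[k]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  # canonical component labels: smallest member id
  vapply(ids, function(i) min(ids[adj[i, ]]), character(1))
}

# Independent solar-elevation oracle: spherical trig with fixed solstice
# declination and the mean-sun hour angle (no equation of time); good to a
# couple of degrees, enough to confirm day/night far from the threshold.
solar_oracle_deg <- function(lat, lon, time_utc, decl_deg) {
  rad <- pi / 180
  frac <- (as.numeric(time_utc) %% 86400) / 3600 # UTC hours
  ha <- ((frac + lon / 15) * 15 - 180) * rad     # mean-sun hour angle
  asin(sin(lat * rad) * sin(decl_deg * rad) +
         cos(lat * rad) * cos(decl_deg * rad) * cos(ha)) / rad
}

# A tiny deterministic photo table for reader/grouping tests.
tiny_photos <- function() {
  data.frame(
    site_id = c("S1", "S1", "S1", "S2"),
    timestamp = c("2018-06-01T10:00:00", "2018-06-01T10:10:00",
                  "2018-06-01T10:20:00", "2018-06-01T23:30:00"),
    is_color = c(TRUE, TRUE, TRUE, FALSE),
    flash_fired = c(FALSE, FALSE, FALSE, TRUE),
    face_visible = c(TRUE, FALSE, FALSE, TRUE),
    face_bbox_pixels = c(20000, 0, 0, 45000),
    behavior_code = c("look_only", "none", "curiosity", "retreat"),
    stringsAsFactors = FALSE)
}
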