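#' Pearson chi-squared test of independence
#'
#' Classic Pearson statistic on an r x c contingency table,
#' \eqn{\sum (O - E)^2 / E}, with df = (r-1)(c-1) and an upper-tail
#' chi-squared p-value. No continuity correction is applied (a Yates-corrected
#' 2x2 statistic is a different quantity; face-capture counts of the kind this
#' package analyses are compared uncorrected).
#'
#' @param counts matrix of nonnegative integer counts, at least 2x2.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' pearson_chi2(matrix(c(52, 46, 12, 98), nrow = 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop_input("pearson_chi2: table must be at least 2x2")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_input("pearson_chi2: counts must be finite and nonnegative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop_input("pearson_chi2: counts must be integers")
  }
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop_degenerate("pearson_chi2: zero row or column total (degenerate table)")
  }
  expected <- outer(rs, cs) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Face-capture (or any) success rate
#'
#' @param numerator nonnegative integer count of successes.
#' @param denominator positive integer count of trials.
#' @return the exact proportion, with a `percent` attribute formatted to one
#'   decimal place (rounding half away from zero).
#' @examples
#' capture_rate(52, 98)   # ~53.1%
#' @export
capture_rate <- function(numerator, denominator) {
  if (denominator <= 0) stop_input("capture_rate: denominator must be positive")
  if (numerator < 0 || numerator > denominator) {
    stop_input("capture_rate: numerator must be in [0, denominator]")
  }
  p <- numerator / denominator
  structure(p, percent = format_percent(p))
}

#' Format a proportion as a percentage
#'
#' Rounds half away from zero (so 0.105 -> "10.5%", 0.1885 -> "18.9%"),
#' unlike base [round()]'s round-half-even.
#'
#' @param p proportion in \[0, 1\].
#' @param digits decimal places (default 1).
#' @export
format_percent <- function(p, digits = 1) {
  x <- p * 100
  m <- 10^digits
  r <- sign(x) * floor(abs(x) * m + 0.5) / m
  sprintf(paste0("%.", digits, "f%%"), r)
}

#' Display a p-value in report style
#'
#' Values below 0.001 print as "< .001"; otherwise three decimals with no
#' leading zero.
#' @param p numeric p-value.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "< .001", sub("^0", "", sprintf("%.3f", p)))
}

#' Cross-classify detection events by behavior and site type
#'
#' Builds the behavior x site-type contingency table (site type: ACD vs
#' conventional), optionally further split by night/day.
#'
#' @param events events data.frame (behavior assigned; `is_night` needed
#'   when `split_by_night`).
#' @param sites site deployment data.frame with `site_id`, `has_acd`.
#' @param split_by_night also cross by night/day (columns become
#'   `acd.night`, `acd.day`, ...).
#' @return integer matrix of counts; rows are behavior categories.
#' @export
behavior_table <- function(events, sites, split_by_night = FALSE) {
  lev <- c("curiosity", "look_only", "none", "retreat", "unknown")
  idx <- match(events$site_id, sites$site_id)
  if (anyNA(idx)) {
    stop_input(paste("behavior_table: events reference unknown site(s):",
                     paste(unique(events$site_id[is.na(idx)]), collapse = ", ")))
  }
  type <- factor(ifelse(sites$has_acd[idx], "acd", "conventional"),
                 levels = c("acd", "conventional"))
  beh <- factor(events$behavior, levels = lev)
  if (split_by_night) {
    if (anyNA(events$is_night)) {
      stop_input("behavior_table: is_night not classified; run classify_night first")
    }
    phase <- factor(ifelse(events$is_night, "night", "day"),
                    levels = c("night", "day"))
    tab <- table(behavior = beh, interaction(type, phase, sep = "."))
  } else {
    tab <- table(behavior = beh, site_type = type)
  }
  m <- unclass(as.matrix(tab))
  storage.mode(m) <- "integer"
  m
}

#' 2x2 retreat-reaction table
#'
#' Retreat vs non-retreat events cross-classified by site type, the table
#' behind a "did the attention device provoke more retreats" test.
#'
#' @inheritParams behavior_table
#' @return 2x2 integer matrix (rows: retreat, other).
#' @export
retreat_table <- function(events, sites) {
  full <- behavior_table(events, sites)
  rbind(retreat = full["retreat", ],
        other = colSums(full[rownames(full) != "retreat", , drop = FALSE]))
}
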