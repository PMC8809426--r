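#' Build the N x k rating table from pairwise verdicts
#'
#' Subjects are the event pairings; categories are the verdicts
#' ("same"/"different"); cell (i, j) counts the raters assigning pairing i
#' to category j. Every row sums to the number of raters.
#'
#' @param ratings a `pair_rating_set`.
#' @param subset optional logical vector over pairings (see
#'   [subset_pairings()]).
#' @return integer matrix with columns `same`, `different`.
#' @export
rating_table <- function(ratings, subset = NULL) {
  stopifnot(inherits(ratings, "pair_rating_set"))
  v <- ratings$verdicts
  if (!is.null(subset)) v <- v[subset, , drop = FALSE]
  cbind(same = rowSums(v == "same"),
        different = rowSums(v == "different"))
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for R raters assigning N subjects to k
#' categories, from the table of assignment counts: with category
#' proportions \eqn{p_j = \sum_i n_{ij} / (NR)} and per-subject agreement
#' \eqn{P_i = (\sum_j n_{ij}^2 - R) / (R(R-1))},
#' \deqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e), \quad
#'       \bar P_e = \sum_j p_j^2.}
#' When all assignments fall in a single category \eqn{\bar P_e = 1} and
#' kappa is undefined; this raises a degenerate-statistic error (the caller
#' may report it as "perfect/degenerate agreement").
#'
#' @param table N x k matrix of assignment counts (constant row sums).
#' @return kappa (numeric scalar, at most 1).
#' @export
fleiss_kappa <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop_input("fleiss_kappa: need at least 2 subjects and 2 categories")
  }
  R <- unique(rowSums(tab))
  if (length(R) != 1L) stop_input("fleiss_kappa: row sums (raters) must be constant")
  if (R < 2) stop_input("fleiss_kappa: need at least 2 raters")
  N <- nrow(tab)
  p_j <- colSums(tab) / (N * R)
  P_e <- sum(p_j^2)
  if (1 - P_e < .Machine$double.eps) {
    stop_degenerate("fleiss_kappa: all assignments in one category; kappa undefined")
  }
  P_i <- (rowSums(tab^2) - R) / (R * (R - 1))
  (mean(P_i) - P_e) / (1 - P_e)
}

#' Large-sample confidence interval for Fleiss' kappa
#'
#' Symmetric normal interval using the large-sample variance
#' \deqn{\widehat{var}(\kappa) = \frac{2}{NR(R-1)} \cdot
#'   \frac{\bar P_e - (2R-3)\bar P_e^2 + 2(R-2)\sum_j p_j^3}{(1-\bar P_e)^2}.}
#'
#' @param table N x k assignment-count matrix.
#' @param level confidence level (default 0.95).
#' @return named vector `c(lower, upper)` with attributes `kappa` and `se`.
#' @export
fleiss_kappa_ci <- function(table, level = 0.95) {
  tab <- as.matrix(table)
  kappa <- fleiss_kappa(tab)
  R <- rowSums(tab)[1]
  N <- nrow(tab)
  p_j <- colSums(tab) / (N * R)
  P_e <- sum(p_j^2)
  v <- 2 / (N * R * (R - 1)) *
    (P_e - (2 * R - 3) * P_e^2 + 2 * (R - 2) * sum(p_j^3)) / (1 - P_e)^2
  if (v <= 0) stop_degenerate("fleiss_kappa_ci: nonpositive variance estimate")
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(v)
  structure(c(lower = kappa - z * se, upper = kappa + z * se),
            kappa = kappa, se = se)
}

#' Select pairings by a binary event attribute
#'
#' The either/or/both subsetting used in attribute-wise agreement analyses:
#' a pairing is retained when the attribute holds for both of its events
#' (`mode = "both"`), for neither (`"neither"`), or for exactly one
#' (`"mixed"`).
#'
#' @param ratings a `pair_rating_set`.
#' @param events events data.frame carrying the attribute columns
#'   (`monochrome`, `flash_fired`, `is_night`, `pinnae_damage`,
#'   `resolution_class`).
#' @param attribute one of "monochrome", "ambient_light", "night",
#'   "pinnae_damage", "resolution_high". `ambient_light` means no IR flash
#'   fired; `resolution_high` uses the median-split class computed once on
#'   the full event set.
#' @param mode "both", "neither" or "mixed".
#' @return logical vector over the pairings of `ratings`.
#' @export
subset_pairings <- function(ratings, events, attribute, mode) {
  stopifnot(inherits(ratings, "pair_rating_set"))
  mode <- match.arg(mode, c("both", "neither", "mixed"))
  attribute <- match.arg(attribute, c("monochrome", "ambient_light", "night",
                                      "pinnae_damage", "resolution_high"))
  idx <- match(ratings$event_ids, events$event_id)
  if (anyNA(idx)) {
    stop_input(paste("subset_pairings: pairings reference events absent from",
                     "the event table:",
                     paste(ratings$event_ids[is.na(idx)], collapse = ", ")))
  }
  attr_val <- switch(attribute,
    monochrome = as.logical(events$monochrome[idx]),
    ambient_light = !as.logical(events$flash_fired[idx]),
    night = as.logical(events$is_night[idx]),
    pinnae_damage = as.logical(events$pinnae_damage[idx]),
    resolution_high = {
      rc <- events$resolution_class[idx]
      if (any(rc == "unset")) {
        stop_input("subset_pairings: run assign_resolution_class first")
      }
      rc == "high"
    })
  if (anyNA(attr_val)) {
    stop_input(paste("subset_pairings: attribute", attribute, "unset for some events"))
  }
  names(attr_val) <- ratings$event_ids
  a <- attr_val[ratings$pairs$event_a]
  b <- attr_val[ratings$pairs$event_b]
  switch(mode, both = a & b, neither = !a & !b, mixed = xor(a, b))
}

#' Fleiss' kappa on an attribute-defined subset of pairings
#'
#' @inheritParams subset_pairings
#' @param level confidence level for the interval.
#' @return list with `attribute`, `mode`, `n_pairings`, `kappa`, `lower`,
#'   `upper` and `status`: "ok", "degenerate" (all retained verdicts in one
#'   category -- perfect agreement with no defined kappa or CI) or "empty".
#' @export
subset_kappa <- function(ratings, events, attribute, mode, level = 0.95) {
  keep <- subset_pairings(ratings, events, attribute, mode)
  out <- list(attribute = attribute, mode = mode, n_pairings = sum(keep),
              kappa = NA_real_, lower = NA_real_, upper = NA_real_,
              status = "empty")
  if (sum(keep) < 2) return(out)
  tab <- rating_table(ratings, keep)
  res <- tryCatch({
    ci <- fleiss_kappa_ci(tab, level)
    list(kappa = attr(ci, "kappa"), lower = ci[["lower"]],
         upper = ci[["upper"]], status = "ok")
  }, facetrap_degenerate_error = function(e) {
    list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
         status = "degenerate")
  })
  out[names(res)] <- res
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (standard midrank tie handling);
#' for two binary vectors this equals the phi coefficient of their 2x2
#' table. The p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 df; an exact permutation
#' p-value (full enumeration) is available for n <= 8.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use exact permutation p (only for n <= 8; default FALSE).
#' @return list with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop_input("spearman_rho: unequal lengths")
  n <- length(x)
  if (n < 3) stop_input("spearman_rho: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_degenerate("spearman_rho: zero variance; correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop_input("spearman_rho: exact enumeration limited to n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p_value <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p_value)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
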