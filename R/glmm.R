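#' Fit a Poisson GLMM of daily detection counts
#'
#' Models site-day detection counts with a log link, fixed covariate
#' effects, and independent Gaussian random intercepts (Laplace
#' approximation via \pkg{lme4}; with no random terms the model reduces to
#' an ordinary Poisson GLM). Continuous covariates named in
#' `scale_covariates` are z-standardized before fitting and the means/SDs
#' are stored on the fit so that effects can be back-transformed to the
#' per-day scale (see [percent_change_per_day()]).
#'
#' @param data detection-history data.frame: one row per site-day with a
#'   `count` response plus covariates (e.g. `days_since_deploy`,
#'   `days_since_lure`, `has_acd`, `is_scrape`) and grouping columns
#'   (`site_id`, `season`, `year`).
#' @param fixed RHS formula of fixed effects, e.g.
#'   `~ has_acd * days_since_deploy + is_scrape`.
#' @param random character vector of grouping columns that get a random
#'   intercept; `character(0)` fits a plain GLM.
#' @param scale_covariates continuous covariates to z-scale (only those
#'   actually present in `data` are used).
#' @param contrasts "treatment" (default) or "sum" (sum-to-zero coding of
#'   factors, needed for type-III tests).
#' @return object of class `facetrap_glmm`: list with the underlying `fit`,
#'   `coefficients` (term/estimate/se), `vcov`, `logLik`, `AIC`, `npar`,
#'   `converged`, `singular`, `scaling`, `fingerprint`, and the formulas.
#' @export
fit_poisson_glmm <- function(data, fixed,
                             random = intersect(c("site_id", "season", "year"),
                                                names(data)),
                             scale_covariates = c("days_since_deploy",
                                                  "days_since_lure"),
                             contrasts = c("treatment", "sum")) {
  contrasts <- match.arg(contrasts)
  if (!"count" %in% names(data)) stop_input("fit_poisson_glmm: no `count` column")
  y <- data$count
  if (any(y < 0) || any(y != round(y))) {
    stop_input("fit_poisson_glmm: counts must be nonnegative integers")
  }
  if (all(y == 0)) stop_input("fit_poisson_glmm: all-zero response")
  miss <- setdiff(random, names(data))
  if (length(miss)) {
    stop_input(paste("fit_poisson_glmm: random grouping column(s) absent:",
                     paste(miss, collapse = ", ")))
  }

  d <- data
  scale_covariates <- intersect(scale_covariates, names(d))
  scaling <- data.frame(covariate = as.character(scale_covariates),
                        mean = rep(NA_real_, length(scale_covariates)),
                        sd = rep(NA_real_, length(scale_covariates)))
  for (i in seq_along(scale_covariates)) {
    cl <- scale_covariates[i]
    m <- mean(d[[cl]]); s <- stats::sd(d[[cl]])
    if (!is.finite(s) || s == 0) {
      stop_input(paste("fit_poisson_glmm: covariate", cl, "has zero variance"))
    }
    scaling$mean[i] <- m; scaling$sd[i] <- s
    d[[cl]] <- (d[[cl]] - m) / s
  }

  rhs <- attr(stats::terms(fixed), "term.labels")
  vars <- all.vars(fixed)
  for (v in c(vars, random)) {
    if (is.character(d[[v]]) || is.logical(d[[v]])) d[[v]] <- factor(d[[v]])
  }
  ctr <- if (contrasts == "sum") "contr.sum" else "contr.treatment"
  ctr_list <- list()
  for (v in vars) if (is.factor(d[[v]])) ctr_list[[v]] <- ctr

  fixed_part <- if (length(rhs)) paste(rhs, collapse = " + ") else "1"
  re_part <- if (length(random)) paste(sprintf("(1 | %s)", random), collapse = " + ")
  form <- stats::as.formula(paste("count ~", fixed_part,
                                  if (length(random)) paste("+", re_part) else ""))

  conv_msgs <- character()
  if (length(random)) {
    fit <- withCallingHandlers(
      lme4::glmer(form, data = d, family = stats::poisson,
                  contrasts = if (length(ctr_list)) ctr_list else NULL),
      warning = function(w) {
        if (grepl("converge|Hessian|gradient", conditionMessage(w), ignore.case = TRUE)) {
          conv_msgs <<- c(conv_msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      },
      message = function(m) {
        if (grepl("singular", conditionMessage(m))) invokeRestart("muffleMessage")
      })
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    n_theta <- length(lme4::getME(fit, "theta"))
    ll <- as.numeric(stats::logLik(fit))
    singular <- lme4::isSingular(fit)
    # hard failure only when the optimizer itself reports one; near-boundary
    # gradient warnings are kept as flags in `convergence_messages`
    converged <- fit@optinfo$conv$opt == 0
    re_var <- vapply(lme4::VarCorr(fit), function(v) as.numeric(v[1, 1]), numeric(1))
  } else {
    fit <- stats::glm(form, data = d, family = stats::poisson,
                      contrasts = if (length(ctr_list)) ctr_list else NULL)
    beta <- stats::coef(fit)
    V <- as.matrix(stats::vcov(fit))
    n_theta <- 0L
    ll <- as.numeric(stats::logLik(fit))
    singular <- FALSE
    converged <- fit$converged
    re_var <- numeric(0)
  }
  npar <- length(beta) + n_theta
  structure(list(
    fit = fit,
    fixed = fixed, random = random, formula = form, contrasts = contrasts,
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = sqrt(diag(V)), row.names = NULL),
    vcov = V,
    ranef_variances = re_var,
    logLik = ll, AIC = -2 * ll + 2 * npar, npar = npar,
    converged = converged, singular = singular,
    convergence_messages = conv_msgs,
    scaling = scaling,
    data = d,
    fingerprint = glmm_fingerprint(data)
  ), class = "facetrap_glmm")
}

glmm_fingerprint <- function(data) {
  num <- vapply(data, is.numeric, logical(1))
  c(n = nrow(data), sum_count = sum(data$count),
    checksum = sum(vapply(data[num], function(x) sum(as.numeric(x)), numeric(1))))
}

#' @export
print.facetrap_glmm <- function(x, ...) {
  cat("Poisson GLMM: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("logLik %.2f  AIC %.1f  npar %d  converged: %s%s\n",
              x$logLik, x$AIC, x$npar, x$converged,
              if (x$singular) " (singular random effects)" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Backward stepwise elimination by likelihood ratio
#'
#' Starting from the full fixed-effects specification, repeatedly removes
#' the eliminable term (marginality respected: a main effect is never
#' removed while it appears in a retained interaction) whose removal
#' reduces the log-likelihood least, as long as the likelihood-ratio test
#' for that removal is non-significant at `alpha`. The random-intercept
#' structure is held fixed. Every step is recorded in an elimination trail
#' so the selection path is auditable.
#'
#' @inheritParams fit_poisson_glmm
#' @param alpha significance level for the LRT stopping rule (default 0.05).
#' @return list with `fit` (final `facetrap_glmm`), `fixed` (final RHS
#'   formula) and `trail` (data.frame: step, term considered, df, LL drop,
#'   p-value, removed?).
#' @export
backward_select <- function(data, fixed, random = intersect(
                              c("site_id", "season", "year"), names(data)),
                            alpha = 0.05, ...) {
  labels <- attr(stats::terms(fixed), "term.labels")
  cur <- labels
  fit <- fit_poisson_glmm(data, rhs_formula(cur), random = random, ...)
  if (!fit$converged) stop_convergence("backward_select: full model did not converge")
  trail <- data.frame(step = integer(), term = character(), df = integer(),
                      ll_drop = numeric(), p_value = numeric(),
                      removed = logical())
  step <- 0L
  repeat {
    elim <- eliminable_terms(cur)
    if (!length(elim)) break
    step <- step + 1L
    cand <- lapply(elim, function(tm) {
      red <- fit_poisson_glmm(data, rhs_formula(setdiff(cur, tm)),
                              random = random, ...)
      if (!red$converged) {
        stop_convergence(paste("backward_select: reduced model dropping", tm,
                               "did not converge"))
      }
      df <- fit$npar - red$npar
      drop <- fit$logLik - red$logLik
      list(term = tm, fit = red, df = df, drop = drop,
           p = stats::pchisq(2 * max(drop, 0), df, lower.tail = FALSE))
    })
    drops <- vapply(cand, `[[`, numeric(1), "drop")
    best <- cand[[which.min(drops)]]
    remove <- best$p > alpha
    trail <- rbind(trail, data.frame(step = step, term = best$term,
                                     df = best$df, ll_drop = best$drop,
                                     p_value = best$p, removed = remove))
    if (!remove) break
    cur <- setdiff(cur, best$term)
    fit <- best$fit
  }
  list(fit = fit, fixed = rhs_formula(cur), trail = trail)
}

rhs_formula <- function(labels) {
  stats::as.formula(paste("~", if (length(labels)) paste(labels, collapse = " + ")
                          else "1"))
}

# terms whose variables are not a strict subset of another retained term's
eliminable_terms <- function(labels) {
  if (!length(labels)) return(character())
  sets <- strsplit(labels, ":", fixed = TRUE)
  keep <- vapply(seq_along(labels), function(i) {
    !any(vapply(seq_along(labels), function(j) {
      i != j && all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  labels[keep]
}

#' Rank fitted models by AIC
#'
#' @param fits named list of `facetrap_glmm` fits on the same data (checked
#'   via a data fingerprint).
#' @return data.frame sorted by AIC with `delta_aic` relative to the best.
#' @export
compare_aic <- function(fits) {
  stopifnot(length(fits) >= 1)
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fps, identical, logical(1), fps[[1]]))) {
    stop_input("compare_aic: fits are not on identical data")
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  out <- data.frame(model = nm,
                    npar = vapply(fits, `[[`, numeric(1), "npar"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  out <- out[order(out$AIC), , drop = FALSE]
  out$delta_aic <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

#' Type-III Wald tests for each fixed-effect term
#'
#' Refits the model with sum-to-zero contrasts for factors (so that each
#' main effect is tested at the average of the other factors' levels, in
#' the presence of its interactions) and performs a Wald chi-squared test
#' of the coefficients belonging to each term, adjusting for all others.
#'
#' @param fit a `facetrap_glmm`.
#' @return data.frame with `term`, `chisq`, `df`, `p_value`.
#' @export
type3_anova <- function(fit) {
  stopifnot(inherits(fit, "facetrap_glmm"))
  if (fit$contrasts != "sum") {
    fit <- fit_poisson_glmm(fit$data, fit$fixed, random = fit$random,
                            scale_covariates = character(), contrasts = "sum")
  }
  X <- if (length(fit$random)) lme4::getME(fit$fit, "X") else stats::model.matrix(fit$fit)
  asgn <- attr(X, "assign")
  labels <- c("(Intercept)", attr(stats::terms(fit$fixed), "term.labels"))
  beta <- fit$coefficients$estimate
  V <- fit$vcov
  rows <- lapply(unique(asgn), function(a) {
    idx <- which(asgn == a)
    b <- beta[idx]
    Vi <- V[idx, idx, drop = FALSE]
    W <- tryCatch(as.numeric(t(b) %*% solve(Vi, b)),
                  error = function(e) stop_degenerate(
                    "type3_anova: singular coefficient covariance"))
    data.frame(term = labels[a + 1L], chisq = W, df = length(idx),
               p_value = stats::pchisq(W, length(idx), lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overdispersion and zero-inflation diagnostics
#'
#' `dispersion_ratio` is the sum of squared Pearson residuals over the
#' residual degrees of freedom (values well above 1 indicate
#' overdispersion); `zero_inflation_ratio` is the observed number of zero
#' counts over the number expected under the fitted (conditional) means.
#'
#' @param fit a `facetrap_glmm`.
#' @return list with `dispersion_ratio` and `zero_inflation_ratio`.
#' @export
glmm_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "facetrap_glmm"))
  mu <- stats::fitted(fit$fit)
  y <- fit$data$count
  pearson <- (y - mu) / sqrt(mu)
  df_resid <- length(y) - fit$npar
  list(dispersion_ratio = sum(pearson^2) / df_resid,
       zero_inflation_ratio = sum(y == 0) / sum(stats::dpois(0, mu)))
}

#' Back-transform a scaled slope to percent change per day
#'
#' A coefficient estimated on a z-scaled day covariate corresponds to a
#' multiplicative rate change of `exp(beta / sd)` per raw day; this returns
#' that change as a percentage.
#'
#' @param beta_scaled coefficient on the standardized covariate.
#' @param covariate_sd_days SD (in days) used in the standardization.
#' @return percent change in the detection rate per day.
#' @examples
#' percent_change_per_day(log(1.01) * 7, 7)  # +1% per day
#' @export
percent_change_per_day <- function(beta_scaled, covariate_sd_days) {
  if (!is.finite(covariate_sd_days) || covariate_sd_days <= 0) {
    stop_input("percent_change_per_day: covariate SD must be positive")
  }
  (exp(beta_scaled / covariate_sd_days) - 1) * 100
}
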