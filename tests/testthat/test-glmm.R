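sim_small_history <- function(seed, n_sites = 25, days = 80,
                              beta = c(int = -2.5, acd = 0.4, dsd = -0.3,
                                       scrape = 0.5, inter = 0),
                              sigma_site = 0.4) {
  set.seed(seed)
  site <- rep(seq_len(n_sites), each = days)
  dsd <- rep(seq_len(days) - 1, n_sites)
  acd <- rep(rep(c(TRUE, FALSE), length.out = n_sites), each = days)
  scrape <- rep(rep(c(TRUE, TRUE, FALSE, FALSE), length.out = n_sites),
                each = days)
  dsd_s <- (dsd - mean(dsd)) / stats::sd(dsd)
  u <- stats::rnorm(n_sites, 0, sigma_site)[site]
  eta <- beta["int"] + beta["acd"] * acd + beta["dsd"] * dsd_s +
    beta["scrape"] * scrape + beta["inter"] * acd * dsd_s + u
  data.frame(site_id = sprintf("S%02d", site), count = stats::rpois(length(eta), exp(eta)),
             days_since_deploy = dsd, has_acd = acd, is_scrape = scrape)
}

test_that("with no random effects the fit equals the IRLS Poisson GLM", {
  d <- sim_small_history(1, sigma_site = 0)
  fit <- fit_poisson_glmm(d, ~ has_acd * days_since_deploy + is_scrape,
                          random = character())
  d2 <- d
  d2$days_since_deploy <- scale(d2$days_since_deploy)[, 1]
  ref <- stats::glm(count ~ has_acd * days_since_deploy + is_scrape,
                    data = d2, family = stats::poisson)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$AIC, stats::AIC(ref), tolerance = 1e-8)
})

test_that("an intercept-only GLM recovers log(mean)", {
  d <- data.frame(count = stats::rpois(500, 2.7))
  fit <- fit_poisson_glmm(d, ~ 1, random = character())
  expect_equal(fit$coefficients$estimate, log(mean(d$count)), tolerance = 1e-8)
})

test_that("a near-zero random-effect variance reproduces the GLM fit", {
  d <- sim_small_history(2, n_sites = 50, days = 150,
                         beta = c(int = -1.5, acd = 0.4, dsd = -0.3,
                                  scrape = 0.5, inter = 0), sigma_site = 0)
  fit <- fit_poisson_glmm(d, ~ has_acd + days_since_deploy)
  glm0 <- fit_poisson_glmm(d, ~ has_acd + days_since_deploy,
                           random = character())
  expect_lt(fit$ranef_variances[["site_id"]], 0.1)
  expect_equal(fit$coefficients$estimate, glm0$coefficients$estimate,
               tolerance = 0.05)
})

test_that("mixed-model estimates recover the generating parameters", {
  d <- sim_small_history(3, n_sites = 40, days = 150,
                         beta = c(int = -2, acd = 0.5, dsd = -0.4,
                                  scrape = 0.6, inter = -0.3),
                         sigma_site = 0.3)
  fit <- fit_poisson_glmm(d, ~ has_acd * days_since_deploy + is_scrape)
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- stats::setNames(fit$coefficients$se, fit$coefficients$term)
  truth <- c("(Intercept)" = -2, has_acdTRUE = 0.5, days_since_deploy = -0.4,
             is_scrapeTRUE = 0.6, "has_acdTRUE:days_since_deploy" = -0.3)
  for (nm in names(truth)) {
    expect_lt(abs(est[[nm]] - truth[[nm]]) / se[[nm]], 4)
  }
})

test_that("input validation catches bad responses and groupings", {
  d <- sim_small_history(4)
  d0 <- d; d0$count <- 0
  expect_error(fit_poisson_glmm(d0, ~ has_acd), "all-zero",
               class = "facetrap_input_error")
  d1 <- d; d1$count[1] <- 1.5
  expect_error(fit_poisson_glmm(d1, ~ has_acd),
               class = "facetrap_input_error")
  expect_error(fit_poisson_glmm(d, ~ has_acd, random = "pack_id"),
               class = "facetrap_input_error")
})

test_that("backward selection respects marginality and drops noise terms", {
  d <- sim_small_history(5, n_sites = 40, days = 120,
                         beta = c(int = -2, acd = 0.8, dsd = 0,
                                  scrape = 0, inter = 0))
  sel <- backward_select(d, ~ has_acd * days_since_deploy + is_scrape,
                         random = "site_id", alpha = 0.05)
  kept <- attr(stats::terms(sel$fixed), "term.labels")
  expect_true("has_acd" %in% kept)
  # marginality: the interaction is considered before its mains
  first_mains <- with(sel$trail, step[term %in% c("has_acd", "days_since_deploy")])
  inter_step <- with(sel$trail, step[term == "has_acd:days_since_deploy" & removed])
  if (length(inter_step) && length(first_mains)) {
    expect_true(all(first_mains > inter_step))
  }
  expect_true(all(c("step", "term", "df", "ll_drop", "p_value", "removed")
                  %in% names(sel$trail)))
})

test_that("a strong true effect survives selection across replicates", {
  kept_acd <- logical(20)
  for (r in 1:20) {
    d <- sim_small_history(100 + r, n_sites = 24, days = 60,
                           beta = c(int = -2, acd = 1.2, dsd = 0,
                                    scrape = 0, inter = 0),
                           sigma_site = 0.3)
    sel <- backward_select(d, ~ has_acd + days_since_deploy + is_scrape,
                           random = "site_id")
    kept_acd[r] <- "has_acd" %in% attr(stats::terms(sel$fixed), "term.labels")
  }
  expect_gte(mean(kept_acd), 0.9)
})

test_that("eliminable_terms never exposes a main inside an interaction", {
  # via selection on a deterministic trail: A:B must be tested before A or B
  d <- sim_small_history(6, n_sites = 20, days = 50,
                         beta = c(int = -2, acd = 0, dsd = 0, scrape = 0,
                                  inter = 0))
  sel <- backward_select(d, ~ has_acd * days_since_deploy, random = "site_id")
  steps <- sel$trail
  ab <- steps$step[steps$term == "has_acd:days_since_deploy"]
  mains <- steps$step[steps$term %in% c("has_acd", "days_since_deploy")]
  if (length(ab) && length(mains)) expect_true(min(mains) > min(ab))
})

test_that("compare_aic ranks by AIC with deltas from the best", {
  d <- sim_small_history(7)
  f1 <- fit_poisson_glmm(d, ~ has_acd, random = character())
  f2 <- fit_poisson_glmm(d, ~ has_acd + days_since_deploy,
                         random = character())
  tab <- compare_aic(list(a = f1, b = f2))
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(tab$delta_aic[2], abs(f1$AIC - f2$AIC), tolerance = 1e-10)
  # two identical fits -> delta 0
  tab2 <- compare_aic(list(x = f1, y = f1))
  expect_equal(tab2$delta_aic, c(0, 0))
  # loglik -100 with 5 params vs -100.5 with 4: AIC 210 vs 209 -> delta 1
  fake <- function(ll, p) structure(list(logLik = ll, AIC = -2 * ll + 2 * p,
                                         npar = p, fingerprint = c(n = 1)),
                                    class = "facetrap_glmm")
  tab3 <- compare_aic(list(big = fake(-100, 5), small = fake(-100.5, 4)))
  expect_equal(tab3$model, c("small", "big"))
  expect_equal(tab3$delta_aic, c(0, 1))
  # mismatched data refuses to rank
  d2 <- sim_small_history(8)
  f3 <- fit_poisson_glmm(d2, ~ has_acd, random = character())
  expect_error(compare_aic(list(f1, f3)), class = "facetrap_input_error")
})

test_that("AIC ranking is invariant to covariate scaling", {
  d <- sim_small_history(9)
  f_scaled <- fit_poisson_glmm(d, ~ has_acd + days_since_deploy,
                               random = "site_id")
  f_raw <- fit_poisson_glmm(d, ~ has_acd + days_since_deploy,
                            random = "site_id",
                            scale_covariates = character())
  expect_equal(f_scaled$AIC, f_raw$AIC, tolerance = 1e-4)
})

clean_term_for_test <- function(nm) {
  if (nm == "(Intercept)") return("(Intercept)")
  sub("^(has_acd|is_scrape)1$", "\\1", nm)
}

test_that("type-III Wald tests reduce to (beta/se)^2 for single-df terms", {
  d <- sim_small_history(10)
  fit <- fit_poisson_glmm(d, ~ has_acd + days_since_deploy,
                          random = "site_id", contrasts = "sum")
  an <- type3_anova(fit)
  co <- fit$coefficients
  for (i in seq_len(nrow(co))) {
    z2 <- (co$estimate[i] / co$se[i])^2
    row <- an[an$term == clean_term_for_test(co$term[i]), ]
    expect_equal(row$chisq, z2, tolerance = 1e-8)
    expect_equal(row$df, 1L)
  }
})

test_that("type-III p-values are calibrated under the null", {
  # scaled-down calibration: 60 replicates, small frames; under a true null
  # the p-value for the tested term should be roughly uniform
  ps <- numeric(60)
  for (r in 1:60) {
    d <- sim_small_history(200 + r, n_sites = 12, days = 40,
                           beta = c(int = -1.5, acd = 0, dsd = 0.3,
                                    scrape = 0, inter = 0),
                           sigma_site = 0)
    fit <- fit_poisson_glmm(d, ~ has_acd + days_since_deploy,
                            random = character(), contrasts = "sum")
    an <- type3_anova(fit)
    ps[r] <- an$p_value[an$term == "has_acd"]
  }
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps < 0.5), 0.25)
})

test_that("diagnostics detect overdispersion and zero inflation", {
  set.seed(15)
  n <- 20000
  x <- stats::rnorm(n)
  mu <- exp(-1 + 0.4 * x)
  d <- data.frame(count = stats::rpois(n, mu), days_since_deploy = x)
  fit <- fit_poisson_glmm(d, ~ days_since_deploy, random = character(),
                          scale_covariates = character())
  di <- glmm_diagnostics(fit)
  expect_gt(di$dispersion_ratio, 0.9); expect_lt(di$dispersion_ratio, 1.1)
  expect_gt(di$zero_inflation_ratio, 0.9); expect_lt(di$zero_inflation_ratio, 1.1)

  # negative-binomial counts at the same mean: dispersion ratio ~ 1 + mu/size
  d2 <- d
  d2$count <- stats::rnbinom(n, size = 1, mu = mu)
  fit2 <- fit_poisson_glmm(d2, ~ days_since_deploy, random = character(),
                           scale_covariates = character())
  expect_gt(glmm_diagnostics(fit2)$dispersion_ratio, 1.3)

  # inject 20% structural zeros: observed zeros exceed Poisson expectation
  d3 <- d
  d3$count[stats::runif(n) < 0.2] <- 0
  fit3 <- fit_poisson_glmm(d3, ~ days_since_deploy, random = character(),
                           scale_covariates = character())
  expect_gt(glmm_diagnostics(fit3)$zero_inflation_ratio, 1)
})

test_that("percent change per day back-transforms scaled slopes", {
  expect_equal(percent_change_per_day(0, 55), 0)
  expect_equal(percent_change_per_day(log(1.01) * 55, 55), 1, tolerance = 1e-10)
  expect_error(percent_change_per_day(0.5, 0), class = "facetrap_input_error")
  # recovery: simulate with a known per-day multiplier and back-transform
  mult <- 0.997 # -0.3% per day
  d <- sim_small_history(16, n_sites = 100, days = 200,
                         beta = c(int = -1, acd = 0, dsd = 0, scrape = 0,
                                  inter = 0), sigma_site = 0)
  sd_days <- stats::sd(d$days_since_deploy)
  set.seed(160)
  d$count <- stats::rpois(nrow(d), exp(-1 + log(mult) * d$days_since_deploy))
  fit <- fit_poisson_glmm(d, ~ days_since_deploy, random = character())
  expect_equal(fit$scaling$sd, sd_days)
  beta_hat <- fit$coefficients$estimate[2]
  pc <- percent_change_per_day(beta_hat, sd_days)
  expect_lt(abs(pc - (mult - 1) * 100), 0.08) # within ~3 MC standard errors
})
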