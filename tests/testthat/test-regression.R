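test_that("OLS recovers exact and hand-computed fits", {
  # noiseless line: exact recovery
  f <- fit_linear_model(exact_line(), y ~ x)
  expect_equal(f$coefficients$estimate, c(3, 2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)

  # tiny case with closed-form OLS: slope Sxy/Sxx = 1.5, intercept 0,
  # R2 = 1 - RSS/SYY = 1 - 1.5/6 = 0.75
  d <- data.frame(x = c(1, 2, 3), y = c(2, 2, 5))
  f2 <- fit_linear_model(d, y ~ x)
  expect_equal(f2$coefficients$estimate, c(0, 1.5), tolerance = 1e-10)
  expect_equal(f2$r_squared, 0.75, tolerance = 1e-10)
})

test_that("the flume dataset yields the canonical scaling fit", {
  f <- fit_linear_model(assembled_flume, Rtot_g_m2 ~ Itot_mW_m2)
  expect_equal(f$coefficients$estimate[1], 35.11, tolerance = 0.01)
  expect_equal(f$coefficients$estimate[2], 0.357, tolerance = 0.002)
  expect_equal(f$r_squared, 0.682, tolerance = 0.001)
  expect_equal(f$adj_r_squared, 0.672, tolerance = 0.001)
  expect_equal(f$f_statistic, 64.43, tolerance = 0.01)
  expect_equal(f$n, 32)
  # the abiotic intercept is consistent with the defaunated control mean
  expect_true(f$coefficients$ci_low[1] <= 32.25 &&
    32.25 <= f$coefficients$ci_high[1])
})

test_that("AIC follows the Gaussian convention counting the residual variance", {
  f <- fit_linear_model(assembled_flume, Rtot_g_m2 ~ Itot_mW_m2)
  n <- f$n
  rss <- sum(f$residuals^2)
  manual <- n * log(2 * pi * rss / n) + n + 2 * (2 + 1)
  expect_equal(f$aic, manual, tolerance = 1e-8)
})

test_that("rank-deficient and undersized designs raise informative errors", {
  d <- data.frame(y = rnorm(10), x = 1:10)
  d$x2 <- 2 * d$x
  expect_error(fit_linear_model(d, y ~ x + x2), "collinear")
  expect_error(fit_linear_model(d[1:3, ], y ~ x + I(x^2)), "observations")
})

test_that("OLS residuals are orthogonal to every design column", {
  f <- fit_linear_model(
    assembled_flume,
    Rtot_g_m2 ~ functional_group + Itot_mW_m2
  )
  X <- stats::model.matrix(f$lm)
  expect_true(all(abs(crossprod(X, f$residuals)) < 1e-8))
})

test_that("stepwise selection on the flume dataset walks the published path", {
  tr <- stepwise_select(assembled_flume, Rtot_g_m2 ~ functional_group * Itot_mW_m2)
  expect_equal(tr$steps$aic, c(270.397, 268.133, 265.712), tolerance = 0.01)
  expect_equal(
    tr$steps$action,
    c("start", "- functional_group:Itot_mW_m2", "- functional_group")
  )
  expect_equal(deparse(tr$selected), "Rtot_g_m2 ~ Itot_mW_m2")
  # the selected model has the lowest AIC among every model visited
  expect_equal(min(tr$visited$aic), tr$fit$aic)
  # independent route: R's own bidirectional stepping lands on the same model
  ref <- stats::step(
    stats::lm(Rtot_g_m2 ~ functional_group * Itot_mW_m2, assembled_flume),
    direction = "both", trace = 0
  )
  expect_equal(sort(names(stats::coef(ref))), sort(tr$fit$coefficients$term))
})

test_that("stepwise retains a categorical term when the groups truly differ", {
  cfg <- generator_config(
    group_offsets = c(deep = 0, intermediate_IBB = 60, shallow = -60),
    sigma = 5, replicate_sigma = 0, seed = 101
  )
  tab <- generate_table(cfg)
  tab$functional_group <- factor(tab$functional_group)
  tr <- stepwise_select(tab, Rtot_g_m2 ~ functional_group * Itot_mW_m2)
  expect_true(any(grepl("functional_group", deparse(tr$selected))))
  # exhaustive enumeration over the three candidate models agrees
  cands <- list(
    Rtot_g_m2 ~ functional_group * Itot_mW_m2,
    Rtot_g_m2 ~ functional_group + Itot_mW_m2,
    Rtot_g_m2 ~ Itot_mW_m2
  )
  aics <- vapply(cands, function(ff) fit_linear_model(tab, ff)$aic, numeric(1))
  expect_equal(tr$fit$aic, min(aics))
})

test_that("a single-predictor scope with strong signal keeps the predictor", {
  d <- data.frame(x = 1:20)
  d$y <- 1 + 3 * d$x + c(-0.5, 0.5)
  tr <- stepwise_select(d, y ~ x)
  expect_equal(nrow(tr$steps), 1)
  expect_equal(deparse(tr$selected), "y ~ x")
})

test_that("adding a truly-null predictor usually worsens AIC", {
  worse <- with_seed(2024, {
    vapply(1:200, function(i) {
      d <- data.frame(x = 1:30, z = rnorm(30))
      d$y <- 1 + 2 * d$x + rnorm(30, sd = 3)
      fit_linear_model(d, y ~ x + z)$aic > fit_linear_model(d, y ~ x)$aic
    }, logical(1))
  })
  expect_gt(mean(worse), 0.5)
})

test_that("Spearman correlation matches hand-ranked cases and the reference route", {
  # d^2 sums to 6: rho = 1 - 6*6/(3*8) = -0.5
  expect_equal(spearman_correlation(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  x <- assembled_flume$Itot_mW_m2
  y <- assembled_flume$Rtot_g_m2
  ours <- spearman_correlation(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "length")
})

test_that("Spearman is invariant under monotone transforms and equals Pearson on ranks", {
  x <- assembled_flume$Itot_mW_m2
  y <- assembled_flume$Rtot_g_m2
  base <- spearman_correlation(x, y)$rho
  expect_equal(spearman_correlation(exp(x / 100), y)$rho, base)
  expect_equal(spearman_correlation(x, log(y))$rho, base)
  expect_equal(base, stats::cor(rank(x), rank(y)))
})

test_that("the correlation report separates rank from product-moment estimates", {
  rep <- correlation_report(assembled_flume)
  get <- function(p, m) rep$estimate[rep$predictor == p & rep$method == m]
  expect_equal(get("metabolism", "pearson"), 0.826, tolerance = 0.001)
  expect_equal(get("density", "pearson"), 0.370, tolerance = 0.001)
  expect_equal(get("metabolism", "spearman"), 0.761, tolerance = 0.001)
  expect_equal(get("density", "spearman"), 0.560, tolerance = 0.001)
  expect_true(all(rep$p_value[rep$predictor == "metabolism"] < 0.001))
})

test_that("dropping the two highest-metabolism treatments keeps a positive trend", {
  out <- leverage_exclusion_refit(assembled_flume, k = 2)
  expect_equal(out$effective_k, 2)
  expect_equal(sort(out$excluded), sort(order(-assembled_flume$Itot_mW_m2)[1:2]))
  slope <- out$fit$coefficients
  expect_lt(abs(slope$estimate[2] - 0.17), 0.01)
  expect_lt(slope$p_value[2], 0.05)

  # k = 0 is the plain fit
  f0 <- leverage_exclusion_refit(assembled_flume, 0)$fit
  full <- fit_linear_model(assembled_flume, Rtot_g_m2 ~ Itot_mW_m2)
  expect_equal(f0$coefficients, full$coefficients)

  # noiseless data: slope unchanged by any exclusion
  noiseless <- generate_table(generator_config(sigma = 0, replicate_sigma = 0, seed = 1))
  for (k in c(0, 2, 5)) {
    expect_equal(
      leverage_exclusion_refit(noiseless, k)$fit$coefficients$estimate[2],
      0.36,
      tolerance = 1e-8
    )
  }
  expect_error(leverage_exclusion_refit(assembled_flume, 30), "k")
})

test_that("ties at the exclusion boundary are all dropped and reported", {
  d <- assembled_flume
  d$Itot_mW_m2[1:3] <- 999 # three-way tie at the top
  out <- leverage_exclusion_refit(d, k = 2)
  expect_equal(out$effective_k, 3)
  expect_equal(sort(out$excluded), 1:3)
})

test_that("R_BIO models select the intercept-only description of the flume data", {
  out <- rbio_models(assembled_flume)
  expect_equal(deparse(out$trace$selected), "R_BIO ~ 1")
  expect_equal(out$mean_rbio, 0.468, tolerance = 0.001)
  co <- out$fit$coefficients
  expect_equal(co$estimate[1], out$mean_rbio) # intercept-only = mean
  expect_lt(abs(co$ci_low[1] - 0.09), 0.01)
  expect_lt(abs(co$ci_high[1] - 0.84), 0.01)
  expect_lt(co$p_value[1], 0.05)
})

test_that("R_BIO models keep density when it truly drives the effect", {
  d <- with_seed(55, {
    data.frame(
      density_ind_m2 = rep(c(13, 32, 64, 127, 255, 382), 5),
      mass_mg_afdw = runif(30, 10, 900)
    )
  })
  d$R_BIO <- 0.1 + 0.004 * d$density_ind_m2 +
    with_seed(56, rnorm(30, sd = 0.05))
  out <- rbio_models(d)
  expect_true(grepl("density_ind_m2", deparse(out$trace$selected)))
  cands <- list(
    R_BIO ~ density_ind_m2 * mass_mg_afdw,
    R_BIO ~ density_ind_m2 + mass_mg_afdw,
    R_BIO ~ density_ind_m2, R_BIO ~ mass_mg_afdw, R_BIO ~ 1
  )
  aics <- vapply(cands, function(ff) fit_linear_model(d, ff)$aic, numeric(1))
  expect_equal(out$fit$aic, min(aics))

  # constant R_BIO: covariates explain nothing
  d2 <- d
  d2$R_BIO <- 0.47
  f <- fit_linear_model(d2, R_BIO ~ density_ind_m2 + mass_mg_afdw)
  expect_equal(f$r_squared, 0, tolerance = 1e-6)
  expect_equal(
    fit_linear_model(d2, R_BIO ~ 1)$coefficients$estimate, 0.47,
    tolerance = 1e-10
  )
})

test_that("95% CIs cover the generating coefficients at the nominal rate", {
  cfg <- generator_config(c = 35, d = 0.36, sigma = 15, seed = 3000)
  cover_c <- logical(500)
  cover_d <- logical(500)
  for (i in 1:500) {
    cfg_i <- cfg
    cfg_i$seed <- 3000L + i
    f <- fit_linear_model(generate_table(cfg_i), Rtot_g_m2 ~ Itot_mW_m2)
    co <- f$coefficients
    cover_c[i] <- co$ci_low[1] <= 35 && 35 <= co$ci_high[1]
    cover_d[i] <- co$ci_low[2] <= 0.36 && 0.36 <= co$ci_high[2]
  }
  expect_gt(mean(cover_c), 0.91)
  expect_lt(mean(cover_c), 0.99)
  expect_gt(mean(cover_d), 0.91)
  expect_lt(mean(cover_d), 0.99)
})
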