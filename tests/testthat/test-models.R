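make_design <- function(n, seed) {
  set.seed(seed)
  data.frame(
    log_dist = log_distance(sample(c(0, 150, 220, 500, 750), n, TRUE)),
    depth_layer = sample(c("bottom", "middle"), n, TRUE)
  )
}

test_that("intercept-only fits equal their closed-form MLEs", {
  y <- c(2, 3, 5, 8)
  f <- fit_glm(y ~ 1, data.frame(y = y), family = "gamma_log")
  expect_equal(unname(f$coefficients$estimate), log(mean(y)), tolerance = 1e-8)
  cnt <- c(2, 4, 6)
  fp <- fit_glm(cnt ~ 1, data.frame(cnt = cnt), family = "poisson_log")
  expect_equal(unname(fp$coefficients$estimate), log(4), tolerance = 1e-8)
})

test_that("gamma log-link likelihood matches a generic optimiser's maximum", {
  d <- make_design(40, 701)
  set.seed(702)
  mu <- exp(2 - 0.2 * d$log_dist)
  d$y <- rgamma(40, shape = 3, rate = 3 / mu)
  f <- fit_glm(y ~ log_dist, d, family = "gamma_log")
  nll <- function(p) {
    m <- exp(p[1] + p[2] * d$log_dist)
    -sum(dgamma(d$y, shape = exp(p[3]), rate = exp(p[3]) / m, log = TRUE))
  }
  opt <- optim(c(2, -0.2, 1), nll, method = "BFGS")
  expect_equal(f$log_likelihood, -opt$value, tolerance = 1e-5)
  expect_equal(unname(f$coefficients$estimate), opt$par[1:2], tolerance = 1e-3)
})

test_that("family preconditions are enforced", {
  d <- data.frame(y = c(0, 1, 2.5))
  expect_error(fit_glm(y ~ 1, d, family = "gamma_log"), "hurdle")
  expect_error(fit_glm(y ~ 1, d, family = "poisson_log"), "integer")
})

test_that("gamma GLM recovers distance-decay coefficients within 2 SE", {
  d <- make_design(500, 703)
  set.seed(704)
  truth <- c(5.42, -0.30, -1.25)
  mu <- exp(truth[1] + truth[2] * d$log_dist +
              truth[3] * (d$depth_layer == "middle"))
  d$y <- rgamma(500, shape = 2, rate = 2 / mu)
  f <- fit_glm(y ~ log_dist + depth_layer, d, family = "gamma_log")
  expect_true(all(abs(f$coefficients$estimate - truth) <
                    2 * f$coefficients$se))
  expect_gt(f$pseudo_r2, 0.2)
})

test_that("hurdle composes binomial and gamma parts with additive likelihood", {
  d <- make_design(400, 705)
  set.seed(706)
  mu <- exp(3 - 0.3 * d$log_dist)
  pr <- plogis(4 - 0.8 * d$log_dist) # zeros concentrated at far stations
  d$y <- ifelse(rbinom(400, 1, pr) == 1, rgamma(400, 2, 2 / mu), 0)
  h <- fit_gamma_hurdle(y ~ log_dist, d, binom_formula = ~log_dist)
  expect_equal(h$log_likelihood,
               h$log_likelihood_binom + h$log_likelihood_gamma)
  expect_equal(h$bic, h$k * log(h$n) - 2 * h$log_likelihood)
  expect_lt(h$binom_coefficients$estimate[2], 0) # presence falls with distance
  # no zeros -> plain gamma fit
  d2 <- d[d$y > 0, ]
  expect_warning(h2 <- fit_gamma_hurdle(y ~ log_dist, d2), "no zeros")
  g2 <- fit_glm(y ~ log_dist, d2, family = "gamma_log")
  expect_equal(h2$coefficients$estimate, g2$coefficients$estimate)
  expect_error(fit_gamma_hurdle(y ~ 1, data.frame(y = c(0, 0, 0))), "all-zero")
})

test_that("likelihood-ratio factor test behaves at its degenerate edges", {
  set.seed(707)
  y <- rpois(32, 16)
  g <- factor(rep(letters[1:8], 4))
  lt <- lr_test_factor(y, g, family = "poisson_log")
  expect_gte(lt$statistic, 0)
  expect_equal(lt$df, 7)
  expect_gte(lt$fit_factor$log_likelihood, lt$fit_null$log_likelihood)
  expect_error(lr_test_factor(y, factor(rep("a", 32))), "2 observed levels")
})

test_that("a strongly shifted group is detected in nearly all replicates", {
  set.seed(708)
  hits <- replicate(100, {
    y <- rpois(32, 16)
    y[1:4] <- rpois(4, 16 + 3 * sqrt(16 / 4) * 2) # one station well separated
    lr_test_factor(y, factor(rep(letters[1:8], each = 4)),
                   family = "poisson_log")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("pairwise contrasts: two levels need no adjustment, outliers dominate", {
  set.seed(709)
  d2 <- data.frame(y = rgamma(20, 2, 2 / exp(3)),
                   group = factor(rep(c("a", "b"), 10)))
  ct2 <- pairwise_contrasts(fit_glm(y ~ group, d2, "gamma_log"), seed = 1)
  expect_equal(ct2$p_adjusted, 2 * pnorm(-abs(ct2$z)), tolerance = 1e-9)
  # one elevated level: its contrasts are the significant ones
  d8 <- data.frame(y = rgamma(64, 4, 4 / exp(2)),
                   group = factor(rep(letters[1:8], each = 8)))
  d8$y[d8$group == "h"] <- rgamma(8, 4, 4 / exp(4))
  ct8 <- pairwise_contrasts(fit_glm(y ~ group, d8, "gamma_log"), seed = 1)
  sig <- ct8$contrast[ct8$p_adjusted < 0.05]
  expect_gt(length(sig), 0)
  expect_true(all(grepl("h", sig)))
})

test_that("Holm-adjusted contrasts control family-wise error under the null", {
  set.seed(710)
  fwer <- replicate(150, {
    d <- data.frame(y = rgamma(40, 3, 3 / exp(2)),
                    group = factor(rep(letters[1:5], each = 8)))
    ct <- pairwise_contrasts(fit_glm(y ~ group, d, "gamma_log"),
                             method = "holm")
    any(ct$p_adjusted < 0.05)
  })
  expect_lte(mean(fwer), 0.07)
})

test_that("BIC candidate set is the five hierarchical models", {
  d <- make_design(60, 711)
  set.seed(712)
  d$y <- rgamma(60, 2, 2 / exp(2 - 0.2 * d$log_dist))
  sel <- bic_select(d$y, d, "log_dist", family = "gamma_log")
  expect_equal(nrow(sel$table), 5)
  expect_setequal(sel$table$candidate,
                  c("intercept", "covariate", "depth", "covariate+depth",
                    "covariate+depth+interaction"))
  expect_equal(sel$table$bic, sort(sel$table$bic))
  expect_equal(sel$best$bic, min(sel$table$bic))
  # hurdle path also enumerates five gamma-component candidates
  yz <- d$y; yz[1:10] <- 0
  selh <- suppressWarnings(bic_select(yz, d, "log_dist",
                                      family = "gamma_hurdle"))
  expect_equal(nrow(selh$table), 5)
})

test_that("pure-noise responses favour the intercept-only model", {
  set.seed(713)
  wins <- replicate(40, {
    d <- make_design(100, sample.int(1e6, 1))
    y <- rgamma(100, 2, 2 / 10)
    bic_select(y, d, "log_dist", family = "gamma_log")$table$candidate[1]
  })
  expect_gt(mean(wins == "intercept"), 0.5)
})

test_that("predictions exponentiate the linear predictor and flag extrapolation", {
  d <- make_design(200, 714)
  set.seed(715)
  d$y <- rgamma(200, 2, 2 / exp(2 - 0.2 * d$log_dist))
  f <- fit_glm(y ~ log_dist, d, "gamma_log")
  beta <- f$coefficients$estimate
  nd <- data.frame(log_dist = c(log_distance(0), log_distance(5000)))
  pr <- predict_response(f, nd)
  expect_equal(unname(pr[1]), exp(beta[1] + beta[2] * log(0.1)),
               tolerance = 1e-10)
  expect_false(attr(pr, "extrapolated")[1])
  expect_true(attr(pr, "extrapolated")[2])
  # hurdle with certain presence reduces to the gamma prediction
  dz <- d; dz$y[1:40] <- 0
  h <- fit_gamma_hurdle(y ~ log_dist, dz)
  pr_h <- predict_response(h, nd)
  p_pos <- predict(h$binom_fit, newdata = nd, type = "response")
  expect_equal(as.numeric(pr_h / p_pos),
               as.numeric(exp(predict(h$fit, newdata = nd))),
               tolerance = 1e-10)
})

test_that("BIC identity holds across families and the hurdle composite", {
  d <- make_design(120, 716)
  set.seed(717)
  d$y <- rgamma(120, 2, 2 / exp(2))
  d$cnt <- rpois(120, 8)
  yz <- d$y; yz[1:30] <- 0
  fits <- list(
    fit_glm(y ~ log_dist, d, "gamma_log"),
    fit_glm(cnt ~ depth_layer, d, "poisson_log"),
    fit_gamma_hurdle(yz ~ log_dist, d)
  )
  for (f in fits) {
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$log_likelihood)
  }
})
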