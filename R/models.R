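#' Distance covariate transform
#'
#' Distances from the focal reef enter models as log(distance + 0.1): the
#' 0.1 m offset keeps the reef station (distance 0) finite and anchors the
#' intercept at log(0.1). Distances are in metres.
#'
#' @param distance_m Absolute distance in metres.
#' @return log(distance_m + 0.1).
#' @export
log_distance <- function(distance_m) {
  if (any(distance_m < 0)) stop("distance must be non-negative")
  log(distance_m + 0.1)
}

#' Echo-intensity covariate transform
#'
#' Linear volume backscatter spans several orders of magnitude across
#' stations, so it enters models on the log10 scale by default.
#'
#' @param sv_linear Linear backscattering coefficient (> 0).
#' @param scale `"log10"` (default) or `"linear"`.
#' @return Transformed covariate.
#' @export
echo_covariate <- function(sv_linear, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  if (any(sv_linear <= 0) && scale == "log10") {
    stop("log10 echo covariate requires positive S_V")
  }
  if (scale == "log10") log10(sv_linear) else sv_linear
}

# Full-ML log-likelihood and parameter count for a fitted stats::glm.
# Gamma fits get their shape re-estimated by ML (the glm deviance-based
# dispersion is not the MLE); Poisson k counts coefficients only.
.glm_loglik <- function(fit, family) {
  y <- fit$y
  mu <- fitted(fit)
  p <- length(coef(fit))
  if (family == "poisson_log") {
    list(ll = sum(stats::dpois(y, mu, log = TRUE)), k = p, shape = NA_real_)
  } else {
    if (fit$deviance < sqrt(.Machine$double.eps) * length(y)) {
      stop("degenerate gamma fit: response has (near-)zero residual variation")
    }
    shape <- MASS::gamma.shape(fit)$alpha
    list(ll = sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE)),
         k = p + 1, shape = shape)
  }
}

.new_model_fit <- function(family, formula, fit, ll, k, shape, fitted_resp, y,
                           extra = list()) {
  n <- length(y)
  pseudo_r2 <- if (stats::sd(y) > 0 && stats::sd(fitted_resp) > 0) {
    stats::cor(y, fitted_resp)^2
  } else NA_real_
  structure(
    c(list(family = family, formula = formula, fit = fit,
           coefficients = .coef_table(fit),
           shape = shape, log_likelihood = ll, n = n, k = k,
           bic = k * log(n) - 2 * ll,
           fitted = fitted_resp, y = y, pseudo_r2 = pseudo_r2),
      extra),
    class = "edna_fit"
  )
}

.coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             row.names = NULL)
}

#' Fit a log-link GLM for eDNA responses
#'
#' Poisson with log link for OTU counts; gamma with log link for strictly
#' positive copy-number responses. Coefficients are maximum-likelihood (IRLS);
#' for the gamma family the shape parameter is additionally estimated by full
#' ML so that the reported log-likelihood and BIC are true ML quantities
#' (the gamma log-link coefficient MLE does not depend on the shape).
#'
#' @param formula Model formula, e.g. `y ~ log_dist + depth_layer`.
#' @param data Data frame; any `depth_layer` column is coded with `"bottom"`
#'   as the reference level.
#' @param family `"poisson_log"` or `"gamma_log"`.
#' @return A `edna_fit`: coefficient table with SEs, shape (gamma),
#'   log-likelihood, n, parameter count k, BIC = k log(n) - 2 logLik,
#'   response-scale fitted values, and pseudo-R² (squared Pearson correlation
#'   of observed and fitted).
#' @export
fit_glm <- function(formula, data, family = c("gamma_log", "poisson_log")) {
  family <- match.arg(family)
  data <- .code_depth(data)
  y <- stats::model.response(stats::model.frame(formula, data))
  if (family == "poisson_log") {
    if (any(y < 0) || any(y != round(y))) {
      stop("poisson family requires non-negative integer response")
    }
    glm_fam <- stats::poisson(link = "log")
  } else {
    if (any(y <= 0)) {
      stop("gamma family requires strictly positive response; ",
           "use fit_gamma_hurdle() for responses containing zeros")
    }
    glm_fam <- stats::Gamma(link = "log")
  }
  fit <- stats::glm(formula, data = data, family = glm_fam)
  if (!fit$converged) stop("GLM did not converge (deviance ",
                           format(fit$deviance), ")")
  lk <- .glm_loglik(fit, family)
  .new_model_fit(family, formula, fit, lk$ll, lk$k, lk$shape, fitted(fit), y)
}

#' Fit a gamma hurdle model
#'
#' Two-part model for non-negative responses with exact zeros: a binomial
#' logit model for presence (y > 0) and a gamma log-link model for the
#' positive magnitudes. The joint log-likelihood is the sum of the two
#' components and k sums their parameter counts (gamma shape included), so
#' the BIC identity holds for the composite. Degenerate inputs (no zeros, or
#' no positives) fall back to the applicable single component with a warning.
#'
#' @param formula Gamma-component formula (response on the left).
#' @param data Data frame.
#' @param binom_formula RHS-only formula for the binomial component; default
#'   `~ 1` (intercept-only presence model).
#' @return A `edna_fit` with `binom_coefficients` and both component fits;
#'   `fitted` is Pr(y>0) x E[y | y>0] on the response scale.
#' @export
fit_gamma_hurdle <- function(formula, data, binom_formula = ~1) {
  data <- .code_depth(data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop("hurdle response must be non-negative")
  pos <- y > 0
  if (all(pos)) {
    warning("no zeros in response; returning plain gamma fit")
    return(fit_glm(formula, data, family = "gamma_log"))
  }
  if (!any(pos)) stop("all-zero response: nothing to fit")

  data$.presence <- as.integer(pos)
  data$.hy <- y # materialise the response so subsetting to positives is safe
  bf <- stats::update(binom_formula, .presence ~ .)
  gf <- stats::update(formula, .hy ~ .)
  fit_b <- stats::glm(bf, data = data, family = stats::binomial())
  fit_g <- stats::glm(gf, data = data[pos, , drop = FALSE],
                      family = stats::Gamma(link = "log"))
  lk_g <- .glm_loglik(fit_g, "gamma_log")
  p_b <- fitted(fit_b)
  ll_b <- sum(stats::dbinom(as.integer(pos), 1, p_b, log = TRUE))
  ll <- ll_b + lk_g$ll
  k <- length(coef(fit_b)) + lk_g$k

  # response-scale fitted values on all rows
  pr_pos <- stats::predict(fit_b, newdata = data, type = "response")
  mu_pos <- exp(stats::predict(fit_g, newdata = data))
  fitted_resp <- pr_pos * mu_pos
  .new_model_fit(
    "gamma_hurdle", formula, fit_g, ll, k, lk_g$shape, fitted_resp, y,
    extra = list(binom_formula = binom_formula,
                 binom_fit = fit_b,
                 binom_coefficients = .coef_table(fit_b),
                 log_likelihood_binom = ll_b,
                 log_likelihood_gamma = lk_g$ll)
  )
}

#' @export
print.edna_fit <- function(x, ...) {
  cat(sprintf("<edna_fit> %s: %s\n", x$family, deparse(x$formula)))
  cat(sprintf("  n = %d, k = %d, logLik = %.2f, BIC = %.2f, pseudo-R² = %.2f\n",
              x$n, x$k, x$log_likelihood, x$bic, x$pseudo_r2))
  print(x$coefficients, digits = 3)
  if (!is.null(x$binom_coefficients)) {
    cat("  binomial component:\n")
    print(x$binom_coefficients, digits = 3)
  }
  invisible(x)
}

# bottom is the reference depth layer throughout
.code_depth <- function(data) {
  if ("depth_layer" %in% names(data)) {
    data$depth_layer <- factor(data$depth_layer, levels = c("bottom", "middle"))
  }
  data
}

#' Likelihood-ratio test for a station (or other factor) effect
#'
#' Compares the intercept-only model to a model with one mean per factor
#' level; -2 (logLik_null - logLik_factor) is referred to a chi-square with
#' (levels - 1) degrees of freedom.
#'
#' @param y Response vector.
#' @param group Factor (>= 2 levels present).
#' @param family `"gamma_log"` or `"poisson_log"`.
#' @return List: `statistic`, `df`, `p_value`, plus both fits.
#' @export
lr_test_factor <- function(y, group, family = c("gamma_log", "poisson_log")) {
  family <- match.arg(family)
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) stop("factor must have >= 2 observed levels")
  d <- data.frame(y = y, group = group)
  fit0 <- fit_glm(y ~ 1, d, family = family)
  fit1 <- fit_glm(y ~ group, d, family = family)
  stat <- 2 * (fit1$log_likelihood - fit0$log_likelihood)
  df <- nlevels(group) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       fit_null = fit0, fit_factor = fit1)
}

#' Tukey-type all-pairs contrasts on a factor fit
#'
#' Wald z statistics for every pairwise difference of factor-level means on
#' the linear-predictor (log) scale, adjusted by the single-step max-|z|
#' method: each p-value is Pr(max_j |Z_j| >= |z_i|) under the joint normal
#' law of the contrasts, evaluated by seeded randomized quasi-Monte-Carlo
#' integration. Holm adjustment is available as a deterministic fallback.
#'
#' @param fit A `edna_fit` from [fit_glm()] whose formula is `y ~ group`.
#' @param method `"single-step"` (default) or `"holm"`.
#' @param seed Seed for the multivariate-normal integration.
#' @return Data frame: `contrast`, `estimate`, `se`, `z`, `p_adjusted`.
#' @export
pairwise_contrasts <- function(fit, method = c("single-step", "holm"),
                               seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "edna_fit"))
  beta <- coef(fit$fit)
  V <- stats::vcov(fit$fit)
  mm <- stats::model.matrix(fit$fit)
  fac <- attr(stats::terms(fit$fit), "term.labels")
  if (length(fac) != 1) stop("fit must have a single factor term")
  lev <- levels(fit$fit$model[[fac]])
  L <- length(lev)
  # level-mean rows on the coefficient basis (treatment coding)
  M <- matrix(0, L, length(beta), dimnames = list(lev, names(beta)))
  M[, "(Intercept)"] <- 1
  for (l in lev[-1]) M[l, paste0(fac, l)] <- 1
  pairs <- utils::combn(L, 2)
  C <- M[pairs[2, ], , drop = FALSE] - M[pairs[1, ], , drop = FALSE]
  rownames(C) <- paste(lev[pairs[2, ]], "-", lev[pairs[1, ]])
  est <- drop(C %*% beta)
  cv <- C %*% V %*% t(C)
  se <- sqrt(diag(cv))
  if (any(se == 0)) stop("singular contrast covariance")
  z <- est / se
  R <- stats::cov2cor(cv)
  if (method == "holm") {
    p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "holm")
  } else {
    set.seed(seed)
    p <- if (nrow(R) == 1) {
      2 * stats::pnorm(-abs(z)) # single contrast: nothing to adjust
    } else {
      vapply(abs(z), function(zi) {
        1 - mvtnorm::pmvnorm(lower = rep(-zi, nrow(R)),
                             upper = rep(zi, nrow(R)), corr = R,
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-4))[1]
      }, numeric(1))
    }
    p <- pmin(pmax(p, 0), 1)
  }
  data.frame(contrast = rownames(C), estimate = est, se = se, z = z,
             p_adjusted = p, row.names = NULL)
}

#' BIC model selection over the hierarchical candidate set
#'
#' Fits the five hierarchical candidates {1; covariate; depth; covariate +
#' depth; covariate + depth + covariate:depth} and returns the minimum-BIC
#' fit with the full ranked table. For the hurdle family, the candidates vary
#' the gamma component; the binomial component is intercept-only by default
#' or mirrors the gamma terms when `binom_policy = "full"`.
#'
#' @param y Response vector.
#' @param data Data frame containing the covariate and `depth_layer`.
#' @param covariate Name of the covariate column (e.g. a [log_distance()]
#'   or [echo_covariate()] transform).
#' @param family `"gamma_log"`, `"poisson_log"` or `"gamma_hurdle"`.
#' @param binom_policy `"intercept"` or `"full"` (hurdle only).
#' @return List: `best` (the minimum-BIC `edna_fit`), `table` (data frame of
#'   candidates ranked by BIC), `fits` (all candidate fits, in candidate
#'   order).
#' @export
bic_select <- function(y, data, covariate, family = c("gamma_log",
                                                      "poisson_log",
                                                      "gamma_hurdle"),
                       binom_policy = c("intercept", "full")) {
  family <- match.arg(family)
  binom_policy <- match.arg(binom_policy)
  stopifnot(covariate %in% names(data), "depth_layer" %in% names(data))
  d <- .code_depth(data)
  d$.y <- y
  rhs <- c("1", covariate, "depth_layer",
           paste(covariate, "+ depth_layer"),
           paste0(covariate, " * depth_layer"))
  labels <- c("intercept", "covariate", "depth", "covariate+depth",
              "covariate+depth+interaction")
  fits <- lapply(rhs, function(r) {
    f <- stats::as.formula(paste(".y ~", r))
    if (family == "gamma_hurdle") {
      bf <- if (binom_policy == "full") stats::as.formula(paste("~", r)) else ~1
      suppressWarnings(fit_gamma_hurdle(f, d, binom_formula = bf))
    } else {
      fit_glm(f, d, family = family)
    }
  })
  tab <- data.frame(
    candidate = labels,
    terms = rhs,
    k = vapply(fits, `[[`, numeric(1), "k"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    bic = vapply(fits, `[[`, numeric(1), "bic")
  )
  ord <- order(tab$bic)
  list(best = fits[[ord[1]]], table = tab[ord, ], fits = fits)
}

#' Predict the expected response from a fitted model
#'
#' Response-scale prediction: exp(linear predictor) for the log-link
#' families; Pr(y > 0) x E[y | y > 0] for the hurdle. Values of the
#' covariate outside the fitted range are allowed but flagged via the
#' `extrapolated` attribute.
#'
#' @param fit A `edna_fit`.
#' @param newdata Data frame of covariate values (and `depth_layer` where the
#'   model uses it).
#' @return Numeric vector of expected responses, with attribute
#'   `extrapolated` (logical per row, where determinable).
#' @export
predict_response <- function(fit, newdata) {
  stopifnot(inherits(fit, "edna_fit"))
  newdata <- .code_depth(newdata)
  mu <- exp(stats::predict(fit$fit, newdata = newdata))
  if (fit$family == "gamma_hurdle") {
    mu <- mu * stats::predict(fit$binom_fit, newdata = newdata,
                              type = "response")
  }
  extrap <- rep(NA, nrow(newdata))
  num_terms <- intersect(names(newdata),
                         names(fit$fit$model)[vapply(fit$fit$model, is.numeric,
                                                     logical(1))])
  if (length(num_terms)) {
    rng <- range(fit$fit$model[[num_terms[1]]])
    extrap <- newdata[[num_terms[1]]] < rng[1] | newdata[[num_terms[1]]] > rng[2]
  }
  attr(mu, "extrapolated") <- extrap
  mu
}
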