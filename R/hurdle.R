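# Zero-altered (hurdle) count models of CPUE
#
# Per-boat lobster counts are modelled in two independent parts: a
# logistic hurdle for P(count > 0) and a zero-truncated Poisson (ZAP) or
# NB2 negative binomial (ZANB) for the positive counts, each on
# NTZ status x pots. The joint likelihood factorises, so the parts are
# maximised separately and combined. Everything is fitted by direct
# maximum likelihood; no model-fitting package is wrapped.

# log(1 - exp(x)) for x <= 0, stable near both ends
.log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# log P(Y = 0) for NB2(mu, theta); theta = Inf is the Poisson limit
.log_f0 <- function(mu, theta) {
  if (is.finite(theta)) -theta * log1p(mu / theta) else -mu
}

.term_col <- function(term, ntz, pots) {
  switch(term,
         intercept = rep(1, length(ntz)),
         ntz = ntz,
         pots = pots,
         ntz_pots = ntz * pots,
         stop_field("terms", paste("unknown term", term)))
}

.build_X <- function(terms, ntz, pots) {
  X <- vapply(terms, .term_col, numeric(length(ntz)), ntz = ntz, pots = pots)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, terms))
  X
}

.check_terms <- function(terms, field) {
  if (terms[1L] != "intercept")
    stop_field(field, "intercept must be present (and first)")
  if ("ntz_pots" %in% terms && !all(c("ntz", "pots") %in% terms))
    stop_field(field, "interaction requires both main effects (marginality)")
  terms
}

#' Design of a hurdle CPUE model
#'
#' Carries the covariates (NTZ open status and pots per boat) and the term
#' sets of the two model parts, plus the count family. Terms come from
#' `intercept`, `ntz`, `pots`, `ntz_pots`; the intercept is mandatory and
#' an interaction requires both main effects.
#'
#' @param ntz_open 0/1 (or logical) NTZ status per boat-day.
#' @param pots numeric pots per boat-day.
#' @param zero_terms,count_terms character term vectors for the hurdle
#'   (zero) and count parts.
#' @param family `"poisson"` (ZAP) or `"negbin"` (ZANB).
#' @return object of class `hurdle_design`.
#' @export
hurdle_design <- function(ntz_open, pots,
                          zero_terms = c("intercept", "ntz", "pots",
                                         "ntz_pots"),
                          count_terms = zero_terms,
                          family = c("negbin", "poisson")) {
  family <- match.arg(family)
  ntz <- as.numeric(ntz_open)
  if (!all(ntz %in% c(0, 1))) stop_field("ntz_open", "must be binary")
  if (length(ntz) != length(pots)) stop_field("pots", "length mismatch")
  if (any(!is.finite(pots)) || any(pots < 0))
    stop_field("pots", "must be finite and non-negative")
  structure(list(ntz = ntz, pots = as.numeric(pots),
                 zero_terms = .check_terms(zero_terms, "zero_terms"),
                 count_terms = .check_terms(count_terms, "count_terms"),
                 X_zero = .build_X(.check_terms(zero_terms, "zero_terms"),
                                   ntz, pots),
                 X_count = .build_X(.check_terms(count_terms, "count_terms"),
                                    ntz, pots),
                 family = family),
            class = "hurdle_design")
}

.check_counts <- function(counts) {
  if (!is_count(counts))
    stop_field("counts", "must be non-negative integers")
  counts
}

#' Hurdle model log-likelihood
#'
#' Joint log-likelihood of the two-part model:
#' zeros contribute `log(1 - pi_i)`; positives contribute
#' `log(pi_i) + log f(y_i; mu_i, theta) - log(1 - f(0; mu_i, theta))`
#' with `pi_i = plogis(X_zero b_zero)` and `mu_i = exp(X_count b_count)`.
#' All terms are evaluated in log space.
#'
#' @param params numeric vector: zero-part coefficients, then count-part
#'   coefficients, then `log(theta)` if the family is `negbin`.
#' @param counts non-negative integer response.
#' @param design a [hurdle_design()].
#' @return scalar log-likelihood.
#' @export
hurdle_loglik <- function(params, counts, design) {
  stopifnot(inherits(design, "hurdle_design"))
  counts <- .check_counts(counts)
  pz <- ncol(design$X_zero); pc <- ncol(design$X_count)
  need <- pz + pc + (design$family == "negbin")
  if (length(params) != need)
    stop_field("params", sprintf("expected %d parameters, got %d", need,
                                 length(params)))
  bz <- params[seq_len(pz)]
  bc <- params[pz + seq_len(pc)]
  theta <- if (design$family == "negbin") exp(params[need]) else Inf
  eta_z <- drop(design$X_zero %*% bz)
  pos <- counts > 0
  # binomial part via plogis on the log scale: log pi, log(1 - pi)
  ll <- sum(stats::plogis(eta_z[!pos], lower.tail = FALSE, log.p = TRUE)) +
    sum(stats::plogis(eta_z[pos], log.p = TRUE))
  if (any(pos)) {
    mu <- exp(drop(design$X_count[pos, , drop = FALSE] %*% bc))
    y <- counts[pos]
    ld <- if (is.finite(theta))
      stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
    else stats::dpois(y, mu, log = TRUE)
    ll <- ll + sum(ld - .log1mexp(.log_f0(mu, theta)))
  }
  ll
}

.fit_part <- function(nll, start, label) {
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  H <- stats::optimHess(opt$par, nll)
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  se <- rep(NA_real_, length(start))
  if (!is.null(vcov)) {
    d <- diag(vcov)
    se[d > 0] <- sqrt(d[d > 0])
  }
  list(par = opt$par, loglik = -opt$value, se = se,
       converged = opt$convergence == 0L, label = label)
}

#' Fit a hurdle model by maximum likelihood
#'
#' The two parts have orthogonal likelihoods and are maximised
#' separately: the hurdle part is a logistic regression of `count > 0`,
#' and the count part a zero-truncated Poisson or NB2 regression of the
#' positive counts (dispersion estimated on the log scale, warm-started
#' from a Poisson fit). Standard errors come from the observed
#' information. Perfect separation in the zero part is detected and
#' reported on the fit.
#'
#' @param counts non-negative integer response.
#' @param design a [hurdle_design()].
#' @return object of class `hurdle_fit` with coefficient vectors and
#'   standard errors per part, `theta`, `loglik`, `aic`, `n_params`,
#'   `converged`, and per-observation `fitted_zero_probs` and
#'   `fitted_conditional_means`.
#' @export
fit_hurdle <- function(counts, design) {
  stopifnot(inherits(design, "hurdle_design"))
  counts <- .check_counts(counts)
  pos <- counts > 0
  if (!any(pos)) stop("all counts are zero: nothing to fit in the count part",
                      call. = FALSE)
  if (all(pos)) stop("no zero counts: the hurdle part is degenerate",
                     call. = FALSE)
  Xz <- design$X_zero
  y01 <- as.numeric(pos)
  nll_zero <- function(b) {
    eta <- drop(Xz %*% b)
    -(sum(stats::plogis(eta[pos], log.p = TRUE)) +
        sum(stats::plogis(eta[!pos], lower.tail = FALSE, log.p = TRUE)))
  }
  zero <- .fit_part(nll_zero, rep(0, ncol(Xz)), "zero")
  separation <- any(abs(zero$par) > 12) &&
    nll_zero(zero$par) < 1e-6 * length(counts)
  if (separation)
    warning("possible complete separation in the zero part; ",
            "coefficients unbounded", call. = FALSE)

  Xc <- design$X_count[pos, , drop = FALSE]
  y <- counts[pos]
  # Poisson warm start for the count-part coefficients
  warm <- tryCatch(
    stats::glm.fit(Xc, y, family = stats::poisson())$coefficients,
    error = function(e) rep(0, ncol(Xc)))
  warm[!is.finite(warm)] <- 0
  negbin <- design$family == "negbin"
  nll_count <- function(p) {
    b <- p[seq_len(ncol(Xc))]
    # log-theta clamped: beyond ~e^30 the NB is numerically Poisson
    theta <- if (negbin) exp(min(p[length(p)], 30)) else Inf
    mu <- exp(drop(Xc %*% b))
    if (any(!is.finite(mu))) return(1e10)  # line-search excursions
    ld <- if (is.finite(theta))
      stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
    else stats::dpois(y, mu, log = TRUE)
    v <- -sum(ld - .log1mexp(.log_f0(mu, theta)))
    if (!is.finite(v)) 1e10 else v
  }
  # two dispersion starts: theta near 1 and near the Poisson limit, so
  # equidispersed data does not strand the optimiser at moderate theta
  count <- if (negbin) {
    fits <- lapply(c(0, 6, 12), function(lt)
      .fit_part(nll_count, c(warm, lt), "count"))
    fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1L)))]]
  } else {
    .fit_part(nll_count, warm, "count")
  }

  bz <- stats::setNames(zero$par, design$zero_terms)
  k <- ncol(Xc)
  bc <- stats::setNames(count$par[seq_len(k)], design$count_terms)
  theta <- if (negbin) exp(min(count$par[k + 1L], 30)) else Inf
  n_params <- length(bz) + k + negbin
  loglik <- zero$loglik + count$loglik
  pi_hat <- stats::plogis(drop(design$X_zero %*% zero$par))
  mu_hat <- exp(drop(design$X_count %*% bc))
  structure(list(
    zero_coefs = bz, zero_se = stats::setNames(zero$se, design$zero_terms),
    count_coefs = bc,
    count_se = stats::setNames(count$se[seq_len(k)], design$count_terms),
    theta = theta,
    log_theta_se = if (negbin) count$se[k + 1L] else NA_real_,
    loglik = loglik, aic = 2 * n_params - 2 * loglik, n_params = n_params,
    converged = zero$converged && count$converged,
    separation = separation,
    fitted_zero_probs = pi_hat, fitted_conditional_means = mu_hat,
    counts = counts, design = design),
    class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  fam <- if (is.finite(x$theta)) "zero-altered negative binomial (ZANB)"
  else "zero-altered Poisson (ZAP)"
  cat(sprintf("%s, n = %d\n", fam, length(x$counts)))
  cat(sprintf("logLik %.3f, AIC %.3f, params %d, converged: %s\n",
              x$loglik, x$aic, x$n_params, x$converged))
  cat("zero part (logit P(count>0)):\n")
  print(round(rbind(estimate = x$zero_coefs, se = x$zero_se), 4))
  cat("count part (log conditional mean):\n")
  print(round(rbind(estimate = x$count_coefs, se = x$count_se), 4))
  if (is.finite(x$theta)) cat(sprintf("dispersion theta = %.4f\n", x$theta))
  invisible(x)
}

#' Coefficient table of a hurdle fit
#'
#' @param fit a `hurdle_fit`.
#' @return data.frame with part, term, estimate, se, z, p.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  tab <- rbind(
    data.frame(part = "zero", term = names(fit$zero_coefs),
               estimate = unname(fit$zero_coefs), se = unname(fit$zero_se)),
    data.frame(part = "count", term = names(fit$count_coefs),
               estimate = unname(fit$count_coefs), se = unname(fit$count_se)))
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  tab
}

.is_nested <- function(fit_full, fit_reduced) {
  df <- fit_full$design; dr <- fit_reduced$design
  same_data <- identical(df$ntz, dr$ntz) && identical(df$pots, dr$pots)
  terms_nested <- all(dr$zero_terms %in% df$zero_terms) &&
    all(dr$count_terms %in% df$count_terms)
  family_ok <- df$family == dr$family ||
    (df$family == "negbin" && dr$family == "poisson")
  same_data && terms_nested && family_ok
}

#' Likelihood-ratio test between nested hurdle fits
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` referred to a chi-squared
#' distribution with the difference in parameter counts as degrees of
#' freedom. For the ZANB-vs-ZAP comparison the dispersion sits on the
#' boundary of its space; `boundary = TRUE` uses the 50:50
#' chi2(0):chi2(1) mixture instead of the plain chi2(1).
#'
#' @param fit_full,fit_reduced nested `hurdle_fit` objects on the same
#'   data.
#' @param boundary use the boundary-corrected mixture p-value.
#' @return list of class `lrt_result`: `chi2`, `df`, `p_value`.
#' @export
lrt <- function(fit_full, fit_reduced, boundary = FALSE) {
  stopifnot(inherits(fit_full, "hurdle_fit"),
            inherits(fit_reduced, "hurdle_fit"))
  if (!.is_nested(fit_full, fit_reduced))
    stop("models are not nested on the same data", call. = FALSE)
  chi2 <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (chi2 < -0.01)
    warning("reduced model out-fits the full model; optimiser artefact",
            call. = FALSE)
  chi2 <- max(chi2, 0)
  df <- fit_full$n_params - fit_reduced$n_params
  p <- stats::pchisq(chi2, df = max(df, 1L), lower.tail = FALSE)
  if (boundary) p <- p / 2
  structure(list(chi2 = chi2, df = df, p_value = p), class = "lrt_result")
}

#' Chi-squared upper-tail p-value for a reported LRT statistic
#'
#' Maps a likelihood-ratio chi-squared statistic and its degrees of
#' freedom to a p-value (e.g. chi2 = 9.710 on 1 df gives p = 0.0018,
#' printed as 0.002).
#'
#' @param chi2 non-negative statistic.
#' @param df degrees of freedom.
#' @return p-value.
#' @export
lrt_pvalue <- function(chi2, df = 1L) {
  if (chi2 < 0) stop_field("chi2", "must be non-negative")
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Choose between ZAP and ZANB on the same design
#'
#' Fits both families with identical term sets and keeps the negative
#' binomial only if it has the lower AIC and the dispersion
#' likelihood-ratio test (1 df) is significant at `alpha`; otherwise the
#' more parsimonious Poisson is kept (ties go to ZAP).
#'
#' @param counts response.
#' @param design a [hurdle_design()]; its family field is ignored.
#' @param alpha significance level for the dispersion LRT.
#' @param boundary passed to [lrt()].
#' @return list `family`, `fit` (chosen), `fit_zap`, `fit_zanb`, `lrt`.
#' @export
select_family <- function(counts, design, alpha = 0.05, boundary = FALSE) {
  dz <- hurdle_design(design$ntz, design$pots, design$zero_terms,
                      design$count_terms, family = "poisson")
  dn <- hurdle_design(design$ntz, design$pots, design$zero_terms,
                      design$count_terms, family = "negbin")
  fit_zap <- fit_hurdle(counts, dz)
  fit_zanb <- fit_hurdle(counts, dn)
  test <- lrt(fit_zanb, fit_zap, boundary = boundary)
  use_nb <- fit_zanb$aic < fit_zap$aic && test$p_value < alpha
  list(family = if (use_nb) "negbin" else "poisson",
       fit = if (use_nb) fit_zanb else fit_zap,
       fit_zap = fit_zap, fit_zanb = fit_zanb, lrt = test)
}

.droppable <- function(terms) {
  if ("ntz_pots" %in% terms) return("ntz_pots")  # marginality: interaction first
  setdiff(terms, "intercept")
}

#' Stepwise simplification to the minimum adequate model
#'
#' Starting from a full fit, repeatedly refits with each droppable term
#' removed (the interaction before its main effects) from each part
#' independently, and drops the term whose likelihood-ratio p-value is
#' largest, provided it exceeds `alpha`. Stops when every remaining
#' droppable term is significant; if the interaction is significant in
#' both parts the full model is the minimum adequate model.
#'
#' @param fit a `hurdle_fit` of the full model.
#' @param alpha retention threshold (default 0.05).
#' @return the simplified `hurdle_fit`, with a `simplification_path`
#'   attribute recording each drop (part, term, chi2, df, p).
#' @export
stepwise_simplify <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "hurdle_fit"))
  path <- list()
  repeat {
    des <- fit$design
    cands <- rbind(
      if (length(.droppable(des$zero_terms)))
        data.frame(part = "zero", term = .droppable(des$zero_terms)),
      if (length(.droppable(des$count_terms)))
        data.frame(part = "count", term = .droppable(des$count_terms)))
    if (is.null(cands) || !nrow(cands)) break
    best <- NULL
    for (i in seq_len(nrow(cands))) {
      zt <- des$zero_terms; ct <- des$count_terms
      if (cands$part[i] == "zero") zt <- setdiff(zt, cands$term[i])
      else ct <- setdiff(ct, cands$term[i])
      red <- fit_hurdle(fit$counts,
                        hurdle_design(des$ntz, des$pots, zt, ct, des$family))
      test <- lrt(fit, red)
      if (is.null(best) || test$p_value > best$p) {
        best <- list(fit = red, p = test$p_value, chi2 = test$chi2,
                     df = test$df, part = cands$part[i],
                     term = cands$term[i])
      }
    }
    if (best$p <= alpha) break
    path[[length(path) + 1L]] <- data.frame(
      part = best$part, term = best$term, chi2 = best$chi2, df = best$df,
      p = best$p)
    fit <- best$fit
  }
  attr(fit, "simplification_path") <-
    if (length(path)) do.call(rbind, path) else
      data.frame(part = character(), term = character(), chi2 = numeric(),
                 df = integer(), p = numeric())
  fit
}

.unconditional_mean <- function(pi, mu, theta) {
  # pi * mu / (1 - f0); pi = 0 short-circuits so mu is irrelevant there
  f0 <- exp(.log_f0(mu, theta))
  ifelse(pi == 0, 0, pi * mu / (1 - f0))
}

#' Expected catch per boat-day from a hurdle fit
#'
#' Unconditional hurdle mean `pi * mu / (1 - f(0; mu, theta))` at given
#' covariates; used e.g. for CPUE standardised to a reference pot number.
#'
#' @param fit a converged `hurdle_fit`.
#' @param ntz_open 0/1 NTZ status.
#' @param pots pots per boat.
#' @return expected lobsters per boat-day.
#' @export
predict_cpue <- function(fit, ntz_open, pots) {
  stopifnot(inherits(fit, "hurdle_fit"))
  if (!fit$converged) stop("fit did not converge; refusing to predict",
                           call. = FALSE)
  ntz <- as.numeric(ntz_open)
  n <- max(length(ntz), length(pots))
  ntz <- rep_len(ntz, n); pots <- rep_len(as.numeric(pots), n)
  Xz <- .build_X(fit$design$zero_terms, ntz, pots)
  Xc <- .build_X(fit$design$count_terms, ntz, pots)
  pi <- stats::plogis(drop(Xz %*% fit$zero_coefs))
  mu <- exp(drop(Xc %*% fit$count_coefs))
  .unconditional_mean(pi, mu, fit$theta)
}

#' Pearson residuals against unconditional fitted means
#'
#' Residuals `(y - E[Y]) / sqrt(Var[Y])` under the fitted hurdle
#' distribution, for residual-vs-fitted model validation plots.
#'
#' @param fit a converged `hurdle_fit`.
#' @return data.frame `fitted`, `residual`.
#' @export
residuals_vs_fitted <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  pi <- fit$fitted_zero_probs
  mu <- fit$fitted_conditional_means
  theta <- fit$theta
  f0 <- exp(.log_f0(mu, theta))
  m1 <- .unconditional_mean(pi, mu, theta)
  ey2_parent <- if (is.finite(theta)) mu + mu^2 / theta + mu^2 else mu + mu^2
  m2 <- ifelse(pi == 0, 0, pi * ey2_parent / (1 - f0))
  v <- pmax(m2 - m1^2, 0)
  data.frame(fitted = m1,
             residual = ifelse(v > 0, (fit$counts - m1) / sqrt(v), 0))
}
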