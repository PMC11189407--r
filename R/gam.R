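# Penalized binomial logistic additive model engine: PIRLS inner loop,
# smoothing-parameter selection by Laplace-approximate REML (or GCV),
# effective degrees of freedom, Wald tests of smooth terms, and centred
# effect curves with pointwise confidence bands.

binomial_deviance <- function(girls, total, mu) {
  y <- girls / total
  term <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  2 * sum(term(girls, total * mu) + term(total - girls, total * (1 - mu)))
}

#' Penalized iteratively reweighted least squares for binomial counts
#'
#' Fits `logit P(girl) = X beta` by maximising the binomial log-likelihood of
#' monthly (successes, totals) aggregates minus the quadratic penalty
#' `sum_j lambda_j beta' S_j beta / 2`, iterating weighted least squares to
#' convergence of the penalized deviance.
#'
#' @param X Model matrix (n x p).
#' @param penalties List of p x p penalty matrices (zero outside each term's
#'   block); may be empty for an unpenalized fit.
#' @param lambda Numeric vector of smoothing parameters, one per penalty.
#' @param successes,totals Integer vectors: girl counts and total births per
#'   row; `0 <= successes <= totals`.
#' @param tol Relative penalized-deviance convergence tolerance (default
#'   1e-8).
#' @param maxit Maximum number of iterations (default 200).
#' @return List of class `"pirls_fit"`: `beta`, `H` (penalized information
#'   `X'WX + S_lambda`), `XtWX`, `deviance`, `penalized_deviance`, `loglik`,
#'   `mu`, `eta`, `weights`, `converged`, `iterations`.
#' @export
fit_pirls <- function(X, penalties, lambda, successes, totals,
                      tol = 1e-8, maxit = 200L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(penalties) != length(lambda))
    stop_ssr("`lambda` must have one entry per penalty")
  if (any(successes < 0) || any(successes > totals))
    stop_ssr("need 0 <= successes <= totals")
  S_lambda <- matrix(0, p, p)
  for (j in seq_along(penalties)) S_lambda <- S_lambda + lambda[j] * penalties[[j]]
  mu <- (successes + 0.5) / (totals + 1)
  eta <- stats::qlogis(mu)
  beta <- NULL
  pdev_old <- Inf
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    w <- totals * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (successes / totals - mu) / (mu * (1 - mu))
    XtW <- t(X * w)
    H <- XtW %*% X + S_lambda
    beta_new <- tryCatch(solve(H, XtW %*% z),
                         error = function(e) qr.solve(H, XtW %*% z))
    eta_new <- as.numeric(X %*% beta_new)
    mu_new <- stats::plogis(eta_new)
    dev <- binomial_deviance(successes, totals, mu_new)
    pdev <- dev + as.numeric(t(beta_new) %*% S_lambda %*% beta_new)
    # step-halve if the penalized deviance worsened (rare, but keeps the
    # aggregated-likelihood iteration monotone)
    if (!is.finite(pdev) || (pdev > pdev_old + 1e-10 && !is.null(beta))) {
      step <- 1
      repeat {
        step <- step / 2
        if (step < 1e-8) break
        beta_try <- beta + step * (beta_new - beta)
        eta_try <- as.numeric(X %*% beta_try)
        mu_try <- stats::plogis(eta_try)
        dev_try <- binomial_deviance(successes, totals, mu_try)
        pdev_try <- dev_try + as.numeric(t(beta_try) %*% S_lambda %*% beta_try)
        if (is.finite(pdev_try) && pdev_try <= pdev_old) {
          beta_new <- beta_try; eta_new <- eta_try; mu_new <- mu_try
          dev <- dev_try; pdev <- pdev_try
          break
        }
      }
    }
    beta <- beta_new; eta <- eta_new; mu <- mu_new
    if (is.finite(pdev_old) &&
        abs(pdev_old - pdev) < tol * (abs(pdev) + 0.1)) {
      converged <- TRUE
      pdev_old <- pdev
      break
    }
    pdev_old <- pdev
  }
  w <- totals * mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(pmax(w, 0)))
  H <- XtWX + S_lambda
  loglik <- sum(stats::dbinom(successes, totals, mu, log = TRUE))
  structure(list(beta = as.numeric(beta), H = H, XtWX = XtWX,
                 S_lambda = S_lambda,
                 deviance = binomial_deviance(successes, totals, mu),
                 penalized_deviance = pdev_old, loglik = loglik,
                 mu = mu, eta = eta, weights = w,
                 converged = converged, iterations = iter),
            class = "pirls_fit")
}

# Log generalized determinant of the block-diagonal total penalty
# sum_j lambda_j S_j, where blocks do not overlap: sum over blocks of
# rank_j * log(lambda_j) + log pseudo-determinant of S_j.
log_det_penalty <- function(penalties, lambda, block_ranks, block_logdets) {
  sum(block_ranks * log(lambda)) + sum(block_logdets)
}

penalty_block_info <- function(penalties) {
  ranks <- numeric(length(penalties))
  logdets <- numeric(length(penalties))
  for (j in seq_along(penalties)) {
    ev <- eigen(penalties[[j]], symmetric = TRUE, only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-9
    ranks[j] <- sum(pos)
    logdets[j] <- sum(log(ev[pos]))
  }
  list(ranks = ranks, logdets = logdets)
}

# Negative Laplace-approximate REML criterion at log-lambda rho.
laml_criterion <- function(rho, X, penalties, successes, totals, binfo,
                           p_total) {
  lambda <- exp(rho)
  fit <- fit_pirls(X, penalties, lambda, successes, totals)
  ld_pen <- log_det_penalty(penalties, lambda, binfo$ranks, binfo$logdets)
  ch <- tryCatch(chol(fit$H), error = function(e) NULL)
  if (is.null(ch)) return(list(value = Inf, fit = fit))
  ld_H <- 2 * sum(log(diag(ch)))
  null_dim <- p_total - sum(binfo$ranks)  # unpenalized coefficient count
  pen <- as.numeric(t(fit$beta) %*% fit$S_lambda %*% fit$beta)
  laml <- fit$loglik - pen / 2 + ld_pen / 2 - ld_H / 2 +
    null_dim * log(2 * pi) / 2
  list(value = -laml, fit = fit)
}

gcv_criterion <- function(rho, X, penalties, successes, totals) {
  lambda <- exp(rho)
  fit <- fit_pirls(X, penalties, lambda, successes, totals)
  edf <- sum(diag(solve(fit$H, fit$XtWX)))
  n <- length(successes)
  list(value = n * fit$deviance / (n - edf)^2, fit = fit)
}

#' Select smoothing parameters by REML or GCV
#'
#' Minimises the chosen criterion over log smoothing parameters by
#' Nelder-Mead (with a derivative-free restart if the first optimum looks
#' flat).
#'
#' @inheritParams fit_pirls
#' @param criterion `"REML"` (Laplace-approximate restricted marginal
#'   likelihood; default) or `"GCV"`.
#' @param init Initial log-lambda vector (default 0 for every penalty).
#' @param restarts Number of additional optimizer starts (default 1).
#' @return List: `lambda`, `criterion`, `value` (criterion at the optimum),
#'   `trace` (evaluation count), `convergence` (optimizer code).
#' @export
select_smoothing <- function(X, penalties, successes, totals,
                             criterion = c("REML", "GCV"),
                             init = NULL, restarts = 1L) {
  criterion <- match.arg(criterion)
  m <- length(penalties)
  if (m == 0)
    return(list(lambda = numeric(0), criterion = criterion, value = NA_real_,
                trace = 0L, convergence = 0L))
  binfo <- penalty_block_info(penalties)
  p_total <- ncol(X)
  evals <- 0L
  obj <- function(rho) {
    rho <- pmin(pmax(rho, -25), 25)
    evals <<- evals + 1L
    if (criterion == "REML")
      laml_criterion(rho, X, penalties, successes, totals, binfo, p_total)$value
    else
      gcv_criterion(rho, X, penalties, successes, totals)$value
  }
  starts <- list(init %||% rep(0, m))
  if (restarts >= 1) starts <- c(starts, list(rep(4, m)))
  if (restarts >= 2) starts <- c(starts, list(rep(-4, m)))
  best <- NULL
  for (s in starts) {
    opt <- if (m == 1) {
      o <- stats::optimize(function(r) obj(r), interval = c(-25, 25))
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-8))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value))
    stop_ssr("smoothing-parameter optimization failed (criterion ",
             criterion, " non-finite); trace: ", evals, " evaluations")
  list(lambda = exp(pmin(pmax(best$par, -25), 25)),
       criterion = criterion, value = best$value, trace = evals,
       convergence = best$convergence %||% 0L)
}

# ---- full model assembly -------------------------------------------------

# Build the complete design from parametric columns + smooth specs.
# Returns X, penalties (full-size), and a term map.
assemble_design <- function(frame, smooth_specs, parametric = NULL) {
  n <- nrow(frame)
  X_par <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(parametric)) {
    parametric <- as.matrix(parametric)
    if (is.null(colnames(parametric)))
      colnames(parametric) <- paste0("par_", seq_len(ncol(parametric)))
    X_par <- cbind(X_par, parametric)
  }
  blocks <- list(X_par)
  term_map <- list(`(parametric)` = seq_len(ncol(X_par)))
  bases <- list()
  penalties <- list()
  col_at <- ncol(X_par)
  for (spec in smooth_specs) {
    x <- frame[[spec$covariate]]
    if (is.null(x)) stop_ssr("frame has no column '", spec$covariate, "'")
    b <- center_basis(build_basis(spec, x))
    p_j <- ncol(b$Xc)
    cols <- col_at + seq_len(p_j)
    term_map[[paste0("s(", spec$covariate, ")")]] <- cols
    bases[[paste0("s(", spec$covariate, ")")]] <- b
    blocks <- c(blocks, list(b$Xc))
    penalties <- c(penalties, list(list(cols = cols, S = b$Sc)))
    col_at <- col_at + p_j
  }
  X <- do.call(cbind, blocks)
  p <- ncol(X)
  full_pens <- lapply(penalties, function(pen) {
    S <- matrix(0, p, p)
    S[pen$cols, pen$cols] <- pen$S
    S
  })
  smooth_names <- names(term_map)[-1]
  colnames(X) <- c(colnames(X_par),
                   unlist(lapply(smooth_names, function(nm)
                     paste0(nm, ".", seq_along(term_map[[nm]])))))
  list(X = X, penalties = full_pens, term_map = term_map, bases = bases,
       n_par = ncol(X_par))
}

#' Fit a penalized-spline binomial logistic additive model
#'
#' The workhorse behind [fit_m0()], [fit_mt0()] and [fit_mta()]: assembles
#' the design from parametric columns and smooth-term specifications, selects
#' smoothing parameters by REML (or GCV), and returns the fitted model with
#' Bayesian coefficient covariance and per-term effective degrees of freedom.
#'
#' @param frame Model frame tibble containing `girls`, `total` and every
#'   covariate named by the smooths.
#' @param smooths List of [smooth_spec()] objects (may be empty).
#' @param parametric Optional numeric matrix of extra parametric columns
#'   (e.g. a folded distributed-lag block), one row per frame row.
#' @param criterion Smoothness selection criterion, `"REML"` or `"GCV"`.
#' @param lambda Optional fixed smoothing-parameter vector (one per smooth);
#'   when supplied, no selection is performed.
#' @param girls_col,total_col Column names of the response counts.
#' @return An object of class `"ssr_gam"`; see [tidy.ssr_gam()],
#'   [glance.ssr_gam()], [effective_dof()], [smooth_pvalue()],
#'   [predict_effect()].
#' @export
ssr_gam <- function(frame, smooths = list(), parametric = NULL,
                    criterion = c("REML", "GCV"), lambda = NULL,
                    girls_col = "girls", total_col = "total") {
  criterion <- match.arg(criterion)
  if (nrow(frame) == 0L) stop_ssr("empty model frame")
  girls <- frame[[girls_col]]
  total <- frame[[total_col]] %||% (frame$boys + frame$girls)
  des <- assemble_design(frame, smooths, parametric)
  if (is.null(lambda) && length(des$penalties) > 0) {
    sel <- select_smoothing(des$X, des$penalties, girls, total,
                            criterion = criterion)
    lambda <- sel$lambda
    crit_value <- sel$value
  } else {
    lambda <- lambda %||% numeric(0)
    crit_value <- NA_real_
  }
  fit <- fit_pirls(des$X, des$penalties, lambda, girls, total)
  if (!fit$converged)
    warning("PIRLS did not converge in ", fit$iterations, " iterations; ",
            "penalized deviance ", format(fit$penalized_deviance),
            call. = FALSE)
  Vp <- solve(fit$H)                      # Bayesian posterior covariance
  Ve <- Vp %*% fit$XtWX %*% Vp            # frequentist covariance of beta-hat
  Fmat <- Vp %*% fit$XtWX                 # edf matrix
  edf_col <- diag(Fmat)
  edf1_col <- 2 * edf_col - diag(Fmat %*% Fmat)
  terms <- names(des$term_map)
  edf_by_term <- vapply(terms, function(t) sum(edf_col[des$term_map[[t]]]),
                        numeric(1))
  edf1_by_term <- vapply(terms, function(t) sum(edf1_col[des$term_map[[t]]]),
                         numeric(1))
  smooth_names <- setdiff(terms, "(parametric)")
  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(des$X)),
    Vp = Vp, Ve = Ve, XtWX = fit$XtWX,
    lambda = stats::setNames(lambda, smooth_names),
    edf_by_term = edf_by_term, edf1_by_term = edf1_by_term,
    edf_total = sum(edf_col),
    deviance = fit$deviance, loglik = fit$loglik,
    null_deviance = binomial_deviance(girls, total,
                                      rep(sum(girls) / sum(total), length(girls))),
    criterion = criterion, criterion_value = crit_value,
    converged = fit$converged,
    fitted = fit$mu, linear_predictor = fit$eta,
    girls = girls, total = total,
    design = des, frame = frame,
    n = nrow(frame)),
    class = "ssr_gam")
}

#' @export
print.ssr_gam <- function(x, ...) {
  cat("Penalized-spline binomial logistic additive model\n")
  cat(sprintf("  n = %d months, deviance = %.2f, total edf = %.2f (%s)\n",
              x$n, x$deviance, x$edf_total, x$criterion))
  sm <- setdiff(names(x$edf_by_term), "(parametric)")
  for (t in sm)
    cat(sprintf("  %s: edf %.3f, lambda %.3g\n", t, x$edf_by_term[[t]],
                x$lambda[[t]]))
  invisible(x)
}

#' Effective degrees of freedom of model terms
#'
#' Trace of the term's block of the influence matrix
#' `(X'WX + S_lambda)^{-1} X'WX`. Parametric (unpenalized) columns contribute
#' exactly 1 each; a fully shrunk smooth approaches 0.
#'
#' @param fit An [ssr_gam()] fit.
#' @param term Term name (e.g. `"s(birth_year)"` or `"(parametric)"`), or
#'   `NULL` for all terms.
#' @return Named numeric vector (or scalar when `term` is given).
#' @export
effective_dof <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "ssr_gam"))
  if (is.null(term)) return(fit$edf_by_term)
  if (!term %in% names(fit$edf_by_term))
    stop_ssr("unknown term '", term, "'; available: ",
             paste(names(fit$edf_by_term), collapse = ", "))
  fit$edf_by_term[[term]]
}

# Rank-r pseudo-inverse quadratic form (Wald statistic for a smooth block).
wald_stat <- function(beta, V, r) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  r <- max(1L, min(length(beta), as.integer(round(r))))
  if (max(eg$values) <= 0) return(list(stat = 0, rank = r))
  vals <- pmax(eg$values[seq_len(r)], max(eg$values) * 1e-12)
  u <- crossprod(eg$vectors[, seq_len(r), drop = FALSE], beta)
  list(stat = sum(u^2 / vals), rank = r)
}

#' Wald-type test of a smooth term against zero
#'
#' Tests the hypothesis that the smooth is identically zero using the term's
#' coefficients and the frequentist covariance of the penalized estimator: a
#' rank-r pseudo-inverse quadratic form, with r the term's bias-corrected
#' effective degrees of freedom rounded to the nearest integer (at least 1),
#' referred to a chi-squared distribution on r degrees of freedom. Using the
#' estimator's sampling covariance rather than the Bayesian one keeps the
#' test's null rejection rate close to nominal even for heavily penalized
#' terms; the test remains approximate and can run slightly above level.
#'
#' @param fit An [ssr_gam()] fit.
#' @param term Smooth term name, e.g. `"s(birth_month)"`.
#' @return One-row tibble: `term`, `statistic`, `df`, `p_value`.
#' @export
smooth_pvalue <- function(fit, term) {
  stopifnot(inherits(fit, "ssr_gam"))
  cols <- fit$design$term_map[[term]]
  if (is.null(cols) || term == "(parametric)")
    stop_ssr("unknown smooth term '", term, "'")
  beta <- fit$coefficients[cols]
  V <- fit$Ve[cols, cols, drop = FALSE]
  if (any(!is.finite(V)))
    stop_ssr("degenerate covariance for term '", term, "'")
  edf1 <- fit$edf1_by_term[[term]]
  ws <- wald_stat(beta, V, edf1)
  p <- stats::pchisq(ws$stat, df = ws$rank, lower.tail = FALSE)
  tibble::tibble(term = term, statistic = ws$stat, df = ws$rank,
                 p_value = p)
}

#' Centred partial-effect curve with pointwise 95% band
#'
#' Evaluates a smooth term's centred effect on the logit scale over a grid,
#' with +/- 1.96 standard-error pointwise bands from the Bayesian coefficient
#' covariance; optionally translated to the probability scale around the
#' model intercept.
#'
#' @param fit An [ssr_gam()] fit.
#' @param term Smooth term name.
#' @param grid Covariate values at which to evaluate (default: 100 points
#'   over the observed range). Values outside the observed range trigger a
#'   warning.
#' @param scale `"logit"` (centred partial effect; default) or
#'   `"probability"` (`plogis(intercept + effect)`, other terms at their
#'   centred zero).
#' @return Tibble: covariate value `x`, `effect`, `se`, `lower`, `upper`.
#' @export
predict_effect <- function(fit, term, grid = NULL,
                           scale = c("logit", "probability")) {
  stopifnot(inherits(fit, "ssr_gam"))
  scale <- match.arg(scale)
  b <- fit$design$bases[[term]]
  if (is.null(b)) stop_ssr("unknown smooth term '", term, "'")
  rng <- b$x_range
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 100)
  if (any(grid < rng[1] | grid > rng[2]))
    warning("grid extends beyond the observed covariate range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  Xg <- b$eval_fun(grid) %*% b$Z
  cols <- fit$design$term_map[[term]]
  beta <- fit$coefficients[cols]
  V <- fit$Vp[cols, cols, drop = FALSE]
  eff <- as.numeric(Xg %*% beta)
  se <- sqrt(pmax(rowSums((Xg %*% V) * Xg), 0))
  out <- tibble::tibble(x = grid, effect = eff, se = se,
                        lower = eff - 1.96 * se, upper = eff + 1.96 * se)
  if (scale == "probability") {
    a <- fit$coefficients[["(Intercept)"]]
    out$effect <- stats::plogis(a + out$effect)
    out$lower <- stats::plogis(a + eff - 1.96 * se)
    out$upper <- stats::plogis(a + eff + 1.96 * se)
    out$se <- NA_real_
  }
  attr(out, "term") <- term
  out
}
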