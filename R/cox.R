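#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood with the Breslow approximation for
#' tied event times, by Newton-Raphson from beta = 0 with step-halving,
#' stopping when the gradient norm falls below `tol` (default 1e-8) or after
#' `max_iter` iterations. Monotone likelihood (perfect separation of the
#' risk sets, recognisable as a diverging coefficient) is flagged on the
#' returned object rather than raised as an error.
#'
#' @param x covariate matrix (subjects x p) or vector; constant columns are
#'   an error.
#' @param time,event survival outcome (days; 1 = death, 0 = censored).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton-Raphson iteration cap.
#' @return object of class `pme_cox`: `coefficients`, `se`, `z`, `p_value`
#'   (Wald), `loglik` (null and fitted), `linear_predictor` (sum of beta * x
#'   per subject, uncentered), `iterations`, `converged`, `flagged` (TRUE on
#'   non-convergence or monotone likelihood).
#' @export
cox_fit <- function(x, time, event, tol = 1e-8, max_iter = 100) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  check_surv(time, event)
  if (nrow(x) != length(time)) stop("dimension mismatch")
  if (anyNA(x)) stop("missing covariate values")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant covariate column")
  if (sum(event) < ncol(x))
    stop("fewer events than covariates")
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  ord <- order(time)
  xo <- x[ord, , drop = FALSE]
  to <- time[ord]; eo <- event[ord]
  et <- sort(unique(to[eo == 1]))
  ## index sets reused every iteration
  risk_idx <- lapply(et, function(t) which(to >= t))
  death_idx <- lapply(et, function(t) which(to == t & eo == 1))

  pll <- function(beta) {
    eta <- drop(xo %*% beta)
    w <- exp(eta)
    ll <- 0
    grad <- numeric(p)
    hess <- matrix(0, p, p)
    for (k in seq_along(et)) {
      r <- risk_idx[[k]]; d <- death_idx[[k]]; nd <- length(d)
      s0 <- sum(w[r])
      s1 <- drop(crossprod(xo[r, , drop = FALSE], w[r]))
      s2 <- crossprod(xo[r, , drop = FALSE] * w[r], xo[r, , drop = FALSE])
      xbar <- s1 / s0
      ll <- ll + sum(eta[d]) - nd * log(s0)
      grad <- grad + colSums(xo[d, , drop = FALSE]) - nd * xbar
      hess <- hess + nd * (s2 / s0 - tcrossprod(xbar))
    }
    list(ll = ll, grad = grad, hess = hess)
  }

  beta <- numeric(p)
  fit0 <- pll(beta)
  ll0 <- fit0$ll
  cur <- fit0
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (sqrt(sum(cur$grad^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$hess, cur$grad), error = function(e) NULL)
    if (is.null(step)) break
    ## step halving: require the partial likelihood not to decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      new <- pll(cand)
      if (new$ll >= cur$ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    cur <- new
  }
  if (sqrt(sum(cur$grad^2)) < tol) converged <- TRUE

  vcov <- tryCatch(solve(cur$hess), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  flagged <- !converged || any(abs(beta) > 15) || anyNA(se)
  lp_all <- drop(x %*% beta)
  names(beta) <- names(se) <- colnames(x)
  z <- beta / se
  structure(list(coefficients = beta, se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 vcov = vcov,
                 loglik = c(null = ll0, fitted = cur$ll),
                 linear_predictor = lp_all,
                 iterations = iter, converged = converged, flagged = flagged),
            class = "pme_cox")
}

#' @export
print.pme_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se, z = x$z, p = x$p_value, check.names = FALSE)
  print(round(tab, 4))
  if (x$flagged) cat("  [flagged: non-convergence or monotone likelihood]\n")
  invisible(x)
}

#' @export
coef.pme_cox <- function(object, ...) object$coefficients

#' @export
predict.pme_cox <- function(object, newdata, ...) {
  drop(as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
         object$coefficients)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood binomial logit fit with an intercept, iterated to a
#' deviance change below `tol` (default 1e-8). Quasi-complete separation
#' (fitted probabilities collapsing to 0/1 with diverging coefficients) is
#' flagged, not silently returned.
#'
#' @param x covariate matrix (subjects x p) or vector.
#' @param y binary response (0/1, logical, or two-level factor).
#' @param tol deviance-change convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @return object of class `pme_logistic`: `coefficients` (intercept first),
#'   `se`, `fitted` (probabilities, strictly inside (0,1)), `deviance`,
#'   `iterations`, `converged`, `flagged`.
#' @export
logistic_fit <- function(x, y, tol = 1e-8, max_iter = 100) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_binary_labels(y)
  if (nrow(x) != length(y)) stop("dimension mismatch")
  if (anyNA(x)) stop("missing covariate values")
  if (all(y == y[1])) stop("degenerate labels: both classes required")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)

  beta <- numeric(p)
  dev <- Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # aliased (constant) columns contribute nothing
    mu <- stats::plogis(drop(X %*% beta))
    newdev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                         (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (abs(dev - newdev) < tol * (abs(newdev) + 0.1)) {
      dev <- newdev; converged <- TRUE; break
    }
    dev <- newdev
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X * w, X)
  vcov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, p, p))
  se <- stats::setNames(sqrt(diag(vcov)), colnames(X))
  ## complete separation: the deviance collapses to zero (perfect fit), or
  ## fitted probabilities pin to 0/1 with runaway coefficients
  sep <- dev < 1e-6 ||
    (any(mu < 1e-8 | mu > 1 - 1e-8) && any(abs(beta[-1]) > 15))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = se, fitted = pmin(pmax(mu, 1e-12), 1 - 1e-12),
                 deviance = dev, iterations = iter,
                 converged = converged, flagged = !converged || sep),
            class = "pme_logistic")
}

#' @export
print.pme_logistic <- function(x, ...) {
  cat("Logistic regression (IRLS)\n")
  print(round(data.frame(coef = x$coefficients, se = x$se), 4))
  if (x$flagged) cat("  [flagged: non-convergence or separation]\n")
  invisible(x)
}

#' @export
coef.pme_logistic <- function(object, ...) object$coefficients

#' @export
predict.pme_logistic <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  b <- object$coefficients
  eta <- drop(cbind(1, as.matrix(newdata)) %*% b)
  if (type == "link") eta else stats::plogis(eta)
}
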