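#' Canonical factor levels for the trap-haul predictors
#' @keywords internal
TRAP_LEVELS <- list(
  year = as.character(2015:2022),
  month = c("October", "November", "December", "January", "February",
            "March", "April", "May"),
  zone = c("RC_A", "RC_B", "RC_C", "RC_D", "RC_E", "RC_F"),
  depth_stratum = c("0-50", "50-100", "100-150", "150-200"),
  lobster_size = c("large", "small")
)

# Short predictor names accepted throughout the abundance stage.
PREDICTOR_COLS <- c(year = "year", month = "month", zone = "zone",
                    depth = "depth_stratum", size = "lobster_size")

#' Trap-haul bycatch table
#'
#' Validates and level-orders a table of lobster-trap hauls with the urchin
#' bycatch count per haul. Categorical predictors are coerced to factors with
#' the canonical level order (year 2015-2022; fishing-season months
#' October-May; zones RC_A-RC_F; depth strata 0-50 through 150-200 m;
#' lobster size large then small), so the first level of each is the
#' reference under treatment coding.
#'
#' @param df data.frame with columns `year`, `month`, `zone`,
#'   `depth_stratum`, `lobster_size`, `urchin_count`.
#' @return A `trap_haul_table` (a validated data.frame).
#' @export
trap_haul_table <- function(df) {
  cols <- c(unname(PREDICTOR_COLS), "urchin_count")
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in unname(PREDICTOR_COLS)) {
    lv <- TRAP_LEVELS[[col]]
    vals <- as.character(df[[col]])
    bad <- setdiff(unique(vals), lv)
    if (length(bad))
      stop("column '", col, "' has level(s) outside the stated set: ",
           paste(bad, collapse = ", "))
    df[[col]] <- factor(vals, levels = lv)
  }
  y <- df$urchin_count
  if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
    stop("urchin_count must be a non-negative integer")
  df$urchin_count <- as.integer(y)
  class(df) <- c("trap_haul_table", "data.frame")
  df
}

#' Treatment-coded design matrix for the abundance model
#'
#' Builds the fixed-effects design matrix with an intercept and
#' reference-level (treatment) coding; the reference is the first canonical
#' level of each predictor (2015, October, RC_A, 0-50 m, large). Predictors
#' may be given by short name (`"year"`, `"month"`, `"zone"`, `"depth"`,
#' `"size"`) or by column name.
#'
#' @param table A [trap_haul_table()] (or compatible data.frame of factors).
#' @param predictors Ordered character vector of predictors.
#' @return Numeric matrix, rows aligned with `table`.
#' @export
design_matrix <- function(table, predictors) {
  if (nrow(table) == 0L) stop("table is empty")
  cols <- ifelse(predictors %in% names(PREDICTOR_COLS),
                 PREDICTOR_COLS[predictors], predictors)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("predictor(s) not in table: ",
                         paste(miss, collapse = ", "))
  if (length(cols) == 0L) return(matrix(1, nrow(table), 1,
                                        dimnames = list(NULL, "(Intercept)")))
  f <- stats::as.formula(paste("~", paste(cols, collapse = " + ")))
  stats::model.matrix(f, data = table)
}

#' Zero-inflated negative binomial log-likelihood
#'
#' The mixture of a point mass at zero (probability `pi`) with an NB2
#' negative binomial (mean `lambda = exp(X beta)`, dispersion `phi`,
#' variance `lambda + lambda^2 / phi`). Each record contributes
#' `log(pi + (1 - pi) * NB(0; lambda, phi))` when `y = 0` and
#' `log((1 - pi) * NB(y; lambda, phi))` otherwise.
#'
#' @param y Non-negative integer counts.
#' @param X Design matrix.
#' @param beta Coefficient vector on the log link.
#' @param phi NB2 dispersion (> 0).
#' @param pi Zero-inflation probability in `[0, 1)`.
#' @return Scalar log-likelihood.
#' @export
zinb_loglik <- function(y, X, beta, phi, pi = 0) {
  if (any(y < 0) || any(y != round(y)))
    stop("y must be non-negative integers")
  stopifnot(phi > 0, pi >= 0, pi < 1)
  lambda <- exp(drop(X %*% beta))
  ll_nb <- stats::dnbinom(y, size = phi, mu = lambda, log = TRUE)
  zero <- y == 0
  out <- numeric(length(y))
  out[!zero] <- log1p(-pi) + ll_nb[!zero]
  out[zero] <- log(pi + (1 - pi) * exp(ll_nb[zero]))
  sum(out)
}

# ---- internal likelihood machinery -----------------------------------------
# Parameter vector layout: c(beta, log(phi) if NB family, logit(pi) if ZI).

fam_has <- function(family) {
  switch(family,
         poisson = c(phi = FALSE, pi = FALSE),
         nb = c(phi = TRUE, pi = FALSE),
         zip = c(phi = FALSE, pi = TRUE),
         zinb = c(phi = TRUE, pi = TRUE),
         stop("unknown family: ", family))
}

unpack_theta <- function(theta, p, family) {
  has <- fam_has(family)
  beta <- theta[seq_len(p)]
  i <- p
  phi <- if (has["phi"]) unname(exp(theta[(i <- i + 1)])) else Inf
  pi <- if (has["pi"]) unname(stats::plogis(theta[i + 1])) else 0
  list(beta = beta, phi = phi, pi = pi)
}

# Negative log-likelihood and analytic gradient for all four families.
count_nll <- function(theta, y, X, family) {
  p <- ncol(X)
  pr <- unpack_theta(theta, p, family)
  lambda <- exp(drop(X %*% pr$beta))
  has <- fam_has(family)
  base_ll <- if (has["phi"])
    stats::dnbinom(y, size = pr$phi, mu = lambda, log = TRUE)
  else stats::dpois(y, lambda, log = TRUE)
  if (!has["pi"]) return(-sum(base_ll))
  zero <- y == 0
  ll <- numeric(length(y))
  ll[!zero] <- log1p(-pr$pi) + base_ll[!zero]
  ll[zero] <- log(pr$pi + (1 - pr$pi) * exp(base_ll[zero]))
  -sum(ll)
}

count_nll_grad <- function(theta, y, X, family) {
  p <- ncol(X)
  pr <- unpack_theta(theta, p, family)
  beta <- pr$beta; phi <- pr$phi; pii <- pr$pi
  lambda <- exp(drop(X %*% beta))
  has <- fam_has(family)
  n <- length(y)
  # per-record d(loglik)/d(eta), d/d(log phi), d/d(logit pi)
  if (has["phi"]) {
    deta <- y - (y + phi) * lambda / (phi + lambda)
    dlphi <- phi * (digamma(y + phi) - digamma(phi) +
                      log(phi / (phi + lambda)) + 1 -
                      (y + phi) / (phi + lambda))
    q0 <- exp(phi * (log(phi) - log(phi + lambda)))  # NB(0; lambda, phi)
    dlogq_deta <- -phi * lambda / (phi + lambda)
    dlogq_dlphi <- phi * (log(phi / (phi + lambda)) + lambda / (phi + lambda))
  } else {
    deta <- y - lambda
    dlphi <- NULL
    q0 <- exp(-lambda)
    dlogq_deta <- -lambda
    dlogq_dlphi <- NULL
  }
  if (has["pi"]) {
    zero <- y == 0
    pz <- pii + (1 - pii) * q0
    wz <- (1 - pii) * q0 / pz            # posterior weight of the NB branch
    deta[zero] <- wz[zero] * dlogq_deta[zero]
    if (has["phi"]) dlphi[zero] <- wz[zero] * dlogq_dlphi[zero]
    dlpi <- numeric(n)
    dlpi[zero] <- pii * (1 - pii) * (1 - q0[zero]) / pz[zero]
    dlpi[!zero] <- -pii
  } else {
    dlpi <- NULL
  }
  g <- c(-drop(crossprod(X, deta)),
         if (has["phi"]) -sum(dlphi),
         if (has["pi"]) -sum(dlpi))
  g
}

# ---- fitting ---------------------------------------------------------------

#' Fit a count model for trap-haul bycatch abundance
#'
#' Maximum-likelihood fit of one of four count families to urchin bycatch
#' counts: Poisson, negative binomial (NB2), and their zero-inflated forms
#' (a constant, intercept-only zero-inflation probability). The mean is
#' `lambda = exp(X beta)` with treatment-coded categorical predictors; the
#' ZINB family adds a dispersion `phi` (variance `lambda + lambda^2/phi`)
#' and a zero-mass probability `pi`.
#'
#' Optimization is quasi-Newton (BFGS) with analytic gradients from a
#' deterministic warm start: `beta` from a Poisson regression, `log phi = 0`,
#' and `logit pi` from the empirical excess-zero fraction. On
#' non-convergence the fit restarts once from a deterministically jittered
#' start and is returned with its `converged` flag and gradient norm either
#' way.
#'
#' @param formula Model formula, e.g. `urchin_count ~ year + zone`; or a
#'   character vector of predictor names (then `response` names the count
#'   column).
#' @param data A [trap_haul_table()] or compatible data.frame.
#' @param family `"poisson"`, `"nb"`, `"zip"` or `"zinb"`.
#' @param response Response column used when `formula` is a character
#'   vector.
#' @return An object of class `count_fit` with components `coefficients`,
#'   `phi`, `pi`, `loglik`, `aic`, `df`, `converged`, `grad_norm`, `fitted`
#'   and the model frame, supporting `print`, `summary`, `coef`, `logLik`,
#'   `AIC`, `predict`, `fitted`, `residuals` and `simulate`.
#' @examples
#' sc <- catch_scenario(n = 500, seed = 7)
#' tab <- make_trap_table(sc)
#' fit <- fit_count_model(urchin_count ~ zone, tab, family = "zinb")
#' fit
#' @export
fit_count_model <- function(formula, data, family = c("zinb", "nb", "zip",
                                                      "poisson"),
                            response = "urchin_count") {
  family <- match.arg(family)
  if (is.character(formula)) {
    X <- design_matrix(data, formula)
    predictors <- formula
    y <- data[[response]]
    fml <- stats::as.formula(paste(
      response, "~",
      if (length(formula)) paste(
        ifelse(formula %in% names(PREDICTOR_COLS),
               PREDICTOR_COLS[formula], formula), collapse = " + ")
      else "1"))
  } else {
    fml <- formula
    mf <- stats::model.frame(fml, data)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    predictors <- attr(stats::terms(fml), "term.labels")
  }
  y <- as.numeric(y)
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integer counts")
  p <- ncol(X)
  has <- fam_has(family)
  if (length(y) <= p + sum(has))
    stop("need more records than parameters (n = ", length(y),
         ", parameters = ", p + sum(has), ")")
  # deterministic warm start
  warm <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta0 <- warm$coefficients
  beta0[!is.finite(beta0)] <- 0
  theta0 <- beta0
  if (has["phi"]) theta0 <- c(theta0, 0)
  if (has["pi"]) {
    p0_obs <- mean(y == 0)
    p0_fit <- mean(exp(-warm$fitted.values))
    excess <- (p0_obs - p0_fit) / max(1 - p0_fit, 1e-8)
    pi0 <- min(max(excess, 0.02), 0.9)
    theta0 <- c(theta0, stats::qlogis(pi0))
  }
  nll0 <- count_nll(theta0, y, X, family)
  run_opt <- function(start) {
    stats::optim(start, count_nll, count_nll_grad, y = y, X = X,
                 family = family, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12),
                 hessian = FALSE)
  }
  opt <- run_opt(theta0)
  gnorm <- function(th) max(abs(count_nll_grad(th, y, X, family))) / length(y)
  grad_norm <- gnorm(opt$par)
  converged <- opt$convergence == 0 && grad_norm < 1e-6
  if (!converged) {
    jit <- 0.05 * sin(1.7 * seq_along(theta0))
    opt2 <- run_opt(theta0 * 1.001 + jit)
    if (opt2$value < opt$value) opt <- opt2
    grad_norm <- gnorm(opt$par)
    converged <- opt$convergence == 0 && grad_norm < 1e-6
  }
  pr <- unpack_theta(opt$par, p, family)
  names(pr$beta) <- colnames(X)
  loglik <- -opt$value
  if (loglik < -nll0 - 1e-6)
    warning("optimum log-likelihood below the warm start; fit is suspect")
  df <- p + sum(has)
  lambda <- exp(drop(X %*% pr$beta))
  # flag near-degenerate columns (separation in a category level)
  colvar <- apply(X, 2, stats::var)
  degen <- names(colvar)[colvar == 0 & names(colvar) != "(Intercept)"]
  if (length(degen))
    warning("constant design column(s): ", paste(degen, collapse = ", "))
  structure(
    list(coefficients = pr$beta,
         phi = if (has["phi"]) pr$phi else NULL,
         pi = if (has["pi"]) pr$pi else NULL,
         family = family, formula = fml, predictors = predictors,
         loglik = loglik, aic = 2 * df - 2 * loglik, df = df,
         converged = converged, grad_norm = grad_norm,
         theta = opt$par, y = y, X = X, fitted_lambda = lambda,
         n = length(y), call = match.call()),
    class = "count_fit"
  )
}

# Model mean and variance per record, by family.
fit_moments <- function(fit) {
  lambda <- fit$fitted_lambda
  pii <- if (is.null(fit$pi)) 0 else fit$pi
  phi <- if (is.null(fit$phi)) Inf else fit$phi
  mu <- (1 - pii) * lambda
  v <- (1 - pii) * lambda * (1 + lambda / phi + pii * lambda)
  list(mean = mu, var = pmax(v, .Machine$double.eps))
}

#' @export
print.count_fit <- function(x, ...) {
  cat("<count_fit>", toupper(x$family), "model:",
      deparse(x$formula), "\n")
  cat(sprintf("  n = %d, df = %d, logLik = %.2f, AIC = %.1f%s\n",
              x$n, x$df, x$loglik, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$phi)) cat(sprintf("  dispersion phi = %.4f\n", x$phi))
  if (!is.null(x$pi)) cat(sprintf("  zero-inflation pi = %.4f\n", x$pi))
  cat("  coefficients (log link):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.count_fit <- function(object, ...) object$coefficients

#' @export
logLik.count_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.count_fit <- function(object, ...) fit_moments(object)$mean

#' @export
predict.count_fit <- function(object, newdata = NULL,
                              type = c("response", "count", "link", "zero"),
                              ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
  } else {
    X <- stats::model.matrix(stats::delete.response(stats::terms(
      object$formula)), newdata)
    X <- X[, names(object$coefficients), drop = FALSE]
    eta <- drop(X %*% object$coefficients)
  }
  pii <- if (is.null(object$pi)) 0 else object$pi
  switch(type,
         link = eta,
         count = exp(eta),
         response = (1 - pii) * exp(eta),
         zero = rep(pii, length(eta)))
}

#' @export
residuals.count_fit <- function(object, type = c("pearson", "response"),
                                ...) {
  type <- match.arg(type)
  mom <- fit_moments(object)
  r <- object$y - mom$mean
  if (type == "pearson") r <- r / sqrt(mom$var)
  r
}

#' @export
simulate.count_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- object$fitted_lambda
  pii <- if (is.null(object$pi)) 0 else object$pi
  phi <- if (is.null(object$phi)) Inf else object$phi
  out <- as.data.frame(replicate(nsim, rzinb(object$n, lambda, phi, pii)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.count_fit <- function(object, ...) {
  h <- stats::optimHess(object$theta, count_nll, count_nll_grad,
                        y = object$y, X = object$X, family = object$family)
  se <- rep(NA_real_, length(object$theta))
  ok <- tryCatch({
    v <- solve(h)
    se <- sqrt(pmax(diag(v), 0))
    TRUE
  }, error = function(e) FALSE)
  p <- length(object$coefficients)
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = se[seq_len(p)],
               `z value` = object$coefficients / se[seq_len(p)])
  res <- list(fit = object, coef_table = tab, se_ok = ok,
              se_extra = se[-seq_len(p)])
  class(res) <- "summary.count_fit"
  res
}

#' @export
print.summary.count_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table:\n")
  stats::printCoefmat(x$coef_table, P.values = FALSE, has.Pvalue = FALSE)
  invisible(x)
}

#' Pearson overdispersion statistic
#'
#' Pearson chi-square divided by residual degrees of freedom under the
#' fitted model's mean-variance relation; values well above 1 flag
#' overdispersion relative to the fitted family.
#'
#' @param fit A `count_fit`.
#' @return Scalar dispersion statistic.
#' @export
overdispersion_check <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  r <- residuals.count_fit(fit, type = "pearson")
  sum(r^2) / (fit$n - fit$df)
}

#' AIC model selection over candidate predictor sets
#'
#' Fits every candidate on the same records and returns the candidates
#' ranked by AIC (ascending), ties broken by fewer parameters. Candidates
#' that fail to fit are kept with a status note rather than aborting the
#' ladder.
#'
#' @param data A [trap_haul_table()] or compatible data.frame.
#' @param candidates Named list; each element a character vector of
#'   predictors or a one-sided/two-sided formula.
#' @param family Count family for every candidate.
#' @param response Response column for character candidates.
#' @return data.frame with columns `model`, `covariates`, `df`, `aic`,
#'   `loglik`, `converged`, `status`, sorted by AIC; the fitted objects are
#'   attached as attribute `"fits"`.
#' @export
model_selection <- function(data, candidates, family = "zinb",
                            response = "urchin_count") {
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  fits <- vector("list", length(candidates))
  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    lab <- if (is.character(cand)) paste(cand, collapse = " + ")
    else paste(deparse(cand), collapse = "")
    res <- tryCatch(
      fit_count_model(cand, data, family = family, response = response),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(model = names(candidates)[i], covariates = lab,
                 df = NA_integer_, aic = NA_real_, loglik = NA_real_,
                 converged = FALSE, status = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      fits[[i]] <<- res
      data.frame(model = names(candidates)[i], covariates = lab,
                 df = res$df, aic = res$aic, loglik = res$loglik,
                 converged = res$converged, status = "ok",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  ord <- order(out$aic, out$df, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- stats::setNames(fits, names(candidates))[out$model]
  out
}

#' The simple and cumulative predictor ladders of the abundance analysis
#'
#' `simple` fits each predictor alone (m1 = year, m2 = month, m3 = zone,
#' m4 = depth, m5 = size); `cumulative` adds predictors in the order year,
#' month, zone, depth, size (M1-M5), with M5 the full model.
#'
#' @return List with elements `simple` and `cumulative`, each a named list
#'   of predictor vectors for [model_selection()].
#' @export
abundance_ladders <- function() {
  list(
    simple = list(m1 = "year", m2 = "month", m3 = "zone", m4 = "depth",
                  m5 = "size"),
    cumulative = list(M1 = "year",
                      M2 = c("year", "month"),
                      M3 = c("year", "month", "zone"),
                      M4 = c("year", "month", "zone", "depth"),
                      M5 = c("year", "month", "zone", "depth", "size"))
  )
}

#' Write a model-selection report to CSV
#'
#' One CSV mirroring the selection table (model, covariates, df, AIC, best
#' flagged) and, optionally, a coefficients CSV for the best fit.
#'
#' @param sel Result of [model_selection()].
#' @param path Output CSV path.
#' @param coef_path Optional coefficients CSV path for the top-ranked model.
#' @return `path`, invisibly.
#' @export
write_model_selection <- function(sel, path, coef_path = NULL) {
  out <- sel
  out$best <- seq_len(nrow(out)) == which.min(out$aic)
  attr(out, "fits") <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(coef_path)) {
    best <- attr(sel, "fits")[[sel$model[which.min(sel$aic)]]]
    if (!is.null(best)) {
      cf <- data.frame(term = names(best$coefficients),
                       estimate = unname(best$coefficients))
      if (!is.null(best$phi))
        cf <- rbind(cf, data.frame(term = "phi", estimate = best$phi))
      if (!is.null(best$pi))
        cf <- rbind(cf, data.frame(term = "pi", estimate = best$pi))
      utils::write.csv(cf, coef_path, row.names = FALSE)
    }
  }
  invisible(path)
}
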