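#' Fit a multilevel model with diagonal residual covariance
#'
#' Fits the marginal Gaussian model used throughout the hormone/status
#' analyses: fixed effects estimated by (restricted) maximum likelihood under
#' a residual covariance that is diagonal, with one free variance per level of
#' the repeated factor(s) (member position within triad, and saliva-collection
#' time in the three-level models) and zero covariances. This is the
#' heteroscedastic generalization of OLS appropriate when triad membership
#' constrains the outcome (one member's top rank constrains the others'), so
#' residual spread differs systematically by member position.
#'
#' Estimation iterates weighted least squares for the fixed effects with
#' closed-form variance updates (residual sum of squares per repeated level
#' divided by `n_g` for ML, or by `n_g - h_g` with `h_g` the level's share of
#' the hat-matrix trace for REML) to the exact (RE)ML fixed point. With a
#' single repeated level REML reproduces ordinary least squares exactly:
#' identical estimates, standard errors, t statistics and residual df.
#'
#' Degrees of freedom for each t test are fractional, by a Satterthwaite
#' approximation: for a contrast `c`,
#' `df = 2 (c'Vc)^2 / sum_g (d(c'Vc)/d s2_g)^2 Var(s2_g)` with
#' `Var(s2_g) = 2 s2_g^2 / nu_g`.
#'
#' When `center = TRUE` all numeric predictors are mean-centered before the
#' design matrix (and hence any interaction products) is formed, so product
#' terms are built from centered components.
#'
#' @param data a data frame.
#' @param formula model formula for the fixed effects, e.g.
#'   `rank ~ ln_t_mean * c_mean`.
#' @param repeated character vector naming the repeated-measure variable(s);
#'   the residual variance groups are their level combinations. `NULL` fits a
#'   single residual variance.
#' @param subject name of the grouping (subject) variable, recorded for
#'   bookkeeping; under a diagonal structure it does not alter the marginal
#'   covariance.
#' @param center mean-center numeric predictors before building interactions.
#' @param method `"REML"` (default) or `"ML"`.
#' @param max_iter,tol iteration control for the variance fixed point.
#' @return An object of class `dmlm` with `coefficients` (term, estimate, se,
#'   t, df, p), `vcov`, `sigma2` (per repeated level), `logLik`, convergence
#'   info, and the model frame. Supports [tidy()], [glance()],
#'   [simple_slopes()].
#' @export
fit_diagonal_mlm <- function(data, formula, repeated = NULL, subject = NULL,
                             center = TRUE, method = c("REML", "ML"),
                             max_iter = 500L, tol = 1e-10) {
  method <- match.arg(method)
  vars <- all.vars(formula)
  need <- unique(c(vars, repeated, subject))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop(sprintf("variables not in data: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  if (nrow(d) < length(vars) + 1) stop("too few complete cases", call. = FALSE)
  if (!is.null(subject) && length(unique(d[[subject]])) < 2) {
    stop("need at least 2 subject groups", call. = FALSE)
  }

  centers <- NULL
  dd <- d
  rhs <- setdiff(vars, vars[1])
  if (center) {
    num <- rhs[vapply(rhs, function(v) is.numeric(d[[v]]), logical(1))]
    centers <- vapply(num, function(v) mean(d[[v]]), numeric(1))
    for (v in num) dd[[v]] <- dd[[v]] - centers[[v]]
  }

  X <- stats::model.matrix(formula, dd)
  y <- dd[[vars[1]]]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("singular design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  g <- if (is.null(repeated)) {
    factor(rep("all", nrow(dd)))
  } else {
    interaction(dd[, repeated, drop = FALSE], drop = TRUE, sep = ":")
  }
  glev <- levels(g)
  G <- length(glev)
  idx <- split(seq_len(nrow(X)), g)
  n_g <- vapply(idx, length, integer(1))
  p <- ncol(X)
  if (any(n_g <= 1) && method == "REML") {
    # single-observation levels leave no residual df; still estimable under ML
    method_note <- "levels with n = 1 present"
  }
  M_g <- lapply(idx, function(i) crossprod(X[i, , drop = FALSE]))
  Xty_g <- lapply(idx, function(i) crossprod(X[i, , drop = FALSE], y[i]))

  s2 <- rep(stats::var(y), G)
  names(s2) <- glev
  beta <- rep(0, p)
  conv <- FALSE
  it <- 0L
  h_g <- rep(0, G)
  for (it in seq_len(max_iter)) {
    XtWX <- Reduce(`+`, Map(function(M, s) M / s, M_g, s2))
    XtWy <- Reduce(`+`, Map(function(v, s) v / s, Xty_g, s2))
    beta_new <- solve(XtWX, XtWy)
    A <- solve(XtWX)
    rss_g <- vapply(seq_len(G), function(k) {
      i <- idx[[k]]
      sum((y[i] - X[i, , drop = FALSE] %*% beta_new)^2)
    }, numeric(1))
    h_g <- vapply(seq_len(G), function(k) sum(A * M_g[[k]]) / s2[k], numeric(1))
    denom <- if (method == "REML") pmax(n_g - h_g, 1e-8) else n_g
    s2_new <- pmax(rss_g / denom, 1e-12)
    delta <- max(abs(s2_new - s2) / (s2 + 1e-12),
                 if (it > 1) max(abs(beta_new - beta)) else Inf)
    beta <- as.numeric(beta_new)
    s2 <- s2_new
    if (it > 1 && delta < tol) { conv <- TRUE; break }
  }
  if (!conv) {
    stop(sprintf("diagonal MLM did not converge in %d iterations (last rel. change %.3g)",
                 max_iter, delta), call. = FALSE)
  }

  XtWX <- Reduce(`+`, Map(function(M, s) M / s, M_g, s2))
  V <- solve(XtWX)
  dimnames(V) <- list(colnames(X), colnames(X))
  h_g <- vapply(seq_len(G), function(k) sum(V * M_g[[k]]) / s2[k], numeric(1))
  nu_g <- if (method == "REML") pmax(n_g - h_g, 1e-8) else n_g

  satt <- function(cvec) {
    u <- V %*% cvec
    f <- drop(crossprod(cvec, u))
    grad <- vapply(seq_len(G), function(k) {
      drop(crossprod(u, M_g[[k]] %*% u)) / s2[k]^2
    }, numeric(1))
    denom <- sum(grad^2 * 2 * s2^2 / nu_g)
    if (denom <= 0) return(Inf)
    2 * f^2 / denom
  }

  se <- unname(sqrt(diag(V)))
  df <- vapply(seq_len(p), function(j) {
    cv <- rep(0, p); cv[j] <- 1; satt(cv)
  }, numeric(1))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)

  rss_g <- vapply(seq_len(G), function(k) {
    i <- idx[[k]]
    sum((y[i] - X[i, , drop = FALSE] %*% beta)^2)
  }, numeric(1))
  n <- nrow(X)
  if (method == "REML") {
    ll <- -0.5 * ((n - p) * log(2 * pi) + sum(n_g * log(s2)) + sum(rss_g / s2) +
                    determinant(XtWX, logarithm = TRUE)$modulus[1])
  } else {
    ll <- -0.5 * (n * log(2 * pi) + sum(n_g * log(s2)) + sum(rss_g / s2))
  }

  out <- list(
    coefficients = tibble::tibble(
      term = colnames(X), estimate = beta, std.error = se,
      statistic = tval, df = df, p.value = pval),
    vcov = V,
    sigma2 = tibble::tibble(level = glev, sigma2 = unname(s2),
                            n = unname(n_g), nu = unname(nu_g)),
    logLik = ll,
    method = method,
    converged = conv,
    iterations = it,
    n = n,
    formula = formula,
    repeated = repeated,
    subject = subject,
    center = center,
    centers = centers,
    model_frame = dd[, need, drop = FALSE],
    design = list(M_g = M_g, satt = satt)
  )
  class(out) <- "dmlm"
  out
}

#' @export
print.dmlm <- function(x, ...) {
  cat(sprintf("Diagonal-covariance multilevel model (%s)\n", x$method))
  cat(sprintf("  n = %d, residual levels = %d, logLik = %.3f\n",
              x$n, nrow(x$sigma2), x$logLik))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a diagonal-covariance multilevel fit
#' @param x a `dmlm` object.
#' @param ... unused.
#' @return Tibble with one row per fixed effect: `term`, `estimate`,
#'   `std.error`, `statistic`, `df`, `p.value`.
#' @export
tidy.dmlm <- function(x, ...) x$coefficients

#' One-row model summary of a diagonal-covariance multilevel fit
#' @param x a `dmlm` object.
#' @param ... unused.
#' @export
glance.dmlm <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, nobs = x$n,
                 n_resid_levels = nrow(x$sigma2),
                 method = x$method, iterations = x$iterations,
                 converged = x$converged)
}

#' Simple slopes of a predictor at moderator values of mean +/- 1 SD
#'
#' Decomposes an interaction by evaluating the conditional slope
#' `b_pred + b_int * m` at moderator values one standard deviation below and
#' above its mean (0 on the centered scale), with the variance
#' `V_pp + m^2 V_ii + 2 m V_pi` from the estimate covariances and fractional
#' Satterthwaite df for each conditional t test.
#'
#' @param fit a `dmlm` fit containing the `predictor:moderator` term.
#' @param predictor,moderator variable names as they appear in the model.
#' @param at moderator offsets in SD units (default `c(-1, 1)`).
#' @return Tibble: `moderator`, `at_sd`, `moderator_value`, `slope`, `se`,
#'   `t`, `df`, `p`.
#' @export
simple_slopes <- function(fit, predictor, moderator, at = c(-1, 1)) {
  stopifnot(inherits(fit, "dmlm"))
  terms <- fit$coefficients$term
  int <- intersect(c(paste0(predictor, ":", moderator),
                     paste0(moderator, ":", predictor)), terms)
  if (length(int) == 0) {
    stop(sprintf("fit has no interaction term between '%s' and '%s'",
                 predictor, moderator), call. = FALSE)
  }
  if (!predictor %in% terms) {
    stop(sprintf("fit has no main-effect term '%s'", predictor), call. = FALSE)
  }
  int <- int[1]
  sd_m <- stats::sd(fit$model_frame[[moderator]])
  p <- length(terms)
  b <- fit$coefficients$estimate
  names(b) <- terms
  purrr::map_dfr(at, function(k) {
    m <- k * sd_m
    cv <- rep(0, p)
    cv[match(predictor, terms)] <- 1
    cv[match(int, terms)] <- m
    slope <- sum(cv * b)
    v <- drop(t(cv) %*% fit$vcov %*% cv)
    df <- fit$design$satt(cv)
    tval <- slope / sqrt(v)
    tibble::tibble(
      moderator = moderator, at_sd = k, moderator_value = m,
      slope = slope, se = sqrt(v), t = tval, df = df,
      p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  })
}
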