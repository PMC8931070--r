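## Regression analyses on simulation output: a left-censored (Tobit)
## model for dyadic demand deficits, a negative binomial model for
## threshold-exceedance counts, and OLS for the log rank-sum
## vulnerability score.  All three report heteroskedasticity-robust
## (sandwich) standard errors.

#' Build the dyadic regression table
#'
#' One row per (origin, destination, alpha) grid cell.  The dependent
#' variable \code{dd} is the final demand deficit in kcal/person/day,
#' left-censored at zero by construction.  Covariates follow the
#' conventions used for display: destination log per-capita GDP; the
#' shock size expressed in kcal/person/day of the destination population
#' (log(1+x) by default, levels via \code{shock_scale}); destination
#' import concentration C4; mutually exclusive origin-destination regime
#' indicators (\code{domestic}, direct link as the omitted baseline,
#' \code{indirect} = finite directed distance >= 2, \code{no_direct_link}
#' = infinite directed distance); origin and destination network
#' covariates (degrees raw, strengths and betweenness log(1+x),
#' clustering and PageRank multiplied by 1000, hub raw); and
#' \code{alpha} as a factor.
#'
#' @param grid a \code{shock_grid}
#' @param features output of \code{\link{node_features}} on the same
#'   network
#' @param network the \code{trade_network} both came from
#' @param shock_scale "log" (log(1+x)) or "level"
#' @return data.frame with 3 N^2 rows at the reference settings
#' @export
build_dyadic_table <- function(grid, features, network,
                               shock_scale = c("log", "level")) {
  shock_scale <- match.arg(shock_scale)
  stopifnot(inherits(grid, "shock_grid"))
  h <- network_hash(network)
  if (!identical(grid$network_hash, h))
    stop("grid was built from a different network (hash mismatch)")
  fh <- attr(features, "network_hash")
  if (!is.null(fh) && !identical(fh, h))
    stop("features were built from a different network (hash mismatch)")

  g <- grid$grid
  ids <- network$countries$id
  io <- match(g$origin, ids)
  jd <- match(g$dest, ids)
  fo <- match(g$origin, features$id)
  fd <- match(g$dest, features$id)

  D <- igraph::distances(as_igraph(network), mode = "out", weights = NA)
  D <- D[ids, ids]
  dist_ij <- D[cbind(io, jd)]

  pop <- network$countries$population
  gdp <- network$countries$gdp
  shock_pcd <- grid$shock[io] / (pop[jd] * grid$days_per_year)

  out <- data.frame(
    origin = g$origin, dest = g$dest,
    alpha = factor(g$alpha),
    dd = g$dd,
    dest_log_pcgdp = log(gdp[jd] / pop[jd]),
    shock = if (shock_scale == "log") log1p(shock_pcd) else shock_pcd,
    c4_dest = features$c4[fd],
    domestic = as.integer(g$origin == g$dest),
    indirect = as.integer(is.finite(dist_ij) & dist_ij >= 2),
    no_direct_link = as.integer(!is.finite(dist_ij)),
    stringsAsFactors = FALSE)
  for (side in c("orig", "dest")) {
    f <- if (side == "orig") fo else fd
    out[[paste0(side, "_in_degree")]] <- features$in_degree[f]
    out[[paste0(side, "_out_degree")]] <- features$out_degree[f]
    out[[paste0(side, "_log_in_strength")]] <- log1p(features$in_strength[f])
    out[[paste0(side, "_log_out_strength")]] <- log1p(features$out_strength[f])
    out[[paste0(side, "_hub")]] <- features$hub[f]
    out[[paste0(side, "_log_betweenness")]] <- log1p(features$betweenness[f])
    out[[paste0(side, "_pagerank")]] <- 1000 * features$pagerank[f]
    out[[paste0(side, "_clustering")]] <- 1000 * features$clustering[f]
  }
  rownames(out) <- NULL
  out
}

#' Default dyadic regression formula
#'
#' The covariate set of the dyadic deficit model: destination per-capita
#' GDP, shock size, destination import concentration, regime indicators,
#' origin and destination network covariates, and alpha dummies.
#'
#' @return a formula usable with \code{\link{tobit_fit}}
#' @export
dyadic_formula <- function() {
  stats::as.formula(paste(
    "dd ~ dest_log_pcgdp + shock + c4_dest + domestic + indirect +",
    "no_direct_link +",
    paste(outer(c("orig_", "dest_"),
                c("in_degree", "out_degree", "log_in_strength",
                  "log_out_strength", "hub", "log_betweenness",
                  "pagerank", "clustering"), paste0),
          collapse = " + "),
    "+ alpha"))
}

#' Drop constant covariates from a model formula
#'
#' Removes right-hand-side terms whose values never vary in the data
#' (e.g. a no-directed-path indicator on a strongly connected network),
#' which would otherwise make the design singular.  Dropped terms are
#' reported in a message.
#'
#' @param formula a model formula
#' @param data data.frame the model will be fitted on
#' @return the pruned formula
#' @export
prune_formula <- function(formula, data) {
  tl <- attr(stats::terms(formula, data = data), "term.labels")
  keep <- vapply(tl, function(tm) {
    v <- tryCatch(eval(str2lang(tm), envir = data),
                  error = function(e) NULL)
    is.null(v) || length(unique(v)) > 1L
  }, logical(1))
  if (all(keep)) return(formula)
  message("dropping constant covariate(s): ",
          paste(tl[!keep], collapse = ", "))
  stats::reformulate(tl[keep],
                     response = all.vars(formula)[1],
                     intercept = attr(stats::terms(formula, data = data),
                                      "intercept") == 1)
}

design_matrix <- function(formula, data, singular_ok = FALSE) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!singular_ok) {
    q <- qr(X)
    if (q$rank < ncol(X)) {
      bad <- setdiff(colnames(X), colnames(X)[q$pivot[seq_len(q$rank)]])
      stop("singular design; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  list(y = y, X = X, mf = mf)
}

#' Tobit (left-censored at zero) regression
#'
#' Censored-normal maximum likelihood: observations at zero contribute
#' the probability mass below zero, positive observations the normal
#' density.  Fitted via \code{survival::survreg} with a gaussian
#' left-censored response; standard errors are robust sandwich estimates
#' with an n/(n-k) small-sample correction; the fit statistic is
#' McFadden's pseudo-R-squared against the intercept-only model.  With
#' no censored observations the estimates coincide with least squares.
#'
#' @param formula model formula; the response must be >= 0
#' @param data data.frame
#' @return an object of class \code{tobit_fit}
#' @export
tobit_fit <- function(formula, data) {
  d <- design_matrix(formula, data)
  y <- d$y
  if (any(y < 0)) stop("Tobit response must be >= 0 (left-censored at 0)")
  if (all(y <= 0)) stop("all observations censored at zero; nothing to fit")
  ev <- y > 0
  X <- d$X
  fit <- survival::survreg(survival::Surv(y, ev, type = "left") ~ X - 1,
                           dist = "gaussian",
                           control = survival::survreg.control(maxiter = 100))
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  k <- length(beta) + 1L            # + log(scale)
  n <- length(y)
  vc <- sandwich::sandwich(fit) * n / (n - k)
  dimnames(vc) <- list(c(names(beta), "log_sigma"),
                       c(names(beta), "log_sigma"))
  null <- survival::survreg(survival::Surv(y, ev, type = "left") ~ 1,
                            dist = "gaussian")
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null))
  structure(list(
    coefficients = beta, sigma = fit$scale,
    se = sqrt(diag(vc))[seq_along(beta)], vcov = vc,
    n = n, n_censored = sum(!ev),
    loglik = ll, loglik_null = ll0,
    pseudo_r2 = 1 - ll / ll0,
    X = X, y = y, formula = formula, fit = fit,
    call = match.call()), class = "tobit_fit")
}

#' Negative binomial (NB2) count regression
#'
#' Mean mu = exp(X beta), variance mu + kappa mu^2, fitted by maximum
#' likelihood via \code{MASS::glm.nb}.  If the dispersion is estimated
#' at the Poisson boundary (kappa -> 0, i.e. theta very large) or the
#' theta iteration fails, the fit falls back to a Poisson GLM with a
#' warning.  Standard errors are HC1 sandwich estimates.
#'
#' @param formula model formula; the response must be non-negative
#'   integers
#' @param data data.frame
#' @return an object of class \code{negbin_fit}
#' @export
negbin_fit <- function(formula, data) {
  d <- design_matrix(formula, data)
  y <- d$y
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("negative binomial response must be non-negative integers")
  if (all(y == 0)) stop("all counts are zero; nothing to fit")
  family_used <- "negbin"
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(formula, data = data,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  theta <- if (!is.null(fit)) fit$theta else Inf
  if (is.null(fit) || !is.finite(theta) || theta > 1e5) {
    warning("dispersion at the Poisson boundary (kappa ~ 0); ",
            "falling back to a Poisson GLM")
    fit <- stats::glm(formula, data = data, family = stats::poisson())
    family_used <- "poisson"
    theta <- Inf
  }
  vc <- sandwich::vcovHC(fit, type = "HC1")
  structure(list(
    coefficients = stats::coef(fit), se = sqrt(diag(vc)), vcov = vc,
    theta = theta, kappa = 1 / theta,
    n = length(y), loglik = as.numeric(stats::logLik(fit)),
    family = family_used,
    X = d$X, y = y, formula = formula, fit = fit,
    call = match.call()), class = "negbin_fit")
}

#' Least squares with robust standard errors
#'
#' OLS via \code{stats::lm} with HC1 sandwich standard errors, R-squared
#' and the overall F statistic.  A rank-deficient design is an error
#' naming the collinear columns.
#'
#' @param formula model formula
#' @param data data.frame
#' @return an object of class \code{ols_fit}
#' @export
ols_fit <- function(formula, data) {
  d <- design_matrix(formula, data)
  fit <- stats::lm(formula, data = data)
  vc <- sandwich::vcovHC(fit, type = "HC1")
  sm <- summary(fit)
  structure(list(
    coefficients = stats::coef(fit), se = sqrt(diag(vc)), vcov = vc,
    n = length(d$y), r_squared = sm$r.squared,
    f_statistic = unname(sm$fstatistic["value"]),
    loglik = as.numeric(stats::logLik(fit)),
    X = d$X, y = d$y, formula = formula, fit = fit,
    call = match.call()), class = "ols_fit")
}

#' Per-standard-deviation (display-scale) coefficients
#'
#' Rescales each slope by the sample standard deviation of its
#' covariate, the scale on which coefficient magnitudes are compared
#' across covariates.  Binary indicator columns and the intercept pass
#' through unscaled; zero-variance covariates are dropped with a note.
#' Standard errors are rescaled identically, so t-statistics are
#' unchanged.
#'
#' @param result a \code{tobit_fit}, \code{negbin_fit} or \code{ols_fit}
#' @return data.frame with term, estimate, se, sd (NA where unscaled),
#'   std_estimate, std_se
#' @export
standardize_coefficients <- function(result) {
  stopifnot(inherits(result, c("tobit_fit", "negbin_fit", "ols_fit")))
  X <- result$X
  beta <- result$coefficients
  se <- result$se[names(beta)]
  terms <- names(beta)
  out <- data.frame(term = terms, estimate = unname(beta),
                    se = unname(se), sd = NA_real_,
                    std_estimate = unname(beta), std_se = unname(se),
                    stringsAsFactors = FALSE)
  dropped <- character(0)
  for (i in seq_along(terms)) {
    x <- X[, terms[i]]
    if (terms[i] == "(Intercept)" || all(x %in% c(0, 1))) next
    s <- stats::sd(x)
    if (s == 0) { dropped <- c(dropped, terms[i]); next }
    out$sd[i] <- s
    out$std_estimate[i] <- beta[i] * s
    out$std_se[i] <- se[i] * s
  }
  if (length(dropped) > 0) {
    out <- out[!out$term %in% dropped, , drop = FALSE]
    message("dropped zero-variance covariate(s): ",
            paste(dropped, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' @export
coef.tobit_fit <- function(object, ...) object$coefficients
#' @export
coef.negbin_fit <- function(object, ...) object$coefficients
#' @export
coef.ols_fit <- function(object, ...) object$coefficients
#' @export
vcov.tobit_fit <- function(object, ...) object$vcov
#' @export
vcov.negbin_fit <- function(object, ...) object$vcov
#' @export
vcov.ols_fit <- function(object, ...) object$vcov
#' @export
logLik.tobit_fit <- function(object, ...)
  structure(object$loglik, df = length(object$coefficients) + 1,
            class = "logLik")

coef_table <- function(x) {
  b <- x$coefficients
  se <- x$se[names(b)]
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- stats::symnum(p, corr = FALSE, na = FALSE,
                  cutpoints = c(0, 0.01, 0.05, 0.1, 1),
                  symbols = c("***", "**", "*", " "))
  data.frame(estimate = b, robust_se = se, z = z, p = p,
             sig = format(stars), stringsAsFactors = FALSE)
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf(
    "Tobit (left-censored at 0) regression: n = %d, censored = %d (%.1f%%)\n",
    x$n, x$n_censored, 100 * x$n_censored / x$n))
  print(round(coef_table(x)[1:4], 4))
  cat(sprintf("sigma = %.4g   logLik = %.2f   McFadden pseudo-R2 = %.3f\n",
              x$sigma, x$loglik, x$pseudo_r2))
  invisible(x)
}

#' @export
print.negbin_fit <- function(x, ...) {
  cat(sprintf("%s count regression: n = %d\n",
              if (x$family == "negbin") "Negative binomial (NB2)"
              else "Poisson (NB dispersion at boundary)", x$n))
  print(round(coef_table(x)[1:4], 4))
  if (is.finite(x$theta))
    cat(sprintf("theta = %.4g (kappa = %.4g)   ", x$theta, x$kappa))
  cat(sprintf("logLik = %.2f\n", x$loglik))
  invisible(x)
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS regression (robust HC1 SEs): n = %d\n", x$n))
  print(round(coef_table(x)[1:4], 4))
  cat(sprintf("R2 = %.4f   F = %.2f\n", x$r_squared, x$f_statistic))
  invisible(x)
}

#' @export
summary.tobit_fit <- function(object, ...) {
  out <- list(fit = object, table = coef_table(object))
  class(out) <- "summary.tobit_fit"; out
}
#' @export
print.summary.tobit_fit <- function(x, ...) {
  print(x$fit); invisible(x)
}
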