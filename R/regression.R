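#' Specification of the mortality regression
#'
#' Describes an OLS regression of an annual outcome on covariates across a
#' stacked (year, group) panel, optionally with an intervention dummy that
#' switches on for one group from a policy year onwards — e.g. a
#' "female after smoking ban" indicator equal to 1 for female observations
#' in 2012 and later, whose coefficient captures the excess post-ban change
#' in female mortality.
#'
#' @param outcome column name of the dependent variable.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param ban_year first year the intervention is active (inclusive);
#'   default 2012.
#' @param ban_group group label the dummy applies to; default `"female"`.
#' @param include_dummy include the intervention dummy? default TRUE.
#' @param bootstrap_reps bootstrap replications for standard errors;
#'   default 1000.
#' @param seed integer seed for the bootstrap resampling.
#' @return list of class `regression_spec`.
#' @export
regression_spec <- function(outcome = "mortality",
                            covariates = c("smoking", "physician"),
                            ban_year = 2012L, ban_group = "female",
                            include_dummy = TRUE,
                            bootstrap_reps = 1000L, seed = 1L) {
  bootstrap_reps <- as.integer(bootstrap_reps)
  if (bootstrap_reps < 1L) {
    stop("regression_spec: bootstrap_reps must be >= 1", call. = FALSE)
  }
  structure(list(outcome = outcome, covariates = covariates,
                 ban_year = as.integer(ban_year), ban_group = ban_group,
                 include_dummy = isTRUE(include_dummy),
                 bootstrap_reps = bootstrap_reps, seed = as.integer(seed)),
            class = "regression_spec")
}

#' Build the stacked design matrix for the panel regression
#'
#' Stacks the (year, group) rows of a long panel into a design matrix with
#' an intercept, the requested covariates, and (if enabled) the
#' intervention dummy `1[group == ban_group & year >= ban_year]`.
#'
#' @param panel data.frame in long format with columns `year`, `group`, the
#'   outcome and the covariates.
#' @param spec a [regression_spec].
#' @param groups group labels to keep; defaults to `c("male", "female")` —
#'   aggregate "total" rows are excluded so strata are not double counted.
#' @return list with `X` (numeric design matrix, named columns), `y`
#'   (outcome vector) and `rows` (the panel rows used, ordered by group then
#'   year).
#' @export
build_design <- function(panel, spec = regression_spec(),
                         groups = c("male", "female")) {
  need <- c("year", "group", spec$outcome, spec$covariates)
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("build_design: panel lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(groups, unique(panel$group))
  if (length(absent)) {
    stop("build_design: group(s) not present in panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  rows <- panel[panel$group %in% groups, , drop = FALSE]
  rows <- rows[order(match(rows$group, groups), rows$year), , drop = FALSE]
  if (spec$include_dummy && !spec$ban_year %in% rows$year) {
    stop("build_design: ban_year ", spec$ban_year,
         " outside panel years", call. = FALSE)
  }
  X <- matrix(1, nrow = nrow(rows), ncol = 1L,
              dimnames = list(NULL, "(Intercept)"))
  for (cv in spec$covariates) X <- cbind(X, rows[[cv]])
  colnames(X) <- c("(Intercept)", spec$covariates)
  if (spec$include_dummy) {
    dummy <- as.numeric(rows$group == spec$ban_group &
                        rows$year >= spec$ban_year)
    X <- cbind(X, after_ban = dummy)
  }
  list(X = X, y = as.numeric(rows[[spec$outcome]]), rows = rows)
}

#' Ordinary least squares on a design matrix
#'
#' Thin wrapper around [stats::lm.fit] returning coefficients, fitted
#' values, residuals and the conventional (centred) R-squared. The design
#' must have full column rank.
#'
#' @param X numeric design matrix including the intercept column.
#' @param y numeric outcome vector.
#' @return list with `coefficients`, `fitted`, `residuals`, `r_squared`,
#'   `n_obs`, `n_params`.
#' @export
fit_ols <- function(X, y) {
  if (nrow(X) <= ncol(X)) {
    stop("fit_ols: need more observations than parameters", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop("fit_ols: singular design (rank ", fit$rank, " < ", ncol(X), ")",
         call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  list(coefficients = fit$coefficients,
       fitted = drop(X %*% fit$coefficients),
       residuals = fit$residuals,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n_obs = nrow(X), n_params = ncol(X))
}

#' Case-resampling bootstrap standard errors
#'
#' Resamples whole (year, group) rows with replacement (size n), refits the
#' OLS on each resample, and reports the standard deviation of each
#' coefficient over the replications — the nonparametric bootstrap SE from
#' the empirical distribution, appropriate when n is too small to lean on
#' asymptotic normality. Rank-deficient resamples are redrawn (bounded);
#' the redraw count is returned as an attribute.
#'
#' @param X design matrix (full column rank).
#' @param y outcome vector.
#' @param reps bootstrap replications (>= 2).
#' @param seed integer seed; the same seed reproduces the SEs bit-exactly.
#' @param max_redraws cap on total redraws of degenerate resamples.
#' @return named numeric vector of standard errors, with attribute
#'   `redraws`.
#' @export
bootstrap_se <- function(X, y, reps = 1000L, seed = 1L, max_redraws = 1000L) {
  reps <- as.integer(reps)
  if (reps < 2L) stop("bootstrap_se: reps must be >= 2", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  set.seed(as.integer(seed))
  coefs <- matrix(NA_real_, nrow = reps, ncol = p,
                  dimnames = list(NULL, colnames(X)))
  redraws <- 0L
  for (b in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
      if (fit$rank == p) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("bootstrap_se: persistent rank deficiency in resamples",
             call. = FALSE)
      }
    }
    coefs[b, ] <- fit$coefficients
  }
  se <- apply(coefs, 2L, stats::sd)
  attr(se, "redraws") <- redraws
  se
}

#' Ramsey RESET specification test
#'
#' Augments the design with the 2nd, 3rd and 4th powers of the fitted
#' values and F-tests the joint nullity of the three added terms:
#' numerator df 3, denominator df `n - p - 3` where p counts the original
#' parameters (intercept included). A significant statistic signals
#' neglected nonlinearity / omitted variables.
#'
#' Degenerate fits (zero residual variance, or augmented terms collinear
#' with the design) carry no evidence of misspecification and are reported
#' as statistic 0 with p-value 1 and `degenerate = TRUE`.
#'
#' @param X design matrix including intercept.
#' @param y outcome vector.
#' @return list with `statistic` (F), `df` (c(3, n - p - 3)), `p_value`,
#'   `degenerate`.
#' @export
reset_test <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  df2 <- n - p - 3L
  if (df2 < 1L) {
    stop("reset_test: insufficient residual df (need n > n_params + 3)",
         call. = FALSE)
  }
  base <- fit_ols(X, y)
  rss0 <- sum(base$residuals^2)
  scale0 <- sum(y^2) / n + 1
  fsd <- stats::sd(base$fitted)
  if (rss0 <= scale0 * 1e-20 || fsd == 0) {
    return(list(statistic = 0, df = c(3L, df2), p_value = 1,
                degenerate = TRUE))
  }
  # Powers of the *standardised* fitted values span the same column space
  # (X contains the intercept and the fitted values) but stay
  # well-conditioned when the fitted values have a narrow range.
  g <- (base$fitted - mean(base$fitted)) / fsd
  aug <- cbind(X, fit2 = g^2, fit3 = g^3, fit4 = g^4)
  fit1 <- stats::lm.fit(aug, y)
  if (fit1$rank < ncol(aug)) {
    return(list(statistic = 0, df = c(3L, df2), p_value = 1,
                degenerate = TRUE))
  }
  rss1 <- sum(fit1$residuals^2)
  f <- ((rss0 - rss1) / 3) / (rss1 / df2)
  list(statistic = f, df = c(3L, df2),
       p_value = stats::pf(f, 3, df2, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Fit the panel regression with bootstrap SEs and RESET diagnostic
#'
#' One-call driver: builds the stacked design from the long panel
#' ([build_design]), fits OLS ([fit_ols]), attaches case-resampling
#' bootstrap standard errors ([bootstrap_se]) and the Ramsey RESET test
#' ([reset_test]).
#'
#' @inheritParams build_design
#' @return object of class `regression_result`: list with `coefficients`,
#'   `bootstrap_se`, `r_squared`, `n_obs`, `reset` (list from
#'   [reset_test]), and the `spec` used.
#' @export
regress_panel <- function(panel, spec = regression_spec(),
                          groups = c("male", "female")) {
  d <- build_design(panel, spec, groups)
  fit <- fit_ols(d$X, d$y)
  se <- bootstrap_se(d$X, d$y, reps = spec$bootstrap_reps, seed = spec$seed)
  rt <- reset_test(d$X, d$y)
  structure(list(coefficients = fit$coefficients, bootstrap_se = se,
                 r_squared = fit$r_squared, n_obs = fit$n_obs,
                 n_params = fit$n_params, reset = rt, spec = spec),
            class = "regression_result")
}

signif_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' @export
print.regression_result <- function(x, digits = 3L, ...) {
  z <- x$coefficients / x$bootstrap_se
  p <- 2 * stats::pnorm(-abs(z))
  cat("OLS with case-resampling bootstrap SEs (", x$spec$bootstrap_reps,
      " reps)\n\n", sep = "")
  tab <- data.frame(
    estimate = formatC(x$coefficients, format = "f", digits = digits),
    boot_se = paste0("(", formatC(x$bootstrap_se, format = "f",
                                  digits = digits), ")"),
    sig = signif_stars(p))
  print(tab)
  cat("\nObservations: ", x$n_obs,
      "\nR-squared: ", formatC(x$r_squared, format = "f", digits = digits),
      "\nRamsey RESET: F(", x$reset$df[1L], ", ", x$reset$df[2L], ") = ",
      formatC(x$reset$statistic, format = "f", digits = 2L),
      ", Prob > F = ", formatC(x$reset$p_value, format = "f", digits = 4L),
      "\nSig.: *** p<0.01, ** p<0.05, * p<0.1\n", sep = "")
  invisible(x)
}

#' Descriptive statistics for panel variables
#'
#' Per-variable mean, standard error of the mean and 95% confidence
#' interval using the t distribution with n − 1 degrees of freedom —
#' appropriate for the short annual series (and four-wave survey averages)
#' this package targets.
#'
#' @param x numeric vector, or data.frame of numeric columns.
#' @param conf confidence level; default 0.95.
#' @return data.frame with columns `variable`, `n`, `mean`, `se`,
#'   `ci_lower`, `ci_upper`.
#' @examples
#' describe_panel(c(27.72, 27.17, 27.01, 29.55))  # mean 27.86
#' @export
describe_panel <- function(x, conf = 0.95) {
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, logical(1L))]
    out <- do.call(rbind, lapply(names(num), function(v) {
      d <- describe_panel(num[[v]], conf)
      d$variable <- v
      d
    }))
    return(out[, c("variable", "n", "mean", "se", "ci_lower", "ci_upper")])
  }
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("describe_panel: need at least 2 observations",
                   call. = FALSE)
  m <- mean(x)
  se <- stats::sd(x) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
  data.frame(variable = "x", n = n, mean = m, se = se,
             ci_lower = m - tcrit * se, ci_upper = m + tcrit * se,
             stringsAsFactors = FALSE)
}
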