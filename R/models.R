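# Mixed-model inference: random-intercept LMMs / binomial GLMMs fitted by
# maximum likelihood, single-term-deletion likelihood-ratio tests, quadratic
# trend tests within robust predictor ranges, marginal contrasts with
# delta-method standard errors, and the central-F critical value used for
# sensitivity power analysis.

#' Fit a random-intercept mixed model by maximum likelihood
#'
#' Gaussian models are fitted with `lme4::lmer(REML = FALSE)`; binomial
#' models with `lme4::glmer` (logit link) using the Laplace approximation by
#' default (`nagq = 1`; larger values switch to adaptive Gauss-Hermite
#' quadrature). Factors are deviation (sum-to-zero) contrast coded by
#' default. Rows with missing values in any model variable are dropped
#' before fitting, and the complete-case data are stored so that nested
#' refits use identical rows. Non-convergence is reported via the
#' `converged` flag, never as an error.
#'
#' @param formula lme4-style model formula including the random intercept,
#'   e.g. `dilation_mm ~ volume + age + (1 | id)`.
#' @param data model data frame.
#' @param family `"gaussian"` or `"binomial"`.
#' @param contrasts contrast function name applied to factor predictors.
#' @param nagq integration points for binomial fits (1 = Laplace).
#' @return Object of class `mixed_fit`: coefficients, standard errors,
#'   covariance, random-intercept variance, log-likelihood, data, and the
#'   underlying `lme4` fit.
#' @export
fit_mixed <- function(formula, data, family = c("gaussian", "binomial"),
                      contrasts = "contr.sum", nagq = 1L) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  vars <- intersect(all.vars(formula), names(data))
  cc <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  grpvar <- vapply(lme4::findbars(formula), function(b) deparse(b[[3]]), "")
  if (!length(grpvar)) stop("fit_mixed requires a random-intercept term")
  if (length(unique(cc[[grpvar[1]]])) < 2L) {
    stop("fit_mixed requires at least 2 grouping units")
  }
  fvars <- vars[vapply(cc, is.factor, logical(1))]
  fvars <- setdiff(fvars, grpvar)
  clist <- stats::setNames(as.list(rep(contrasts, length(fvars))), fvars)
  fit <- withCallingHandlers(
    if (family == "gaussian") {
      lme4::lmer(formula, data = cc, REML = FALSE,
                 contrasts = if (length(clist)) clist else NULL)
    } else {
      lme4::glmer(formula, data = cc, family = stats::binomial(),
                  nAGQ = nagq,
                  contrasts = if (length(clist)) clist else NULL)
    },
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri <- vc$vcov[vc$grp == grpvar[1] & vc$var1 == "(Intercept)"][1]
  structure(list(
    formula = formula, family = family, contrasts = clist,
    coef = beta, se = sqrt(diag(V)), vcov = V,
    ranef_var = ri, logLik = as.numeric(stats::logLik(fit)),
    df = attr(stats::logLik(fit), "df"), nobs = nrow(cc),
    converged = is.null(msgs) ||
      !any(grepl("failed to converge", msgs, ignore.case = TRUE)),
    data = cc, model = fit), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Mixed model (", x$family, ", ML): ",
      deparse(x$formula), "\n", sep = "")
  print(round(cbind(estimate = x$coef, se = x$se), 4))
  cat("random-intercept variance:", signif(x$ranef_var, 4),
      " logLik:", round(x$logLik, 2), " n:", x$nobs, "\n")
  invisible(x)
}

# fixed-effect term labels of an lme4 formula
fixed_terms_ <- function(formula) {
  attr(stats::terms(lme4::nobars(formula)), "term.labels")
}

# rebuild an lme4 formula from fixed terms + the original random parts
rebuild_formula_ <- function(formula, fixed) {
  resp <- deparse(formula[[2]])
  bars <- vapply(lme4::findbars(formula),
                 function(b) paste0("(", deparse(b), ")"), "")
  rhs <- paste(c(if (length(fixed)) fixed else "1", bars), collapse = " + ")
  stats::as.formula(paste(resp, "~", rhs), env = environment(formula))
}

#' Likelihood-ratio test of a single term deletion
#'
#' Refits the model without `term` on the identical complete-case rows and
#' compares by likelihood ratio: `chisq = 2 (logLik_full - logLik_reduced)`,
#' degrees of freedom = number of parameters dropped, p from the upper
#' chi-square tail. Raises if the term participates in a retained
#' interaction.
#'
#' @param fit full model from [fit_mixed()].
#' @param term fixed-effect term label to delete.
#' @return List with `term`, `chisq`, `df`, `p` and the reduced fit.
#' @export
lrt_single_term <- function(fit, term) {
  labs <- fixed_terms_(fit$formula)
  if (!term %in% labs) stop("term '", term, "' is not in the model")
  keep <- setdiff(labs, term)
  parts <- function(lbl) strsplit(lbl, ":", fixed = TRUE)[[1]]
  higher <- vapply(keep, function(l) all(parts(term) %in% parts(l)) &&
                     length(parts(l)) > length(parts(term)), logical(1))
  if (any(higher)) {
    stop("cannot delete '", term, "': it participates in retained ",
         "interaction(s) ", paste(keep[higher], collapse = ", "))
  }
  red <- fit_mixed(rebuild_formula_(fit$formula, keep), fit$data,
                   family = fit$family)
  chisq <- max(0, 2 * (fit$logLik - red$logLik))
  df <- fit$df - red$df
  list(term = term, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE), reduced = red)
}

#' Quadratic trend test within a robust predictor range
#'
#' Trims rows outside the `trim` quantiles of the predictor (to minimise
#' edge effects on the quadratic term), centres the predictor, then
#' compares linear vs. linear-plus-quadratic fits with a 1-df likelihood-
#' ratio test. Centring leaves the quadratic coefficient unchanged.
#'
#' @param data model data frame.
#' @param outcome,predictor column names.
#' @param covariates additional fixed-effect term labels.
#' @param group random-intercept grouping column.
#' @param family `"gaussian"` or `"binomial"`.
#' @param trim predictor quantile range retained; `c(0, 1)` disables
#'   trimming.
#' @return List with both fits, the LRT (`chisq`, `df`, `p`) and the
#'   quadratic coefficient and its standard error.
#' @export
quadratic_test <- function(data, outcome, predictor, covariates = character(),
                           group = "id", family = "gaussian",
                           trim = c(0.01, 0.99)) {
  data <- as.data.frame(data)
  x <- data[[predictor]]
  qs <- stats::quantile(x, trim, na.rm = TRUE)
  keep <- !is.na(x) & x >= qs[1] & x <= qs[2]
  if (!any(keep)) stop("quadratic_test: trimming removed every row")
  d <- data[keep, , drop = FALSE]
  d$.x <- d[[predictor]] - mean(d[[predictor]], na.rm = TRUE)
  f_lin <- stats::as.formula(paste(
    outcome, "~", paste(c(".x", covariates,
                          paste0("(1 | ", group, ")")), collapse = " + ")))
  f_quad <- stats::as.formula(paste(
    outcome, "~", paste(c(".x", "I(.x^2)", covariates,
                          paste0("(1 | ", group, ")")), collapse = " + ")))
  fl <- fit_mixed(f_lin, d, family = family)
  fq <- fit_mixed(f_quad, d, family = family)
  chisq <- max(0, 2 * (fq$logLik - fl$logLik))
  list(fit_linear = fl, fit_quadratic = fq,
       chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE),
       quad_coef = unname(fq$coef["I(.x^2)"]),
       quad_se = unname(fq$se["I(.x^2)"]))
}

#' Marginal contrasts between factor levels
#'
#' Estimated marginal means per level of `factor` — covariates held at the
#' values in `at` (sample means otherwise), other factors averaged with
#' equal weights — and pairwise differences with delta-method standard
#' errors, all as linear combinations of the fixed-effect coefficients.
#'
#' @param fit model from [fit_mixed()].
#' @param factor factor name in the fitted design.
#' @param at named list of covariate values at which to evaluate.
#' @param pairs list of level pairs to contrast (default: all unordered
#'   pairs).
#' @return List with `means` (per-level estimate and SE) and `contrasts`
#'   (pairwise estimate, SE, z, p).
#' @export
marginal_contrasts <- function(fit, factor, at = list(), pairs = NULL) {
  d <- fit$data
  if (!factor %in% names(d) || !is.factor(d[[factor]])) {
    stop("'", factor, "' is not a factor in the fitted design")
  }
  tt <- stats::delete.response(stats::terms(lme4::nobars(fit$formula)))
  vars <- setdiff(all.vars(tt), factor)
  grid1 <- list(stats::setNames(list(levels(d[[factor]])), factor))
  others <- lapply(vars, function(v) {
    if (is.factor(d[[v]])) {
      stats::setNames(list(levels(d[[v]])), v)
    } else {
      val <- if (v %in% names(at)) at[[v]] else mean(d[[v]], na.rm = TRUE)
      stats::setNames(list(val), v)
    }
  })
  grid <- expand.grid(c(grid1[[1]], unlist(others, recursive = FALSE)),
                      stringsAsFactors = FALSE)
  for (v in names(grid)) {
    if (is.factor(d[[v]])) grid[[v]] <- factor(grid[[v]], levels(d[[v]]))
  }
  X <- stats::model.matrix(tt, grid,
                           contrasts.arg = if (length(fit$contrasts))
                             fit$contrasts else NULL)
  lev <- levels(d[[factor]])
  Xbar <- t(vapply(lev, function(l) colMeans(X[grid[[factor]] == l, ,
                                               drop = FALSE]),
                   numeric(ncol(X))))
  est <- drop(Xbar %*% fit$coef)
  Vm <- Xbar %*% fit$vcov %*% t(Xbar)
  means <- data.frame(level = lev, estimate = est, se = sqrt(diag(Vm)),
                      row.names = NULL)
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  }
  ctr <- do.call(rbind, lapply(pairs, function(p) {
    if (!all(p %in% lev)) stop("level(s) absent from the design: ",
                               paste(setdiff(p, lev), collapse = ", "))
    i <- match(p[1], lev); j <- match(p[2], lev)
    L <- Xbar[i, ] - Xbar[j, ]
    e <- sum(L * fit$coef)
    s <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    z <- if (s > 0) e / s else 0
    data.frame(contrast = paste(p[1], "-", p[2]), estimate = e, se = s,
               z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }))
  rownames(ctr) <- NULL
  list(means = means, contrasts = ctr)
}

#' Critical value of the central F distribution
#'
#' Upper-tail `alpha` quantile, as used in sensitivity power analysis of a
#' repeated-measures design.
#'
#' @param alpha error probability in (0, 1).
#' @param df1,df2 numerator and denominator degrees of freedom (> 0).
#' @return The critical F value.
#' @export
critical_f <- function(alpha, df1, df2) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.finite(df1) || !is.finite(df2) || df1 <= 0 || df2 <= 0) {
    stop("degrees of freedom must be positive")
  }
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}
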