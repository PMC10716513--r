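# Multiple imputation of missing trial-level measures by chained equations
# with regression trees (donor-based, non-parametric), and Rubin-rules
# pooling of downstream model fits.

# One CART imputation draw: fit a tree of y on the predictors over observed
# rows, locate each missing row's terminal leaf, and sample a donor from the
# observed y values in that leaf.
cart_draw_ <- function(y, preds, miss) {
  df <- cbind(data.frame(.y = y), preds)
  fit <- rpart::rpart(.y ~ ., data = df[!miss, , drop = FALSE],
                      method = "anova",
                      control = rpart::rpart.control(minbucket = 5, cp = 1e-4,
                                                     xval = 0))
  if (nrow(fit$frame) == 1L) {  # no split: donors are all observed values
    return(sample(y[!miss], sum(miss), replace = TRUE))
  }
  leaf_rows <- which(fit$frame$var == "<leaf>")
  leaf_mean <- fit$frame$yval[leaf_rows]
  pred_new <- stats::predict(fit, newdata = df[miss, , drop = FALSE])
  leaf_of_new <- leaf_rows[match(pred_new, leaf_mean)]
  where_obs <- fit$where  # leaf row index per training row
  yobs <- y[!miss]
  vapply(leaf_of_new, function(lf) {
    donors <- yobs[where_obs == lf]
    if (!length(donors)) donors <- yobs
    donors[sample.int(length(donors), 1L)]
  }, numeric(1))
}

# One PMM draw: linear model on observed rows, match each missing row's
# predicted value to the k nearest observed predictions, sample a donor.
pmm_draw_ <- function(y, preds, miss, k = 5L) {
  df <- cbind(data.frame(.y = y), preds)
  fit <- stats::lm(.y ~ ., data = df[!miss, , drop = FALSE])
  yhat_obs <- stats::predict(fit)
  yhat_mis <- stats::predict(fit, newdata = df[miss, , drop = FALSE])
  yobs <- y[!miss]
  vapply(yhat_mis, function(p) {
    d <- abs(yhat_obs - p)
    cand <- order(d)[seq_len(min(k, length(d)))]
    yobs[cand[sample.int(length(cand), 1L)]]
  }, numeric(1))
}

#' Multiple imputation of a trial table
#'
#' Chained-equation imputation of the numeric columns that contain missing
#' cells, using a non-parametric regression-tree learner (default) or
#' predictive mean matching. Each of the `m` imputations runs an independent
#' chain: missing cells are initialised by random draws from the observed
#' values, then each incomplete column (visited in order of increasing
#' missingness) is re-imputed from all other analysis columns for `maxit`
#' iterations. Imputed values are donor-based, hence always within the
#' observed range. Observed cells are identical across all `m` tables.
#'
#' @param table analysis trial table (data frame); id and design columns
#'   must be complete.
#' @param m number of imputations.
#' @param method `"cart"` (regression trees) or `"pmm"` (predictive mean
#'   matching).
#' @param seed integer seed.
#' @param vars columns to impute; default: all numeric columns with any
#'   missing cell.
#' @param maxit chained-equation iterations per imputation.
#' @return An object of class `imputation_set`: list with `m`, `method`,
#'   `vars`, `seed` and `tables` (list of completed data frames).
#' @export
impute_trials <- function(table, m = 100, method = c("cart", "pmm"),
                          seed = 1, vars = NULL, maxit = 5L) {
  method <- match.arg(method)
  table <- as.data.frame(table)
  numcols <- names(table)[vapply(table, is.numeric, logical(1))]
  if (is.null(vars)) {
    vars <- numcols[vapply(table[numcols], anyNA, logical(1))]
  }
  if (length(vars)) {
    allmiss <- vars[vapply(table[vars], function(v) all(is.na(v)), logical(1))]
    if (length(allmiss)) {
      stop("cannot impute entirely missing column(s): ",
           paste(allmiss, collapse = ", "))
    }
    if (!all(vars %in% numcols)) stop("impute_trials handles numeric columns")
  }
  # predictors: all analysis columns except ids and the target
  predcols <- setdiff(names(table), c("id", "trial"))
  draw <- if (method == "cart") cart_draw_ else pmm_draw_

  out <- with_seed_(seed, {
    if (!length(vars)) {
      replicate(m, table, simplify = FALSE)
    } else {
      ord <- vars[order(vapply(table[vars], function(v) mean(is.na(v)),
                               numeric(1)))]
      lapply(seq_len(m), function(j) {
        tab <- table
        for (v in ord) {  # initialise from observed marginals
          mi <- is.na(tab[[v]])
          tab[[v]][mi] <- sample(tab[[v]][!mi], sum(mi), replace = TRUE)
        }
        for (it in seq_len(maxit)) {
          for (v in ord) {
            mi <- is.na(table[[v]])
            if (!any(mi)) next
            preds <- tab[setdiff(predcols, v)]
            y <- tab[[v]]
            y[mi] <- NA
            tab[[v]][mi] <- draw(y, preds, mi)
          }
        }
        tab
      })
    }
  })
  structure(list(m = m, method = method, vars = vars, seed = seed,
                 tables = out),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, "(", x$method, "), columns:",
      if (length(x$vars)) paste(x$vars, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Pool model fits across imputations (Rubin's rules)
#'
#' Combines `m` fits of the same model specification: pooled estimate is the
#' mean of the per-imputation estimates; total variance is the within-
#' imputation variance W plus `(1 + 1/m)` times the between-imputation
#' variance B; degrees of freedom follow the classic
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2` formula.
#'
#' @param fits list of [fit_mixed()] results (or any objects with `coef`
#'   and `se` numeric vectors of matching names).
#' @return Data frame with pooled `estimate`, `se`, `df`, `statistic`, `p`
#'   per coefficient.
#' @export
pool_fits <- function(fits) {
  m <- length(fits)
  if (m < 2L) stop("pooling requires at least 2 fits")
  getcoef <- function(f) if (inherits(f, "mixed_fit")) f$coef else f$coef
  getse <- function(f) if (inherits(f, "mixed_fit")) f$se else f$se
  nm <- names(getcoef(fits[[1]]))
  for (f in fits) {
    if (!identical(names(getcoef(f)), nm)) {
      stop("pool_fits: mismatched coefficient sets across fits")
    }
  }
  est <- do.call(rbind, lapply(fits, getcoef))
  se <- do.call(rbind, lapply(fits, getse))
  qbar <- colMeans(est)
  W <- colMeans(se^2)
  B <- apply(est, 2, stats::var)
  Tt <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  stat <- qbar / sqrt(Tt)
  data.frame(term = nm, estimate = qbar, se = sqrt(Tt), df = df,
             statistic = stat,
             p = 2 * stats::pt(abs(stat), df, lower.tail = FALSE),
             row.names = NULL)
}
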