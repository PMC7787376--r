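#' Multiple imputation by fully conditional specification
#'
#' Chained-equations imputation of a respondent-level analysis table.
#' Each incomplete variable is imputed in rotation from a conditional
#' model on all other modelled variables: continuous variables by Bayesian
#' linear regression with proper posterior parameter draws (scaled
#' inverse-chi-squared for the residual variance, normal for the
#' coefficients, then a fresh noise draw per missing cell), binary
#' variables by logistic regression with coefficients drawn from the
#' asymptotic posterior and Bernoulli imputation. The cycle repeats
#' `maxit` times per imputation; observed cells are never altered.
#'
#' @param data A data frame. Columns in `vars` must be numeric (continuous)
#'   or two-valued 0/1 / logical (binary); other columns are carried
#'   through untouched.
#' @param m Number of imputations (>= 2; default 20).
#' @param maxit Chained-equation cycles per imputation (default 10).
#' @param seed Required integer seed; the whole run is reproducible from it.
#' @param vars Variables to impute and to use as predictors of each other
#'   (default: every numeric/logical column except `respondent_id`). At
#'   least one of them must be fully observed.
#' @param ridge Small ridge added to the cross-product matrix for
#'   numerical stability (default 1e-5).
#' @return An object of class `vad_mids`: list with `imputations` (list of
#'   `m` completed tibbles), `m`, `maxit`, `seed`, `where` (logical matrix
#'   of originally-missing cells), `method` (named vector over `vars`).
#' @export
impute_fcs <- function(data, m = 20, maxit = 10, seed,
                       vars = NULL, ridge = 1e-5) {
  if (missing(seed) || is.null(seed)) {
    stop("impute_fcs() requires an explicit seed", call. = FALSE)
  }
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  data <- tibble::as_tibble(data)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, function(x)
      is.numeric(x) || is.logical(x), logical(1))]
    vars <- setdiff(vars, "respondent_id")
  }
  absent <- setdiff(vars, names(data))
  if (length(absent) > 0) stop("unknown vars: ", paste(absent, collapse = ", "),
                               call. = FALSE)
  work <- as.data.frame(data[vars])
  for (v in vars) if (is.logical(work[[v]])) work[[v]] <- as.numeric(work[[v]])
  method <- vapply(vars, function(v) {
    obs <- work[[v]][!is.na(work[[v]])]
    if (length(obs) == 0) stop("variable ", v, " is entirely missing",
                               call. = FALSE)
    if (all(obs %in% c(0, 1)) && length(unique(obs)) <= 2) "logistic"
    else "normal"
  }, character(1))
  where <- is.na(as.matrix(work))
  incomplete <- vars[colSums(where[, vars, drop = FALSE]) > 0]
  if (length(incomplete) > 0 && all(vars %in% incomplete)) {
    stop("at least one modelled variable must be fully observed",
         call. = FALSE)
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  imputations <- vector("list", m)
  for (imp in seq_len(m)) {
    filled <- work
    # initial fill: random draws from the observed margin
    for (v in incomplete) {
      nmis <- sum(where[, v])
      obs <- filled[[v]][!where[, v]]
      filled[[v]][where[, v]] <- sample(obs, nmis, replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in incomplete) {
        preds <- setdiff(vars, v)
        filled[[v]][where[, v]] <- impute_one(
          y = filled[[v]], X = as.matrix(filled[preds]),
          mis = where[, v], method = method[[v]], ridge = ridge
        )
      }
    }
    done <- data
    for (v in vars) {
      col <- filled[[v]]
      if (is.logical(data[[v]])) col <- as.logical(col)
      done[[v]] <- col
    }
    imputations[[imp]] <- done
  }
  structure(list(imputations = imputations, m = m, maxit = maxit,
                 seed = seed, where = where, method = method, vars = vars),
            class = "vad_mids")
}

# one conditional-model draw; returns imputed values for the missing cells
impute_one <- function(y, X, mis, method, ridge = 1e-5) {
  Xobs <- cbind(1, X[!mis, , drop = FALSE])
  Xmis <- cbind(1, X[mis, , drop = FALSE])
  yobs <- y[!mis]
  if (method == "normal") {
    xtx <- crossprod(Xobs)
    pen <- diag(ridge * (diag(xtx) + 1), ncol(xtx))
    V <- solve(xtx + pen)
    beta_hat <- V %*% crossprod(Xobs, yobs)
    resid <- yobs - Xobs %*% beta_hat
    df <- max(1, length(yobs) - ncol(Xobs))
    sigma2 <- sum(resid^2) / stats::rchisq(1, df)
    beta <- beta_hat + t(chol(sigma2 * (V + t(V)) / 2)) %*%
      stats::rnorm(ncol(Xobs))
    as.vector(Xmis %*% beta + sqrt(sigma2) * stats::rnorm(nrow(Xmis)))
  } else {
    # logistic with asymptotic-posterior coefficient draw
    fit <- suppressWarnings(stats::glm.fit(Xobs, yobs,
                                           family = stats::binomial()))
    beta_hat <- fit$coefficients
    beta_hat[is.na(beta_hat)] <- 0
    w <- fit$weights
    xtwx <- crossprod(Xobs * sqrt(pmax(w, 1e-8)))
    pen <- diag(ridge * (diag(xtwx) + 1), ncol(xtwx))
    V <- solve(xtwx + pen)
    beta <- beta_hat + t(chol((V + t(V)) / 2)) %*% stats::rnorm(ncol(Xobs))
    p <- stats::plogis(as.vector(Xmis %*% beta))
    stats::rbinom(nrow(Xmis), 1, p)
  }
}

#' Extract one completed dataset
#' @param mids A `vad_mids` object from [impute_fcs()].
#' @param i Imputation index in 1..m.
#' @return The i-th completed tibble.
#' @export
complete_table <- function(mids, i = 1) {
  stopifnot(inherits(mids, "vad_mids"))
  if (i < 1 || i > mids$m) stop("i must lie in 1..m", call. = FALSE)
  mids$imputations[[i]]
}

#' @export
print.vad_mids <- function(x, ...) {
  cat("<vad_mids> m =", x$m, "imputations,", x$maxit,
      "cycles, seed", x$seed, "\n")
  nmis <- colSums(x$where)
  nmis <- nmis[nmis > 0]
  if (length(nmis)) {
    cat("missing cells:",
        paste(names(nmis), nmis, sep = "=", collapse = ", "), "\n")
  } else cat("no missing cells\n")
  invisible(x)
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines m (estimate, SE) pairs: pooled estimate = mean; total variance
#' T = W + (1 + 1/m) B with W the mean squared SE and B the between-
#' imputation variance; degrees of freedom by the Barnard-Rubin
#' small-sample formula when a complete-data df is supplied, else the
#' classic large-sample formula. When all estimates are identical (B = 0)
#' the pooled SE reduces to the within-imputation SE and the reference
#' distribution is taken as normal (infinite df).
#'
#' @param estimates Numeric vector of per-imputation point estimates
#'   (m >= 2).
#' @param ses Numeric vector of per-imputation standard errors.
#' @param df_com Complete-data degrees of freedom (e.g. n - p - 1) for the
#'   Barnard-Rubin adjustment; `Inf` (default) gives the classic formula.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `vad_pooled`: `estimate`, `se`, `W`, `B`,
#'   `T`, `df`, `riv`, `fmi`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high`, `m`.
#' @examples
#' pool_estimates(c(1, 2), c(.5, .5))  # W .25, B .5, T 1
#' @export
pool_estimates <- function(estimates, ses, df_com = Inf, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations to pool", call. = FALSE)
  if (length(ses) != m) stop("estimates and ses differ in length",
                             call. = FALSE)
  qbar <- mean(estimates)
  W <- mean(ses^2)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B == 0) {
    df <- Inf
    riv <- 0
  } else {
    riv <- (1 + 1 / m) * B / W
    df_old <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    if (is.finite(df_com)) {
      lambda <- (1 + 1 / m) * B / Tv
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  se <- sqrt(Tv)
  stat <- qbar / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else
    2 * stats::pnorm(-abs(stat))
  tq <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    estimate = qbar, se = se, W = W, B = B, T = Tv, df = df,
    riv = riv, fmi = if (Tv > 0) (1 + 1 / m) * B / Tv else 0,
    statistic = stat, p.value = p,
    conf.low = qbar - tq * se, conf.high = qbar + tq * se,
    conf_level = conf_level, m = m
  ), class = "vad_pooled")
}

#' @export
print.vad_pooled <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate %.4f (SE %.4f), t = %.3f, df = %.1f, p = %.4g\n",
    x$estimate, x$se, x$statistic, x$df, x$p.value))
  cat(sprintf("  W = %.5f, B = %.5f, T = %.5f, m = %d, fmi = %.3f\n",
              x$W, x$B, x$T, x$m, x$fmi))
  invisible(x)
}

#' Run an analysis on every completed dataset and pool it
#'
#' Applies `fn` -- any analysis returning a tibble with columns `term`,
#'   `estimate`, `se` (optionally `df_com`) -- to each completed copy and
#' pools each term's estimates by Rubin's rules. Model-fit statistics that
#' have no within-imputation variance attached (R-squared, F) are not
#' poolable this way; report them as across-imputation ranges with
#' [fit_stat_range()].
#'
#' @param mids A `vad_mids` object.
#' @param fn Function of one completed data frame returning a tibble with
#'   `term`, `estimate`, `se` and optionally a constant `df_com` column.
#' @param df_com Complete-data df override passed to [pool_estimates()];
#'   `NULL` uses `fn`'s `df_com` column when present, else `Inf`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per term: pooled `estimate`, `se`,
#'   `statistic`, `df`, `p.value`, `conf.low`, `conf.high`, `B`, `W`,
#'   `fmi`.
#' @export
pooled_analysis <- function(mids, fn, df_com = NULL, conf_level = 0.95) {
  stopifnot(inherits(mids, "vad_mids"))
  per <- purrr::map(mids$imputations, function(dat) {
    res <- fn(dat)
    if (!all(c("term", "estimate", "se") %in% names(res))) {
      stop("fn must return columns term, estimate, se", call. = FALSE)
    }
    res
  })
  terms <- per[[1]]$term
  for (res in per) {
    if (!identical(res$term, terms)) {
      stop("fn returned differing terms across imputations", call. = FALSE)
    }
  }
  purrr::map_dfr(terms, function(tm) {
    est <- vapply(per, function(r) r$estimate[r$term == tm], numeric(1))
    se <- vapply(per, function(r) r$se[r$term == tm], numeric(1))
    dfc <- if (!is.null(df_com)) df_com
      else if ("df_com" %in% names(per[[1]])) {
        per[[1]]$df_com[per[[1]]$term == tm]
      } else Inf
    p <- pool_estimates(est, se, df_com = dfc, conf_level = conf_level)
    tibble::tibble(term = tm, estimate = p$estimate, se = p$se,
                   statistic = p$statistic, df = p$df, p.value = p$p.value,
                   conf.low = p$conf.low, conf.high = p$conf.high,
                   B = p$B, W = p$W, fmi = p$fmi)
  })
}

#' Range of a fit statistic across completed datasets
#'
#' Applies a scalar-valued function to every completed copy and reports
#' the minimum and maximum -- the conventional way to present
#' non-poolable fit statistics (R-squared, F) under multiple imputation.
#' With complete data the range collapses to a point.
#'
#' @param mids A `vad_mids` object.
#' @param fn Function of one completed data frame returning a single
#'   number.
#' @param name Label for the statistic (default `"statistic"`).
#' @return A one-row tibble: `statistic`, `min`, `max`.
#' @export
fit_stat_range <- function(mids, fn, name = "statistic") {
  stopifnot(inherits(mids, "vad_mids"))
  vals <- vapply(mids$imputations, function(dat) as.numeric(fn(dat)),
                 numeric(1))
  tibble::tibble(statistic = name, min = min(vals), max = max(vals))
}
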