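#' Survival-aware multiple imputation of missing covariates
#'
#' Chained-equations imputation of missing covariate values, with the event
#' indicator and the Nelson-Aalen cumulative-hazard estimate (computed once on
#' the full dataset, evaluated at each participant's observed time) included
#' as predictors, as recommended for Cox-model covariate imputation. Numeric
#' columns are imputed by Bayesian linear regression draws, logical columns by
#' logistic regression draws, and factors with 3 or more levels by multinomial
#' regression draws ([nnet::multinom()]). Missingness is only allowed in
#' covariates, never in `time`, `event` or `exposure`.
#'
#' @param data a survival dataset (see [build_survival_dataset()]): columns
#'   `time`, `event`, `exposure` and covariates, possibly with `NA`s.
#' @param m number of imputed datasets.
#' @param maxit chained-equation iterations per imputation.
#' @param seed RNG seed.
#' @return object of class `imputed_datasets`: list with `datasets` (length
#'   `m`), `m`, and the names of imputed columns. With no missing values the
#'   `m` datasets are identical copies of the input.
#' @export
impute_missing <- function(data, m = 10, maxit = 5, seed = 1L) {
  if (!all(c("time", "event", "exposure") %in% names(data)))
    stop("`data` must have columns time, event, exposure")
  key <- c("time", "event", "exposure")
  if (any(is.na(data$time)) || any(is.na(data$event)) || any(is.na(data$exposure)))
    stop("missing values are only allowed in covariates, not time/event/exposure")
  drop_cols <- intersect(c("id", "participant_id"), names(data))
  covs <- setdiff(names(data), c(key, drop_cols))
  na_cols <- covs[vapply(covs, function(cl) anyNA(data[[cl]]), logical(1))]
  frac <- vapply(na_cols, function(cl) mean(is.na(data[[cl]])), numeric(1))
  if (any(frac >= 1)) stop(sprintf("column(s) entirely missing: %s",
                                   paste(na_cols[frac >= 1], collapse = ", ")))
  if (any(frac > 0.5))
    warning(sprintf("column(s) with more than 50%% missing: %s",
                    paste(na_cols[frac > 0.5], collapse = ", ")))

  if (length(na_cols) == 0) {
    return(structure(list(datasets = replicate(m, data, simplify = FALSE),
                          m = m, imputed = character(0)),
                     class = "imputed_datasets"))
  }

  # Nelson-Aalen cumulative hazard at each observed time, from the full data
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = data.frame(time = data$time, event = as.logical(data$event)),
                          stype = 2, ctype = 1)
  na_step <- stats::stepfun(sf$time, c(0, sf$cumhaz))
  aux <- data.frame(event = as.numeric(data$event), na_cumhaz = na_step(data$time),
                    exposure = as.numeric(data$exposure))

  set.seed(stage_seed(seed, "participants") + 7L)
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    imp <- data
    # initial fill: draw from the observed margin
    for (cl in na_cols) {
      miss <- is.na(imp[[cl]])
      obs <- imp[[cl]][!miss]
      imp[[cl]][miss] <- sample(obs, sum(miss), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (cl in na_cols) {
        miss <- is.na(data[[cl]])
        rhs <- cbind(imp[setdiff(covs, cl)], aux)
        imp[[cl]][miss] <- draw_imputation(data[[cl]], imp[[cl]], rhs, miss)
      }
    }
    datasets[[k]] <- imp
  }
  structure(list(datasets = datasets, m = m, imputed = na_cols),
            class = "imputed_datasets")
}

# one conditional draw for the missing entries of `orig` given predictors
draw_imputation <- function(orig, current, rhs, miss) {
  yobs <- orig[!miss]
  X <- stats::model.matrix(~ ., data = rhs)
  if (is.numeric(orig) && !is.logical(orig)) {
    # Bayesian linear regression draw (sigma^2 from scaled inv-chi-square,
    # beta from its normal posterior), as in standard chained-equation `norm`
    Xo <- X[!miss, , drop = FALSE]
    qrx <- qr(Xo)
    keep <- qrx$pivot[seq_len(qrx$rank)]
    Xo <- Xo[, keep, drop = FALSE]
    bhat <- qr.coef(qr(Xo), yobs)
    res <- yobs - Xo %*% bhat
    df <- max(length(yobs) - ncol(Xo), 1)
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    V <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
    bstar <- bhat + drop(chol(sigma2 * V) %*% stats::rnorm(ncol(Xo)))
    mu <- drop(X[miss, keep, drop = FALSE] %*% bstar)
    return(mu + stats::rnorm(sum(miss), 0, sqrt(sigma2)))
  }
  if (is.logical(orig)) {
    dfit <- data.frame(y = as.numeric(yobs), rhs[!miss, , drop = FALSE])
    g <- suppressWarnings(stats::glm(y ~ ., data = dfit, family = stats::binomial()))
    p <- suppressWarnings(stats::predict(g, newdata = rhs[miss, , drop = FALSE],
                                         type = "response"))
    return(stats::runif(sum(miss)) < p)
  }
  # factor with >= 2 levels: multinomial draw
  dfit <- data.frame(y = factor(yobs), rhs[!miss, , drop = FALSE])
  fitm <- suppressWarnings(nnet::multinom(y ~ ., data = dfit, trace = FALSE))
  p <- stats::predict(fitm, newdata = rhs[miss, , drop = FALSE], type = "probs")
  lev <- levels(dfit$y)
  if (length(lev) == 2) p <- cbind(1 - p, p)
  p <- matrix(p, ncol = length(lev))
  picks <- apply(p, 1, function(pr) sample(lev, 1, prob = pr))
  factor(picks, levels = levels(orig))
}

#' @export
print.imputed_datasets <- function(x, ...) {
  cat(sprintf("Multiple imputation: m = %d dataset(s), imputed column(s): %s\n",
              x$m, if (length(x$imputed)) paste(x$imputed, collapse = ", ") else "none"))
  invisible(x)
}

#' Fit a Cox model on each imputed dataset and pool by Rubin's rules
#'
#' The pooled log hazard ratio is the mean of the per-imputation estimates;
#' its variance is the within-imputation mean plus `(1 + 1/m)` times the
#' between-imputation variance. The interval uses the standard small-sample
#' degrees of freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2`; with zero
#' between-imputation variance (e.g. no missing data) the pooled result
#' reduces exactly to a single fit.
#'
#' @param imputations an [impute_missing()] result.
#' @param spec a [model_spec()].
#' @param ... passed to [fit_cox()].
#' @return a pooled `cox_result` (no `fit` component; `n_imputations_pooled`
#'   records `m`).
#' @export
fit_cox_pooled <- function(imputations, spec = model_spec(2), ...) {
  stopifnot(inherits(imputations, "imputed_datasets"))
  fits <- lapply(imputations$datasets, fit_cox, spec = spec, ...)
  q <- vapply(fits, function(f) f$log_hr, numeric(1))
  w <- vapply(fits, function(f) f$log_hr_se^2, numeric(1))
  m <- imputations$m
  qbar <- mean(q)
  W <- mean(w)
  B <- if (m > 1) stats::var(q) else 0
  Tvar <- W + (1 + 1 / m) * B
  se <- sqrt(Tvar)
  df <- if (B <= .Machine$double.eps * max(W, 1)) Inf
        else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  tq <- if (is.finite(df)) stats::qt(0.975, df) else 1.959964
  out <- fits[[1]]
  out$hr <- exp(qbar)
  out$log_hr <- qbar
  out$log_hr_se <- se
  out$ci_low <- exp(qbar - tq * se)
  out$ci_high <- exp(qbar + tq * se)
  out$n_imputations_pooled <- m
  out$between_variance <- B
  out$within_variance <- W
  out$fit <- NULL
  out
}
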