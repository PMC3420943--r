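#' Variable transforms used by the association models
#'
#' The mapping is fixed by the study design and enforced by the pipeline
#' configuration: relative compound proportions (tissue/stage-style data)
#' use `arcsin_sqrt` (`f(x) = asin(sqrt(x))`, defined on `[0, 1]`);
#' absolute compound amounts in micrograms (population-style data) use
#' `ln_shift` (`f(x) = ln(x + 0.01)`, shift exactly 0.01); expression
#' intensities use `sqrt`.  `NA`/`NaN` propagate; out-of-domain values are
#' an error naming the offending index.
#'
#' @param values numeric vector.
#' @param tag one of `"arcsin_sqrt"`, `"ln_shift"`, `"sqrt"`,
#'   `"identity"`.
#' @param name optional variable name carried on the result.
#' @return a `transformed_variable`: list `name`, `raw`, `tag`, `values`.
#' @export
apply_transform <- function(values, tag = c("arcsin_sqrt", "ln_shift",
                                            "sqrt", "identity"),
                            name = NULL) {
  tag <- match.arg(tag)
  stopifnot(is.numeric(values))
  check <- function(bad, what) {
    bad <- which(bad & !is.na(values))
    if (length(bad) > 0) {
      stop(tag, ": ", what, " at index ", bad[1],
           " (value ", values[bad[1]], ")")
    }
  }
  out <- switch(tag,
    arcsin_sqrt = {
      check(values < 0 | values > 1, "value outside [0, 1]")
      asin(sqrt(values))
    },
    ln_shift = {
      check(values < 0, "negative amount")
      log(values + 0.01)
    },
    sqrt = {
      check(values < 0, "negative value")
      sqrt(values)
    },
    identity = values)
  structure(list(name = name %||% tag, raw = values, tag = tag,
                 values = out),
            class = "transformed_variable")
}

tv_values <- function(x) {
  if (inherits(x, "transformed_variable")) x$values else as.numeric(x)
}

#' Fit an expression-phenotype association model
#'
#' Gaussian-error linear model by ordinary least squares when no grouping
#' is given ("GLM" on transformed variables); with a grouping factor, a
#' random-intercept linear mixed model fitted by REML ("LME with
#' population as random factor").  Reports coefficients, per-term p-values
#' (t-based for the fixed model; Wald normal approximation for fixed
#' effects of the mixed model), adjusted R-squared
#' (`1 - (1 - R^2)(n - 1)/(n - k - 1)`, fixed-only model) and AIC.
#'
#' @param response numeric vector or [apply_transform()] result.
#' @param predictors named list of numeric vectors or
#'   `transformed_variable`s.
#' @param population optional grouping factor for the random intercept.
#' @return an `association_result`: data frame (`term`, `estimate`, `p`)
#'   with attributes `adj_r2`, `aic`, `n`, `model_kind`, `fit`.
#' @export
fit_association <- function(response, predictors, population = NULL) {
  y <- tv_values(response)
  stopifnot(is.list(predictors))
  if (length(predictors) > 0 && is.null(names(predictors))) {
    stop("predictors must be named")
  }
  df <- data.frame(.y = y)
  for (nm in names(predictors)) df[[nm]] <- tv_values(predictors[[nm]])
  if (!is.null(population)) df$.pop <- factor(population)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  k <- length(predictors)
  n <- nrow(df)
  if (n < k + 1 + 3) {
    stop("need at least 3 complete cases more than parameters (n = ", n,
         ", parameters = ", k + 1, ")")
  }
  terms <- names(predictors)
  rhs <- if (k == 0) "1" else paste(terms, collapse = " + ")
  X <- model.matrix(stats::as.formula(paste("~", rhs)), df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  if (is.null(population)) {
    fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = df)
    sm <- summary(fit)
    coefs <- sm$coefficients
    out <- data.frame(term = rownames(coefs), estimate = coefs[, 1],
                      p = coefs[, 4], stringsAsFactors = FALSE)
    adj_r2 <- sm$adj.r.squared
    aic <- AIC(fit)
    kind <- "fixed_only"
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .pop)"))
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
    coefs <- coef(summary(fit))
    zs <- coefs[, "t value"]
    out <- data.frame(term = rownames(coefs), estimate = coefs[, 1],
                      p = 2 * pnorm(-abs(zs)), stringsAsFactors = FALSE)
    adj_r2 <- NA_real_  # undefined for the mixed model; see vignette
    aic <- AIC(fit)
    kind <- "random_intercept_population"
  }
  rownames(out) <- NULL
  structure(out, adj_r2 = adj_r2, aic = aic, n = n, model_kind = kind,
            df_method = if (kind == "fixed_only") "t (residual df)"
                        else "z (normal approximation)",
            fit = fit, class = c("association_result", "data.frame"))
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s model, n = %d, AIC = %.2f%s\n",
              attr(x, "model_kind"), attr(x, "n"), attr(x, "aic"),
              if (is.na(attr(x, "adj_r2"))) "" else
                sprintf(", adj R^2 = %.3f", attr(x, "adj_r2"))))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Backward stepwise simplification by AIC
#'
#' Starting from the full model, iteratively removes the single term whose
#' removal most decreases AIC and stops when no removal decreases it
#' (so the final AIC is never above the full model's).  Ties are broken by
#' term-name order; the elimination path is returned as an attribute.
#' Mixed models are compared on maximum-likelihood AIC (REML likelihoods
#' are not comparable across fixed-effect structures); the returned final
#' model is refitted by REML.
#'
#' @inheritParams fit_association
#' @return the final [fit_association()] result with attributes
#'   `elimination_log` (character vector) and `aic_path` (numeric).
#' @export
stepwise_aic <- function(response, predictors, population = NULL) {
  model_aic <- function(terms) {
    y <- tv_values(response)
    df <- data.frame(.y = y)
    for (nm in names(predictors)) df[[nm]] <- tv_values(predictors[[nm]])
    if (!is.null(population)) df$.pop <- factor(population)
    df <- df[complete.cases(df), , drop = FALSE]
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    if (is.null(population)) {
      AIC(lm(stats::as.formula(paste(".y ~", rhs)), data = df))
    } else {
      AIC(suppressMessages(lme4::lmer(
        stats::as.formula(paste(".y ~", rhs, "+ (1 | .pop)")),
        data = df, REML = FALSE)))
    }
  }
  current <- sort(names(predictors))
  aic_cur <- model_aic(current)
  log_lines <- sprintf("start: AIC = %.4f, terms = {%s}", aic_cur,
                       paste(current, collapse = ", "))
  aic_path <- aic_cur
  repeat {
    if (length(current) == 0) break
    cand <- vapply(current, function(tm)
      model_aic(setdiff(current, tm)), numeric(1))
    best <- names(cand)[which.min(cand)]  # ties: first in sorted order
    if (cand[[best]] < aic_cur - 1e-10) {
      current <- setdiff(current, best)
      aic_cur <- cand[[best]]
      aic_path <- c(aic_path, aic_cur)
      log_lines <- c(log_lines,
                     sprintf("drop %s: AIC = %.4f", best, aic_cur))
    } else break
  }
  log_lines <- c(log_lines, sprintf("final: AIC = %.4f, terms = {%s}",
                                    aic_cur, paste(current, collapse = ", ")))
  res <- fit_association(response, predictors[current], population)
  attr(res, "elimination_log") <- log_lines
  attr(res, "aic_path") <- aic_path
  attr(res, "aic_ml_final") <- aic_cur
  res
}
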