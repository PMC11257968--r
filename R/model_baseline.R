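#' Train the age + sex logistic baseline
#'
#' An unregularized maximum-likelihood logistic regression with age at the
#' predictive-interval start and sex as the only features — the reference
#' every richer model must beat. Under perfect separation (flagged by glm
#' warnings / huge coefficients) the fit falls back to a tiny-ridge glmnet
#' fit and records the fallback.
#'
#' @param age numeric age in years at the interval start.
#' @param sex character ("female"/"male") or 0/1 male indicator.
#' @param y binary labels.
#' @return object of class `mortclock_baseline` with `coef`
#'   (intercept, age, male).
#' @export
train_baseline <- function(age, sex, y) {
  if (length(unique(y)) < 2L) {
    stop("baseline training labels are single-class", call. = FALSE)
  }
  male <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(as.character(sex) == "male")
  } else as.numeric(sex)
  df <- data.frame(y = y, age = age, male = male)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ age + male, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || anyNA(coef(fit)) ||
      any(abs(coef(fit)[-1]) > 1e3, na.rm = TRUE)) {
    # tiny ridge keeps the fit finite under separation
    X <- cbind(age = age, male = male)
    gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 1e-6)
    cf <- as.numeric(c(gfit$a0, as.matrix(gfit$beta)))
    out <- list(coef = setNames(cf, c("(Intercept)", "age", "male")),
                separation_fallback = TRUE)
  } else {
    out <- list(coef = coef(fit), vcov = stats::vcov(fit),
                separation_fallback = FALSE)
  }
  structure(out, class = "mortclock_baseline")
}

#' @export
print.mortclock_baseline <- function(x, ...) {
  cat("<mortclock_baseline> logit p =",
      sprintf("%.4f %+.4f*age %+.4f*male", x$coef[1], x$coef[2], x$coef[3]),
      if (isTRUE(x$separation_fallback)) "(ridge fallback)" else "", "\n")
  invisible(x)
}

#' @param object a `mortclock_baseline`.
#' @param age,sex covariates as in [train_baseline()].
#' @param ... unused.
#' @return probability vector.
#' @rdname train_baseline
#' @export
predict.mortclock_baseline <- function(object, age, sex, ...) {
  male <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(as.character(sex) == "male")
  } else as.numeric(sex)
  plogis(object$coef[1] + object$coef[2] * age + object$coef[3] * male)
}
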