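# Univariate logistic risk model, including the packaged published
# lactate/pyruvate survival-risk model.

#' Fit a univariate logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary outcome on one
#' predictor. Under (quasi-)perfect separation a warning is raised and a
#' ridge-penalized estimate (small L2 penalty via glmnet) is returned
#' instead of the diverging ML fit.
#'
#' @param x numeric predictor (e.g. the Lac/Pyr ratio).
#' @param labels binary outcome.
#' @return Object of class \code{logistic_model}: \code{intercept},
#'   \code{slope}, \code{odds_ratio} = exp(slope), \code{converged},
#'   \code{penalized} and the underlying fit.
#' @export
fit_univariate_logistic <- function(x, labels) {
  y <- as_binary_labels(labels)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(y)) != 2) stop("both classes required", call. = FALSE)
  w <- withCallingHandlers(
    {
      fit <- stats::glm(y ~ x, family = stats::binomial())
      NULL
    },
    warning = function(cond) {
      invokeRestart("muffleWarning")
    }
  )
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)) > 50) ||
    max(abs(fit$fitted.values - y)) < 1e-8
  if (separated) {
    warning("perfect or quasi-perfect separation; returning a ",
            "ridge-penalized estimate", call. = FALSE)
    X <- cbind(x, jitter_col = 0)  # glmnet needs >= 2 columns
    g <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = 0.05, standardize = FALSE)
    b <- as.numeric(stats::coef(g))
    out <- list(intercept = b[1], slope = b[2], penalized = TRUE)
  } else {
    b <- stats::coef(fit)
    out <- list(intercept = unname(b[1]), slope = unname(b[2]),
                penalized = FALSE)
  }
  out$odds_ratio <- exp(out$slope)
  out$n <- length(y)
  out$fit <- if (out$penalized) NULL else fit
  structure(out, class = "logistic_model")
}

#' Published lactate/pyruvate logistic risk model
#'
#' The packaged reference model for 5-year mortality risk in small
#' (<= 2 cm) primary tumors: logit(P) = -12.24 + 1.80 * Lac/Pyr. Note that
#' the published odds ratio (6.08) differs slightly from exp(1.80) = 6.05,
#' consistent with rounding of the slope before printing; this package
#' stores the printed coefficients.
#'
#' @return A \code{logistic_model} with the printed coefficients.
#' @examples
#' predict(reference_logistic_model(), 6.8)  # probability 0.5
#' @export
reference_logistic_model <- function() {
  structure(list(intercept = -12.24, slope = 1.80,
                 odds_ratio = exp(1.80), penalized = FALSE, n = NA_integer_,
                 fit = NULL),
            class = "logistic_model")
}

#' Predict event probabilities from a logistic model
#'
#' @param object a \code{logistic_model}.
#' @param newdata numeric vector of predictor values.
#' @param ... unused.
#' @return Probabilities P(y = 1 | x).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  stats::plogis(object$intercept + object$slope * as.numeric(newdata))
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> logit(P) = %.4g + %.4g x | OR = %.4g%s\n",
              x$intercept, x$slope, x$odds_ratio,
              if (x$penalized) " (ridge-penalized)" else ""))
  invisible(x)
}
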