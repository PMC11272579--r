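# Ridge-stabilized IRLS for the two-parameter logistic choice model.
# A tiny penalty (default 1e-4) keeps near-separated fits finite without
# materially moving well-identified estimates.
ridge_logistic <- function(X, y, lambda = 1e-4, tol = 1e-8, max_iter = 100) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu)) - lambda * beta
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  H <- crossprod(X, X * (mu * (1 - mu))) + diag(lambda, ncol(X))
  list(beta = beta, vcov = tryCatch(solve(H), error = function(e) NULL),
       converged = converged && max(abs(beta)) < 1e3,
       loglik = sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))))
}

#' Fit the logistic persistence model
#'
#' Fits `P(abandon) = plogis(beta0 + beta1 * sv_m)` to one participant's
#' choices by maximum likelihood (Newton/IRLS with a small ridge penalty for
#' numerical stability), where `sv_m` is the chosen valuation model's
#' abandonment value (best alternative minus current goal). `beta1` is the
#' inverse temperature; `-beta0/beta1` is the indifference point, the
#' abandonment value at which the participant is equally likely to persist or
#' abandon — positive values mean over-persistence relative to the model.
#'
#' Degenerate inputs (all-persist or all-abandon responses, i.e. complete
#' separation; a constant predictor; non-convergence) produce a flagged fit
#' with `converged = FALSE` and a warning, to be excluded downstream.
#'
#' @param data A `gp_dataset` (rows for a single participant), or any data
#'   frame with an `abandon` column and the model's `sv_` column.
#' @param model One of `"tree_search"`, `"offer_max"`, `"myopic"`,
#'   `"prospective"`.
#' @param lambda Ridge penalty (default `1e-4`).
#' @param tol,max_iter IRLS convergence tolerance and iteration cap.
#' @return An object of class `persistence_fit` with elements `beta0`,
#'   `beta1`, `ip`, `converged`, `n_obs`, `model`, `vcov`, `loglik`.
#' @seealso [indifference_point()], [loo_cv_compare()]
#' @examples
#' set.seed(1)
#' sv <- rnorm(500, 0, 3)
#' y <- rbinom(500, 1, plogis(-2 + 1 * sv))
#' d <- data.frame(abandon = y, sv_tree_search = sv)
#' f <- fit_persistence(d)
#' coef(f)
#' indifference_point(f)
#' @export
fit_persistence <- function(data, model = "tree_search", lambda = 1e-4,
                            tol = 1e-8, max_iter = 100) {
  model <- match.arg(model,
                     c("tree_search", "offer_max", "myopic", "prospective"))
  sv <- data[[paste0("sv_", model)]]
  y <- data$abandon
  keep <- !is.na(sv) & !is.na(y)
  sv <- sv[keep]
  y <- y[keep]
  flagged <- NULL
  if (length(unique(y)) < 2) flagged <- "separation: constant response"
  if (stats::sd(sv) == 0) flagged <- "degenerate predictor: constant sv"
  fit <- ridge_logistic(cbind(1, sv), y, lambda, tol, max_iter)
  if (is.null(flagged) && !fit$converged) flagged <- "non-convergence"
  if (!is.null(flagged)) warning("flagged persistence fit: ", flagged)
  ip <- if (is.null(flagged) && abs(fit$beta[2]) > 1e-6) {
    -fit$beta[1] / fit$beta[2]
  } else NA_real_
  structure(list(beta0 = fit$beta[1], beta1 = fit$beta[2], ip = ip,
                 converged = is.null(flagged), flag = flagged,
                 n_obs = length(y), model = model, vcov = fit$vcov,
                 loglik = fit$loglik),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("Persistence fit (%s model, %d choices)\n", x$model, x$n_obs))
  if (!x$converged) cat("  ** flagged:", x$flag, "**\n")
  cat(sprintf("  beta0 (intercept)        : %8.4f\n", x$beta0))
  cat(sprintf("  beta1 (inverse temp.)    : %8.4f\n", x$beta1))
  cat(sprintf("  indifference point (IP)  : %8.4f\n", x$ip))
  invisible(x)
}

#' @export
coef.persistence_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
summary.persistence_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else rep(NA_real_, 2)
  out <- list(coefficients = cbind(Estimate = coef(object), `Std. Error` = se,
                                   `z value` = coef(object) / se),
              ip = object$ip, model = object$model, n_obs = object$n_obs,
              converged = object$converged, loglik = object$loglik)
  class(out) <- "summary.persistence_fit"
  out
}

#' @export
print.summary.persistence_fit <- function(x, ...) {
  cat(sprintf("Logistic persistence model (%s values), n = %d\n", x$model,
              x$n_obs))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Indifference point: %0.4f   log-likelihood: %0.2f\n",
              x$ip, x$loglik))
  invisible(x)
}

#' @export
predict.persistence_fit <- function(object, newdata = NULL,
                                    type = c("response", "link"), ...) {
  type <- match.arg(type)
  sv <- if (is.data.frame(newdata)) {
    newdata[[paste0("sv_", object$model)]]
  } else newdata
  if (is.null(sv)) stop("newdata with the model's sv column (or a numeric sv vector) is required")
  eta <- unname(object$beta0 + object$beta1 * sv)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
plot.persistence_fit <- function(x, data = NULL, n_bins = 8, ...) {
  sv_grid <- seq(-10, 10, length.out = 200)
  graphics::plot(sv_grid, predict(x, sv_grid), type = "l", ylim = c(0, 1),
                 xlab = "abandonment value (sv)",
                 ylab = "P(abandon)", ...)
  graphics::abline(h = 0.5, lty = 3)
  if (is.finite(x$ip)) graphics::abline(v = x$ip, col = 2, lty = 2)
  if (!is.null(data)) {
    sv <- data[[paste0("sv_", x$model)]]
    br <- stats::quantile(sv, seq(0, 1, length.out = n_bins + 1), na.rm = TRUE)
    g <- cut(sv, unique(br), include.lowest = TRUE)
    graphics::points(tapply(sv, g, mean), tapply(data$abandon, g, mean),
                     pch = 19)
  }
  invisible(x)
}

#' Indifference point of a logistic persistence fit
#'
#' `IP = -beta0 / beta1`: the abandonment value at which the fitted
#' probability of switching is exactly 0.5. Positive IP quantifies the
#' persistence bias — how much better than the current goal the best
#' alternative must be before the participant is indifferent.
#'
#' @param fit A [fit_persistence()] object (or anything with `beta0`,
#'   `beta1`).
#' @param tol `beta1` magnitudes at or below this are treated as undefined.
#' @return The indifference point (a real number).
#' @export
indifference_point <- function(fit, tol = 1e-6) {
  if (abs(fit$beta1) <= tol) stop("indifference point undefined: |beta1| <= tol")
  -fit$beta0 / fit$beta1
}

#' Fit the persistence model to every participant
#'
#' @param dataset A `gp_dataset` covering one or more participants.
#' @param model Valuation model whose `sv` is the predictor.
#' @return Data frame with one row per participant: `pid`, `beta0`, `beta1`,
#'   `ip`, `converged`, `n_obs`. Flagged fits carry `NA` IP.
#' @export
fit_cohort <- function(dataset, model = "tree_search") {
  pids <- unique(dataset$pid)
  rows <- lapply(pids, function(p) {
    f <- suppressWarnings(fit_persistence(dataset[dataset$pid == p, ], model))
    data.frame(pid = p, beta0 = f$beta0, beta1 = f$beta1, ip = f$ip,
               converged = f$converged, n_obs = f$n_obs)
  })
  do.call(rbind, rows)
}
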