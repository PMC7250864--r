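#' Logistic model of uridylation probability versus 3' truncation
#'
#' Fits, by maximum likelihood, `P(uridylated) = logistic(b0 + b1 * x)`
#' where `x` is the 3' truncation in nucleotides (`x = -end_offset`, so
#' larger `x` means a shorter RNA; genomic extensions enter as negative
#' truncation, putting truncated and extended molecules on one signed
#' axis). Newton-Raphson iterations stop when the gradient norm drops
#' below `tol` (default 1e-8) or after `max_iter` iterations. Standard
#' errors come from the observed information at the optimum. Complete or
#' quasi-separation (outcomes perfectly ordered by `x`, hence a monotone
#' likelihood and unbounded coefficients) is detected up front and
#' flagged rather than raised.
#'
#' @param tail_calls Output of [call_tails()] (failed junctions are
#'   dropped), or any data.frame with `end_offset` and `is_uridylated`.
#' @param truncation_only If TRUE, genomically extended reads
#'   (`end_offset > 0`) are excluded from the fit.
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return List of class `uridylation_logistic`: `beta0`, `beta1`,
#'   `se_beta0`, `se_beta1`, `log_likelihood`, `null_log_likelihood`
#'   (slope fixed at 0), `wald_z_slope`, `wald_p_slope`, `n`,
#'   `converged`, `separation_flag`, `n_iter`.
#' @export
fit_uridylation_logistic <- function(tail_calls, truncation_only = FALSE,
                                     tol = 1e-8, max_iter = 50L) {
  d <- tail_calls[tail_calls$junction_found %in% c(NA, TRUE), , drop = FALSE]
  d <- d[!is.na(d$is_uridylated), , drop = FALSE]
  if (truncation_only) d <- d[d$end_offset <= 0L, , drop = FALSE]
  x <- -as.numeric(d$end_offset)
  y <- as.numeric(d$is_uridylated)
  n <- length(y)
  if (n < 10L) stop("fit_uridylation_logistic: need >= 10 tail calls")
  if (all(y == 0) || all(y == 1)) {
    stop("fit_uridylation_logistic: both outcomes must be present")
  }
  separation <- max(x[y == 0]) <= min(x[y == 1]) ||
    max(x[y == 1]) <= min(x[y == 0])
  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - p))
    w <- p * (1 - p)
    H <- crossprod(X, X * w)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta <- beta + step
  }
  p <- stats::plogis(drop(X %*% beta))
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) c(NA_real_, NA_real_))
  # slope-free null: intercept MLE is the logit of the observed rate
  p0 <- mean(y)
  ll0 <- n * (p0 * log(p0) + (1 - p0) * log1p(-p0))
  z <- unname(beta[2] / se[2])
  structure(list(
    beta0 = unname(beta[1]), beta1 = unname(beta[2]),
    se_beta0 = unname(se[1]), se_beta1 = unname(se[2]),
    log_likelihood = ll, null_log_likelihood = ll0,
    wald_z_slope = z,
    wald_p_slope = 2 * stats::pnorm(-abs(z)),
    n = n,
    converged = converged && !separation,
    separation_flag = separation,
    n_iter = iter
  ), class = "uridylation_logistic")
}

#' @export
print.uridylation_logistic <- function(x, ...) {
  cat("Logistic model of uridylation vs 3' truncation\n")
  cat(sprintf("  n = %d, converged = %s%s\n", x$n, x$converged,
              if (x$separation_flag) " (separation detected)" else ""))
  cat(sprintf("  intercept b0 = %.4f (SE %.4f)\n", x$beta0, x$se_beta0))
  cat(sprintf("  slope     b1 = %.4f per nt truncation (SE %.4f)\n",
              x$beta1, x$se_beta1))
  cat(sprintf("  Wald z = %.3f, two-sided p = %.3g\n",
              x$wald_z_slope, x$wald_p_slope))
  cat(sprintf("  logLik = %.4f (null %.4f)\n",
              x$log_likelihood, x$null_log_likelihood))
  invisible(x)
}
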