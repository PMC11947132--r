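#' Center IPD covariates on aggregate-data targets
#'
#' Standard MAIC preprocessing: every matched covariate is shifted by the
#' comparator trial's published pooled mean (or proportion), so that the
#' weight solver's gradient is exactly the mean-matching condition.
#'
#' @param data Patient-level tibble containing the matched covariates.
#' @param targets An `agd_summary`, or a named numeric vector of target
#'   values.
#' @param covariates Character vector of covariates to match.
#' @return A numeric matrix (patients x covariates) of centered values, with
#'   the target vector attached as attribute `"targets"`.
#' @export
center_covariates <- function(data, targets, covariates = matching_covariates()) {
  if (!length(covariates)) rlang::abort("`covariates` must be non-empty")
  tv <- target_values(targets)
  missing_t <- setdiff(covariates, names(tv))
  if (length(missing_t)) {
    rlang::abort(paste0("covariate(s) absent from targets: ",
                        paste(missing_t, collapse = ", ")))
  }
  missing_d <- setdiff(covariates, names(data))
  if (length(missing_d)) {
    rlang::abort(paste0("covariate(s) absent from data: ",
                        paste(missing_d, collapse = ", ")))
  }
  X <- as.matrix(data[covariates])
  if (!is.numeric(X)) rlang::abort("matched covariates must be numeric")
  if (anyNA(X)) {
    rlang::abort("missing values among matched covariates; drop incomplete patients first (see `drop_incomplete()`)")
  }
  Xc <- sweep(X, 2L, tv[covariates])
  degen <- apply(Xc, 2L, function(col) max(col) == min(col) && col[1] != 0)
  if (any(degen)) {
    rlang::abort(paste0("matching infeasible: covariate(s) constant in IPD but different from target: ",
                        paste(covariates[degen], collapse = ", ")))
  }
  attr(Xc, "targets") <- tv[covariates]
  Xc
}

target_values <- function(targets) {
  if (inherits(targets, "agd_summary")) {
    stats::setNames(targets$baseline_targets$value,
                    targets$baseline_targets$covariate)
  } else if (is.numeric(targets) && !is.null(names(targets))) {
    targets
  } else {
    rlang::abort("`targets` must be an agd_summary or a named numeric vector")
  }
}

#' Drop patients with missing matched covariates
#'
#' Complete-case filter on the matching covariates, with a message counting
#' dropped patients.
#' @inheritParams center_covariates
#' @return The filtered tibble.
#' @export
drop_incomplete <- function(data, covariates = matching_covariates()) {
  keep <- stats::complete.cases(data[intersect(covariates, names(data))])
  if (any(!keep)) {
    rlang::inform(sprintf("dropped %d patient(s) with missing matched covariates",
                          sum(!keep)))
  }
  data[keep, , drop = FALSE]
}

#' Estimate MAIC weights by method of moments
#'
#' Finds per-patient weights `w_i = exp(x_i^c . beta)` (with `x_i^c` the
#' covariates centered on the comparator targets) such that the weighted
#' pooled means and proportions of the matched covariates exactly equal the
#' published targets. `beta` minimizes the smooth convex objective
#' `Q(beta) = sum_i exp(x_i^c . beta)`, whose gradient is precisely the
#' mean-matching condition; this is the method-of-moments solution of the
#' propensity-style logistic model for trial enrolment. Newton's method with
#' analytic gradient and Hessian is used, with step-halving and a BFGS
#' fallback if the Hessian becomes ill-conditioned.
#'
#' @param data Patient-level tibble; must contain the matched covariates and
#'   (for per-arm effective sample sizes) an `arm` column.
#' @param targets An `agd_summary` or named numeric vector of target values.
#' @param covariates Covariates to match (names into `data` and `targets`).
#' @param max_iter Newton iteration cap.
#' @param tol Convergence is declared when the gradient max-norm is at most
#'   `tol * n`.
#'
#' @return A `maic_weights` object: per-patient weights plus solver state
#'   (`beta`, `converged`, `iterations`, `gradient_norm`,
#'   `objective_value`) and effective sample sizes (`ess_total`,
#'   `ess_by_arm`). Use [generics::tidy()] for per-patient weights,
#'   [generics::glance()] for one-row diagnostics.
#' @export
estimate_weights <- function(data, targets, covariates = matching_covariates(),
                             max_iter = 500L, tol = 1e-10) {
  Xc <- center_covariates(data, targets, covariates)
  n <- nrow(Xc)
  if (n <= ncol(Xc)) {
    rlang::abort("need more patients than matched covariates")
  }

  # 1-d feasibility: each target must lie inside the range of IPD values
  # (equivalently each centered column must straddle zero) unless already met
  infeasible <- apply(Xc, 2L, function(col) {
    !(min(col) < 0 && max(col) > 0) && any(col != 0)
  })
  if (any(infeasible)) {
    rlang::abort(paste0(
      "matching infeasible: target outside the range of IPD values for: ",
      paste(colnames(Xc)[infeasible], collapse = ", ")))
  }

  active <- apply(Xc, 2L, function(col) any(col != 0))
  Xa <- Xc[, active, drop = FALSE]
  beta <- stats::setNames(numeric(ncol(Xc)), colnames(Xc))
  iterations <- 0L
  if (ncol(Xa)) {
    if (qr(Xa)$rank < ncol(Xa)) {
      rlang::abort("matched covariates are collinear after centering; remove redundant covariates")
    }
    sol <- solve_tilting(Xa, max_iter = max_iter, tol = tol)
    beta[active] <- sol$beta
    iterations <- sol$iterations
  }

  w <- as.vector(exp(Xc %*% beta))
  grad_norm <- max(abs(crossprod(Xc, w)))
  converged <- grad_norm <= tol * n

  arms <- if ("arm" %in% names(data)) data$arm else factor(rep("all", n))
  ess_by_arm <- vapply(split(w, arms), effective_sample_size, numeric(1))

  structure(
    list(weights = w,
         beta = beta,
         converged = converged,
         iterations = iterations,
         gradient_norm = grad_norm,
         objective_value = sum(w),
         ess_total = effective_sample_size(w),
         ess_by_arm = ess_by_arm,
         covariates = covariates,
         targets = attr(Xc, "targets"),
         arm = arms,
         id = if ("id" %in% names(data)) data$id else as.character(seq_len(n)),
         n = n),
    class = "maic_weights")
}

# Newton minimization of Q(beta) = sum(exp(X beta)); gradient X'w, Hessian
# X' diag(w) X. Convex, so step-halving on Q is a sufficient globalizer.
solve_tilting <- function(X, max_iter, tol) {
  n <- nrow(X)
  beta <- numeric(ncol(X))
  w <- rep(1, n)
  Q <- n
  for (it in seq_len(max_iter)) {
    g <- as.vector(crossprod(X, w))
    if (max(abs(g)) <= tol * n) {
      return(list(beta = beta, iterations = it - 1L))
    }
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(solve_tilting_bfgs(X, beta, max_iter, tol))
    }
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      w_new <- exp(as.vector(X %*% cand))
      Q_new <- sum(w_new)
      if (is.finite(Q_new) && Q_new <= Q) break
      alpha <- alpha / 2
      if (alpha < 1e-12) {
        rlang::abort("matching infeasible: weight objective cannot decrease (targets likely outside the convex hull of the IPD covariates)")
      }
    }
    if (sqrt(sum(cand^2)) > 1e3) {
      rlang::abort("matching infeasible: tilting coefficients diverging (targets on or outside the convex hull of the IPD covariates)")
    }
    beta <- cand
    w <- w_new
    Q <- Q_new
  }
  list(beta = beta, iterations = max_iter)
}

solve_tilting_bfgs <- function(X, beta0, max_iter, tol) {
  n <- nrow(X)
  fit <- stats::optim(beta0,
                      fn = function(b) sum(exp(as.vector(X %*% b))),
                      gr = function(b) as.vector(crossprod(X, exp(as.vector(X %*% b)))),
                      method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  list(beta = fit$par, iterations = as.integer(fit$counts[["function"]]))
}

#' Effective sample size of a weight vector
#'
#' `(sum w)^2 / sum(w^2)`: the number of equally weighted observations
#' carrying the same information as the weighted sample. Equals `n` exactly
#' when all weights are equal, is at most `n` always, and is invariant to
#' rescaling all weights by a positive constant.
#'
#' @param weights Nonnegative numeric vector, not all zero.
#' @return A single number in `[1, length(weights)]`.
#' @export
effective_sample_size <- function(weights) {
  if (inherits(weights, "maic_weights")) weights <- weights$weights
  if (!length(weights) || any(weights < 0) || !is.numeric(weights)) {
    rlang::abort("`weights` must be a nonnegative numeric vector")
  }
  s <- sum(weights)
  if (s <= 0) rlang::abort("all weights are zero; ESS undefined")
  s^2 / sum(weights^2)
}

#' Rescale MAIC weights
#'
#' Multiplies all weights by a positive constant. The ESS, weighted means and
#' every scale-invariant weighted estimator downstream are unchanged; only
#' the display scale of individual weights differs.
#'
#' @param ws A `maic_weights` object.
#' @param mode `"raw"` (leave as solved), `"sum_to_n"` (weights sum to the
#'   number of patients) or `"mean_one"` (average weight 1; identical to
#'   `sum_to_n`).
#' @return The rescaled `maic_weights`.
#' @export
rescale_weights <- function(ws, mode = c("raw", "sum_to_n", "mean_one")) {
  stopifnot(inherits(ws, "maic_weights"))
  mode <- rlang::arg_match(mode)
  k <- switch(mode,
              raw = 1,
              sum_to_n = ws$n / sum(ws$weights),
              mean_one = ws$n / sum(ws$weights))
  ws$weights <- ws$weights * k
  ws$objective_value <- sum(ws$weights)
  ws
}

#' @export
print.maic_weights <- function(x, ...) {
  cat("<maic_weights>\n")
  cat(sprintf("  %d patients, %d matched covariates (%s)\n",
              x$n, length(x$covariates), paste(x$covariates, collapse = ", ")))
  cat(sprintf("  converged: %s in %d iterations (|grad|_max = %.3g)\n",
              x$converged, x$iterations, x$gradient_norm))
  cat(sprintf("  ESS: %.1f of %d (%s)\n", x$ess_total, x$n,
              paste(sprintf("%s %.1f", names(x$ess_by_arm), x$ess_by_arm),
                    collapse = ", ")))
  invisible(x)
}

#' Weighted pooled means of the matched covariates
#'
#' Convenience check of the exact-balance contract: returns the weighted
#' pooled mean of each matched covariate next to its target.
#' @param data The IPD table used to fit `ws`.
#' @param ws A `maic_weights` object.
#' @return A tibble with columns `covariate`, `weighted_mean`, `target`.
#' @export
check_balance <- function(data, ws) {
  stopifnot(inherits(ws, "maic_weights"))
  purrr::map_dfr(ws$covariates, function(cv) {
    tibble::tibble(covariate = cv,
                   weighted_mean = sum(ws$weights * data[[cv]]) / sum(ws$weights),
                   target = ws$targets[[cv]])
  })
}

#' Export weights to CSV
#'
#' Writes patient id, raw weight and the `sum_to_n` rescaled weight.
#' @param ws A `maic_weights` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(ws, path) {
  stopifnot(inherits(ws, "maic_weights"))
  tb <- generics::tidy(ws)
  readr::write_csv(tb, path)
  invisible(path)
}
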