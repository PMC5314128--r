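# Conditional Poisson (multinomial) likelihood for the self-controlled case
# series. Conditioning on each patient's event total reduces the Poisson
# interval counts to a per-patient multinomial over that patient's intervals
# with probabilities proportional to length x rate, which removes all fixed
# between-person confounding.

# design matrix from an intervals tibble; reference levels are the baseline
# category, the first observed age band, and season 1 (corner-point coding —
# exposure-term IRRs are invariant to this choice)
.sccs_design <- function(intervals, adjust_age, adjust_season) {
  cat <- intervals$category
  terms <- list()
  for (lev in c("pre_exposure", "exposed")) {
    if (any(cat == lev)) terms[[lev]] <- as.numeric(cat == lev)
  }
  if (adjust_age) {
    bands <- sort(unique(intervals$age_band))
    for (b in bands[-1]) {
      terms[[paste0("age_band_", b)]] <- as.numeric(intervals$age_band == b)
    }
  }
  if (adjust_season) {
    seas <- sort(unique(intervals$season))
    for (s in setdiff(seas, min(seas))) {
      terms[[paste0("season_", s)]] <- as.numeric(intervals$season == s)
    }
  }
  if (length(terms) == 0L) return(matrix(0, nrow(intervals), 0L))
  do.call(cbind, terms)
}

# loglik, gradient and hessian of the conditional likelihood
# ll = sum_ij n_ij log( t_ij e^{x_ij b} / sum_k t_ik e^{x_ik b} )
# pidx: integer patient index 1..G (every index present); N_by_pid: length G
.sccs_ll <- function(beta, X, t, n_ev, pidx, N_by_pid, pid_labels = NULL) {
  eta <- if (ncol(X)) drop(X %*% beta) else numeric(nrow(X))
  w <- t * exp(eta)
  D <- rowsum(w, pidx, reorder = TRUE)[, 1L]
  ll <- sum(n_ev * (log(t) + eta)) - sum(N_by_pid * log(D))
  if (!is.finite(ll)) {
    bad <- which(!is.finite(log(D)))
    lab <- if (is.null(pid_labels)) bad else pid_labels[bad]
    abort(paste0("non-finite conditional likelihood (patient ",
                 paste(utils::head(lab, 3), collapse = ", "), ")"),
          class = "sccs_numeric_error")
  }
  mu <- w * (N_by_pid[pidx] / D[pidx])
  grad <- drop(crossprod(X, n_ev - mu))
  Xbar <- rowsum(w * X, pidx, reorder = TRUE) / D
  H <- -(crossprod(X, X * mu) - crossprod(Xbar, Xbar * N_by_pid))
  list(ll = ll, grad = grad, hess = H, mu = mu)
}

#' Conditional SCCS log-likelihood with exact derivatives
#'
#' Evaluates the multinomial form of the conditional Poisson log-likelihood
#' at a coefficient vector, together with its analytic gradient and Hessian.
#' Mostly useful for testing and for external optimisers; [sccs_fit()] wraps
#' the Newton iteration.
#'
#' @param intervals An intervals tibble with `patient_id`, `category`,
#'   `age_band`, `season`, `length_days`, `events`.
#' @param beta Named coefficient vector matching the design implied by
#'   `adjust_age`/`adjust_season` (see [sccs_fit()]).
#' @param adjust_age,adjust_season Include age-band / season terms.
#' @return A list `ll`, `grad`, `hess`.
#' @export
sccs_loglik <- function(intervals, beta, adjust_age = TRUE, adjust_season = TRUE) {
  X <- .sccs_design(intervals, adjust_age, adjust_season)
  ids <- sort(unique(intervals$patient_id))
  pidx <- match(intervals$patient_id, ids)
  N <- rowsum(as.numeric(intervals$events), pidx, reorder = TRUE)[, 1L]
  res <- .sccs_ll(beta, X, as.numeric(intervals$length_days),
                  as.numeric(intervals$events), pidx, N, ids)
  res[c("ll", "grad", "hess")]
}

#' Fit the SCCS conditional Poisson model
#'
#' Estimates log incidence-rate ratios for the exposure categories
#' (pre-exposure and exposed, relative to baseline), with optional age-band
#' and season adjustment, by Newton-Raphson with step-halving from a zero
#' start. Patients without events, and patients whose intervals all share one
#' covariate pattern (who contribute a constant to the conditional
#' likelihood), are dropped and counted; age/season levels never observed
#' are dropped from the design. The covariance is the inverse negative
#' Hessian at the optimum.
#'
#' @inheritParams sccs_loglik
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `sccs_fit`: a list with `coef`, `cov`,
#'   `loglik`, `n_cases_used`, `n_dropped_noninformative`, `converged`,
#'   `iterations`, `separation` (terms with |coef| > 10, flagged with a
#'   warning), and the interval/design bookkeeping needed by [sccs_wald()]
#'   and [sccs_contrast()].
#' @export
#' @examples
#' ints <- toy_fixture("irr3_pair")$intervals
#' fit <- sccs_fit(ints, adjust_age = FALSE, adjust_season = FALSE)
#' exp(coef(fit)["exposed"])  # 3
sccs_fit <- function(intervals, adjust_age = TRUE, adjust_season = TRUE,
                     tol = 1e-8, max_iter = 100L) {
  ints <- tibble::as_tibble(intervals)
  req <- c("patient_id", "category", "age_band", "season", "length_days", "events")
  missing <- setdiff(req, names(ints))
  if (length(missing)) abort(paste0("intervals lack column(s): ", paste(missing, collapse = ", ")))

  ev_by <- rowsum(as.numeric(ints$events), ints$patient_id, reorder = TRUE)
  with_event <- rownames(ev_by)[ev_by[, 1L] > 0]
  n_no_event <- length(unique(ints$patient_id)) - length(with_event)
  ints <- ints[ints$patient_id %in% with_event, , drop = FALSE]

  pattern <- paste(ints$category,
                   if (adjust_age) ints$age_band else 0L,
                   if (adjust_season) ints$season else 0L)
  first_of_pattern <- !duplicated(paste(ints$patient_id, pattern))
  n_patterns <- rowsum(as.numeric(first_of_pattern), ints$patient_id, reorder = TRUE)
  informative <- rownames(n_patterns)[n_patterns[, 1L] > 1]
  n_dropped <- length(with_event) - length(informative)
  ints <- ints[ints$patient_id %in% informative, , drop = FALSE]
  if (length(informative) == 0L) {
    abort("no informative cases: every patient's intervals share a single covariate pattern",
          class = "sccs_estimation_error")
  }

  X <- .sccs_design(ints, adjust_age, adjust_season)
  if (ncol(X) == 0L) {
    abort("empty design: nothing to estimate", class = "sccs_estimation_error")
  }
  ids <- sort(unique(ints$patient_id))
  pidx <- match(ints$patient_id, ids)
  t <- as.numeric(ints$length_days)
  n_ev <- as.numeric(ints$events)
  N <- rowsum(n_ev, pidx, reorder = TRUE)[, 1L]

  beta <- rep(0, ncol(X))
  names(beta) <- colnames(X)
  state <- .sccs_ll(beta, X, t, n_ev, pidx, N, ids)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(state$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(state$hess, -state$grad), error = function(e) {
      abort("singular Hessian in Newton step: model not identifiable from these intervals",
            class = "sccs_estimation_error")
    })
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      cand_state <- tryCatch(.sccs_ll(cand, X, t, n_ev, pidx, N, ids),
                             error = function(e) NULL)
      if (!is.null(cand_state) && cand_state$ll >= state$ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- beta; cand_state <- state; break }
    }
    beta <- cand
    state <- cand_state
  }
  if (max(abs(state$grad)) < tol) converged <- TRUE
  if (!converged) warn("SCCS fit did not converge; results flagged")
  separation <- names(beta)[abs(beta) > 10]
  if (length(separation)) {
    warn(paste0("possible separation: |log IRR| > 10 for ",
                paste(separation, collapse = ", ")))
  }
  cov <- solve(-state$hess)
  dimnames(cov) <- list(names(beta), names(beta))
  structure(
    list(coef = beta, cov = cov, loglik = state$ll,
         n_cases_used = length(informative),
         n_dropped_noninformative = n_dropped,
         n_dropped_no_event = n_no_event,
         converged = converged, iterations = iter, separation = separation,
         adjust_age = adjust_age, adjust_season = adjust_season),
    class = "sccs_fit"
  )
}

#' @export
coef.sccs_fit <- function(object, ...) object$coef

#' @export
vcov.sccs_fit <- function(object, ...) object$cov

#' @export
logLik.sccs_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' @export
print.sccs_fit <- function(x, ...) {
  cat("SCCS conditional Poisson fit\n")
  cat("  cases used:", x$n_cases_used,
      " dropped (non-informative):", x$n_dropped_noninformative, "\n")
  cat("  log-likelihood:", format(x$loglik), " converged:", x$converged,
      "in", x$iterations, "iterations\n\n")
  print(tidy(x, exponentiate = TRUE), n = Inf)
  invisible(x)
}

#' Wald estimate, confidence interval and p-value for one model term
#'
#' @param fit An [sccs_fit()] object.
#' @param term Term name (e.g. `"exposed"`, `"pre_exposure"`).
#' @param level Confidence level (default 0.95, matching a two-sided 5%
#'   significance test).
#' @return A one-row tibble `term`, `irr`, `ci_low`, `ci_high`, `p_value`.
#' @export
sccs_wald <- function(fit, term, level = 0.95) {
  if (!term %in% names(fit$coef)) {
    abort(paste0("term not in fit: ", term), class = "sccs_lookup_error")
  }
  b <- fit$coef[[term]]
  se <- sqrt(fit$cov[term, term])
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = term,
    irr = exp(b),
    ci_low = exp(b - z * se),
    ci_high = exp(b + z * se),
    p_value = 2 * pnorm(-abs(b / se))
  )
}

#' Wald estimate for the ratio of two model terms
#'
#' Estimates `exp(coef[term_a] - coef[term_b])` — e.g. the incidence during
#' treatment relative to the pre-exposure window — with variance
#' `var_a + var_b - 2 cov_ab`.
#'
#' @inheritParams sccs_wald
#' @param term_a,term_b Term names; the result is the rate in `term_a`
#'   relative to `term_b`.
#' @return A one-row tibble as in [sccs_wald()], with term
#'   `"term_a vs term_b"`.
#' @export
sccs_contrast <- function(fit, term_a, term_b, level = 0.95) {
  for (tm in c(term_a, term_b)) {
    if (!tm %in% names(fit$coef)) {
      abort(paste0("term not in fit: ", tm), class = "sccs_lookup_error")
    }
  }
  d <- fit$coef[[term_a]] - fit$coef[[term_b]]
  v <- fit$cov[term_a, term_a] + fit$cov[term_b, term_b] - 2 * fit$cov[term_a, term_b]
  se <- sqrt(pmax(v, 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = paste(term_a, "vs", term_b),
    irr = exp(d),
    ci_low = exp(d - z * se),
    ci_high = exp(d + z * se),
    p_value = if (se > 0) 2 * pnorm(-abs(d / se)) else as.numeric(d != 0)
  )
}

#' Tidy an SCCS fit
#'
#' @param x An [sccs_fit()] object.
#' @param exponentiate Report IRRs instead of log-IRRs.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy sccs_fit
#' @export
tidy.sccs_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$cov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(x$coef),
    estimate = unname(x$coef),
    std.error = unname(se),
    statistic = unname(x$coef / se),
    p.value = unname(2 * pnorm(-abs(x$coef / se))),
    conf.low = unname(x$coef - z * se),
    conf.high = unname(x$coef + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at an SCCS fit
#'
#' @param x An [sccs_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble of fit diagnostics.
#' @method glance sccs_fit
#' @export
glance.sccs_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    df = length(x$coef),
    n_cases_used = x$n_cases_used,
    n_dropped_noninformative = x$n_dropped_noninformative,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Serialise a fit to JSON
#'
#' @param fit An [sccs_fit()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(coef = as.list(fit$coef), cov = fit$cov,
         diagnostics = as.list(glance(fit))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
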