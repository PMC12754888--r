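#' Score opt-out based vaccine hesitancy per respondent
#'
#' Counts how many of a respondent's presented tasks were answered with the
#' opt-out ("neither vaccine"); a respondent is hesitant when the count
#' reaches `threshold` (default: at least 3 of the 6 tasks, trap included).
#'
#' @param data a `choice_data` object.
#' @param threshold opt-out count at or above which a respondent is
#'   hesitant (default 3).
#' @param n_tasks number of tasks every respondent must have answered
#'   (default 6); a mismatch is an error.
#' @param include_trap count the trap task (default `TRUE`). When `FALSE`,
#'   pass the matching `n_tasks` (5).
#' @return data.frame with `respondent_id`, `optout_count`, `hesitant`.
#' @export
score_optout <- function(data, threshold = 3L, n_tasks = 6L,
                         include_trap = TRUE) {
  stopifnot(inherits(data, "choice_data"))
  ch <- data$choices
  if (!include_trap) ch <- ch[!ch$is_trap, , drop = FALSE]
  chosen <- ch[ch$chosen == 1L, , drop = FALSE]
  counts <- table(factor(chosen$respondent_id,
                         levels = data$respondents$respondent_id))
  if (any(counts != n_tasks)) {
    stop("respondent(s) with task count != ", n_tasks, ": ",
         paste(utils::head(names(counts)[counts != n_tasks]),
               collapse = ", "), call. = FALSE)
  }
  opt <- chosen[chosen$alternative == "optout", , drop = FALSE]
  oc <- table(factor(opt$respondent_id,
                     levels = data$respondents$respondent_id))
  data.frame(respondent_id = data$respondents$respondent_id,
             optout_count = as.integer(oc),
             hesitant = as.integer(oc) >= threshold,
             stringsAsFactors = FALSE)
}

#' Share of task responses answered with the opt-out
#'
#' @param data a `choice_data` object, or a list with `n_optout` and
#'   `n_tasks` counts.
#' @return percentage of all task responses where opt-out was chosen.
#' @export
optout_task_proportion <- function(data) {
  if (inherits(data, "choice_data")) {
    chosen <- data$choices[data$choices$chosen == 1L, , drop = FALSE]
    if (!nrow(chosen)) stop("empty dataset", call. = FALSE)
    return(100 * mean(chosen$alternative == "optout"))
  }
  if (is.list(data) && all(c("n_optout", "n_tasks") %in% names(data))) {
    if (data$n_tasks <= 0) stop("empty dataset", call. = FALSE)
    return(100 * data$n_optout / data$n_tasks)
  }
  stop("pass a choice_data object or list(n_optout=, n_tasks=)",
       call. = FALSE)
}

#' Cumulative opt-out curve
#'
#' For k = 1..n_tasks, the percentage of respondents whose opt-out count is
#' at least k. Non-increasing in k; the last entry is the fraction opting
#' out on every task.
#'
#' @param scores data.frame from [score_optout].
#' @param n_tasks number of tasks (default 6).
#' @return data.frame with `k` and `percent_at_least_k`.
#' @export
cumulative_optout_curve <- function(scores, n_tasks = 6L) {
  if (!nrow(scores)) stop("no scores", call. = FALSE)
  k <- seq_len(n_tasks)
  pct <- vapply(k, function(kk) 100 * mean(scores$optout_count >= kk),
                numeric(1))
  data.frame(k = k, percent_at_least_k = pct)
}

#' Odds ratio of a 2x2 contingency table
#'
#' `OR = (a*d)/(b*c)` with the Woolf log-scale interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Cells are
#' exposed-case `a`, exposed-control `b`, unexposed-case `c`,
#' unexposed-control `d`.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param z critical value (default 1.96).
#' @param correction add 0.5 to every cell (Haldane-Anscombe) when any cell
#'   is zero (default `FALSE`: zero cells are an error).
#' @return list with `or`, `ci_low`, `ci_high`.
#' @export
two_by_two_or <- function(a, b, c, d, z = 1.96, correction = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count", call. = FALSE)
  if (any(cells == 0)) {
    if (!correction) {
      stop("zero cell; use correction = TRUE for Haldane-Anscombe 0.5",
           call. = FALSE)
    }
    cells <- cells + 0.5
  }
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se))
}

#' Univariate odds-ratio table for binary hesitancy predictors
#'
#' Crosses each binary predictor against the hesitancy flag and reports the
#' 2x2 odds ratio with a Woolf interval (the univariate analysis of the
#' hesitancy model; identical to a univariate logistic fit for a binary
#' predictor).
#'
#' @param covariates respondent-level data.frame of 0/1 predictors.
#' @param hesitant logical/0-1 outcome vector.
#' @param predictors column names to tabulate.
#' @param z critical value (default 1.96).
#' @param correction apply the 0.5 continuity correction to zero cells
#'   (useful for small simulated samples; default `FALSE`).
#' @return data.frame with counts, `or`, `ci_low`, `ci_high` per predictor.
#' @export
univariate_or_table <- function(covariates, hesitant, predictors,
                                z = 1.96, correction = FALSE) {
  hesitant <- as.integer(hesitant)
  rows <- lapply(predictors, function(p) {
    x <- as.integer(covariates[[p]])
    a <- sum(x == 1 & hesitant == 1)
    b <- sum(x == 1 & hesitant == 0)
    cc <- sum(x == 0 & hesitant == 1)
    d <- sum(x == 0 & hesitant == 0)
    orr <- two_by_two_or(a, b, cc, d, z = z, correction = correction)
    data.frame(predictor = p, a = a, b = b, c = cc, d = d,
               or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multivariate logistic regression by iteratively reweighted least squares
#'
#' From-scratch Newton/IRLS logistic fit with an intercept, starting at
#' zero, converged when the score max-norm drops below `tol`. Reports
#' adjusted odds ratios with Wald intervals.
#'
#' @param covariates respondent-level data.frame.
#' @param outcome logical/0-1 outcome vector (hesitant flag).
#' @param predictors column names to include (numeric or 0/1; build dummies
#'   beforehand for factors, e.g. via [hesitancy_model_frame]).
#' @param tol score max-norm tolerance (default 1e-8).
#' @param max_iter maximum iterations (default 50).
#' @param z critical value for intervals (default 1.96).
#' @return object of class `logistic_fit`: `coef`, `se`, `vcov`,
#'   `aor_table`, `loglik`, `converged`, `n_iterations`.
#' @export
fit_logistic <- function(covariates, outcome, predictors, tol = 1e-8,
                         max_iter = 50L, z = 1.96) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(lapply(covariates[predictors],
                                            as.numeric))))
  if (nrow(X) <= ncol(X)) stop("more parameters than observations",
                               call. = FALSE)
  const <- apply(X[, -1L, drop = FALSE], 2L, function(v)
    max(v) == min(v))
  if (any(const)) {
    stop("constant predictor(s): ",
         paste(colnames(X)[-1L][const], collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    W <- mu * (1 - mu)
    info <- crossprod(X, W * X)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("singular information in logistic fit", call. = FALSE))
    ll_at <- function(b) {
      m <- stats::plogis(drop(X %*% b))
      sum(y * log(pmax(m, 1e-300)) + (1 - y) * log(pmax(1 - m, 1e-300)))
    }
    lambda <- 1
    ll_cur <- ll_at(beta)
    while (ll_at(beta + lambda * step) < ll_cur - 1e-12 && lambda > 1e-8) {
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    if (max(abs(beta)) > 30) {
      stop("coefficient '", colnames(X)[which.max(abs(beta))],
           "' diverging; possible perfect separation", call. = FALSE)
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, (mu * (1 - mu)) * X)
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)
  keep <- setdiff(colnames(X), "(Intercept)")
  aor <- data.frame(predictor = keep,
                    coef = unname(beta[keep]),
                    se = unname(se[keep]),
                    aor = exp(unname(beta[keep])),
                    ci_low = exp(unname(beta[keep] - z * se[keep])),
                    ci_high = exp(unname(beta[keep] + z * se[keep])),
                    stringsAsFactors = FALSE)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  structure(list(coef = beta, se = se, vcov = vcov, aor_table = aor,
                 loglik = ll, converged = converged, n_iterations = iter),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> logLik ", format(x$loglik),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(x$aor_table, digits = 3)
  invisible(x)
}

#' Model frame for the hesitancy regression
#'
#' Expands the simulated respondent table into the numeric predictor coding
#' of the hesitancy model: age in years (continuous), SES as two dummies
#' against the lower class, all remaining covariates 0/1.
#'
#' @param respondents respondent table from [generate_population].
#' @return data.frame of numeric predictors.
#' @export
hesitancy_model_frame <- function(respondents) {
  data.frame(
    age = respondents$age,
    male = as.numeric(respondents$male),
    married = as.numeric(respondents$married),
    city = as.numeric(respondents$city),
    healthcare_worker = as.numeric(respondents$healthcare_worker),
    ses_upper = as.numeric(respondents$ses == "upper"),
    ses_middle = as.numeric(respondents$ses == "middle"),
    prior_covid = as.numeric(respondents$prior_covid),
    diabetes = as.numeric(respondents$diabetes),
    hypertension = as.numeric(respondents$hypertension),
    heart_disease = as.numeric(respondents$heart_disease),
    asthma = as.numeric(respondents$asthma),
    family_covid = as.numeric(respondents$family_covid)
  )
}
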