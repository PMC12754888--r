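#' Code a choice dataset for conditional-logit estimation
#'
#' Builds the long-format numeric design matrix: one row per alternative per
#' respondent-task, dummy coding against each attribute's reference level,
#' cost numeric in INR. Opt-out rows have all attribute columns zero, plus
#' an alternative-specific constant column when `include_optout_asc = TRUE`.
#' Trap tasks are excluded by default so estimation uses only the five
#' experimental tasks per respondent.
#'
#' @param data a `choice_data` object.
#' @param attrs attribute list; defaults to the design's.
#' @param include_optout_asc add an `optout_asc` indicator column (default
#'   `TRUE`).
#' @param drop_trap exclude trap tasks from the coded data (default `TRUE`).
#' @param drop_optout drop opt-out rows entirely, and with them any
#'   respondent-task whose chosen alternative was the opt-out (default
#'   `FALSE`).
#' @param subset optional respondent filter for subgroup / sensitivity
#'   fits: a logical vector over the respondent table, a quoted expression
#'   (e.g. `quote(healthcare_worker == 1)`), or such an expression as a
#'   string.
#' @return object of class `coded_choices`: list with numeric matrix `X`,
#'   integer `group` (respondent-task index), `chosen` 0/1 vector,
#'   `respondent` id per row.
#' @export
code_dataset <- function(data, attrs = NULL, include_optout_asc = TRUE,
                         drop_trap = TRUE, drop_optout = FALSE,
                         subset = NULL) {
  stopifnot(inherits(data, "choice_data"))
  if (is.null(attrs)) attrs <- data$design$attrs
  attrs <- check_attrs(attrs)
  ch <- data$choices
  if (drop_trap) ch <- ch[!ch$is_trap, , drop = FALSE]
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- str2lang(subset)
    keep_r <- if (is.logical(subset)) subset else
      eval(subset, envir = as.data.frame(data$respondents),
           enclos = parent.frame())
    if (!is.logical(keep_r) || length(keep_r) != nrow(data$respondents)) {
      stop("'subset' must give one logical per respondent", call. = FALSE)
    }
    keep_ids <- data$respondents$respondent_id[keep_r]
    ch <- ch[ch$respondent_id %in% keep_ids, , drop = FALSE]
  }
  if (drop_optout) {
    opt_chosen <- ch[ch$alternative == "optout" & ch$chosen == 1L,
                     c("respondent_id", "task_id")]
    if (nrow(opt_chosen)) {
      key <- paste(ch$respondent_id, ch$task_id)
      drop_key <- paste(opt_chosen$respondent_id, opt_chosen$task_id)
      ch <- ch[!key %in% drop_key, , drop = FALSE]
    }
    ch <- ch[ch$alternative != "optout", , drop = FALSE]
  }
  if (!nrow(ch)) stop("no choice rows left to code", call. = FALSE)

  cols <- coded_columns(attrs)
  # coded rows per design task/alternative, then join onto the long table
  cm <- coded_task_matrices(data$design$tasks, attrs)
  task_ids <- vapply(data$design$tasks, `[[`, integer(1L), "task_id")
  ti <- match(ch$task_id, task_ids)
  if (anyNA(ti)) stop("choice rows reference unknown task ids",
                      call. = FALSE)
  X <- matrix(0, nrow(ch), length(cols), dimnames = list(NULL, cols))
  isA <- ch$alternative == "A"
  isB <- ch$alternative == "B"
  X[isA, ] <- cm$Xa[ti[isA], , drop = FALSE]
  X[isB, ] <- cm$Xb[ti[isB], , drop = FALSE]
  if (include_optout_asc && !drop_optout) {
    X <- cbind(X, optout_asc = as.numeric(ch$alternative == "optout"))
  }
  group <- match(paste(ch$respondent_id, ch$task_id),
                 unique(paste(ch$respondent_id, ch$task_id)))
  chosen_per_group <- tapply(ch$chosen, group, sum)
  if (any(chosen_per_group != 1L)) {
    stop("each respondent-task must have exactly one chosen alternative",
         call. = FALSE)
  }
  structure(list(X = X, group = as.integer(group),
                 chosen = as.integer(ch$chosen),
                 respondent = ch$respondent_id),
            class = "coded_choices")
}

#' @export
print.coded_choices <- function(x, ...) {
  cat("<coded_choices> ", nrow(x$X), " rows, ", max(x$group), " groups, ",
      ncol(x$X), " columns\n", sep = "")
  invisible(x)
}

#' Conditional-logit log-likelihood, gradient and Hessian
#'
#' `LL = sum_g [x_chosen' beta - log sum_j exp(x_j' beta)]` over
#' respondent-task groups, with log-sum-exp stabilisation. The gradient is
#' `sum_g (x_chosen - sum_j p_j x_j)` and the Hessian is minus the Fisher
#' information `sum_g [sum_j p_j x_j x_j' - (sum_j p_j x_j)(...)']`.
#'
#' @param beta coefficient vector.
#' @param coded a `coded_choices` object.
#' @return list with `loglik`, `gradient`, `hessian`.
#' @export
clogit_loglik <- function(beta, coded) {
  X <- coded$X
  if (length(beta) != ncol(X)) {
    stop("beta has length ", length(beta), ", need ", ncol(X),
         call. = FALSE)
  }
  g <- coded$group
  eta <- drop(X %*% beta)
  gmax <- as.vector(tapply(eta, g, max))[g]
  e <- exp(eta - gmax)
  denom <- as.vector(rowsum(e, g))
  P <- e / denom[g]
  ll <- sum((eta - gmax - log(denom[g]))[coded$chosen == 1L])
  Gm <- rowsum(P * X, g)                      # groups x p: sum_j p_j x_j
  grad <- colSums(X[coded$chosen == 1L, , drop = FALSE]) - colSums(Gm)
  hess <- -(crossprod(X, P * X) - crossprod(Gm))
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' Fit a conditional logit by Newton-Raphson maximum likelihood
#'
#' Starts from `beta = 0`, takes Newton steps with step-halving whenever a
#' step does not improve the log-likelihood, and declares convergence when
#' the gradient max-norm drops below `tol`. The covariance matrix is the
#' inverse observed information at the optimum.
#'
#' @param coded a `coded_choices` object from [code_dataset].
#' @param tol gradient max-norm tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @return object of class `clogit_fit`: `beta`, `se`, `vcov`, `loglik`,
#'   `loglik_null` (at zero), `n_groups`, `converged`, `n_iterations`.
#' @export
fit_clogit <- function(coded, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(coded, "coded_choices"))
  X <- coded$X
  # a column constant within every group carries no choice information
  within_var <- vapply(seq_len(ncol(X)), function(j) {
    rng <- tapply(X[, j], coded$group, function(v) max(v) - min(v))
    max(rng)
  }, numeric(1))
  if (any(within_var == 0)) {
    stop("column(s) constant within all groups: ",
         paste(colnames(X)[within_var == 0], collapse = ", "),
         call. = FALSE)
  }
  p <- ncol(X)
  beta <- rep(0, p)
  cur <- clogit_loglik(beta, coded)
  ll0 <- cur$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur$gradient)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-cur$hessian, cur$gradient), error = function(e)
      stop("singular Hessian at iteration ", iter, call. = FALSE))
    if (any(!is.finite(step))) {
      stop("non-finite Newton step; possible separation", call. = FALSE)
    }
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      new <- clogit_loglik(cand, coded)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        stop("step-halving failed to improve the likelihood", call. = FALSE)
      }
    }
    beta <- beta + lambda * step
    cur <- new
    if (max(abs(beta)) > 1e3) {
      drift <- colnames(X)[which.max(abs(beta))]
      stop("coefficient '", drift, "' drifting to infinity; ",
           "possible perfect separation", call. = FALSE)
    }
  }
  if (!converged && max(abs(cur$gradient)) < tol) converged <- TRUE
  info <- -cur$hessian
  vcov <- tryCatch(solve(info), error = function(e)
    stop("information matrix singular at the optimum", call. = FALSE))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(beta = beta, se = sqrt(diag(vcov)), vcov = vcov,
                 loglik = cur$loglik, loglik_null = ll0,
                 n_groups = max(coded$group), converged = converged,
                 n_iterations = iter,
                 gradient_norm = max(abs(cur$gradient))),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("<clogit_fit> ", x$n_groups, " choice sets, logLik ",
      format(x$loglik), if (!x$converged) "  [NOT CONVERGED]", "\n",
      sep = "")
  print(round(cbind(coef = x$beta, se = x$se), 4))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(beta)` with `CI = exp(beta +/- z * se)`.
#'
#' @param fit a `clogit_fit` (or any object with `beta` and `se`).
#' @param z critical value (default 1.96 for 95% intervals).
#' @return data.frame with `term`, `coef`, `se`, `or`, `ci_low`, `ci_high`.
#' @export
odds_ratios <- function(fit, z = 1.96) {
  data.frame(term = names(fit$beta),
             coef = unname(fit$beta),
             se = unname(fit$se),
             or = exp(unname(fit$beta)),
             ci_low = exp(unname(fit$beta - z * fit$se)),
             ci_high = exp(unname(fit$beta + z * fit$se)),
             stringsAsFactors = FALSE)
}

#' Cluster-robust (sandwich) covariance for a conditional-logit fit
#'
#' Score contributions are summed within clusters (normally respondents, who
#' answer several tasks) before forming the meat of the sandwich. The
#' default fit reports classical inverse-information standard errors; this
#' is the optional robust alternative.
#'
#' @param fit a `clogit_fit`.
#' @param coded the `coded_choices` the fit was estimated on.
#' @param cluster cluster id per row of `coded$X`; defaults to
#'   `coded$respondent`.
#' @return covariance matrix.
#' @export
vcov_cluster <- function(fit, coded, cluster = coded$respondent) {
  X <- coded$X
  g <- coded$group
  eta <- drop(X %*% fit$beta)
  gmax <- as.vector(tapply(eta, g, max))[g]
  e <- exp(eta - gmax)
  P <- e / as.vector(rowsum(e, g))[g]
  U_rows <- (coded$chosen - P) * X           # per-row score contribution
  U <- rowsum(U_rows, cluster)
  meat <- crossprod(U)
  fit$vcov %*% meat %*% fit$vcov
}
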