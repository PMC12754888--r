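#' Willingness to pay for an attribute level
#'
#' The monetary value of moving from the reference level to `level`:
#' `WTP = -beta_level / beta_cost`, in the cost attribute's currency (INR
#' here). The standard error is first-order (delta method) over the 2x2
#' sub-covariance of `(beta_level, beta_cost)` with gradient
#' `(-1/beta_cost, beta_level/beta_cost^2)`; the interval is
#' `WTP +/- z * se`. A parametric-bootstrap interval (multivariate-normal
#' draws of the coefficient vector) is available as a cross-check.
#'
#' @param fit a `clogit_fit`.
#' @param level coded column name of the level (e.g. `"effectiveness_90"`),
#'   or several.
#' @param cost_name coded column name of the cost coefficient.
#' @param z critical value for the interval (default 1.96).
#' @param usd_rate INR per USD for the converted column (default 77).
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap draws (bootstrap method only).
#' @param seed RNG seed (bootstrap method only).
#' @return data.frame with `level`, `wtp`, `se`, `ci_low`, `ci_high`, `usd`.
#' @export
wtp <- function(fit, level, cost_name = "cost", z = 1.96, usd_rate = 77,
                method = c("delta", "bootstrap"), n_boot = 2000L,
                seed = 1L) {
  method <- match.arg(method)
  if (!cost_name %in% names(fit$beta)) {
    stop("cost coefficient '", cost_name, "' not in fit", call. = FALSE)
  }
  missing <- setdiff(level, names(fit$beta))
  if (length(missing)) {
    stop("coefficient(s) not in fit: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bc <- fit$beta[[cost_name]]
  if (abs(bc) < 1e-12) stop("cost coefficient is zero; WTP undefined",
                            call. = FALSE)
  out <- lapply(level, function(lv) {
    bl <- fit$beta[[lv]]
    point <- -bl / bc
    if (method == "delta") {
      V <- fit$vcov[c(lv, cost_name), c(lv, cost_name)]
      grad <- c(-1 / bc, bl / bc^2)
      se <- sqrt(drop(grad %*% V %*% grad))
    } else {
      V <- fit$vcov[c(lv, cost_name), c(lv, cost_name)]
      old <- set_local_seed(seed)
      on.exit(restore_seed(old))
      L <- chol(V)
      draws <- matrix(stats::rnorm(2L * n_boot), n_boot, 2L) %*% L
      draws <- sweep(draws, 2L, c(bl, bc), "+")
      ratios <- -draws[, 1L] / draws[, 2L]
      se <- stats::sd(ratios)
    }
    data.frame(level = lv, wtp = point, se = se,
               ci_low = point - z * se, ci_high = point + z * se,
               usd = point / usd_rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' WTP table for every non-reference level
#'
#' @inheritParams wtp
#' @param attrs attribute list used to enumerate the coded levels; the cost
#'   attribute itself is skipped.
#' @return data.frame as in [wtp], one row per level.
#' @export
wtp_table <- function(fit, attrs, cost_name = "cost", z = 1.96,
                      usd_rate = 77) {
  attrs <- check_attrs(attrs)
  lv <- setdiff(coded_columns(attrs), cost_name)
  lv <- intersect(lv, names(fit$beta))
  wtp(fit, lv, cost_name = cost_name, z = z, usd_rate = usd_rate)
}

#' Relative attribute importance (RAI)
#'
#' For each categorical attribute, the utility range is the spread between
#' its largest and smallest part-worth, the reference level contributing 0.
#' RAI is each range as a percentage of the summed ranges. The continuous
#' cost attribute is excluded by default: a "range" for a continuous
#' attribute is not well defined without picking an arbitrary span.
#'
#' @param fit a `clogit_fit`, or a named coefficient vector over
#'   [coded_columns].
#' @param attrs attribute list.
#' @param exclude attribute names left out of the denominator (default
#'   `"cost"`).
#' @return data.frame with `attribute`, `utility_range`, `rai_percent`
#'   (summing to 100).
#' @export
rai <- function(fit, attrs, exclude = "cost") {
  attrs <- check_attrs(attrs)
  beta <- if (inherits(fit, "clogit_fit")) fit$beta else fit
  keep <- attrs[!names(attrs) %in% exclude]
  if (!length(keep)) stop("no attributes left after exclusion",
                          call. = FALSE)
  ranges <- vapply(keep, function(a) {
    if (a$coding == "continuous") {
      stop("continuous attribute '", a$name,
           "' has no part-worth range; exclude it", call. = FALSE)
    }
    cn <- paste(a$name, a$codes[a$levels != a$reference], sep = "_")
    if (!all(cn %in% names(beta))) {
      stop("missing coefficient(s) for attribute '", a$name, "'",
           call. = FALSE)
    }
    pw <- c(0, unname(beta[cn]))   # reference level has part-worth 0
    max(pw) - min(pw)
  }, numeric(1))
  data.frame(attribute = names(keep),
             utility_range = unname(ranges),
             rai_percent = 100 * unname(ranges) / sum(ranges),
             stringsAsFactors = FALSE)
}

#' Convert INR amounts to USD at a fixed study rate
#'
#' @param amount amount(s) in INR.
#' @param rate INR per USD (default 77, the Nov 2021 study rate).
#' @param digits rounding of the returned USD value (default 2).
#' @return USD amount(s).
#' @export
convert_inr_usd <- function(amount, rate = 77, digits = 2) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("conversion rate must be a positive scalar", call. = FALSE)
  }
  round(amount / rate, digits)
}
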