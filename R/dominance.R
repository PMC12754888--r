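#' Dominance between two profiles
#'
#' Profile `a` dominates `b` when, attribute by attribute, `a`'s level is
#' weakly preferred to `b`'s under the attribute's stated preference order
#' (levels that are incomparable must be equal) and strictly preferred on at
#' least one attribute. Used to build trap tasks where one alternative is
#' unambiguously better.
#'
#' @param a,b named character vectors or one-row data.frames giving one level
#'   per attribute.
#' @param attrs list of [dce_attribute].
#' @return `"a_dominates"`, `"b_dominates"` or `"none"`.
#' @export
is_dominant_pair <- function(a, b, attrs) {
  attrs <- check_attrs(attrs)
  a <- as_profile(a, attrs)
  b <- as_profile(b, attrs)
  a_weak <- TRUE; b_weak <- TRUE
  a_strict <- FALSE; b_strict <- FALSE
  for (at in attrs) {
    la <- a[[at$name]]; lb <- b[[at$name]]
    if (la == lb) next
    ab <- at$strict_better[la, lb]
    ba <- at$strict_better[lb, la]
    if (ab) {
      a_strict <- TRUE; b_weak <- FALSE
    } else if (ba) {
      b_strict <- TRUE; a_weak <- FALSE
    } else {
      # incomparable and unequal: neither can dominate
      a_weak <- FALSE; b_weak <- FALSE
    }
  }
  if (a_weak && a_strict) return("a_dominates")
  if (b_weak && b_strict) return("b_dominates")
  "none"
}

as_profile <- function(p, attrs) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    p <- unlist(p[1L, , drop = TRUE])
  }
  missing <- setdiff(names(attrs), names(p))
  if (length(missing)) {
    stop("profile lacks attribute(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (at in attrs) {
    if (!p[[at$name]] %in% at$levels) {
      stop("invalid level '", p[[at$name]], "' for attribute '", at$name,
           "'", call. = FALSE)
    }
  }
  as.list(p[names(attrs)])
}

#' The default trap (dominance) task
#'
#' A fixed pair in which vaccine A is unambiguously better than vaccine B on
#' every attribute with a stated preference direction (origin is held equal):
#' A = 90% protection, 5 years, one injection, no common side effects,
#' 1-in-one-crore serious risk, Indian product, free; B = 50% protection,
#' 6 months, three injections, systemic side effects, 1-in-one-lakh risk,
#' Indian product, Rs. 2000.
#'
#' @param attrs the grid from [covid_vaccine_attributes] (labels must match).
#' @return a [choice_task] with `is_trap = TRUE` (A dominates).
#' @export
trap_task <- function(attrs = covid_vaccine_attributes()) {
  attrs <- check_attrs(attrs)
  a <- c(effectiveness = "90% protection", duration = "5 years",
         injections = "One", side_effects = "No common side effects",
         serious_risk = "1 in one crore (1 in 1,00,00,000)",
         origin = "Indian product", cost = "Free")
  b <- c(effectiveness = "50% protection", duration = "6 months",
         injections = "Three", side_effects = "Fever, body pain for 1-2 days",
         serious_risk = "1 in one lakh (1 in 1,00,000)",
         origin = "Indian product", cost = "Rs. 2000")
  if (is_dominant_pair(a, b, attrs) != "a_dominates") {
    stop("trap pair is not dominant under the supplied grid", call. = FALSE)
  }
  choice_task(profile_a = a, profile_b = b, attrs = attrs, is_trap = TRUE)
}
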