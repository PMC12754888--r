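#' Define a DCE attribute
#'
#' An attribute is one characteristic of a hypothetical alternative (e.g.
#' vaccine effectiveness) together with its discrete levels. Categorical
#' attributes enter the choice model as dummy indicators against a reference
#' level; a continuous attribute (cost) enters as a single numeric column.
#'
#' @param name attribute identifier (used as prefix of coded column names).
#' @param levels character vector of level labels, length >= 2, in display
#'   order.
#' @param coding `"dummy"` (categorical) or `"continuous"`.
#' @param reference reference level label (categorical only); its part-worth
#'   is fixed at zero.
#' @param values numeric value per level (continuous only; e.g. price in INR
#'   with "Free" = 0).
#' @param codes short syntactic codes per level used to build coded column
#'   names (`<name>_<code>`); defaults to a sanitised version of the labels.
#' @param better preference direction used only for dominance checks: one of
#'   `"increasing"` (later levels preferred), `"decreasing"` (earlier levels
#'   preferred), `NULL` (all level pairs incomparable), or a list of
#'   `c(better, worse)` label pairs whose transitive closure defines a strict
#'   partial order.
#' @return an object of class `dce_attribute`.
#' @export
dce_attribute <- function(name, levels,
                          coding = c("dummy", "continuous"),
                          reference = levels[1L],
                          values = NULL,
                          codes = NULL,
                          better = NULL) {
  coding <- match.arg(coding)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L) {
    stop("attribute '", name, "' needs at least 2 levels", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("attribute '", name, "' has duplicated levels", call. = FALSE)
  }
  if (coding == "dummy") {
    if (!reference %in% levels) {
      stop("reference level '", reference, "' not among levels of '",
           name, "'", call. = FALSE)
    }
    if (!is.null(values)) {
      stop("'values' is only meaningful for continuous attributes",
           call. = FALSE)
    }
  } else {
    if (is.null(values) || length(values) != length(levels) ||
        !is.numeric(values)) {
      stop("continuous attribute '", name,
           "' requires one numeric value per level", call. = FALSE)
    }
    reference <- NA_character_
  }
  if (is.null(codes)) codes <- sanitize_code(levels)
  codes <- as.character(codes)
  if (length(codes) != length(levels) || anyDuplicated(codes)) {
    stop("'codes' must be unique, one per level", call. = FALSE)
  }
  strict <- build_strict_preference(levels, better)
  structure(
    list(name = name, levels = levels, coding = coding,
         reference = reference, values = values, codes = codes,
         strict_better = strict),
    class = "dce_attribute"
  )
}

sanitize_code <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  ifelse(grepl("^[0-9]", x), paste0("l", x), x)
}

# Strict-preference matrix (rows strictly preferred to columns) from a
# direction keyword or explicit better/worse pairs; closed under transitivity
# and checked for antisymmetry.
build_strict_preference <- function(levels, better) {
  k <- length(levels)
  m <- matrix(FALSE, k, k, dimnames = list(levels, levels))
  if (is.null(better)) return(m)
  if (is.character(better) && length(better) == 1L) {
    ord <- switch(better,
                  increasing = seq_len(k),
                  decreasing = rev(seq_len(k)),
                  stop("'better' keyword must be 'increasing' or 'decreasing'",
                       call. = FALSE))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (match(i, ord) > match(j, ord)) m[i, j] <- TRUE
    }
    return(m)
  }
  for (p in better) {
    if (length(p) != 2L || !all(p %in% levels)) {
      stop("each 'better' pair must be c(better_level, worse_level)",
           call. = FALSE)
    }
    m[p[1L], p[2L]] <- TRUE
  }
  # transitive closure (Warshall)
  for (mid in seq_len(k)) {
    m <- m | (m[, mid] %o% m[mid, ])
  }
  if (any(m & t(m)) || any(diag(m))) {
    stop("preference pairs form a cycle; not a valid partial order",
         call. = FALSE)
  }
  m
}

#' @export
print.dce_attribute <- function(x, ...) {
  cat("<dce_attribute> ", x$name, " (", x$coding, ")\n", sep = "")
  cat("  levels: ", paste(x$levels, collapse = " | "), "\n", sep = "")
  if (x$coding == "dummy") cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' The COVID-19 vaccine attribute grid
#'
#' The seven-attribute grid used throughout the package examples: vaccine
#' effectiveness (3 levels), duration of protection (4), number of injections
#' (3), common side effects (3), risk of severe/serious side effects (2),
#' vaccine origin (2) and cost per injection (6 price points, continuous in
#' INR with "Free" = 0). Reference levels are 50% protection, 6 months,
#' three injections, no common side effects, 1-in-one-crore risk and an
#' imported product. The full factorial over this grid has
#' 3*4*3*3*2*2*6 = 2592 profiles.
#'
#' Preference directions used for dominance/trap construction: effectiveness
#' and duration increasing; injections, serious risk and cost decreasing;
#' "no common side effects" strictly preferred to either side-effect profile
#' (local vs systemic incomparable); vaccine origin incomparable a priori.
#'
#' @return list of [dce_attribute] objects.
#' @export
covid_vaccine_attributes <- function() {
  list(
    dce_attribute("effectiveness",
      levels = c("50% protection", "70% protection", "90% protection"),
      reference = "50% protection",
      codes = c("50", "70", "90"),
      better = "increasing"),
    dce_attribute("duration",
      levels = c("6 months", "1 year", "2 years", "5 years"),
      reference = "6 months",
      codes = c("6m", "1y", "2y", "5y"),
      better = "increasing"),
    dce_attribute("injections",
      levels = c("One", "Two", "Three"),
      reference = "Three",
      codes = c("one", "two", "three"),
      better = "decreasing"),
    dce_attribute("side_effects",
      levels = c("No common side effects",
                 "Injection site pain redness and swelling for 1-2 days",
                 "Fever, body pain for 1-2 days"),
      reference = "No common side effects",
      codes = c("none", "local", "systemic"),
      better = list(
        c("No common side effects",
          "Injection site pain redness and swelling for 1-2 days"),
        c("No common side effects", "Fever, body pain for 1-2 days"))),
    dce_attribute("serious_risk",
      levels = c("1 in one lakh (1 in 1,00,000)",
                 "1 in one crore (1 in 1,00,00,000)"),
      reference = "1 in one crore (1 in 1,00,00,000)",
      codes = c("lakh", "crore"),
      better = "increasing"),
    dce_attribute("origin",
      levels = c("Indian product", "Imported product"),
      reference = "Imported product",
      codes = c("indian", "imported"),
      better = NULL),
    dce_attribute("cost",
      levels = c("Free", "Rs. 250", "Rs. 500", "Rs. 1000", "Rs. 1500",
                 "Rs. 2000"),
      coding = "continuous",
      values = c(0, 250, 500, 1000, 1500, 2000),
      codes = c("free", "250", "500", "1000", "1500", "2000"),
      better = "decreasing")
  )
}

check_attrs <- function(attrs) {
  if (!length(attrs)) stop("empty attribute list", call. = FALSE)
  ok <- vapply(attrs, inherits, logical(1L), what = "dce_attribute")
  if (!all(ok)) stop("all elements must be dce_attribute objects",
                     call. = FALSE)
  nm <- vapply(attrs, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("duplicated attribute names", call. = FALSE)
  names(attrs) <- nm
  attrs
}

#' Enumerate the full factorial of profiles
#'
#' Lists every distinct profile (one level per attribute) exactly once, in
#' lexicographic order with the first attribute varying slowest.
#'
#' @param attrs list of [dce_attribute].
#' @return data.frame with one character column per attribute, one row per
#'   profile.
#' @export
enumerate_full_factorial <- function(attrs) {
  attrs <- check_attrs(attrs)
  lv <- lapply(attrs, `[[`, "levels")
  # expand.grid varies the first factor fastest; reverse to make the first
  # attribute the slowest-moving (lexicographic order)
  g <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  names(g) <- names(attrs)
  rownames(g) <- NULL
  g
}

#' Number of unordered profile pairs
#'
#' @param n_profiles number of distinct profiles (>= 2).
#' @return `n_profiles * (n_profiles - 1) / 2`.
#' @export
count_unique_pairs <- function(n_profiles) {
  if (!is.numeric(n_profiles) || length(n_profiles) != 1L ||
      n_profiles < 2 || n_profiles != floor(n_profiles)) {
    stop("'n_profiles' must be a single integer >= 2", call. = FALSE)
  }
  n_profiles * (n_profiles - 1) / 2
}

#' Johnson-Orme rule-of-thumb minimum DCE sample size
#'
#' `N >= 500 * c / (t * a)` where `c` is the maximum number of levels of any
#' attribute, `t` the number of choice tasks per respondent, and `a` the
#' number of alternatives per task. Returned rounded up.
#'
#' @param c maximum levels of any attribute.
#' @param t choice tasks per respondent.
#' @param a alternatives per task.
#' @return minimum number of respondents (integer).
#' @export
johnson_orme_min_n <- function(c, t, a) {
  for (v in list(c = c, t = t, a = a)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      stop("all of c, t, a must be >= 1", call. = FALSE)
    }
  }
  as.integer(ceiling(500 * c / (t * a)))
}

#' Coded column names of an attribute grid
#'
#' One dummy column per non-reference level of each categorical attribute
#' (in grid order), plus one numeric column per continuous attribute.
#'
#' @param attrs list of [dce_attribute].
#' @return character vector of column names.
#' @export
coded_columns <- function(attrs) {
  attrs <- check_attrs(attrs)
  unlist(lapply(attrs, function(a) {
    if (a$coding == "continuous") return(a$name)
    keep <- a$levels != a$reference
    paste(a$name, a$codes[keep], sep = "_")
  }), use.names = FALSE)
}

#' Code profiles into a numeric design matrix
#'
#' Dummy-codes categorical attributes against their reference level and maps
#' continuous attributes through their numeric level values.
#'
#' @param profiles data.frame of level labels (one column per attribute), as
#'   produced by [enumerate_full_factorial], or a single named character
#'   vector.
#' @param attrs list of [dce_attribute].
#' @return numeric matrix, one row per profile, columns per [coded_columns].
#' @export
code_profiles <- function(profiles, attrs) {
  attrs <- check_attrs(attrs)
  if (is.character(profiles)) {
    profiles <- as.data.frame(as.list(profiles), stringsAsFactors = FALSE)
  }
  cols <- coded_columns(attrs)
  n <- nrow(profiles)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (a in attrs) {
    lab <- profiles[[a$name]]
    if (is.null(lab)) stop("profiles lack attribute '", a$name, "'",
                           call. = FALSE)
    idx <- match(lab, a$levels)
    if (anyNA(idx)) {
      bad <- unique(lab[is.na(idx)])
      stop("unknown level label(s) for '", a$name, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (a$coding == "continuous") {
      X[, a$name] <- a$values[idx]
    } else {
      keep <- which(a$levels != a$reference)
      for (k in keep) {
        X[, paste(a$name, a$codes[k], sep = "_")] <- as.numeric(idx == k)
      }
    }
  }
  X
}

#' Decode a coded matrix back to level labels
#'
#' Inverse of [code_profiles]; used mainly for round-trip checks and report
#' rendering.
#'
#' @param X coded numeric matrix with columns per [coded_columns].
#' @param attrs list of [dce_attribute].
#' @return data.frame of level labels.
#' @export
decode_profiles <- function(X, attrs) {
  attrs <- check_attrs(attrs)
  out <- vector("list", length(attrs))
  names(out) <- names(attrs)
  for (a in attrs) {
    if (a$coding == "continuous") {
      idx <- match(X[, a$name], a$values)
      if (anyNA(idx)) stop("continuous value not on the level grid for '",
                           a$name, "'", call. = FALSE)
      out[[a$name]] <- a$levels[idx]
    } else {
      keep <- which(a$levels != a$reference)
      cn <- paste(a$name, a$codes[keep], sep = "_")
      D <- X[, cn, drop = FALSE]
      hit <- D %*% keep  # 0 if all dummies zero (reference)
      ref <- match(a$reference, a$levels)
      idx <- ifelse(rowSums(D) == 0, ref, as.vector(hit))
      out[[a$name]] <- a$levels[idx]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read an attribute grid from a JSON config file
#'
#' The file holds an array of objects with fields `name`, `levels`, and
#' optionally `coding`, `reference`, `values`, `codes` and `better` (either a
#' direction keyword or an array of `[better, worse]` label pairs).
#'
#' @param path path to a JSON file.
#' @return list of [dce_attribute].
#' @export
read_attribute_grid <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  attrs <- lapply(cfg, function(s) {
    better <- s$better
    if (!is.null(better) && is.list(better)) {
      better <- lapply(better, function(p) unlist(p, use.names = FALSE))
    }
    dce_attribute(
      name = s$name,
      levels = unlist(s$levels),
      coding = if (is.null(s$coding)) "dummy" else s$coding,
      reference = if (is.null(s$reference)) unlist(s$levels)[1L] else
        s$reference,
      values = if (is.null(s$values)) NULL else unlist(s$values),
      codes = if (is.null(s$codes)) NULL else unlist(s$codes),
      better = better
    )
  })
  check_attrs(attrs)
}
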