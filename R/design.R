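#' A paired choice task
#'
#' One DCE task: two hypothetical vaccine profiles plus the implicit opt-out
#' ("neither vaccine") alternative.
#'
#' @param profile_a,profile_b named character vectors (one level per
#'   attribute); must differ.
#' @param attrs list of [dce_attribute].
#' @param task_id integer id (assigned later if `NA`).
#' @param is_trap whether one profile must dominate the other (checked).
#' @param block_id block assignment (or `NA`).
#' @return object of class `choice_task`.
#' @export
choice_task <- function(profile_a, profile_b, attrs, task_id = NA_integer_,
                        is_trap = FALSE, block_id = NA_integer_) {
  attrs <- check_attrs(attrs)
  a <- as_profile(profile_a, attrs)
  b <- as_profile(profile_b, attrs)
  if (identical(a, b)) stop("the two profiles of a task must differ",
                            call. = FALSE)
  if (is_trap && is_dominant_pair(a, b, attrs) == "none") {
    stop("trap task requires one profile to dominate the other",
         call. = FALSE)
  }
  structure(list(task_id = task_id, profile_a = a, profile_b = b,
                 is_trap = is_trap, block_id = block_id),
            class = "choice_task")
}

#' Assemble a design from choice tasks
#'
#' @param tasks list of [choice_task]; ids are (re)assigned 1..n in order.
#' @param attrs list of [dce_attribute].
#' @param n_blocks number of blocks (or `NA` before blocking).
#' @param criterion_value log-determinant of the information matrix at the
#'   construction coefficients (or `NA`).
#' @return object of class `dce_design`.
#' @export
dce_design <- function(tasks, attrs, n_blocks = NA_integer_,
                       criterion_value = NA_real_) {
  attrs <- check_attrs(attrs)
  for (i in seq_along(tasks)) tasks[[i]]$task_id <- i
  structure(list(tasks = tasks, attrs = attrs, n_blocks = n_blocks,
                 criterion_value = criterion_value),
            class = "dce_design")
}

#' @export
print.dce_design <- function(x, ...) {
  nt <- sum(vapply(x$tasks, `[[`, logical(1L), "is_trap"))
  cat("<dce_design> ", length(x$tasks), " tasks (", nt, " trap), ",
      if (is.na(x$n_blocks)) "unblocked" else
        paste0(x$n_blocks, " blocks"), "\n", sep = "")
  if (!is.na(x$criterion_value)) {
    cat("  D-criterion (log-det):", format(x$criterion_value), "\n")
  }
  invisible(x)
}

# Coded rows of both vaccine alternatives for a list of tasks:
# matrices Xa, Xb (task x coded columns)
coded_task_matrices <- function(tasks, attrs) {
  pa <- do.call(rbind, lapply(tasks, function(t)
    as.data.frame(t$profile_a, stringsAsFactors = FALSE)))
  pb <- do.call(rbind, lapply(tasks, function(t)
    as.data.frame(t$profile_b, stringsAsFactors = FALSE)))
  list(Xa = code_profiles(pa, attrs), Xb = code_profiles(pb, attrs))
}

#' Conditional-logit Fisher information of a design
#'
#' Sums, over tasks, `sum_j p_j x_j x_j' - (sum_j p_j x_j)(sum_j p_j x_j)'`
#' where `p_j` are the logit choice probabilities of the task's alternatives
#' at `beta`. By default only the two vaccine alternatives enter (the model
#' used at the design-construction stage); with `include_optout = TRUE` an
#' all-zero opt-out row is added to every task.
#'
#' @param design a [dce_design], or a list of [choice_task].
#' @param beta coefficient vector (default all zero) of length
#'   `length(coded_columns(attrs))`.
#' @param attrs attribute list; taken from the design when omitted.
#' @param include_optout add an all-zero third alternative per task.
#' @return symmetric positive semidefinite matrix.
#' @export
information_matrix <- function(design, beta = NULL, attrs = NULL,
                               include_optout = FALSE) {
  if (inherits(design, "dce_design")) {
    tasks <- design$tasks
    if (is.null(attrs)) attrs <- design$attrs
  } else {
    tasks <- design
    if (is.null(attrs)) stop("'attrs' required when passing a task list",
                             call. = FALSE)
  }
  attrs <- check_attrs(attrs)
  cm <- coded_task_matrices(tasks, attrs)
  p <- ncol(cm$Xa)
  if (is.null(beta)) beta <- rep(0, p)
  if (length(beta) != p) {
    stop("beta has length ", length(beta), "; coded width is ", p,
         call. = FALSE)
  }
  M <- matrix(0, p, p, dimnames = list(colnames(cm$Xa), colnames(cm$Xa)))
  for (i in seq_along(tasks)) {
    X <- rbind(cm$Xa[i, ], cm$Xb[i, ])
    if (include_optout) X <- rbind(X, 0)
    eta <- drop(X %*% beta)
    pr <- exp(eta - max(eta))
    pr <- pr / sum(pr)
    xbar <- colSums(pr * X)
    M <- M + crossprod(X, pr * X) - tcrossprod(xbar)
  }
  M
}

#' Candidate pair set for design search
#'
#' Either enumerates all unordered profile pairs (small grids) or draws a
#' seeded uniform sample of distinct pairs from the full pair space without
#' enumerating it (the grid here has 3,357,936 pairs).
#'
#' @param profiles data.frame of profiles ([enumerate_full_factorial]).
#' @param attrs list of [dce_attribute].
#' @param n number of candidate pairs to sample; `NULL` enumerates all
#'   (refused above 500,000 pairs).
#' @param seed RNG seed for sampling.
#' @return object of class `candidate_set`.
#' @export
candidate_pairs <- function(profiles, attrs, n = NULL, seed = 1L) {
  attrs <- check_attrs(attrs)
  N <- nrow(profiles)
  if (N < 2L) stop("need at least 2 profiles", call. = FALSE)
  total <- count_unique_pairs(N)
  if (is.null(n)) {
    if (total > 5e5) {
      stop("pair space has ", format(total, big.mark = ","),
           " pairs; pass 'n' to sample candidates", call. = FALSE)
    }
    i <- rep(seq_len(N - 1L), times = (N - 1L):1L)
    j <- unlist(lapply(seq_len(N - 1L), function(k) (k + 1L):N))
    pairs <- cbind(i, j)
  } else {
    if (n > total) n <- total
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
    keys <- integer(0)
    while (length(keys) < n) {
      need <- n - length(keys)
      i <- sample.int(N, 2L * need + 10L, replace = TRUE)
      j <- sample.int(N, 2L * need + 10L, replace = TRUE)
      lo <- pmin(i, j); hi <- pmax(i, j)
      ok <- lo < hi
      keys <- unique(c(keys, (lo[ok] - 1) * N + hi[ok]))
    }
    keys <- keys[seq_len(n)]
    pairs <- cbind(i = as.integer((keys - 1) %/% N + 1),
                   j = as.integer((keys - 1) %% N + 1))
  }
  structure(list(pairs = pairs, profiles = profiles, attrs = attrs,
                 Xp = code_profiles(profiles, attrs)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", nrow(x$pairs), " candidate pairs over ",
      nrow(x$profiles), " profiles\n", sep = "")
  invisible(x)
}

#' D-optimal selection of choice sets (modified Fedorov exchange)
#'
#' Starting from a seeded random subset of `n_sets` candidate pairs, the
#' exchange repeatedly swaps one included task for the excluded candidate
#' that most increases the log-determinant of the accumulated conditional
#' logit information at `beta0` (default zero: a utility-neutral design),
#' and stops at a full pass with no improving swap. At `beta0 = 0` each pair
#' contributes the rank-one information `0.25 * dx dx'` where `dx` is the
#' coded difference of its two profiles, so determinant updates use the
#' standard rank-two exchange formula.
#'
#' A ridge of `1e-8` on the information diagonal is used inside the search
#' only (small designs can pass through singular states); the returned
#' `criterion_value` is ridge-free and must be finite.
#'
#' @param candidates a `candidate_set` (see [candidate_pairs]) or a list of
#'   [choice_task].
#' @param n_sets number of choice sets to select.
#' @param beta0 construction coefficients (default zero vector).
#' @param seed RNG seed for the subsample and the starting subset.
#' @param n_candidate_sample if given, the candidate set is first reduced to
#'   a seeded subsample of this size.
#' @param attrs required when `candidates` is a plain task list.
#' @return a [dce_design] with `criterion_value` set; attribute
#'   `"criterion_trace"` records the (ridged) objective after each accepted
#'   swap.
#' @export
d_optimal_select <- function(candidates, n_sets, beta0 = NULL, seed = 1L,
                             n_candidate_sample = NULL, attrs = NULL) {
  if (inherits(candidates, "candidate_set")) {
    attrs <- candidates$attrs
    Xa <- candidates$Xp[candidates$pairs[, 1L], , drop = FALSE]
    Xb <- candidates$Xp[candidates$pairs[, 2L], , drop = FALSE]
    prof_pairs <- candidates$pairs
    profiles <- candidates$profiles
  } else {
    if (is.null(attrs)) stop("'attrs' required for a plain task list",
                             call. = FALSE)
    attrs <- check_attrs(attrs)
    cm <- coded_task_matrices(candidates, attrs)
    Xa <- cm$Xa; Xb <- cm$Xb
    prof_pairs <- NULL
    profiles <- NULL
    tasks_in <- candidates
  }
  n_cand <- nrow(Xa)
  p <- ncol(Xa)
  if (is.null(beta0)) beta0 <- rep(0, p)
  if (length(beta0) != p) stop("beta0 has wrong length", call. = FALSE)

  old <- set_local_seed(seed)
  on.exit(restore_seed(old))

  if (!is.null(n_candidate_sample) && n_candidate_sample < n_cand) {
    keep <- sort(sample.int(n_cand, n_candidate_sample))
    Xa <- Xa[keep, , drop = FALSE]; Xb <- Xb[keep, , drop = FALSE]
    if (!is.null(prof_pairs)) prof_pairs <- prof_pairs[keep, , drop = FALSE]
    if (is.null(prof_pairs)) tasks_in <- tasks_in[keep]
    n_cand <- length(keep)
  }
  if (n_sets > n_cand) {
    stop("n_sets (", n_sets, ") exceeds candidate count (", n_cand, ")",
         call. = FALSE)
  }

  # pair information at beta0 is w * dx dx' with w = pA * pB; fold sqrt(w)
  # into the difference rows so exchanges are plain rank-one updates
  eta_a <- drop(Xa %*% beta0); eta_b <- drop(Xb %*% beta0)
  pa <- 1 / (1 + exp(eta_b - eta_a))
  Z <- (Xa - Xb) * sqrt(pa * (1 - pa))

  ridge <- 1e-8
  logdet_ridged <- function(idx) {
    M <- crossprod(Z[idx, , drop = FALSE]) + diag(ridge, p)
    d <- determinant(M, logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }

  if (n_sets == n_cand) {
    sel <- seq_len(n_cand)
    trace <- numeric(0)
  } else {
    sel <- sample.int(n_cand, n_sets)
    M <- crossprod(Z[sel, , drop = FALSE]) + diag(ridge, p)
    obj <- logdet_ridged(sel)
    trace <- obj
    repeat {
      improved <- FALSE
      for (slot in seq_len(n_sets)) {
        Minv <- solve(M)
        ZM <- Z %*% Minv              # n_cand x p
        d_all <- rowSums(ZM * Z)      # candidate variances
        zi <- Z[sel[slot], ]
        d_i <- sum(zi * (Minv %*% zi))
        v <- drop(ZM %*% zi)          # cross terms d_ij
        ratio <- (1 + d_all) * (1 - d_i) + v^2
        ratio[sel] <- -Inf            # cannot add an already-included task
        j <- which.max(ratio)
        if (is.finite(ratio[j]) && ratio[j] > 1 && log(ratio[j]) > 1e-10) {
          i_old <- sel[slot]
          M <- M - tcrossprod(Z[i_old, ]) + tcrossprod(Z[j, ])
          sel[slot] <- j
          obj <- obj + log(ratio[j])
          trace <- c(trace, obj)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }

  Mfin <- crossprod(Z[sel, , drop = FALSE])
  dfin <- determinant(Mfin, logarithm = TRUE)
  if (dfin$sign <= 0 || !is.finite(as.numeric(dfin$modulus))) {
    stop("selected design is singular at beta0; try a larger n_sets or ",
         "more candidates", call. = FALSE)
  }
  criterion <- as.numeric(dfin$modulus)

  if (!is.null(prof_pairs)) {
    tasks <- lapply(sel, function(k) {
      choice_task(unlist(profiles[prof_pairs[k, 1L], , drop = TRUE]),
                  unlist(profiles[prof_pairs[k, 2L], , drop = TRUE]),
                  attrs = attrs)
    })
  } else {
    tasks <- tasks_in[sel]
  }
  out <- dce_design(tasks, attrs, criterion_value = criterion)
  attr(out, "criterion_trace") <- trace
  attr(out, "selected") <- sel
  out
}

#' Randomly partition a design's tasks into equal blocks
#'
#' Trap tasks are left unblocked (`block_id = NA`); they are shown to every
#' respondent.
#'
#' @param design a [dce_design].
#' @param n_blocks number of blocks; must divide the non-trap task count.
#' @param seed RNG seed.
#' @return the design with `block_id` filled in and `n_blocks` set.
#' @export
assign_blocks <- function(design, n_blocks, seed = 1L) {
  stopifnot(inherits(design, "dce_design"))
  idx <- which(!vapply(design$tasks, `[[`, logical(1L), "is_trap"))
  n <- length(idx)
  if (n %% n_blocks != 0) {
    stop(n, " non-trap tasks cannot be split evenly into ", n_blocks,
         " blocks", call. = FALSE)
  }
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  perm <- sample(idx)
  per <- n / n_blocks
  for (b in seq_len(n_blocks)) {
    for (k in perm[((b - 1) * per + 1):(b * per)]) {
      design$tasks[[k]]$block_id <- b
    }
  }
  design$n_blocks <- as.integer(n_blocks)
  design
}

#' Chi-square goodness-of-fit test of uniform block allocation
#'
#' Pearson test of observed block counts against equal expected counts,
#' `df = n_blocks - 1`.
#'
#' @param block_counts vector of per-block respondent (or task) counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
block_balance_test <- function(block_counts) {
  k <- length(block_counts)
  if (k < 2L) stop("need at least 2 blocks", call. = FALSE)
  total <- sum(block_counts)
  if (total <= 0) stop("expected counts are zero", call. = FALSE)
  E <- total / k
  stat <- sum((block_counts - E)^2 / E)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

#' Write / read a design as long-format CSV
#'
#' Two rows per task (alternatives A and B) with columns `task_id`,
#' `block_id`, `is_trap`, `alternative`, and one column per attribute
#' holding the level label.
#'
#' @param design a [dce_design].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "dce_design"))
  rows <- lapply(design$tasks, function(t) {
    base <- data.frame(task_id = t$task_id, block_id = t$block_id,
                       is_trap = t$is_trap,
                       alternative = c("A", "B"),
                       stringsAsFactors = FALSE)
    cbind(base, rbind(as.data.frame(t$profile_a, stringsAsFactors = FALSE),
                      as.data.frame(t$profile_b, stringsAsFactors = FALSE)))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param attrs attribute list to validate the labels against.
#' @export
read_design_csv <- function(path, attrs) {
  attrs <- check_attrs(attrs)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tasks <- lapply(split(df, df$task_id), function(d) {
    d <- d[order(d$alternative), , drop = FALSE]
    choice_task(
      profile_a = unlist(d[1L, names(attrs), drop = TRUE]),
      profile_b = unlist(d[2L, names(attrs), drop = TRUE]),
      attrs = attrs,
      is_trap = as.logical(d$is_trap[1L]),
      block_id = if (is.na(d$block_id[1L])) NA_integer_ else
        as.integer(d$block_id[1L])
    )
  })
  tasks <- unname(tasks[order(as.integer(names(tasks)))])
  blocks <- unique(stats::na.omit(vapply(tasks, `[[`, integer(1L),
                                         "block_id")))
  des <- dce_design(tasks, attrs,
                    n_blocks = if (length(blocks)) max(blocks) else
                      NA_integer_)
  des
}

# Seed handling: all randomised operations take an explicit seed and restore
# the caller's RNG state afterwards.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
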