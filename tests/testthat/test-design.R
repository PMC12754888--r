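test_that("information matrix has the closed form for a single pair", {
  a <- toy_attrs()
  t1 <- choice_task(c(speed = "fast", colour = "red", size = "s"),
                    c(speed = "slow", colour = "red", size = "s"), a)
  M <- information_matrix(list(t1), attrs = a)
  dx <- code_profiles(c(speed = "fast", colour = "red", size = "s"), a) -
    code_profiles(c(speed = "slow", colour = "red", size = "s"), a)
  expect_equal(M, 0.25 * crossprod(dx), ignore_attr = TRUE)
})

test_that("information matrix matches a finite-difference Hessian oracle", {
  # Fisher info = -Hessian of any alternative's log-probability (the
  # log-sum-exp curvature is the same whichever alternative is chosen)
  a <- toy_attrs()
  set.seed(3)
  f <- enumerate_full_factorial(a)
  tasks <- lapply(1:3, function(i) {
    ij <- sample(nrow(f), 2)
    choice_task(unlist(f[ij[1], ]), unlist(f[ij[2], ]), a)
  })
  beta <- stats::rnorm(length(coded_columns(a)), sd = 0.5)
  M <- information_matrix(tasks, beta = beta, attrs = a)
  cm_rows <- lapply(tasks, function(t)
    rbind(code_profiles(as.data.frame(t$profile_a), a),
          code_profiles(as.data.frame(t$profile_b), a)))
  H <- matrix(0, length(beta), length(beta))
  for (X in cm_rows) {
    f1 <- function(b) {
      eta <- drop(X %*% b)
      eta[1] - log(sum(exp(eta)))
    }
    H <- H + fd_hessian(f1, beta)
  }
  expect_equal(M, -H, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("information matrix is symmetric PSD and superadditive", {
  a <- toy_attrs()
  f <- enumerate_full_factorial(a)
  set.seed(8)
  tasks <- lapply(1:6, function(i) {
    ij <- sample(nrow(f), 2)
    choice_task(unlist(f[ij[1], ]), unlist(f[ij[2], ]), a)
  })
  prev <- NULL
  for (k in seq_along(tasks)) {
    M <- information_matrix(tasks[seq_len(k)], attrs = a)
    expect_equal(M, t(M))
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    expect_true(all(ev > -1e-10))
    if (!is.null(prev)) expect_true(all(ev >= prev - 1e-10))
    prev <- ev
  }
  expect_error(information_matrix(tasks, beta = c(1, 2), attrs = a),
               "length")
})

test_that("Fedorov exchange attains the exhaustive optimum on a toy space", {
  a <- toy_attrs()
  f <- enumerate_full_factorial(a)
  # six fixed candidate pairs over a 4-column coded space
  set.seed(21)
  pairs <- cbind(sample(nrow(f), 6), sample(nrow(f), 6))
  pairs[pairs[, 1] == pairs[, 2], 2] <-
    (pairs[pairs[, 1] == pairs[, 2], 2] %% nrow(f)) + 1L
  tasks <- lapply(seq_len(6), function(k)
    choice_task(unlist(f[pairs[k, 1], ]), unlist(f[pairs[k, 2], ]), a))
  Xp <- code_profiles(f, a)
  Z <- 0.5 * (Xp[pairs[, 1], ] - Xp[pairs[, 2], ])  # sqrt(0.25) scaling
  best <- -Inf
  for (s in utils::combn(6, 4, simplify = FALSE)) {
    d <- determinant(crossprod(Z[s, ]), logarithm = TRUE)
    if (d$sign > 0) best <- max(best, as.numeric(d$modulus))
  }
  fit <- d_optimal_select(tasks, n_sets = 4, seed = 5, attrs = a)
  expect_equal(fit$criterion_value, best, tolerance = 1e-9)
})

test_that("exchange criterion is monotone and seeded runs reproduce", {
  a <- covid_vaccine_attributes()
  f <- enumerate_full_factorial(a)
  cand <- candidate_pairs(f, a, n = 600, seed = 2)
  d1 <- d_optimal_select(cand, 30, seed = 9)
  d2 <- d_optimal_select(cand, 30, seed = 9)
  expect_identical(lapply(d1$tasks, `[[`, "profile_a"),
                   lapply(d2$tasks, `[[`, "profile_a"))
  expect_equal(d1$criterion_value, d2$criterion_value)
  tr <- attr(d1, "criterion_trace")
  expect_true(all(diff(tr) > 0))
  expect_true(is.finite(d1$criterion_value))

  # selecting everything returns the full-set criterion
  all6 <- d_optimal_select(cand, nrow(cand$pairs), seed = 1)
  Minfo <- information_matrix(all6, attrs = a)
  expect_equal(all6$criterion_value,
               as.numeric(determinant(Minfo, logarithm = TRUE)$modulus),
               tolerance = 1e-8)
})

test_that("optimised design beats seeded random subsets", {
  a <- covid_vaccine_attributes()
  f <- enumerate_full_factorial(a)
  cand <- candidate_pairs(f, a, n = 1000, seed = 4)
  opt <- d_optimal_select(cand, 40, seed = 4)
  Xp <- cand$Xp
  Z <- 0.5 * (Xp[cand$pairs[, 1], ] - Xp[cand$pairs[, 2], ])
  set.seed(123)
  rand_crit <- replicate(100, {
    s <- sample(nrow(Z), 40)
    d <- determinant(crossprod(Z[s, ]), logarithm = TRUE)
    if (d$sign > 0) as.numeric(d$modulus) else -Inf
  })
  expect_true(opt$criterion_value >= max(rand_crit))
})

test_that("block assignment is an even seeded partition", {
  des <- study_design()
  blocks <- vapply(des$tasks, `[[`, integer(1), "block_id")
  is_trap <- vapply(des$tasks, `[[`, logical(1), "is_trap")
  expect_equal(sum(is_trap), 1L)
  expect_true(all(is.na(blocks[is_trap])))
  expect_equal(unname(table(blocks[!is_trap])), rep(5L, 8L),
               ignore_attr = TRUE)

  a <- toy_attrs()
  f <- enumerate_full_factorial(a)
  tasks <- lapply(1:5, function(i)
    choice_task(unlist(f[i, ]), unlist(f[i + 5, ]), a))
  d5 <- assign_blocks(dce_design(tasks, a), 5, seed = 1)
  expect_equal(sort(vapply(d5$tasks, `[[`, integer(1), "block_id")), 1:5)
  r1 <- assign_blocks(dce_design(tasks, a), 5, seed = 7)
  r2 <- assign_blocks(dce_design(tasks, a), 5, seed = 7)
  expect_identical(vapply(r1$tasks, `[[`, integer(1), "block_id"),
                   vapply(r2$tasks, `[[`, integer(1), "block_id"))
  expect_error(assign_blocks(dce_design(tasks, a), 2), "evenly")
})

test_that("block balance chi-square test", {
  eq <- block_balance_test(rep(12, 8))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$df, 7L)
  ub <- block_balance_test(c(10, 20))
  expect_equal(ub$statistic, 10 / 3)
  expect_equal(ub$df, 1L)
  for (k in c(2, 5, 10)) {
    expect_equal(block_balance_test(rep(5, 8) * k)$statistic, 0)
  }
  expect_error(block_balance_test(c(0, 0)), "zero")
})

test_that("dominance follows the stated partial orders", {
  a <- covid_vaccine_attributes()
  va <- c(effectiveness = "90% protection", duration = "5 years",
          injections = "One", side_effects = "No common side effects",
          serious_risk = "1 in one crore (1 in 1,00,00,000)",
          origin = "Indian product", cost = "Free")
  vb <- c(effectiveness = "50% protection", duration = "6 months",
          injections = "Three",
          side_effects = "Fever, body pain for 1-2 days",
          serious_risk = "1 in one lakh (1 in 1,00,000)",
          origin = "Indian product", cost = "Rs. 2000")
  expect_equal(is_dominant_pair(va, vb, a), "a_dominates")
  expect_equal(is_dominant_pair(vb, va, a), "b_dominates")
  expect_equal(is_dominant_pair(va, va, a), "none")

  # trade-off: a cheaper, b more effective -> incomparable overall
  ta <- va; ta["effectiveness"] <- "50% protection"
  tb <- va; tb["cost"] <- "Rs. 500"
  expect_equal(is_dominant_pair(ta, tb, a), "none")

  # origin is incomparable: differing origin alone blocks dominance
  oa <- va
  ob <- va; ob["origin"] <- "Imported product"; ob["cost"] <- "Rs. 250"
  expect_equal(is_dominant_pair(oa, ob, a), "none")

  # asymmetry property over random pairs
  f <- enumerate_full_factorial(a)
  set.seed(5)
  for (i in 1:40) {
    ij <- sample(nrow(f), 2)
    r1 <- is_dominant_pair(unlist(f[ij[1], ]), unlist(f[ij[2], ]), a)
    r2 <- is_dominant_pair(unlist(f[ij[2], ]), unlist(f[ij[1], ]), a)
    expect_equal(r1 == "a_dominates", r2 == "b_dominates")
    expect_equal(r1 == "none", r2 == "none")
  }
})

test_that("trap task construction and design CSV round-trip", {
  des <- study_design()
  expect_true(des$tasks[[41]]$is_trap)
  path <- tempfile(fileext = ".csv")
  write_design_csv(des, path)
  back <- read_design_csv(path, des$attrs)
  expect_equal(length(back$tasks), 41L)
  expect_equal(back$n_blocks, 8L)
  expect_equal(lapply(back$tasks, `[[`, "profile_a"),
               lapply(des$tasks, `[[`, "profile_a"))
  expect_equal(vapply(back$tasks, `[[`, integer(1), "block_id"),
               vapply(des$tasks, `[[`, integer(1), "block_id"))
})
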