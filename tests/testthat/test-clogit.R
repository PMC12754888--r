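test_that("log-likelihood at zero equals -G*log(n_alternatives)", {
  set.seed(1)
  X2 <- matrix(rnorm(20), 20, 1)
  g2 <- rep(1:10, each = 2)
  ch2 <- as.integer(sequence(rep(2, 10)) == 1)
  expect_equal(clogit_loglik(0, make_coded(X2, g2, ch2))$loglik,
               -10 * log(2))
  X3 <- matrix(rnorm(72), 36, 2)
  g3 <- rep(1:12, each = 3)
  ch3 <- as.integer(sequence(rep(3, 12)) == 2)
  expect_equal(clogit_loglik(c(0, 0), make_coded(X3, g3, ch3))$loglik,
               -12 * log(3))
})

test_that("gradient and Hessian match central finite differences", {
  set.seed(42)
  X <- matrix(rnorm(90), 30, 3)
  g <- rep(1:10, each = 3)
  ch <- as.integer(unlist(lapply(1:10, function(i)
    sample(c(1, 0, 0)))))
  coded <- make_coded(X, g, ch)
  beta <- rnorm(3, sd = 0.7)
  got <- clogit_loglik(beta, coded)
  f <- function(b) clogit_loglik(b, coded)$loglik
  expect_equal(got$gradient, fd_gradient(f, beta), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(got$hessian, fd_hessian(f, beta), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("likelihood is invariant to per-group constant utility shifts", {
  set.seed(9)
  X <- matrix(rnorm(40), 20, 2)
  g <- rep(1:10, each = 2)
  ch <- rep(c(1L, 0L), 10)
  coded <- make_coded(X, g, ch)
  beta <- c(0.4, -0.2)
  base <- clogit_loglik(beta, coded)$loglik
  # add a column that is constant within every group; any coefficient on it
  # must leave the conditional likelihood unchanged
  Xc <- cbind(X, gconst = rnorm(10)[g])
  shifted <- clogit_loglik(c(beta, 5), make_coded(Xc, g, ch))$loglik
  expect_equal(shifted, base, tolerance = 1e-10)
})

test_that("one-parameter MLE matches a grid-search oracle", {
  set.seed(7)
  n_g <- 80
  x_diff <- rep(1, n_g)
  true_b <- 0.8
  p <- stats::plogis(true_b * x_diff)
  chose1 <- stats::rbinom(n_g, 1, p)
  X <- matrix(as.vector(rbind(x_diff, 0)), ncol = 1)  # alternating rows
  g <- rep(seq_len(n_g), each = 2)
  ch <- as.vector(rbind(chose1, 1L - chose1))
  coded <- make_coded(X, g, ch)
  fit <- fit_clogit(coded)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) clogit_loglik(b, coded)$loglik,
               numeric(1))
  expect_equal(unname(fit$beta), grid[which.max(ll)], tolerance = 1e-3)
  expect_true(fit$converged)
  expect_true(fit$loglik >= fit$loglik_null)
  expect_lt(fit$gradient_norm, 1e-8)
})

test_that("a symmetric dataset yields beta of zero", {
  # mirrored tasks: every difference vector appears with both choices
  X <- matrix(as.vector(rbind(c(1, 1, -1, -1), 0)), ncol = 1)
  g <- rep(1:4, each = 2)
  ch <- as.vector(rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L)))
  fit <- fit_clogit(make_coded(X, g, ch))
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)
})

test_that("degenerate inputs raise informative errors", {
  X <- matrix(c(1, 1, 1, 1), 4, 1)        # constant within all groups
  g <- rep(1:2, each = 2)
  ch <- rep(c(1L, 0L), 2)
  expect_error(fit_clogit(make_coded(X, g, ch)), "constant within")
  bad <- make_coded(matrix(rnorm(4), 4, 1), g, c(1L, 1L, 1L, 0L))
  expect_error(clogit_loglik(c(1, 2), bad), "length")
})

test_that("estimates recover the truth on simulated data", {
  fx <- sim_fixture(n = 2000, seed = 31, p_inattentive = 0,
                    hesitant_optout_shift = 0, optout_asc = -1)
  coded <- code_dataset(apply_trap_filter(fx$dat)$passed)
  fit <- fit_clogit(coded)
  truth <- c(published_part_worths(), optout_asc = -1)
  z <- abs(fit$beta - truth[names(fit$beta)]) / fit$se
  expect_true(all(z < 3))
  expect_true(fit$converged)
})

test_that("cost rescaling divides beta(cost) and changes nothing else", {
  fx <- sim_fixture(n = 400, seed = 13, p_inattentive = 0,
                    hesitant_optout_shift = 0, optout_asc = -1)
  coded <- code_dataset(apply_trap_filter(fx$dat)$passed)
  fit1 <- fit_clogit(coded)
  coded2 <- coded
  coded2$X[, "cost"] <- coded2$X[, "cost"] / 1000
  fit2 <- fit_clogit(coded2)
  expect_equal(fit2$beta[["cost"]], fit1$beta[["cost"]] * 1000,
               tolerance = 1e-6)
  keep <- setdiff(names(fit1$beta), "cost")
  expect_equal(fit1$beta[keep], fit2$beta[keep], tolerance = 1e-7)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)

  # WTP is invariant under the same rescaling (cost now per 1000 INR)
  w1 <- wtp(fit1, "effectiveness_90")
  w2 <- wtp(fit2, "effectiveness_90")
  expect_equal(w1$wtp, w2$wtp * 1000, tolerance = 1e-5)
})

test_that("fits agree with survival::clogit on seeded datasets", {
  skip_if_not_installed("survival")
  library(survival)   # clogit() builds a coxph() call resolved in the caller
  des <- study_design()
  for (s in 1:20) {
    cfg <- sim_config(n_respondents = 60, seed = 100 + s,
                      p_inattentive = 0, hesitant_optout_shift = 0,
                      optout_asc = -1)
    pop <- generate_population(cfg, des$n_blocks)
    dat <- simulate_choices(pop, des, cfg)
    coded <- code_dataset(dat)
    fit <- fit_clogit(coded)
    df <- data.frame(coded$X, chosen = coded$chosen, grp = coded$group)
    ref <- survival::clogit(
      chosen ~ . - grp + strata(grp),
      data = df, method = "exact")
    expect_equal(fit$beta, coef(ref)[names(fit$beta)], tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  }
})

test_that("odds ratios reproduce the published arithmetic", {
  fake <- list(beta = c(a = 1.005, b = 0.658, c = 0),
               se = c(a = 0.018, b = 0.017, c = 0.1))
  or <- odds_ratios(fake)
  expect_equal(round(or$or[1], 2), 2.73)
  expect_equal(round(or$or[2], 2), 1.93)
  expect_equal(round(or$ci_low[1], 2), 2.64)
  expect_equal(round(or$ci_high[1], 2), 2.83)
  expect_equal(or$or[3], 1)
  expect_equal(or$ci_low[3] * or$ci_high[3], 1, tolerance = 1e-12)
})

test_that("cluster-robust vcov is PSD and near classical here", {
  fx <- sim_fixture(n = 400, seed = 13, p_inattentive = 0,
                    hesitant_optout_shift = 0, optout_asc = -1)
  coded <- code_dataset(apply_trap_filter(fx$dat)$passed)
  fit <- fit_clogit(coded)
  V <- vcov_cluster(fit, coded)
  expect_true(all(eigen(V, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  ratio <- sqrt(diag(V)) / fit$se
  expect_true(all(ratio > 0.5 & ratio < 2))
})
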