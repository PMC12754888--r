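test_that("population marginals match the configured prevalences", {
  cfg <- sim_config(n_respondents = 10000, seed = 5)
  pop <- generate_population(cfg, 8)
  pv <- cfg$prevalences
  # 3 binomial SDs around the target prevalence
  within3 <- function(x, p) abs(mean(x) - p) < 3 * sqrt(p * (1 - p) / 1e4)
  expect_true(within3(pop$male, 0.6103))
  expect_true(within3(pop$city, pv$city))
  expect_true(within3(pop$asthma, pv$asthma))
  expect_true(within3(pop$ses == "upper", pv$ses[["upper"]]))
  expect_true(within3(!pop$attentive, cfg$p_inattentive))
  expect_true(min(pop$age) >= 18)
  # propensity intercept calibration is exact in expectation
  expect_equal(mean(pop$hesitancy_propensity), cfg$target_hesitant,
               tolerance = 1e-8)
  expect_true(within3(pop$hesitant_class, cfg$target_hesitant))
  expect_true(all(pop$block_id %in% 1:8))
})

test_that("an empty population and null associations behave", {
  cfg0 <- sim_config(n_respondents = 0)
  expect_equal(nrow(generate_population(cfg0)), 0L)
  null_or <- default_hesitancy_log_or() * 0
  cfg <- sim_config(n_respondents = 500, hesitancy_log_or = null_or,
                    seed = 3)
  pop <- generate_population(cfg, 8)
  expect_equal(stats::sd(pop$hesitancy_propensity), 0)
  expect_equal(mean(pop$hesitancy_propensity), cfg$target_hesitant,
               tolerance = 1e-8)
  expect_error(sim_config(p_inattentive = 1.2), "p_inattentive")
})

test_that("neutral utilities give uniform choice frequencies", {
  beta0 <- published_part_worths() * 0
  cfg <- sim_config(n_respondents = 400, true_beta = beta0,
                    optout_asc = 0, hesitant_optout_shift = 0,
                    p_inattentive = 0, seed = 17)
  des <- study_design()
  pop <- generate_population(cfg, des$n_blocks)
  dat <- simulate_choices(pop, des, cfg)
  chosen <- dat$choices[dat$choices$chosen == 1, ]
  n <- nrow(chosen)          # 400 * 6 = 2400 >= 10000/3 draws per arm
  for (alt in c("A", "B", "optout")) {
    expect_true(abs(mean(chosen$alternative == alt) - 1 / 3) <
                  3 * sqrt((1 / 3) * (2 / 3) / n))
  }
})

test_that("a dominant coefficient forces the better alternative", {
  a <- covid_vaccine_attributes()
  f <- enumerate_full_factorial(a)
  base <- unlist(f[1, ])      # 50% protection profile, everything else ref
  alt <- base; alt["effectiveness"] <- "90% protection"
  task <- choice_task(alt, base, a)
  tr <- trap_task(a)
  des <- assign_blocks(dce_design(list(task), a), 1, seed = 1)
  des <- dce_design(c(des$tasks, list(tr)), a, n_blocks = 1,
                    criterion_value = 0)
  beta <- published_part_worths() * 0
  beta["effectiveness_90"] <- 20      # effectively infinite preference
  cfg <- sim_config(n_respondents = 300, true_beta = beta,
                    optout_asc = -20, hesitant_optout_shift = 0,
                    p_inattentive = 0, seed = 23)
  pop <- generate_population(cfg, 1)
  dat <- simulate_choices(pop, des, cfg)
  first <- dat$choices[dat$choices$task_id == 1L &
                         dat$choices$chosen == 1, ]
  expect_true(mean(first$alternative == "A") > 0.99)
})

test_that("an inattentive-only population fails the trap at rate 2/3", {
  cfg <- sim_config(n_respondents = 3000, p_inattentive = 1, seed = 29)
  des <- study_design()
  pop <- generate_population(cfg, des$n_blocks)
  # a fully inattentive population cannot hit the opt-out share target
  dat <- suppressWarnings(simulate_choices(pop, des, cfg))
  fl <- apply_trap_filter(dat)
  expect_true(abs(fl$fail_fraction - 2 / 3) <
                3 * sqrt((2 / 3) * (1 / 3) / 3000))
  # partition is exhaustive and disjoint
  expect_equal(nrow(fl$passed$respondents) + nrow(fl$failed$respondents),
               3000L)
  expect_length(intersect(fl$passed$respondents$respondent_id,
                          fl$failed$respondents$respondent_id), 0)
})

test_that("an opt-out answer on the trap counts as failure by default", {
  fx <- sim_fixture(n = 800, seed = 7)
  fl <- apply_trap_filter(fx$dat)
  ch <- fx$dat$choices
  trap_opt <- ch[ch$is_trap & ch$chosen == 1 &
                   ch$alternative == "optout", "respondent_id"]
  expect_true(length(trap_opt) > 0)
  expect_true(all(trap_opt %in% fl$failed$respondents$respondent_id))
  # permissive variant: opt-out treated as a legitimate trap answer
  fl2 <- apply_trap_filter(fx$dat, optout_fails = FALSE)
  expect_true(all(trap_opt %in% fl2$passed$respondents$respondent_id))
  expect_lt(fl2$fail_fraction, fl$fail_fraction)
})

test_that("every respondent-task has exactly one chosen alternative", {
  fx <- sim_fixture(n = 800, seed = 7)
  agg <- tapply(fx$dat$choices$chosen,
                paste(fx$dat$choices$respondent_id,
                      fx$dat$choices$task_id), sum)
  expect_true(all(agg == 1))
  expect_equal(nrow(fx$dat$choices), 800L * 6L * 3L)
})

test_that("simulation is reproducible and trap failure is monotone", {
  des <- study_design()
  cfgA <- sim_config(n_respondents = 300, seed = 77)
  popA <- generate_population(cfgA, des$n_blocks)
  d1 <- simulate_choices(popA, des, cfgA)
  d2 <- simulate_choices(popA, des, cfgA)
  expect_identical(d1$choices, d2$choices)

  fails <- vapply(c(0, 0.3, 0.8), function(pi) {
    cfg <- sim_config(n_respondents = 1500, p_inattentive = pi, seed = 55)
    pop <- generate_population(cfg, des$n_blocks)
    dat <- suppressWarnings(simulate_choices(pop, des, cfg))
    apply_trap_filter(dat)$fail_fraction
  }, numeric(1))
  expect_true(all(diff(fails) > 0))
})

test_that("task-level choice frequencies track the logit probabilities", {
  fx <- sim_fixture(n = 2000, seed = 31, p_inattentive = 0,
                    hesitant_optout_shift = 0, optout_asc = -1)
  des <- fx$des
  cm <- vaxdce:::coded_task_matrices(des$tasks, des$attrs)
  beta <- fx$cfg$true_beta
  ua <- drop(cm$Xa %*% beta); ub <- drop(cm$Xb %*% beta)
  ch <- fx$dat$choices[fx$dat$choices$chosen == 1, ]
  for (t in c(1, 20, 41)) {
    den <- exp(ua[t]) + exp(ub[t]) + exp(-1)
    pA <- exp(ua[t]) / den
    sub <- ch[ch$task_id == t, ]
    expect_true(abs(mean(sub$alternative == "A") - pA) <
                  3 * sqrt(pA * (1 - pA) / nrow(sub)) + 1e-12)
  }
})

test_that("choice data CSV round-trips", {
  fx <- sim_fixture(n = 800, seed = 7)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_choice_data_csv(fx$dat, p1, p2)
  back <- read_choice_data_csv(p1, p2, fx$des)
  expect_equal(back$choices, fx$dat$choices)
  expect_equal(back$respondents$hesitancy_propensity,
               fx$dat$respondents$hesitancy_propensity, tolerance = 1e-12)
})
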