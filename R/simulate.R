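#' Simulation configuration for synthetic DCE respondents
#'
#' The stated synthetic world: conditional-logit choosers over
#' {Vaccine A, Vaccine B, opt-out} with true part-worths defaulting to the
#' published main-effects coefficients; a hesitancy-prone latent propensity
#' that raises opt-out utility; an inattentive subpopulation answering all
#' tasks uniformly at random (and therefore failing the trap task at rate
#' 2/3); and respondent covariates drawn independently at the published
#' marginal prevalences with hesitancy association structure given by the
#' published adjusted odds ratios.
#'
#' @param n_respondents number of respondents to simulate.
#' @param true_beta named coefficient vector over [coded_columns] of
#'   `attrs`; defaults to [published_part_worths].
#' @param optout_asc opt-out alternative-specific constant (utility); `NULL`
#'   calibrates it at simulation time so the expected task-level opt-out
#'   share equals `target_optout_share` (see [calibrate_optout_asc]).
#' @param hesitant_optout_shift opt-out utility increment for members of
#'   the latent hesitancy-prone class (default 4; see vignette for the
#'   calibration argument behind the default).
#' @param p_inattentive probability a respondent is inattentive (default
#'   0.10).
#' @param target_hesitant expected hesitancy propensity used to calibrate the
#'   propensity intercept (default 0.1592).
#' @param target_optout_share expected opt-out share of task responses used
#'   when `optout_asc = NULL` (default 0.1578).
#' @param prevalences covariate prevalence list
#'   ([default_covariate_prevalences]).
#' @param hesitancy_log_or named log odds ratios of covariates on hesitancy
#'   ([default_hesitancy_log_or]).
#' @param deterministic_trap if `TRUE` attentive respondents always pass the
#'   trap task; default `FALSE` (probabilistic chooser on all tasks).
#' @param seed master RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_respondents = 10000,
                       true_beta = published_part_worths(),
                       optout_asc = NULL,
                       hesitant_optout_shift = 4,
                       p_inattentive = 0.10,
                       target_hesitant = 0.1592,
                       target_optout_share = 0.1578,
                       prevalences = default_covariate_prevalences(),
                       hesitancy_log_or = default_hesitancy_log_or(),
                       deterministic_trap = FALSE,
                       seed = 1L) {
  stopifnot(n_respondents >= 0, n_respondents == floor(n_respondents))
  if (p_inattentive < 0 || p_inattentive > 1) {
    stop("p_inattentive must be in [0, 1]", call. = FALSE)
  }
  for (nm in c("male", "married", "city", "healthcare_worker", "prior_covid",
               "family_covid", "diabetes", "hypertension", "heart_disease",
               "asthma")) {
    p <- prevalences[[nm]]
    if (is.null(p) || p < 0 || p > 1) {
      stop("prevalence '", nm, "' missing or outside [0, 1]", call. = FALSE)
    }
  }
  if (target_hesitant <= 0 || target_hesitant >= 1) {
    stop("target_hesitant must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 true_beta = true_beta, optout_asc = optout_asc,
                 hesitant_optout_shift = hesitant_optout_shift,
                 p_inattentive = p_inattentive,
                 target_hesitant = target_hesitant,
                 target_optout_share = target_optout_share,
                 prevalences = prevalences,
                 hesitancy_log_or = hesitancy_log_or,
                 deterministic_trap = deterministic_trap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a respondent population
#'
#' Covariates are drawn independently at the configured marginal
#' prevalences. Each respondent gets a hesitancy propensity
#' `plogis(intercept + sum(covariate * log_OR))` whose intercept is
#' calibrated by root-finding so the population mean equals
#' `target_hesitant`; a latent hesitancy-class draw
#' `Bernoulli(hesitancy_propensity)` (class members get the opt-out utility
#' shift during choice simulation); an attentiveness flag
#' `Bernoulli(1 - p_inattentive)`; and a uniformly random design block.
#'
#' @param config a [sim_config].
#' @param n_blocks number of design blocks to assign respondents to.
#' @return data.frame of class `dce_population`, one row per respondent.
#' @export
generate_population <- function(config, n_blocks = 8L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_respondents
  pv <- config$prevalences
  old <- set_local_seed(config$seed)
  on.exit(restore_seed(old))
  if (n == 0L) {
    return(structure(data.frame(respondent_id = integer(0)),
                     class = c("dce_population", "data.frame")))
  }
  age <- pv$age_mean + pv$age_sd * stats::rnorm(n)
  while (any(bad <- age < pv$age_min)) {  # truncate at adulthood
    age[bad] <- pv$age_mean + pv$age_sd * stats::rnorm(sum(bad))
  }
  ses <- sample(names(pv$ses), n, replace = TRUE, prob = pv$ses)
  vax <- sample(names(pv$vaccination), n, replace = TRUE,
                prob = pv$vaccination)
  pop <- data.frame(
    respondent_id = seq_len(n),
    age = age,
    male = stats::rbinom(n, 1L, pv$male),
    married = stats::rbinom(n, 1L, pv$married),
    city = stats::rbinom(n, 1L, pv$city),
    healthcare_worker = stats::rbinom(n, 1L, pv$healthcare_worker),
    ses = ses,
    prior_covid = stats::rbinom(n, 1L, pv$prior_covid),
    family_covid = stats::rbinom(n, 1L, pv$family_covid),
    diabetes = stats::rbinom(n, 1L, pv$diabetes),
    hypertension = stats::rbinom(n, 1L, pv$hypertension),
    heart_disease = stats::rbinom(n, 1L, pv$heart_disease),
    asthma = stats::rbinom(n, 1L, pv$asthma),
    vaccination = vax,
    stringsAsFactors = FALSE
  )
  lp <- hesitancy_linear_predictor(pop, config$hesitancy_log_or)
  intercept <- calibrate_hesitancy_intercept(lp, config$target_hesitant)
  pop$hesitancy_propensity <- stats::plogis(intercept + lp)
  pop$hesitant_class <- stats::rbinom(n, 1L, pop$hesitancy_propensity)
  pop$attentive <- stats::rbinom(n, 1L, 1 - config$p_inattentive) == 1L
  pop$block_id <- sample.int(n_blocks, n, replace = TRUE)
  attr(pop, "hesitancy_intercept") <- intercept
  class(pop) <- c("dce_population", "data.frame")
  pop
}

# Covariate contribution to the hesitancy log-odds, matching the coding of
# the published multivariate model: age continuous (per year, centred at the
# population mean so the intercept calibration is well-scaled), SES as two
# dummies against the lower class.
hesitancy_linear_predictor <- function(pop, log_or) {
  lp <- log_or[["age"]] * (pop$age - mean(pop$age)) +
    log_or[["male"]] * pop$male +
    log_or[["married"]] * pop$married +
    log_or[["city"]] * pop$city +
    log_or[["healthcare_worker"]] * pop$healthcare_worker +
    log_or[["ses_upper"]] * (pop$ses == "upper") +
    log_or[["ses_middle"]] * (pop$ses == "middle") +
    log_or[["prior_covid"]] * pop$prior_covid +
    log_or[["diabetes"]] * pop$diabetes +
    log_or[["hypertension"]] * pop$hypertension +
    log_or[["heart_disease"]] * pop$heart_disease +
    log_or[["asthma"]] * pop$asthma +
    log_or[["family_covid"]] * pop$family_covid
  as.numeric(lp)
}

calibrate_hesitancy_intercept <- function(lp, target) {
  f <- function(c0) mean(stats::plogis(c0 + lp)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Calibrate the opt-out alternative-specific constant
#'
#' Solves for the opt-out ASC such that, averaging over the design's tasks
#' and the population's hesitancy propensities, the expected conditional
#' logit probability of choosing opt-out equals `target` (mixing in the
#' uniform 1/3 choice of the inattentive fraction).
#'
#' @param design a blocked [dce_design] (trap included).
#' @param pop a population from [generate_population].
#' @param config a [sim_config].
#' @param target expected opt-out share of task responses; defaults to
#'   `config$target_optout_share`.
#' @return the calibrated ASC (scalar utility).
#' @export
calibrate_optout_asc <- function(design, pop, config,
                                 target = config$target_optout_share) {
  cm <- coded_task_matrices(design$tasks, design$attrs)
  ua <- drop(cm$Xa %*% config$true_beta)
  ub <- drop(cm$Xb %*% config$true_beta)
  pr <- pop$hesitancy_propensity
  sh <- config$hesitant_optout_shift
  p_in <- config$p_inattentive
  f <- function(asc) {
    # expected P(opt-out), averaging over tasks, respondents and the
    # latent hesitancy class (propensity = class probability)
    po <- vapply(seq_along(ua), function(t) {
      den <- exp(ua[t]) + exp(ub[t])
      p0 <- exp(asc) / (den + exp(asc))
      p1 <- exp(asc + sh) / (den + exp(asc + sh))
      mean(pr * p1 + (1 - pr) * p0)
    }, numeric(1))
    p_in / 3 + (1 - p_in) * mean(po) - target
  }
  lo <- -20; hi <- 20
  if (f(lo) >= 0) {
    # inattentive uniform choice alone meets/exceeds the target share;
    # push attentive opt-out as low as the search box allows
    warning("opt-out target unreachable; using optout_asc = ", lo,
            call. = FALSE)
    return(lo)
  }
  if (f(hi) <= 0) {
    warning("opt-out target unreachable; using optout_asc = ", hi,
            call. = FALSE)
    return(hi)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Simulate choices over a blocked design
#'
#' Each respondent answers the five tasks of their block plus the trap task.
#' Attentive respondents choose by a conditional logit over
#' {A, B, opt-out} with utilities `U_A = x_A' beta`, `U_B = x_B' beta`,
#' `U_optout = asc + shift * hesitant_class` (draws via the Gumbel
#' argmax representation); inattentive respondents choose uniformly over the
#' three alternatives on every task. With `deterministic_trap = TRUE`
#' attentive respondents always pick the dominant trap alternative.
#'
#' @param pop population from [generate_population].
#' @param design a blocked [dce_design] containing at least one trap task.
#' @param config a [sim_config].
#' @return object of class `choice_data`: list with `choices` (long
#'   data.frame respondent_id, task_id, alternative, is_trap, chosen),
#'   `respondents` (the population), `design`, and `optout_asc` actually
#'   used.
#' @export
simulate_choices <- function(pop, design, config) {
  stopifnot(inherits(design, "dce_design"), inherits(config, "sim_config"))
  blocks <- vapply(design$tasks, `[[`, integer(1L), "block_id")
  is_trap <- vapply(design$tasks, `[[`, logical(1L), "is_trap")
  task_ids <- vapply(design$tasks, `[[`, integer(1L), "task_id")
  if (!any(is_trap)) stop("design has no trap task", call. = FALSE)
  if (nrow(pop) > 0 &&
      any(!pop$block_id %in% blocks[!is_trap])) {
    stop("population references blocks missing from the design",
         call. = FALSE)
  }
  asc <- config$optout_asc
  if (is.null(asc)) asc <- calibrate_optout_asc(design, pop, config)

  cm <- coded_task_matrices(design$tasks, design$attrs)
  ua <- drop(cm$Xa %*% config$true_beta)
  ub <- drop(cm$Xb %*% config$true_beta)

  trap_pos <- which(is_trap)
  # tasks seen by each respondent: their block's tasks, then every trap task
  by_block <- lapply(seq_len(max(blocks, na.rm = TRUE)), function(b)
    which(!is_trap & blocks == b))
  per_block <- lengths(by_block)
  if (length(unique(per_block[per_block > 0])) > 1L) {
    stop("blocks have unequal task counts", call. = FALSE)
  }

  old <- set_local_seed(config$seed + 1L)
  on.exit(restore_seed(old))

  n <- nrow(pop)
  block_mat <- do.call(rbind, by_block)          # block x tasks-per-block
  pos_mat <- cbind(block_mat[pop$block_id, , drop = FALSE],
                   matrix(trap_pos, n, length(trap_pos), byrow = TRUE))
  k <- ncol(pos_mat)                             # tasks per respondent
  Ua <- matrix(ua[pos_mat], n, k)
  Ub <- matrix(ub[pos_mat], n, k)
  uo <- asc + config$hesitant_optout_shift * pop$hesitant_class

  # Gumbel-argmax draw of the conditional logit choice, all tasks at once
  pick <- matrix(0L, n, k)
  for (t in seq_len(k)) {
    G <- matrix(-log(-log(stats::runif(3L * n))), n, 3L)
    pick[, t] <- max.col(cbind(Ua[, t], Ub[, t], uo) + G,
                         ties.method = "first")
  }
  inatt <- !pop$attentive
  if (any(inatt)) {
    pick[inatt, ] <- matrix(sample.int(3L, sum(inatt) * k, replace = TRUE),
                            sum(inatt), k)
  }
  if (config$deterministic_trap && length(trap_pos)) {
    dom <- vapply(trap_pos, function(tp) {
      d <- is_dominant_pair(design$tasks[[tp]]$profile_a,
                            design$tasks[[tp]]$profile_b, design$attrs)
      if (d == "a_dominates") 1L else 2L
    }, integer(1L))
    trap_cols <- (k - length(trap_pos) + 1L):k
    for (jj in seq_along(trap_cols)) {
      pick[pop$attentive, trap_cols[jj]] <- dom[jj]
    }
  }

  pick_vec <- as.vector(t(pick))                 # respondent-major
  alt <- rep(c("A", "B", "optout"), times = n * k)
  choices <- data.frame(
    respondent_id = rep(pop$respondent_id, each = k * 3L),
    task_id = rep(as.vector(t(matrix(task_ids[pos_mat], n, k))), each = 3L),
    alternative = alt,
    is_trap = rep(as.vector(t(matrix(is_trap[pos_mat], n, k))), each = 3L),
    chosen = as.integer(rep(pick_vec, each = 3L) == rep(1:3, n * k)),
    stringsAsFactors = FALSE
  )
  structure(list(choices = choices, respondents = pop, design = design,
                 optout_asc = asc),
            class = "choice_data")
}

#' @export
print.choice_data <- function(x, ...) {
  cat("<choice_data> ", nrow(x$respondents), " respondents, ",
      nrow(x$choices) / 3L, " task responses\n", sep = "")
  invisible(x)
}

#' Apply the trap-question quality filter
#'
#' A respondent passes the trap task iff they chose its dominant
#' alternative; by default choosing the dominated vaccine or the opt-out
#' both count as failure. `optout_fails = FALSE` treats the opt-out as a
#' legitimate preference and fails only respondents who picked the
#' dominated vaccine (the variant under which a fully opt-out respondent
#' can survive the filter). Returns the passed and failed partitions and
#' the failure fraction.
#'
#' @param data a `choice_data` object from [simulate_choices].
#' @param optout_fails whether an opt-out answer on the trap counts as a
#'   failure (default `TRUE`).
#' @return list with `passed`, `failed` (both `choice_data`) and
#'   `fail_fraction`.
#' @export
apply_trap_filter <- function(data, optout_fails = TRUE) {
  stopifnot(inherits(data, "choice_data"))
  trap_pos <- which(vapply(data$design$tasks, `[[`, logical(1L), "is_trap"))
  if (!length(trap_pos)) stop("design has no trap task", call. = FALSE)
  dom_alt <- vapply(trap_pos, function(tp) {
    t <- data$design$tasks[[tp]]
    switch(is_dominant_pair(t$profile_a, t$profile_b, data$design$attrs),
           a_dominates = "A", b_dominates = "B",
           stop("trap task is not dominant", call. = FALSE))
  }, character(1L))
  names(dom_alt) <- vapply(trap_pos, function(tp)
    as.character(data$design$tasks[[tp]]$task_id), character(1L))

  ch <- data$choices
  trap_rows <- ch[ch$is_trap & ch$chosen == 1L, ]
  ids <- data$respondents$respondent_id
  if (!all(ids %in% trap_rows$respondent_id)) {
    stop("some respondents have no trap response", call. = FALSE)
  }
  ok <- trap_rows$alternative == dom_alt[as.character(trap_rows$task_id)]
  if (!optout_fails) ok <- ok | trap_rows$alternative == "optout"
  passed_id <- trap_rows$respondent_id[ok]
  pass <- ids %in% passed_id

  subset_cd <- function(keep_ids) {
    structure(list(
      choices = ch[ch$respondent_id %in% keep_ids, , drop = FALSE],
      respondents = data$respondents[
        data$respondents$respondent_id %in% keep_ids, , drop = FALSE],
      design = data$design, optout_asc = data$optout_asc),
      class = "choice_data")
  }
  list(passed = subset_cd(ids[pass]),
       failed = subset_cd(ids[!pass]),
       fail_fraction = mean(!pass))
}

#' Write / read a choice dataset as CSV
#'
#' The long choice table and the respondent covariate table are written as
#' two separate CSV files keyed by `respondent_id`.
#'
#' @param data a `choice_data` object.
#' @param choices_path,respondents_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_choice_data_csv <- function(data, choices_path, respondents_path) {
  stopifnot(inherits(data, "choice_data"))
  utils::write.csv(data$choices, choices_path, row.names = FALSE)
  utils::write.csv(as.data.frame(data$respondents), respondents_path,
                   row.names = FALSE)
  invisible(c(choices_path, respondents_path))
}

#' @rdname write_choice_data_csv
#' @param design the [dce_design] the dataset was collected on.
#' @export
read_choice_data_csv <- function(choices_path, respondents_path, design) {
  structure(list(choices = utils::read.csv(choices_path,
                                           stringsAsFactors = FALSE),
                 respondents = utils::read.csv(respondents_path,
                                               stringsAsFactors = FALSE),
                 design = design, optout_asc = NA_real_),
            class = "choice_data")
}
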