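#' Build the full experimental design
#'
#' Pipeline wrapper: enumerate the factorial, sample candidate pairs,
#' run the Fedorov exchange at zero construction coefficients, block the
#' selected sets, and append the dominance trap task (unblocked, shown to
#' everyone).
#'
#' @param attrs attribute grid (default [covid_vaccine_attributes]).
#' @param n_sets number of experimental choice sets (default 40).
#' @param n_blocks number of blocks (default 8).
#' @param n_candidates candidate pairs sampled from the full pair space
#'   before the exchange (default 100000).
#' @param seed master seed; sub-steps use fixed offsets so stages are
#'   individually reproducible.
#' @param beta0 construction coefficients (default zero).
#' @return a blocked [dce_design] with the trap task appended last.
#' @export
run_design <- function(attrs = covid_vaccine_attributes(), n_sets = 40L,
                       n_blocks = 8L, n_candidates = 100000L, seed = 1L,
                       beta0 = NULL) {
  attrs <- check_attrs(attrs)
  profiles <- enumerate_full_factorial(attrs)
  n_pairs <- count_unique_pairs(nrow(profiles))
  cand <- candidate_pairs(profiles, attrs,
                          n = min(n_candidates, n_pairs),
                          seed = seed + 11L)
  des <- d_optimal_select(cand, n_sets = n_sets, beta0 = beta0,
                          seed = seed + 23L)
  des <- assign_blocks(des, n_blocks = n_blocks, seed = seed + 37L)
  tasks <- c(des$tasks, list(trap_task(attrs)))
  out <- dce_design(tasks, attrs, n_blocks = des$n_blocks,
                    criterion_value = des$criterion_value)
  attr(out, "criterion_trace") <- attr(des, "criterion_trace")
  out
}

#' Run the complete simulated study
#'
#' Simulates a population over a design, applies the trap filter, fits the
#' conditional logit on the trap-passed respondents' five experimental
#' tasks, and computes odds ratios, WTP, RAI and the opt-out hesitancy
#' analyses (task-level opt-out share, per-respondent scoring over all six
#' tasks, cumulative curve, univariate 2x2 odds ratios and the multivariate
#' logistic regression).
#'
#' @param design a blocked [dce_design] with a trap task; built via
#'   [run_design] when `NULL`.
#' @param config a [sim_config].
#' @param include_optout_asc include the opt-out ASC column in estimation
#'   (default `TRUE`).
#' @param hesitancy_threshold opt-out count defining hesitancy (default 3).
#' @param rai_exclude attributes excluded from the RAI denominator (default
#'   `"cost"`).
#' @param subset optional respondent filter restricting the
#'   conditional-logit fit (subgroup / sensitivity analyses): a quoted
#'   expression or string over the respondent table, e.g.
#'   `quote(healthcare_worker == 1)`, or the special value `"trap_failed"`
#'   to fit on trap-failed respondents instead of trap-passed.
#' @param design_seed seed for [run_design] when `design` is `NULL`.
#' @param n_candidates candidate-pair budget for [run_design].
#' @return list of class `dce_study` with elements `design`, `population`,
#'   `data`, `trap`, `fit`, `odds_ratios`, `wtp`, `rai`,
#'   `optout_share_percent`, `scores`, `hesitant_fraction`, `curve`,
#'   `univariate`, `multivariate`.
#' @export
run_study <- function(design = NULL, config = sim_config(),
                      include_optout_asc = TRUE, hesitancy_threshold = 3L,
                      rai_exclude = "cost", subset = NULL,
                      design_seed = 1L, n_candidates = 100000L) {
  if (is.null(design)) {
    design <- run_design(seed = design_seed, n_candidates = n_candidates)
  }
  pop <- generate_population(config, n_blocks = design$n_blocks)
  data <- simulate_choices(pop, design, config)
  trap <- apply_trap_filter(data)
  analysed <- trap$passed

  sub <- subset
  if (is.character(sub) && identical(sub, "trap_failed")) {
    sub <- quote(trap_failed)
  }
  if (identical(sub, quote(trap_failed))) {
    analysed <- trap$failed
    sub <- NULL
  }
  coded <- code_dataset(analysed, include_optout_asc = include_optout_asc,
                        subset = sub)
  fit <- fit_clogit(coded)
  ors <- odds_ratios(fit)
  wtps <- wtp_table(fit, design$attrs)
  rais <- rai(fit, design$attrs, exclude = rai_exclude)

  n_trap <- sum(vapply(design$tasks, `[[`, logical(1L), "is_trap"))
  tasks_per_resp <- (length(design$tasks) - n_trap) / design$n_blocks +
    n_trap
  scores <- score_optout(analysed, threshold = hesitancy_threshold,
                         n_tasks = tasks_per_resp)
  share <- optout_task_proportion(analysed)
  curve <- cumulative_optout_curve(scores)
  frame <- hesitancy_model_frame(analysed$respondents)
  binary_preds <- c("male", "married", "city", "healthcare_worker",
                    "prior_covid", "diabetes", "hypertension",
                    "heart_disease", "asthma", "family_covid")
  uni <- univariate_or_table(frame, scores$hesitant, binary_preds,
                             correction = TRUE)
  # a binary predictor with an empty outcome cross-cell is unidentifiable
  # in the multivariate model (its MLE diverges); drop it, as the emulated
  # study did for its one non-estimable covariate
  h <- as.integer(scores$hesitant)
  droppable <- vapply(names(frame), function(p) {
    x <- frame[[p]]
    all(x %in% c(0, 1)) &&
      min(sum(x & h), sum(x & !h), sum(!x & h), sum(!x & !h)) == 0
  }, logical(1))
  if (any(droppable)) {
    warning("dropping unidentifiable hesitancy predictor(s): ",
            paste(names(frame)[droppable], collapse = ", "),
            call. = FALSE)
  }
  multi <- fit_logistic(frame, scores$hesitant,
                        names(frame)[!droppable])

  structure(list(design = design, population = pop, data = data,
                 trap = trap["fail_fraction"], fit = fit,
                 odds_ratios = ors, wtp = wtps, rai = rais,
                 optout_share_percent = share, scores = scores,
                 hesitant_fraction = mean(scores$hesitant),
                 curve = curve, univariate = uni, multivariate = multi),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  cat("<dce_study>\n")
  cat("  respondents analysed:", nrow(x$scores), "\n")
  cat("  trap failure:", sprintf("%.2f%%", 100 * x$trap$fail_fraction),
      "\n")
  cat("  opt-out task share:", sprintf("%.2f%%", x$optout_share_percent),
      "\n")
  cat("  hesitant (>= 3/6 opt-outs):",
      sprintf("%.2f%%", 100 * x$hesitant_fraction), "\n")
  cat("  top RAI:\n")
  top <- x$rai[order(-x$rai$rai_percent), ][1:2, ]
  cat(sprintf("    %s %.1f%%\n", top$attribute, top$rai_percent))
  invisible(x)
}

#' Read a run configuration from JSON
#'
#' Recognised fields (all optional): `seed`, `n_respondents`, `n_sets`,
#' `n_blocks`, `n_candidates`, `p_inattentive`, `optout_asc`,
#' `hesitant_optout_shift`, `include_optout_asc`, `hesitancy_threshold`,
#' `rai_exclude`, `attribute_grid` (path to a grid JSON), `subset`
#' (expression string over respondent columns, or `"trap_failed"`).
#'
#' @param path JSON file path.
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(seed = 1L, n_respondents = 10000L, n_sets = 40L,
                   n_blocks = 8L, n_candidates = 100000L,
                   p_inattentive = 0.10, optout_asc = NULL,
                   hesitant_optout_shift = 4,
                   include_optout_asc = TRUE, hesitancy_threshold = 3L,
                   rai_exclude = "cost", attribute_grid = NULL,
                   subset = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  if (!is.null(out$attribute_grid) && !file.exists(out$attribute_grid)) {
    stop("attribute_grid file not found: ", out$attribute_grid,
         call. = FALSE)
  }
  out
}

#' Pipeline entry points used by the command-line wrapper
#'
#' `cli_design()` builds and writes the design CSV plus a criterion log;
#' `cli_run_all()` runs the full study and writes the report bundle
#' (coefficient/OR table, WTP table, RAI table, hesitancy tables, opt-out
#' curve, and a Markdown summary). Outputs are reproducible byte-for-byte
#' for a fixed config.
#'
#' @param config path to a JSON run config, or a list as returned by
#'   [read_run_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output paths (`cli_design`) or the `dce_study`
#'   object (`cli_run_all`).
#' @export
cli_design <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) read_run_config(config) else config
  attrs <- if (is.null(cfg$attribute_grid)) covid_vaccine_attributes()
           else read_attribute_grid(cfg$attribute_grid)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  des <- run_design(attrs, n_sets = cfg$n_sets, n_blocks = cfg$n_blocks,
                    n_candidates = cfg$n_candidates, seed = cfg$seed)
  design_path <- file.path(out_dir, "design.csv")
  write_design_csv(des, design_path)
  log_path <- file.path(out_dir, "design_log.txt")
  writeLines(c(
    sprintf("seed: %d", cfg$seed),
    sprintf("n_candidates: %d", cfg$n_candidates),
    sprintf("n_sets: %d  n_blocks: %d", cfg$n_sets, cfg$n_blocks),
    sprintf("criterion_value (log-det): %.6f", des$criterion_value)
  ), log_path)
  invisible(c(design_path, log_path))
}

#' @rdname cli_design
#' @export
cli_run_all <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) read_run_config(config) else config
  attrs <- if (is.null(cfg$attribute_grid)) covid_vaccine_attributes()
           else read_attribute_grid(cfg$attribute_grid)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  des <- run_design(attrs, n_sets = cfg$n_sets, n_blocks = cfg$n_blocks,
                    n_candidates = cfg$n_candidates, seed = cfg$seed)
  sc <- sim_config(n_respondents = cfg$n_respondents,
                   optout_asc = cfg$optout_asc,
                   hesitant_optout_shift = cfg$hesitant_optout_shift,
                   p_inattentive = cfg$p_inattentive,
                   seed = cfg$seed)
  study <- run_study(design = des, config = sc,
                     include_optout_asc = cfg$include_optout_asc,
                     hesitancy_threshold = cfg$hesitancy_threshold,
                     rai_exclude = cfg$rai_exclude,
                     subset = cfg$subset)
  write_study_report(study, out_dir)
  invisible(study)
}

#' Write the report bundle of a study
#'
#' @param study a `dce_study` from [run_study].
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(study, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    design = file.path(out_dir, "design.csv"),
    coefficients = file.path(out_dir, "coefficients.csv"),
    wtp = file.path(out_dir, "wtp.csv"),
    rai = file.path(out_dir, "rai.csv"),
    curve = file.path(out_dir, "optout_curve.csv"),
    univariate = file.path(out_dir, "hesitancy_univariate.csv"),
    multivariate = file.path(out_dir, "hesitancy_multivariate.csv"),
    report = file.path(out_dir, "report.md")
  )
  write_design_csv(study$design, paths[["design"]])
  utils::write.csv(study$odds_ratios, paths[["coefficients"]],
                   row.names = FALSE)
  utils::write.csv(study$wtp, paths[["wtp"]], row.names = FALSE)
  utils::write.csv(study$rai, paths[["rai"]], row.names = FALSE)
  utils::write.csv(study$curve, paths[["curve"]], row.names = FALSE)
  utils::write.csv(study$univariate, paths[["univariate"]],
                   row.names = FALSE)
  utils::write.csv(study$multivariate$aor_table, paths[["multivariate"]],
                   row.names = FALSE)

  md <- c(
    "# Simulated DCE study report", "",
    sprintf("- respondents analysed (trap passed): %d",
            nrow(study$scores)),
    sprintf("- trap failure rate: %.2f%%", 100 * study$trap$fail_fraction),
    sprintf("- opt-out share of task responses: %.2f%%",
            study$optout_share_percent),
    sprintf("- hesitant respondents (>= 3/6 opt-outs): %.2f%%",
            100 * study$hesitant_fraction),
    sprintf("- conditional logit: logLik %.3f, %d iterations%s",
            study$fit$loglik, study$fit$n_iterations,
            if (study$fit$converged) "" else " (NOT converged)"),
    "",
    "## Main effects (coefficient, SE, OR, 95% CI)", "",
    md_table(within(study$odds_ratios, {
      coef <- round(coef, 4); se <- round(se, 4); or <- round(or, 2)
      ci_low <- round(ci_low, 2); ci_high <- round(ci_high, 2)
    })),
    "",
    "## Willingness to pay (INR / USD)", "",
    md_table(within(study$wtp, {
      wtp <- round(wtp, 1); se <- round(se, 1)
      ci_low <- round(ci_low, 1); ci_high <- round(ci_high, 1)
      usd <- round(usd, 2)
    })),
    "",
    "## Relative attribute importance", "",
    md_table(within(study$rai, {
      utility_range <- round(utility_range, 4)
      rai_percent <- round(rai_percent, 1)
    })),
    "",
    "## Cumulative opt-out curve", "",
    md_table(within(study$curve, {
      percent_at_least_k <- round(percent_at_least_k, 2)
    })),
    "",
    "## Hesitancy predictors (adjusted ORs)", "",
    md_table(within(study$multivariate$aor_table, {
      coef <- round(coef, 4); se <- round(se, 4); aor <- round(aor, 2)
      ci_low <- round(ci_low, 2); ci_high <- round(ci_high, 2)
    }))
  )
  writeLines(md, paths[["report"]])
  invisible(paths)
}

md_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r)
    paste0("| ", paste(trimws(as.character(r)), collapse = " | "), " |"))
  c(hdr, sep, body)
}
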