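# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A 41-task blocked design over the default grid (40 experimental sets in
# 8 blocks + trap), from a reduced candidate sample so the helper stays fast.
study_design <- function() {
  if (is.null(.fixtures$design)) {
    a <- covid_vaccine_attributes()
    f <- enumerate_full_factorial(a)
    cand <- candidate_pairs(f, a, n = 2000, seed = 42)
    des <- d_optimal_select(cand, 40, seed = 42)
    des <- assign_blocks(des, 8, seed = 42)
    .fixtures$design <- dce_design(c(des$tasks, list(trap_task(a))), a,
                                   n_blocks = 8,
                                   criterion_value = des$criterion_value)
  }
  .fixtures$design
}

# Small toy grid: two binary attributes plus a 3-level one.
toy_attrs <- function() {
  list(
    dce_attribute("speed", c("slow", "fast"), better = "increasing"),
    dce_attribute("colour", c("red", "blue")),
    dce_attribute("size", c("s", "m", "l"), better = "increasing")
  )
}

# Hand-built coded_choices object (structure documented in ?code_dataset).
make_coded <- function(X, group, chosen, respondent = group) {
  structure(list(X = X, group = as.integer(group),
                 chosen = as.integer(chosen),
                 respondent = respondent),
            class = "coded_choices")
}

# Independent central-finite-difference gradient and Hessian of a scalar fn.
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h
    ej <- numeric(p); ej[j] <- h
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                  f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
  }
  (H + t(H)) / 2
}

# Simulate a small study and return the pieces tests need, cached per key.
sim_fixture <- function(n = 800, seed = 7, ...) {
  key <- paste0("sim_", n, "_", seed, "_",
                paste(deparse(list(...)), collapse = ""))
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_config(n_respondents = n, seed = seed, ...)
    des <- study_design()
    pop <- generate_population(cfg, des$n_blocks)
    dat <- simulate_choices(pop, des, cfg)
    .fixtures[[key]] <- list(cfg = cfg, des = des, pop = pop, dat = dat)
  }
  .fixtures[[key]]
}
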