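# Shared fixtures, built in code and cached for the duration of the test
# run (featurization is the slow step, the data are deterministic).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small synthetic study for unit tests.
tiny_sim <- function() {
  cached("tiny_sim", pcmscreen::simulate_pcm_data(n_compounds = 60,
                                                  seed = 42))
}

tiny_examples <- function() {
  cached("tiny_examples", {
    sim <- tiny_sim()
    suppressWarnings(suppressMessages(pcmscreen::assemble_examples(
      sim$records, targets = sim$panel, compounds = sim$compounds,
      panel = sim$panel)))
  })
}

tiny_external_examples <- function() {
  cached("tiny_external", {
    sim <- tiny_sim()
    suppressWarnings(suppressMessages(pcmscreen::assemble_examples(
      sim$external, targets = sim$panel, compounds = sim$compounds,
      panel = sim$panel)))
  })
}

# A hand-made example tibble with a few features, for operations that only
# need labeled feature rows (augmentation, metrics plumbing).
toy_examples <- function(n_active = 10, n_inactive = 90, target = "T1",
                         seed = 1) {
  withr::with_seed(seed, {
    n <- n_active + n_inactive
    tibble::tibble(
      compound_id = sprintf("c%03d", seq_len(n)),
      target_id = target,
      label = rep(c("active", "inactive"), c(n_active, n_inactive)),
      origin = "original",
      P_a = stats::rnorm(n), P_b = stats::rnorm(n),
      L_x = stats::rnorm(n), L_y = stats::rnorm(n)
    )
  })
}

blosum62 <- function() {
  cached("blosum62", {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    env$BLOSUM62
  })
}
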