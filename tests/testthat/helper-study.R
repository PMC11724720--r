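# The full-scale synthetic study (default generator settings, seed 42),
# assembled once and shared by the end-to-end performance tests.

full_sim <- function() {
  cached("full_sim", pcmscreen::simulate_pcm_data(seed = 42))
}

full_examples <- function() {
  cached("full_examples", {
    sim <- full_sim()
    suppressWarnings(suppressMessages(pcmscreen::assemble_examples(
      sim$records, targets = sim$panel, compounds = sim$compounds,
      panel = sim$panel)))
  })
}

full_external_examples <- function() {
  cached("full_external", {
    sim <- full_sim()
    suppressWarnings(suppressMessages(pcmscreen::assemble_examples(
      sim$external, targets = sim$panel, compounds = sim$compounds,
      panel = sim$panel)))
  })
}

binary_labels <- function(examples) {
  as.integer(examples$label == "active")
}
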