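# Shared study conditions for the analysis stages. Every stage regenerates
# the dataset from this spec; generation is deterministic and cheap, so no
# intermediate binaries are kept.

suppressMessages(library(bindprop))

study_enrichment <- function() {
  stats::setNames(
    c(0.76, 1.00, 0.95, 0.90, 1.90, 0.90, 0.50, 1.10, 1.70, 1.40,
      1.05, 0.60, 1.60, 1.50, 0.80, 0.97, 1.05, 2.25, 1.45, 1.00), AA3)
}

study_spec <- function(n_proteins = 2000) {
  composition_spec(n_proteins = n_proteins,
                   enrichment_valid = study_enrichment(),
                   seed = 20250931 %% 2^31)
}

study_dataset <- function(n_proteins = 2000) {
  generate_composition_dataset(study_spec(n_proteins))
}
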