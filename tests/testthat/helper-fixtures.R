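# Small deterministic fixtures shared across tests.

# A tiny noiseless series with known truth, fast to build.
noiseless_series <- function(seed = 1, pairs = 2, pulses = 24) {
  simulate_train_series(generator_config(n_train_pairs = pairs,
                                         pulses_per_train = pulses,
                                         poisson = FALSE, jitter_sd = 0,
                                         seed = seed))
}

# Hand-written three-atom PDB (C, N, O) fixture.
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   GLY A   2       3.800   0.000   0.000  1.00  0.00           N",
    "ATOM      3  O   GLY A   3       0.000   3.800   0.000  1.00  0.00           O",
    "END"), path)
  path
}

# Same atoms with the element column blank (forces name-based inference).
write_tiny_pdb_noelem <- function(path) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  N   GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  O   GLY A   3       0.000   3.800   0.000  1.00  0.00",
    "END"), path)
  path
}
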