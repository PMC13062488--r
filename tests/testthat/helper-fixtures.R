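# Shared fixture molecules, parsed once per test session (the parser caches
# by SMILES, so later parse_molecule() calls on these strings are free).

toy_smiles <- vapply(toy_suite(), `[[`, "", "smiles")
invisible(parse_molecules(toy_smiles))

# a small deterministic set of grammar molecules for property-style loops
property_molecules <- function(n = 120, seed = 11) {
  reg <- simulate_regression(n = ceiling(n / 2), noise_sd = 0, seed = seed)
  cls <- simulate_classification(n = 2 * floor(n / 4), seed = seed + 1)
  unique(c(reg$smiles, cls$smiles))
}
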