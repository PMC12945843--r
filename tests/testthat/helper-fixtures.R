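# Shared fixtures and independent oracles for the suite.

ref_fixture <- function() load_reference_substances()

ref_substance <- function(name) {
  fix <- ref_fixture()
  nm <- vapply(fix$substances, function(s) s$name, character(1))
  fix$substances[[match(name, nm)]]
}

# naive re-implementations used as oracles; deliberately written from the
# defining formulas, independent of the package internals
naive_ra <- function(a, b) {
  sqrt(4 * (a[[1]] - b[[1]])^2 + (a[[2]] - b[[2]])^2 + (a[[3]] - b[[3]])^2)
}

naive_chi <- function(vm, dt_drug, dt_exc, temperature = 298, R = 8.314) {
  vm * (dt_drug - dt_exc)^2 / (R * temperature)
}

# heavy atoms in a simple (bracket-free) SMILES: one letter per C/N/O/S
smiles_heavy_atoms <- function(smiles) {
  lengths(regmatches(smiles, gregexpr("[CNOS]", smiles)))
}
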