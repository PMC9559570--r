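# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, builder(), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

# default-scale simulated genome + haplotype pair (deterministic)
simFixture <- function() fixture("sim", function() {
    cfg <- simConfig(nReads = 400, nMolecules = 60)
    sim <- simulateGenome(cfg, seed = 101)
    pair <- buildHaplotypePair(sim$genome, sim$structure)
    mols <- simulateMolecules(sim$genome, sim$structure, cfg, seed = 101)
    rd <- simulateReads(mols, cfg, seed = 101)
    list(cfg = cfg, genome = sim$genome, structure = sim$structure,
         pair = pair, molecules = mols, reads = rd$reads,
         provenance = rd$provenance)
})

# classification of the 400 fixture reads (shared by several tests)
classifiedFixture <- function() fixture("classified", function() {
    fx <- simFixture()
    calls <- classifyReads(fx$reads, fx$pair)
    merge(calls, fx$provenance, by = "readId")
})
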