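# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 10-residue chain with strongly coupled phi dynamics (the planted system of
# the end-to-end recovery checks).
chain10_strong <- function() {
  fixture("chain10_strong", function() {
    s <- make_chain_structure(10)
    sim <- make_coupled_trajectory(s, frames = 5000, kappa = 0.9, m = 4,
                                   seed = 0)
    list(structure = s, sim = sim)
  })
}

chain10_noise <- function() {
  fixture("chain10_noise", function() {
    s <- make_chain_structure(10)
    sim <- make_coupled_trajectory(s, frames = 5000, kappa = 0, m = 4,
                                   seed = 0)
    list(structure = s, sim = sim)
  })
}

# Two-chain ladder: the contact graph has cross-chain rungs, so alternative
# routes exist and bootstrap route stability is informative.
ladder_sim <- function(kappa, seed = 0) {
  key <- sprintf("ladder_k%.2f_s%d", kappa, seed)
  fixture(key, function() {
    s <- make_chain_structure(8, n_chains = 2)
    coupled <- paste0("A:", 2:8)
    sim <- make_coupled_trajectory(s, frames = 1200, coupled = coupled,
                                   kappa = kappa, m = 4, seed = seed)
    list(structure = s, sim = sim, coupled = coupled)
  })
}
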