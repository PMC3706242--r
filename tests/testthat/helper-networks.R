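# Shared fixtures: reduced hand-built networks and cached reference states.

# Two-species toy network A -> B (rate k*A) with B decay (kb*B).
toy_ab_network <- function(k = 0.7, kb = 0) {
  rx <- list(
    list(id = "convert", fig = 1L, label = "A -> B",
         stoich = c(A = -1, B = 1), rate = quote(k * A)),
    list(id = "b_decay", fig = 2L, label = "B -> 0",
         stoich = c(B = -1), rate = quote(kb * B))
  )
  celiacqsp:::compile_network(c("A", "B"), rx, c(k = k, kb = kb),
                              variant = "patient", diet = 0)
}

# Pure first-order decay network, one species.
toy_decay_network <- function(k = 0.3) {
  rx <- list(
    list(id = "decay", fig = 1L, label = "X -> 0",
         stoich = c(X = -1), rate = quote(k * X))
  )
  celiacqsp:::compile_network("X", rx, c(k = k),
                              variant = "patient", diet = 0)
}

# Reference steady states are expensive enough to share across tests.
cached_refs <- local({
  refs <- NULL
  function() {
    if (is.null(refs)) refs <<- cd_references(cd_parameters())
    refs
  }
})

# Random non-negative states over a network's species, reproducible.
random_states <- function(net, n, seed = 42, scale = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    setNames(runif(length(net$species), 0, scale), net$species)
  })
}

# Independent per-species bookkeeping oracle for dx/dt: accumulate each
# reaction's stoichiometric contribution species by species, without the
# stoichiometric matrix.
bookkeeping_rhs <- function(net, state) {
  v <- reaction_rates(net, state)
  out <- setNames(numeric(length(net$species)), net$species)
  for (j in seq_along(net$stoich)) {
    st <- net$stoich[[j]]
    for (sp in names(st)) {
      out[[sp]] <- out[[sp]] + st[[sp]] * v[[j]]
    }
  }
  out
}
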