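test_that("healthy steady state has no activated cells, cytokines, zonulin or antibodies", {
  refs <- cached_refs()
  x <- refs$x_healthy
  quiet <- intersect(celiacqsp:::cd_activation_species(), names(x))
  expect_true(all(x[quiet] < 1e-8))
  expect_equal(x[["IEC"]],
               param_value(cd_parameters(), "IEC_healthy"),
               tolerance = 1e-6)
  net <- build_network(cd_parameters(), "healthy")
  expect_lt(max(abs(rhs(net, x))), 1e-6)
})

test_that("steady states are fixed points of the dynamics", {
  p <- cd_parameters()
  refs <- cached_refs()
  for (cond in list(list(refs$x_gluten, "gluten"),
                    list(refs$x_gfd, "gfd"))) {
    net <- build_network(p, "patient", diet = cond[[2]])
    tr <- simulate_model(net, cond[[1]], c(0, 200))
    drift <- abs(unlist(tr[2, net$species]) - cond[[1]]) /
      pmax(cond[[1]], 1e-6)
    expect_lt(max(drift), 5e-3)
  }
})

test_that("steady_state agrees with a long (2+ year) integration", {
  p <- cd_parameters()
  refs <- cached_refs()
  conds <- list(
    list(build_network(p, "patient", diet = "gluten"),
         cd_initial_state(p, "patient"), refs$x_gluten),
    list(build_network(p, "patient", diet = "gfd"),
         refs$x_gluten, refs$x_gfd),
    list(build_network(p, "healthy"),
         cd_initial_state(p, "healthy"), refs$x_healthy)
  )
  for (cn in conds) {
    end <- celiacqsp:::run_to_rest(cn[[1]], cn[[2]], t_max = 1000)
    rel <- abs(end - cn[[3]]) / pmax(abs(cn[[3]]), 1e-6)
    expect_lt(max(rel), 5e-3)
  }
})

test_that("healthy variant relaxes to the quiescent state from arbitrary activation", {
  p <- cd_parameters()
  net <- build_network(p, "healthy")
  set.seed(7)
  x0 <- setNames(runif(14, 0, 2), net$species)
  end <- celiacqsp:::run_to_rest(net, x0, t_max = 2000)
  quiet <- intersect(celiacqsp:::cd_activation_species(), net$species)
  expect_true(all(end[quiet] < 1e-6))
  expect_equal(end[["IEC"]], param_value(p, "IEC_healthy"),
               tolerance = 1e-4)
})
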