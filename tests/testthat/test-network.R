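test_that("patient network has 16 species and a consistent stoichiometry", {
  net <- build_network(cd_parameters(), "patient")
  expect_length(net$species, 16L)
  expect_gte(nrow(net$reactions), 16L)
  expect_identical(dim(net$N), c(16L, nrow(net$reactions)))
  expect_true(all(net$N == round(net$N)))
})

test_that("healthy variant mounts no immune response", {
  net <- build_network(cd_parameters(), "healthy")
  expect_length(net$species, 14L)
  expect_false(any(c("APC", "aAPC") %in% net$species))
  for (st in random_states(net, 5, seed = 1)) {
    v <- reaction_rates(net, st)
    expect_identical(v[["iec_activation"]], 0)
    expect_identical(v[["iel_activation"]], 0)
    expect_identical(v[["tcell_activation"]], 0)
  }
})

test_that("zero antibody-synthesis constant silences antibody production", {
  p <- param_update(cd_parameters(), ksab = 0)
  net <- build_network(p, "patient")
  for (st in random_states(net, 5, seed = 2)) {
    expect_identical(reaction_rates(net, st)[["ab_synthesis"]], 0)
  }
})

test_that("only inflow and supply terms fire at the zero state", {
  net <- build_network(cd_parameters(), "patient")
  x0 <- setNames(rep(0, 16), net$species)
  v <- reaction_rates(net, x0)
  nonzero <- names(v)[v > 0]
  expect_setequal(nonzero, c("gluten_inflow", "iec_maturation",
                             "iel_supply", "tcell_supply",
                             "apc_differentiation"))
})

test_that("transport law: zero flux for intact zonulin-free epithelium, linear in lumen peptides", {
  p <- cd_parameters()
  net <- build_network(p, "patient")
  x <- setNames(rep(0.5, 16), net$species)
  x["Zon"] <- 0
  x["IEC"] <- param_value(p, "IEC_healthy")
  expect_identical(reaction_rates(net, x)[["gluten_transport"]], 0)

  y <- setNames(runif(16, 0.1, 1), net$species)
  y2 <- y
  y2["Glut_lum"] <- 2 * y["Glut_lum"]
  r1 <- reaction_rates(net, y)[["gluten_transport"]]
  r2 <- reaction_rates(net, y2)[["gluten_transport"]]
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("all rates are non-negative over random states", {
  for (variant in c("patient", "healthy")) {
    net <- build_network(cd_parameters(), variant)
    for (st in random_states(net, 20, seed = 3, scale = 5)) {
      expect_true(all(reaction_rates(net, st) >= 0))
    }
  }
})

test_that("rhs equals N v and matches the per-species bookkeeping oracle", {
  for (variant in c("patient", "healthy")) {
    net <- build_network(cd_parameters(), variant)
    for (st in random_states(net, 50, seed = 4, scale = 3)) {
      d <- rhs(net, st)
      expect_equal(max(abs(d - bookkeeping_rhs(net, st))), 0,
                   tolerance = 1e-12)
    }
  }
})

test_that("rates consuming a species vanish when that species is zero", {
  net <- build_network(cd_parameters(), "patient")
  for (st in random_states(net, 10, seed = 5)) {
    for (sp in net$species) {
      st0 <- st
      st0[sp] <- 0
      v <- reaction_rates(net, st0)
      consuming <- which(net$N[sp, ] < 0)
      expect_true(all(v[consuming] == 0),
                  info = paste("species", sp))
    }
  }
})

test_that("missing parameters and negative states are rejected by name", {
  p <- cd_parameters()
  p_missing <- p[p$name != "ksab", ]
  expect_error(suppressWarnings(build_network(p_missing, "patient")),
               "ksab")
  # healthy variant does not need the APC-only parameters
  p_no_apc <- p[p$name != "k_act_apc", ]
  expect_silent(suppressWarnings(build_network(p_no_apc, "healthy")))

  net <- build_network(p, "patient")
  x <- setNames(rep(0.1, 16), net$species)
  x["Ab"] <- -0.01
  expect_error(reaction_rates(net, x), "Ab")
})
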