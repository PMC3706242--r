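test_that("diet protocols validate their inputs", {
  expect_s3_class(diet_protocol(c(0, 10), c("gluten", "gfd")),
                  "cd_diet_protocol")
  expect_error(diet_protocol(c(0, 0), c("gluten", "gfd")), "increasing")
  expect_error(diet_protocol(0, "paleo"), "invalid diet")
  expect_error(diet_protocol(c(0, 1), "gluten"), "length")
  # numeric custom inflow is accepted
  prot <- diet_protocol(c(0, 5), list("gluten", 0.5))
  expect_identical(prot$diet[[2]], 0.5)
})

test_that("intervention mappings touch exactly one parameter family", {
  p <- cd_parameters()
  cases <- list(
    tg2_inhibitor = "TG2_level",
    ifng_antibody = "kdeg_if21",
    il15_antibody = "kdeg_il15",
    permeability_inhibitor = "k_act_iec",
    dq2_blocker = "k_act_apc"
  )
  for (kind in names(cases)) {
    target <- cases[[kind]]
    p2 <- apply_intervention(p, kind, 0.5)
    changed <- p$name[p2$value != p$value]
    expect_identical(changed, target)
  }
  # complete inhibition zeroes the scaled constants
  expect_identical(param_value(
    apply_intervention(p, "tg2_inhibitor", 1), "TG2_level"), 0)
  expect_identical(param_value(
    apply_intervention(p, "dq2_blocker", 1), "k_act_apc"), 0)
  expect_identical(param_value(
    apply_intervention(p, "permeability_inhibitor", 1), "k_act_iec"), 0)
})

test_that("strength 0 is the identity and invalid specs error", {
  p <- cd_parameters()
  for (kind in intervention_kinds()) {
    expect_identical(apply_intervention(p, kind, 0)$value, p$value)
  }
  expect_error(apply_intervention(p, "aspirin", 1), "arg")
  expect_error(apply_intervention(p, "dq2_blocker", 1.5), "strength")
  expect_error(apply_intervention(p, "dq2_blocker", -0.1), "strength")
})

test_that("a no-switch protocol stays at the steady state", {
  p <- cd_parameters()
  prot <- diet_protocol(0, "gluten")
  sc <- run_diet_switch(p, prot, horizon = 60, dt = 5)
  expect_true(all(abs(sc$trajectory$antibody_pct - 100) < 0.5))
  expect_true(all(abs(diff(sc$trajectory$villous_area_pct)) < 0.1))
})

test_that("horizon must cover the protocol", {
  p <- cd_parameters()
  prot <- diet_protocol(c(0, 100), c("gluten", "gfd"))
  expect_error(run_diet_switch(p, prot, horizon = 50), "horizon")
})

test_that("robustness scan is reproducible and respects degenerate boxes", {
  p <- cd_parameters()
  # degenerate boxes: lo = hi = value -> every draw equals the endpoint
  p_deg <- p
  has <- !is.na(p_deg$ci_lo)
  p_deg$ci_lo[has] <- p_deg$value[has]
  p_deg$ci_hi[has] <- p_deg$value[has]
  rb <- robustness_scan(p_deg, "dq2_blocker", 1, n_draws = 2, seed = 3)
  ep <- intervention_endpoint(p_deg, "dq2_blocker", 1)
  expect_equal(rb$antibody_pct, rep(ep$antibody_pct, 2), tolerance = 1e-6)
  expect_equal(rb$villous_area_pct, rep(ep$villous_area_pct, 2),
               tolerance = 1e-6)

  rb1 <- robustness_scan(p, "tg2_inhibitor", 1, n_draws = 3, seed = 17)
  rb2 <- robustness_scan(p, "tg2_inhibitor", 1, n_draws = 3, seed = 17)
  expect_identical(rb1$antibody_pct, rb2$antibody_pct)
  g <- glance(rb1)
  expect_identical(g$n_draws, 3L)
  expect_true(g$ab_q025 <= g$ab_median && g$ab_median <= g$ab_q975)
})
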