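test_that("sink terms follow the footnote formulas and the on/off switch", {
  sk <- sink_ratios(0.05, 1 / 35, 0.025)
  x <- sink_terms(sk, gamma = 0.5)
  expect_equal(unname(x["x1"]), 1.5 * 0.05 * 0.5 + 5 / 35, tolerance = 1e-12)
  expect_equal(unname(x["x2"]), 0.0625, tolerance = 1e-12)
  expect_equal(unname(x["x3"]), 0.0375 + 1 / 35, tolerance = 1e-12)
  expect_equal(unname(x["x4"]),
               0.0375 + 0.1 + 0.167 * (1 - 0.025 - 0.025), tolerance = 1e-12)

  # disabled: all four zero, including the starch term
  expect_equal(unname(sink_terms(sk, 0.5, enabled = FALSE)),
               c(0, 0, 0, 0))

  # gamma cancels in the pairwise sums
  for (sk2 in list(sk, default_sink_ratios())) {
    x0 <- sink_terms(sk2, 0); x1 <- sink_terms(sk2, 1)
    expect_equal(x0[["x1"]] + x0[["x2"]], x1[["x1"]] + x1[["x2"]])
    expect_equal(x0[["x3"]] + x0[["x4"]], x1[["x3"]] + x1[["x4"]])
  }
})

test_that("demand entries reproduce the printed stoichiometric anchors", {
  # standard PEP-CK minimum requirement, n = 2.5, no leakiness
  r <- cell_requirements(demand_scenario("PEPCK_STANDARD", phi_leak = 0,
                                         n_mito = 2.5))
  expect_equal(r$atp_total, 3.5714286, tolerance = 1e-6)
  expect_equal(r$nadph_total, 2.2857143, tolerance = 1e-6)

  # n = 3.0 variant: 3.50 ATP, 2.25 NADPH
  r3 <- cell_requirements(demand_scenario("PEPCK_STANDARD", phi_leak = 0,
                                          n_mito = 3))
  expect_equal(r3$atp_total, 3.5)
  expect_equal(r3$nadph_total, 2.25)

  # NADP-ME simplest scenario: BS ATP:NADPH = 2:0, M = 3:2
  r2 <- cell_requirements(demand_scenario("NADP_ME", phi_leak = 0,
                                          gamma = 0.5))
  expect_equal(c(r2$atp_BS, r2$nadph_BS), c(2, 0))
  expect_equal(c(r2$atp_M, r2$nadph_M), c(3, 2))

  # pure PEP-CK simplest scenario: BS:total ATP ratio 3:4 (derived from
  # the cell entries, not the inconsistent printed ratio column)
  rp <- cell_requirements(demand_scenario("PURE_PEPCK", phi_leak = 0,
                                          gamma = 0.5))
  expect_equal(rp$ratio_atp_BS, 3 / 4)
})

test_that("whole-leaf requirements and their gamma-invariance", {
  expect_equal(whole_leaf_requirements(demand_scenario("NADP_ME")),
               c(N_req = 2, A_req = 5.32))
  a <- 1 / 3.5
  expect_equal(
    whole_leaf_requirements(demand_scenario("PEPCK_STANDARD", n_mito = 2.5)),
    c(N_req = 2 + a * 1.16, A_req = 3 + 2 * a * 1.16), tolerance = 1e-12)

  # totals do not depend on gamma, for every subtype, sinks on or off
  for (st in setdiff(subtype_names(), "TRIPLE")) {
    for (on in c(FALSE, TRUE)) {
      mk <- function(g) demand_scenario(st, gamma = g, eta = 0.7,
                                        sinks = default_sink_ratios(),
                                        sinks_on = on)
      expect_equal(whole_leaf_requirements(mk(0.2)),
                   whole_leaf_requirements(mk(0.9)),
                   info = paste(st, on))
    }
  }
})

test_that("M + BS entries always sum to the totals", {
  for (st in subtype_names()) {
    r <- cell_requirements(demand_scenario(st, eta = 0.6, eta1 = 0.5,
                                           eta2 = 0.2, gamma = 0.35,
                                           sinks = default_sink_ratios(),
                                           sinks_on = TRUE))
    expect_equal(r$nadph_M + r$nadph_BS, r$nadph_total, info = st)
    expect_equal(r$atp_M + r$atp_BS, r$atp_total, info = st)
  }
})

test_that("mixture formulas are continuous in the pure-subtype limits", {
  fields <- c("nadph_M", "nadph_BS", "atp_M", "atp_BS")
  as_vec <- function(r) unlist(r[fields])
  pure <- as_vec(cell_requirements(demand_scenario("NADP_ME", gamma = 0.4)))
  aspm <- as_vec(cell_requirements(demand_scenario("ASP_MALATE",
                                                   gamma = 0.4)))
  for (st in c("NADPME_ASPMAL", "NADPME_PEPCK")) {
    at1 <- as_vec(cell_requirements(demand_scenario(st, gamma = 0.4,
                                                    eta = 1)))
    expect_equal(at1, pure, info = st)
  }
  nad <- as_vec(cell_requirements(demand_scenario("NAD_ME", gamma = 0.4)))
  expect_equal(
    as_vec(cell_requirements(demand_scenario("NADME_PEPCK", gamma = 0.4,
                                             eta = 1))),
    nad)
  expect_equal(
    as_vec(cell_requirements(demand_scenario("TRIPLE", gamma = 0.4,
                                             eta1 = 1, eta2 = 0))),
    pure)
  expect_equal(
    as_vec(cell_requirements(demand_scenario("TRIPLE", gamma = 0.4,
                                             eta1 = 0, eta2 = 1))),
    aspm)
})

test_that("NADP-ME-family NADPH totals equal 2 + x1 + x2", {
  sk <- default_sink_ratios()
  for (st in c("NADP_ME", "NADPME_ASPMAL", "NADPME_PEPCK", "TRIPLE")) {
    sc <- demand_scenario(st, gamma = 0.3, eta = 0.6, eta1 = 0.5,
                          eta2 = 0.2, sinks = sk, sinks_on = TRUE)
    r <- cell_requirements(sc)
    expect_equal(r$nadph_total, 2 + r$x1 + r$x2, info = st)
  }
})

test_that("missing mixture parameters raise a named error", {
  expect_error(cell_requirements(demand_scenario("NADPME_PEPCK")), "'eta'")
  expect_error(cell_requirements(demand_scenario("TRIPLE", eta1 = 0.5)),
               "'eta2'")
})
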