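# Shared fixtures: everything built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

basic_eff <- function() efficiency_stoichiometry()

basic_me_budget <- function(eff = basic_eff()) {
  scenario_budget(demand_scenario("NADP_ME"), eff)
}

case_solution <- function(name, scenario = demand_scenario("NADP_ME")) {
  p <- load_preset(name)
  b <- scenario_budget(scenario, p$efficiency)
  solve_cell_fluxes(b, absorption_cascade(p$leaf), p$photosystems,
                    p$efficiency)
}

# Independent 1-D bisection oracle for the cell-type system: root of the
# difference between the r-expression from the PSII constraint and the one
# from the PSI constraint, with s(x) substituted from the photon balance.
bisect_cell_flux_x <- function(budget, optics, ps, eff, tol = 1e-12) {
  J_LET <- budget$J_LET
  J_tot <- J_LET + budget$J_CET
  A_BS <- budget$photons * optics$a_BS / (optics$a_BS + optics$a_M)
  s_of <- function(x) eff$Phi1LL * A_BS - x * eff$Phi1LL / eff$Phi2LL
  h <- function(x) {
    s <- s_of(x)
    ((1 - ps$alpha) / ps$alpha) * x / (J_LET - x) -
      ((1 - ps$f_bsPSI) / ps$f_bsPSI) * s / (J_tot - s)
  }
  # restrict to the domain where both r-expressions are defined
  # (0 < s(x) < J_tot; s is decreasing in x) to avoid the pole at s = J_tot
  lo <- max(J_LET * 1e-9,
            (eff$Phi1LL * A_BS - J_tot) * eff$Phi2LL / eff$Phi1LL + 1e-9)
  hi <- min(J_LET * (1 - 1e-9),
            eff$Phi2LL * A_BS - 1e-9)
  if (lo >= hi) return(NA_real_)
  # locate a sign change on a fine grid, then refine
  xs <- seq(lo, hi, length.out = 4001)
  hv <- suppressWarnings(vapply(xs, h, numeric(1)))
  ok <- which(is.finite(hv[-1]) & is.finite(hv[-length(hv)]) &
                hv[-1] * hv[-length(hv)] <= 0)
  if (length(ok) == 0) return(NA_real_)
  stats::uniroot(h, c(xs[ok[1]], xs[ok[1] + 1]), tol = tol)$root
}

# Brute-force residual-grid oracle for the triple-pathway solve (basic
# scenario, sinks off): squared residuals of the two balance equations
# written out directly from the demand table entries, minimised on a
# coarse grid and then on a 1e-4 grid around the coarse optimum.
grid_triple_oracle <- function(phi, f_n, f_a, rho) {
  op <- 1 + phi
  sweep_grid <- function(gs, es) {
    r1 <- outer(2 * gs, es * op, "-") - f_n * 2               # NADPH
    bs_atp <- outer(2 * gs + 1, (1 - es * (1 + rho)) * op, "+")
    tot_atp <- 3 + (1 + es * (1 + rho)) * op
    r2 <- bs_atp - matrix(f_a * tot_atp, nrow = length(gs),
                          ncol = length(es), byrow = TRUE)
    idx <- arrayInd(which.min(r1^2 + r2^2), dim(r1))
    c(gs[idx[1]], es[idx[2]])
  }
  coarse <- sweep_grid(seq(0, 1, by = 0.01), seq(0, 1, by = 0.01))
  sweep_grid(seq(max(0, coarse[1] - 0.02), min(1, coarse[1] + 0.02), by = 1e-4),
             seq(max(0, coarse[2] - 0.02), min(1, coarse[2] + 0.02), by = 1e-4))
}
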