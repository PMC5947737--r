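# Demand-supply matching: the BS:total requirement ratios of the demand
# bookkeeping are affine in the unknowns (gamma, eta, eta1), because every
# cell entry is affine in them and the totals are gamma-free. Each matching
# equation is therefore written in cross-multiplied form
#   g(theta) = BS_requirement(theta) - target * total_requirement(theta) = 0
# and the exact affine coefficients are extracted by evaluating g at basis
# points. Closed-form solves throughout; a brute-force residual-grid oracle
# lives in the test suite only.

ratio_for <- function(scenario, currency) {
  r <- cell_requirements(scenario)
  if (currency == "NADPH") r$ratio_nadph_BS else r$ratio_atp_BS
}

# g(scenario) = BS - target * total, for the chosen currency
match_residual <- function(scenario, currency, target) {
  r <- cell_requirements(scenario)
  if (currency == "NADPH") r$nadph_BS - target * r$nadph_total
  else r$atp_BS - target * r$atp_total
}

#' Solve the BS share of 3-PGA reduction (gamma) from one balance
#'
#' Sets the BS:total requirement ratio of the chosen energy currency equal
#' to the corresponding BS production fraction from the cell-type solution
#' and solves the affine equation for gamma. Solutions outside \[0, 1\] are
#' returned with `feasible = FALSE` (the model uses them diagnostically,
#' e.g. the mostly negative gamma-for-ATP of the pure PEP-CK type).
#'
#' @param scenario A [demand_scenario()]; its `gamma` is the unknown (any
#'   imposed value is ignored). `eta`/`eta1`/`eta2` must be set if the
#'   subtype needs them.
#' @param production A [solve_cell_fluxes()] result supplying `f_nadph_BS`
#'   and `f_atp_BS`.
#' @param currency `"NADPH"` or `"ATP"`.
#' @return An object of class `match_result` with the solved `gamma`,
#'   `residual`, `feasible` and `diagnosis`.
#' @export
solve_gamma <- function(scenario, production, currency = c("NADPH", "ATP")) {
  currency <- match.arg(currency)
  target <- if (currency == "NADPH") production$f_nadph_BS
            else production$f_atp_BS
  g <- function(gm) {
    sc <- scenario; sc$gamma <- gm
    match_residual(sc, currency, target)
  }
  g0 <- g(0); slope <- g(1) - g0
  if (abs(slope) < 1e-12)
    stop("degenerate: requirement ratio does not depend on gamma",
         call. = FALSE)
  gamma <- -g0 / slope
  feasible <- gamma >= 0 && gamma <= 1
  match_result(
    gamma = gamma, residual = g(gamma), feasible = feasible,
    diagnosis = if (feasible) "ok" else
      sprintf("gamma = %.3f outside [0,1]: %s balance unattainable by shifting 3-PGA reduction",
              gamma, currency)
  )
}

#' Solve the primary-route fraction (eta) for a double mixed pathway
#'
#' For the NADP-ME + aspartate-malate mixture the ATP requirement ratio is
#' eta-free, so gamma is solved first from the ATP balance and eta then
#' from the NADPH balance. For the NAD-ME + PEP-CK mixture the NADPH ratio
#' is eta-free, so gamma comes from the NADPH balance and eta from the ATP
#' balance. For NADP-ME + PEP-CK both ratios involve (gamma, eta) and the
#' 2x2 affine system is solved simultaneously. Solutions with eta outside
#' \[0, 1\] are flagged infeasible: eta > 1 means the secondary route would
#' have to run backwards, i.e. it cannot supplement the primary one.
#'
#' @param scenario A [demand_scenario()] whose subtype is one of
#'   `NADPME_ASPMAL`, `NADPME_PEPCK`, `NADME_PEPCK`; `gamma` and `eta` are
#'   the unknowns.
#' @param production A [solve_cell_fluxes()] result.
#' @return A `match_result` with `gamma`, `eta`, `residuals`, `feasible`,
#'   `diagnosis`.
#' @export
solve_eta_double <- function(scenario, production) {
  st <- scenario$subtype
  if (!st %in% c("NADPME_ASPMAL", "NADPME_PEPCK", "NADME_PEPCK"))
    stop("subtype must be a double mixed pathway", call. = FALSE)
  f_n <- production$f_nadph_BS
  f_a <- production$f_atp_BS

  if (st == "NADPME_PEPCK") {
    sol <- solve_affine_2x2(
      function(gm, et) {
        sc <- scenario; sc$gamma <- gm; sc$eta <- et
        c(match_residual(sc, "NADPH", f_n), match_residual(sc, "ATP", f_a))
      })
    gamma <- sol[1]; eta <- sol[2]
  } else if (st == "NADPME_ASPMAL") {
    sc0 <- scenario; sc0$eta <- 1      # ATP ratio is eta-free
    gamma <- solve_gamma(sc0, production, "ATP")$gamma
    eta <- solve_affine_1d(function(et) {
      sc <- scenario; sc$gamma <- gamma; sc$eta <- et
      match_residual(sc, "NADPH", f_n)
    })
  } else { # NADME_PEPCK: NADPH ratio is eta-free
    sc0 <- scenario; sc0$eta <- 1
    gamma <- solve_gamma(sc0, production, "NADPH")$gamma
    eta <- solve_affine_1d(function(et) {
      sc <- scenario; sc$gamma <- gamma; sc$eta <- et
      match_residual(sc, "ATP", f_a)
    })
  }

  scf <- scenario; scf$gamma <- gamma; scf$eta <- eta
  res <- c(NADPH = match_residual(scf, "NADPH", f_n),
           ATP = match_residual(scf, "ATP", f_a))
  feasible <- gamma >= 0 && gamma <= 1 && eta >= 0 && eta <= 1
  match_result(
    gamma = gamma, eta = eta, residual = res, feasible = feasible,
    diagnosis = if (feasible) "ok"
      else if (eta > 1) sprintf(
        "eta = %.2f > 1: secondary %s route physiologically impossible here",
        eta, if (st == "NADPME_ASPMAL") "aspartate-malate" else "PEP-CK")
      else "solution outside [0,1]"
  )
}

#' Solve the triple decarboxylation pathway (gamma, eta1, eta2)
#'
#' Three unknowns exceed the two balance equations, so the BS:M NADP-MDH
#' abundance ratio is imposed as `eta2 = rho_MDH * eta1` (reported to be up
#' to 0.39 in maize), reducing the system to a 2x2 affine solve in
#' (gamma, eta1). With `rho_MDH = 0` this reduces to the
#' NADP-ME + PEP-CK double solve.
#'
#' @param scenario A [demand_scenario()] with subtype `TRIPLE`.
#' @param production A [solve_cell_fluxes()] result.
#' @param rho_MDH Imposed eta2 : eta1 ratio (default 0.39).
#' @return A `match_result` with `gamma`, `eta1`, `eta2`, `residuals`,
#'   `feasible`, `diagnosis`.
#' @export
solve_triple <- function(scenario, production, rho_MDH = 0.39) {
  stopifnot(scenario$subtype == "TRIPLE", rho_MDH >= 0)
  f_n <- production$f_nadph_BS
  f_a <- production$f_atp_BS
  sol <- solve_affine_2x2(
    function(gm, e1) {
      sc <- scenario; sc$gamma <- gm; sc$eta1 <- e1; sc$eta2 <- rho_MDH * e1
      c(match_residual(sc, "NADPH", f_n), match_residual(sc, "ATP", f_a))
    })
  gamma <- sol[1]; eta1 <- sol[2]; eta2 <- rho_MDH * eta1
  scf <- scenario; scf$gamma <- gamma; scf$eta1 <- eta1; scf$eta2 <- eta2
  res <- c(NADPH = match_residual(scf, "NADPH", f_n),
           ATP = match_residual(scf, "ATP", f_a))
  feasible <- gamma >= 0 && gamma <= 1 && eta1 >= 0 && eta2 >= 0 &&
    eta1 + eta2 <= 1
  match_result(gamma = gamma, eta1 = eta1, eta2 = eta2, rho_MDH = rho_MDH,
               residual = res, feasible = feasible,
               diagnosis = if (feasible) "ok" else "solution outside bounds")
}

#' Self-consistent demand-supply matching
#'
#' The single-pass solves above take the production fractions from a budget
#' built with the *pure* primary subtype, but a solved mixture changes the
#' whole-leaf ATP requirement and hence the production fractions. This
#' fixed-point loop alternates (solve gamma/eta) and (rebuild budget and
#' cell fluxes with the mixed-type requirement) until the solved unknowns
#' stop moving. For pure subtypes the requirement is independent of gamma
#' and the loop converges in one iteration. The drift of the production
#' fractions between the first and final pass is reported; it is expected
#' to be below 0.01.
#'
#' @param scenario A [demand_scenario()] (pure subtype, double mixture, or
#'   `TRIPLE`).
#' @param preset A [parameter_preset()] supplying optics, photosystems and
#'   efficiencies.
#' @param rho_MDH eta2 : eta1 ratio for the triple pathway.
#' @param currency Balance used for pure-subtype gamma solving.
#' @param tol Convergence tolerance on the solved unknowns (default 1e-10).
#' @param max_iter Maximum fixed-point iterations (default 100).
#' @return The final `match_result`, augmented with `iterations`,
#'   `converged`, and `production_drift` (max abs change of
#'   `f_nadph_BS`/`f_atp_BS` between first and final pass).
#' @export
self_consistent_match <- function(scenario, preset, rho_MDH = 0.39,
                                  currency = "NADPH",
                                  tol = 1e-10, max_iter = 100) {
  stopifnot(tol > 0, max_iter >= 1)
  optics <- absorption_cascade(preset$leaf)
  eff <- preset$efficiency
  is_double <- scenario$subtype %in%
    c("NADPME_ASPMAL", "NADPME_PEPCK", "NADME_PEPCK")
  is_triple <- scenario$subtype == "TRIPLE"

  solve_once <- function(production) {
    if (is_double) solve_eta_double(scenario, production)
    else if (is_triple) solve_triple(scenario, production, rho_MDH)
    else solve_gamma(scenario, production, currency)
  }
  budget_for <- function(match) {
    sc <- scenario
    sc$gamma <- match$gamma
    if (is_double) sc$eta <- match$eta
    if (is_triple) { sc$eta1 <- match$eta1; sc$eta2 <- match$eta2 }
    scenario_budget(sc, eff)
  }
  unknowns <- function(m) c(m$gamma, m$eta, m$eta1, m$eta2)

  # first pass: production fractions from the pure primary-route budget
  sc0 <- scenario
  if (is_double) sc0$eta <- 1
  if (is_triple) { sc0$eta1 <- 1; sc0$eta2 <- 0 }
  if (is.null(sc0$gamma)) sc0$gamma <- 0.5
  budget <- scenario_budget(sc0, eff)
  production <- solve_cell_fluxes(budget, optics, preset$photosystems, eff)
  first_prod <- c(production$f_nadph_BS, production$f_atp_BS)
  match <- solve_once(production)

  converged <- FALSE
  iterations <- 0
  for (i in seq_len(max_iter)) {
    iterations <- i
    budget <- budget_for(match)
    production <- solve_cell_fluxes(budget, optics, preset$photosystems, eff)
    match_new <- solve_once(production)
    delta <- max(abs(unknowns(match_new) - unknowns(match)))
    match <- match_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("no convergence after %d iterations", max_iter),
         call. = FALSE)
  match$iterations <- iterations
  match$converged <- TRUE
  match$production_drift <-
    max(abs(c(production$f_nadph_BS, production$f_atp_BS) - first_prod))
  match
}

match_result <- function(...) structure(list(...), class = "match_result")

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>\n")
  for (nm in c("gamma", "eta", "eta1", "eta2"))
    if (!is.null(x[[nm]])) cat(sprintf("  %s = %.4f\n", nm, x[[nm]]))
  cat(sprintf("  feasible: %s  (%s)\n", x$feasible, x$diagnosis))
  if (!is.null(x$iterations))
    cat(sprintf("  converged in %d iteration(s); production drift %.4f\n",
                x$iterations, x$production_drift))
  invisible(x)
}

# ---- affine solvers ----

# scalar affine root of g (g must be exactly affine)
solve_affine_1d <- function(g) {
  g0 <- g(0); slope <- g(1) - g0
  if (abs(slope) < 1e-12) stop("degenerate affine equation", call. = FALSE)
  -g0 / slope
}

# root of an affine map R^2 -> R^2; g(a, b) returns the two residuals
solve_affine_2x2 <- function(g) {
  g00 <- g(0, 0)
  A <- cbind(g(1, 0) - g00, g(0, 1) - g00)
  if (abs(det(A)) < 1e-12)
    stop("singular matching system", call. = FALSE)
  as.numeric(solve(A, -g00))
}
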