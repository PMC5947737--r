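#' Whole-leaf electron budget under NADPH and ATP co-limitation
#'
#' Converts per-CO2 NADPH and ATP requirements into linear (LET) and cyclic
#' (CET) electron fluxes. LET supplies all NADPH (2 e- per NADPH) and, via
#' its proton pumping, part of the ATP; CET tops up the ATP deficit. With
#' the default stoichiometry (H_LET = 3, h = 4) LET alone yields
#' ATP:NADPH = 1.5, so the deficit is exactly the demand beyond that ratio.
#' Photon cost sums the per-photosystem costs of each flux; the quantum
#' yield is its reciprocal, on a per-carboxylation basis.
#'
#' @param N_req NADPH required per CO2 carboxylated.
#' @param A_req ATP required per CO2 carboxylated.
#' @param eff An [efficiency_stoichiometry()].
#' @return An object of class `whole_leaf_budget` with fields `N_req`,
#'   `A_req`, `J_LET`, `J_CET`, `atp_from_LET`, `f_CET`, `photons`,
#'   `Phi_CO2`, `frac_atp_LET`, and `atp_surplus` (TRUE when LET alone
#'   overshoots the ATP demand, in which case `J_CET` is floored at 0).
#' @export
#' @examples
#' eff <- efficiency_stoichiometry()
#' b <- electron_budget(2, 3 + 2 * 1.16, eff)
#' c(b$f_CET, b$Phi_CO2)  # 0.537, 0.071
electron_budget <- function(N_req, A_req, eff) {
  J_LET <- 2 * N_req
  atp_from_LET <- J_LET * eff$H_LET / eff$h
  deficit <- A_req - atp_from_LET
  J_CET <- max(0, deficit) * eff$h / eff$H_CET
  photons <- J_LET * (1 / eff$Phi2LL + 1 / eff$Phi1LL) + J_CET / eff$Phi1LL
  structure(list(
    N_req = N_req, A_req = A_req,
    J_LET = J_LET, J_CET = J_CET, atp_from_LET = atp_from_LET,
    f_CET = J_CET / (J_LET + J_CET),
    photons = photons, Phi_CO2 = 1 / photons,
    frac_atp_LET = min(1, atp_from_LET / A_req),
    atp_surplus = deficit < 0,
    eff = eff
  ), class = "whole_leaf_budget")
}

#' Electron budget for a demand scenario
#'
#' Composition of [whole_leaf_requirements()] and [electron_budget()].
#'
#' @param scenario A [demand_scenario()].
#' @param eff An [efficiency_stoichiometry()].
#' @return A `whole_leaf_budget`.
#' @export
scenario_budget <- function(scenario, eff = efficiency_stoichiometry()) {
  req <- whole_leaf_requirements(scenario)
  electron_budget(req[["N_req"]], req[["A_req"]], eff)
}

#' @export
print.whole_leaf_budget <- function(x, ...) {
  cat("<whole_leaf_budget>\n")
  cat(sprintf("  demand:  NADPH = %.4f  ATP = %.4f per CO2\n",
              x$N_req, x$A_req))
  cat(sprintf("  fluxes:  J_LET = %.4f  J_CET = %.4f e- per CO2  (f_CET = %.3f)\n",
              x$J_LET, x$J_CET, x$f_CET))
  cat(sprintf("  photons = %.3f per CO2   Phi_CO2 = %.4f mol mol-1\n",
              x$photons, x$Phi_CO2))
  cat(sprintf("  ATP from LET: %.4f (fraction %.2f)%s\n",
              x$atp_from_LET, x$frac_atp_LET,
              if (x$atp_surplus) "  [ATP surplus: J_CET floored at 0]" else ""))
  invisible(x)
}

#' Flatten a whole-leaf budget to a one-row data frame
#'
#' @param budget A `whole_leaf_budget`.
#' @return One-row `data.frame`.
#' @export
budget_record <- function(budget) {
  as.data.frame(budget[c("N_req", "A_req", "J_LET", "J_CET", "atp_from_LET",
                         "f_CET", "photons", "Phi_CO2", "frac_atp_LET")])
}
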