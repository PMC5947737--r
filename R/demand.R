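#' Supported decarboxylation subtypes and mixtures
#'
#' Labels for the three classical C4 decarboxylation subtypes, the
#' supplementary aspartate-malate mechanism, the hypothetical "pure" PEP-CK
#' type (all decarboxylation ATP drawn from BS chloroplasts), the three
#' double mixtures, and the triple NADP-ME + aspartate-malate + PEP-CK
#' pathway.
#'
#' @return Character vector of subtype labels.
#' @export
subtype_names <- function() {
  c("NADP_ME", "NAD_ME", "PEPCK_STANDARD", "ASP_MALATE", "PURE_PEPCK",
    "NADPME_ASPMAL", "NADPME_PEPCK", "NADME_PEPCK", "TRIPLE")
}

#' Photorespiration and alternative-sink flux ratios
#'
#' Ratios of oxygenation, nitrate reduction and day respiration to Rubisco
#' carboxylation. The basic model uses (0, 0, 0); the illustrative values
#' with sinks are (1/20, 1/35, 1/40).
#'
#' @param nu_oc Oxygenation : carboxylation ratio (>= 0).
#' @param nu_nc Nitrate-reduction : carboxylation ratio (>= 0).
#' @param nu_rc Day-respiration : carboxylation ratio (>= 0).
#' @return An object of class `sink_ratios`.
#' @export
sink_ratios <- function(nu_oc = 0, nu_nc = 0, nu_rc = 0) {
  stopifnot(nu_oc >= 0, nu_nc >= 0, nu_rc >= 0)
  structure(list(nu_oc = nu_oc, nu_nc = nu_nc, nu_rc = nu_rc),
            class = "sink_ratios")
}

#' Illustrative sink ratios with photorespiration and alternative sinks
#'
#' Oxygenation:carboxylation 1:20, nitrate-reduction:carboxylation 1:35,
#' day-respiration:carboxylation 1:40.
#'
#' @return A [sink_ratios()] object.
#' @export
default_sink_ratios <- function() sink_ratios(1 / 20, 1 / 35, 1 / 40)

#' Demand scenario: subtype plus stoichiometric parameters
#'
#' @param subtype One of [subtype_names()].
#' @param phi_leak Leakiness: fraction of CO2 released in BS that leaks back
#'   to M, inflating the C4-cycle flux per carboxylation by `1 + phi_leak`.
#'   Default 0.16.
#' @param gamma Fraction of the 3-PGA reduction phase occurring in BS cells
#'   (required by the cell-type demand entries; default 0.5).
#' @param eta Fraction of C4 acids following the primary decarboxylation
#'   route (double mixtures only).
#' @param eta1,eta2 Primary (NADP-ME) and aspartate-malate route fractions
#'   (triple pathway only).
#' @param n_mito Mitochondrial ATP produced per NADH oxidised (standard
#'   PEP-CK subtype); 2.5 or 3.0 by convention. The malate fraction is the
#'   derived `a = 1/(1 + n_mito)`.
#' @param sinks A [sink_ratios()].
#' @param sinks_on Logical switch: when `FALSE` (the basic model) all four
#'   x sink terms are zero, including the starch-synthesis term.
#' @param phi_extra Extra chloroplastic ATP required per C4 cycle (default 2).
#' @return An object of class `demand_scenario`.
#' @export
demand_scenario <- function(subtype, phi_leak = 0.16, gamma = 0.5,
                            eta = NULL, eta1 = NULL, eta2 = NULL,
                            n_mito = 2.5, sinks = sink_ratios(),
                            sinks_on = FALSE, phi_extra = 2) {
  subtype <- match.arg(subtype, subtype_names())
  if (!is.null(gamma) && (gamma < 0 || gamma > 1))
    stop("gamma: fraction out of [0,1]", call. = FALSE)
  if (n_mito <= 0) stop("n_mito must be > 0", call. = FALSE)
  structure(
    list(subtype = subtype, phi_leak = phi_leak, gamma = gamma,
         eta = eta, eta1 = eta1, eta2 = eta2, n_mito = n_mito,
         a_malate = 1 / (1 + n_mito), sinks = sinks, sinks_on = sinks_on,
         phi_extra = phi_extra),
    class = "demand_scenario"
  )
}

#' Photorespiration / nitrate / starch sink terms x1-x4
#'
#' The four additive terms entering the cell-type demand entries when
#' photorespiration and alternative electron and ATP sinks are considered:
#' x1, x3 fall in M (3-PGA reduction share of the PCO cycle plus nitrate
#' reduction), x2, x4 in BS (the remaining PCO costs and starch synthesis).
#' When `enabled` is FALSE all four are zero — this is the basic model, in
#' which even the starch term is off.
#'
#' @param sinks A [sink_ratios()].
#' @param gamma BS share of 3-PGA reduction.
#' @param enabled Logical; the sink-term on/off switch.
#' @return Named numeric vector `c(x1, x2, x3, x4)`.
#' @export
sink_terms <- function(sinks, gamma, enabled = TRUE) {
  if (!enabled) return(c(x1 = 0, x2 = 0, x3 = 0, x4 = 0))
  o <- sinks$nu_oc; nn <- sinks$nu_nc; r <- sinks$nu_rc
  c(x1 = 1.5 * o * (1 - gamma) + 5 * nn,
    x2 = 1.5 * o * gamma + 0.5 * o,
    x3 = 1.5 * o * (1 - gamma) + nn,
    x4 = 1.5 * o * gamma + 2 * o + 0.167 * (1 - 0.5 * o - r))
}

#' Cell-type-specific NADPH and ATP requirements per CO2 assimilated
#'
#' Evaluates the demand bookkeeping for the scenario's subtype: NADPH and
#' ATP required in M and BS cells per mol CO2 carboxylated, their totals,
#' and the BS:total requirement ratios. The BS:total ratios are always
#' derived from the cell entries themselves (for the pure PEP-CK type this
#' reproduces the simplest-scenario 3:4 BS:total ATP ratio). Ratios outside
#' \[0, 1\] are returned with `feasible = FALSE` rather than clamped: such
#' scenarios are used diagnostically.
#'
#' @param scenario A [demand_scenario()].
#' @return An object of class `cell_requirements`.
#' @export
#' @examples
#' # standard PEP-CK minimum: 3.572 ATP and 2.286 NADPH per CO2
#' r <- cell_requirements(demand_scenario("PEPCK_STANDARD", phi_leak = 0))
#' c(r$atp_total, r$nadph_total)
cell_requirements <- function(scenario) {
  st <- scenario$subtype
  phi <- scenario$phi_leak
  g <- need_param(scenario, "gamma")
  pe <- scenario$phi_extra
  x <- sink_terms(scenario$sinks, g, scenario$sinks_on)
  x1 <- unname(x["x1"]); x2 <- unname(x["x2"])
  x3 <- unname(x["x3"]); x4 <- unname(x["x4"])
  op <- 1 + phi

  eta <- scenario$eta; eta1 <- scenario$eta1; eta2 <- scenario$eta2
  if (st %in% c("NADPME_ASPMAL", "NADPME_PEPCK", "NADME_PEPCK"))
    eta <- need_param(scenario, "eta")
  if (st == "TRIPLE") {
    eta1 <- need_param(scenario, "eta1")
    eta2 <- need_param(scenario, "eta2")
  }

  nadph <- switch(st,
    NADP_ME = c(M = op + 2 * (1 - g) + x1, BS = -op + 2 * g + x2),
    NADPME_ASPMAL = ,
    NADPME_PEPCK = c(M = eta * op + 2 * (1 - g) + x1,
                     BS = -eta * op + 2 * g + x2),
    TRIPLE = c(M = eta1 * op + 2 * (1 - g) + x1,
               BS = -eta1 * op + 2 * g + x2),
    PEPCK_STANDARD = c(M = scenario$a_malate * op + 2 * (1 - g) + x1,
                       BS = 2 * g + x2),
    # NAD_ME, ASP_MALATE, PURE_PEPCK, NADME_PEPCK
    c(M = 2 * (1 - g) + x1, BS = 2 * g + x2)
  )

  atp <- switch(st,
    PEPCK_STANDARD = c(M = scenario$a_malate * pe * op + 2 * (1 - g) + x3,
                       BS = 1 + 2 * g + x4),
    PURE_PEPCK = c(M = 2 * (1 - g) + x3,
                   BS = 1 + 2 * g + op + x4),
    NADPME_PEPCK = ,
    NADME_PEPCK = c(M = eta * pe * op + 2 * (1 - g) + x3,
                    BS = (1 - eta) * op + 1 + 2 * g + x4),
    TRIPLE = c(M = (eta1 + eta2) * pe * op + 2 * (1 - g) + x3,
               BS = (1 - eta1 - eta2) * op + 1 + 2 * g + x4),
    # NADP_ME, NAD_ME, ASP_MALATE, NADPME_ASPMAL
    c(M = pe * op + 2 * (1 - g) + x3, BS = 1 + 2 * g + x4)
  )

  nadph_total <- sum(nadph)
  atp_total <- sum(atp)
  ratio_n <- unname(nadph["BS"]) / nadph_total
  ratio_a <- unname(atp["BS"]) / atp_total
  structure(list(
    subtype = st,
    nadph_M = unname(nadph["M"]), nadph_BS = unname(nadph["BS"]),
    atp_M = unname(atp["M"]), atp_BS = unname(atp["BS"]),
    nadph_total = nadph_total, atp_total = atp_total,
    ratio_nadph_BS = ratio_n, ratio_atp_BS = ratio_a,
    x1 = x1, x2 = x2, x3 = x3, x4 = x4,
    feasible = ratio_n >= 0 && ratio_n <= 1 && ratio_a >= 0 && ratio_a <= 1
  ), class = "cell_requirements")
}

#' Whole-leaf NADPH and ATP requirement per CO2 carboxylated
#'
#' Totals of the cell-type demand entries. For the NADP-ME / NAD-ME
#' subtypes with sinks off this is `(2, 3 + phi_extra * (1 + phi_leak))`.
#'
#' @param scenario A [demand_scenario()].
#' @return Named numeric vector `c(N_req, A_req)`.
#' @export
whole_leaf_requirements <- function(scenario) {
  r <- cell_requirements(scenario)
  c(N_req = r$nadph_total, A_req = r$atp_total)
}

#' @export
print.cell_requirements <- function(x, ...) {
  cat(sprintf("<cell_requirements %s>\n", x$subtype))
  cat(sprintf("  NADPH: M = %.4f  BS = %.4f  total = %.4f  BS:total = %.4f\n",
              x$nadph_M, x$nadph_BS, x$nadph_total, x$ratio_nadph_BS))
  cat(sprintf("  ATP:   M = %.4f  BS = %.4f  total = %.4f  BS:total = %.4f\n",
              x$atp_M, x$atp_BS, x$atp_total, x$ratio_atp_BS))
  if (!x$feasible) cat("  (requirement ratio outside [0,1]: diagnostic)\n")
  invisible(x)
}

need_param <- function(scenario, field) {
  v <- scenario[[field]]
  if (is.null(v))
    stop(sprintf("subtype %s requires parameter '%s'",
                 scenario$subtype, field), call. = FALSE)
  v
}
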