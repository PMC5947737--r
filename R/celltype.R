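#' Partition LET and CET electron fluxes between cell types
#'
#' Solves for the bundle-sheath LET flux `x`, BS CET flux `y` and the
#' BS:M absorptance-per-photosystem ratio `r = k_BS : k_M` that
#' simultaneously satisfy, per mol CO2:
#' \enumerate{
#'   \item the BS photon balance
#'     `x (1/Phi2LL + 1/Phi1LL) + y / Phi1LL = A_BS`, where `A_BS` is the
#'     photons absorbed by BS cells (the M balance then holds identically);
#'   \item the PSII allocation constraint
#'     `alpha = (x/r) / ((x/r) + (J_LET - x))`;
#'   \item the PSI allocation constraint
#'     `f_bsPSI = (s/r) / ((s/r) + (J_tot - s))` with `s = x + y`.
#' }
#' Substituting `s(x)` from (1) and equating the two expressions for `r`
#' from (2) and (3) gives a quadratic in `x`; the admissible root
#' (`0 <= x <= J_LET`, `r > 0`) is returned together with all derived
#' cell-type indicators.
#'
#' @param budget A [electron_budget()] result (must use the same `eff`).
#' @param optics An [absorption_cascade()] result.
#' @param ps A [photosystem_distribution()].
#' @param eff The [efficiency_stoichiometry()] used for `budget`.
#' @return An object of class `cell_type_solution`; see Details for fields.
#'
#' @details Fields of the returned object: the fluxes `x`, `y`, `s`; the
#' ratio `r`; `u`/`v`, the fractions of M-/BS-absorbed light driving LET;
#' `beta`, the fraction of CET-engaged PSI located in BS; `CxT`, the ratio
#' of PSI engaged in CET to total PSII; PSI:PSII ratios for the whole leaf
#' and per cell type (`psi_psii_BS` is a flagged `Inf` when BS holds no
#' PSII); `photosys_BS_M`, the BS:M total photosystem ratio; per-cell CET
#' fractions `f_CET_BS`, `f_CET_M`; the BS:M electron-flux ratio
#' `e_flux_BS_M`; `cet_share_BS`; the BS production fractions `f_nadph_BS`,
#' `f_atp_BS`; `atp_BS_from_CET`; and `feasible` with its `violations`.
#' Solutions with `u`, `v` outside \[0, 1\], `y` outside \[0, J_CET\] or
#' `r <= 0` are returned flagged, not suppressed: the feasible range of
#' alpha is mapped by exactly these flags.
#' @export
#' @examples
#' p <- load_preset("case_III")
#' b <- scenario_budget(demand_scenario("NADP_ME"), p$efficiency)
#' s <- solve_cell_fluxes(b, absorption_cascade(p$leaf), p$photosystems,
#'                        p$efficiency)
#' round(s$r, 2)  # 3.41
solve_cell_fluxes <- function(budget, optics, ps, eff) {
  P2 <- 1 / eff$Phi2LL
  P1 <- 1 / eff$Phi1LL
  J_LET <- budget$J_LET
  J_CET <- budget$J_CET
  J_tot <- J_LET + J_CET
  stopifnot(J_LET > 0)

  # photons absorbed per CO2 in each cell type
  A_BS <- budget$photons * optics$a_BS / (optics$a_BS + optics$a_M)
  A_M <- budget$photons * optics$a_M / (optics$a_BS + optics$a_M)

  alpha <- ps$alpha
  fps <- ps$f_bsPSI
  # s(x) = S0 - S1 * x from the BS photon balance
  S0 <- eff$Phi1LL * A_BS
  S1 <- eff$Phi1LL / eff$Phi2LL

  r_from_psi <- function(s) {
    if (fps == 0) return(NA_real_)
    if (fps == 1) return(Inf)
    ((1 - fps) / fps) * s / (J_tot - s)
  }

  if (alpha == 0) {
    x <- 0
  } else if (alpha == 1) {
    x <- J_LET
  } else if (fps == 0 || fps == 1) {
    # all (or none) of PSI in BS pins s; x follows from the photon balance
    s_target <- if (fps == 1) J_tot else 0
    x <- (S0 - s_target) / S1
  } else {
    K_A <- (1 - alpha) / alpha
    K_F <- (1 - fps) / fps
    # K_A x (J_tot - S0 + S1 x) = K_F (S0 - S1 x)(J_LET - x)
    c2 <- (K_A - K_F) * S1
    c1 <- K_A * (J_tot - S0) + K_F * (S0 + S1 * J_LET)
    c0 <- -K_F * S0 * J_LET
    if (abs(c2) < 1e-13 * max(1, abs(c1))) {
      roots <- -c0 / c1
    } else {
      disc <- c1^2 - 4 * c2 * c0
      if (disc < 0)
        stop("no admissible root: negative discriminant", call. = FALSE)
      roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
    }
    admissible <- vapply(roots, function(x0) {
      is.finite(x0) && x0 >= -1e-12 && x0 <= J_LET + 1e-12 &&
        (x0 / (J_LET - x0)) * K_A > 0
    }, logical(1))
    if (!any(admissible))
      stop("no admissible root for x in [0, J_LET] with r > 0",
           call. = FALSE)
    if (sum(admissible) > 1 && diff(range(roots[admissible])) > 1e-9)
      stop("ambiguous solution: two admissible roots", call. = FALSE)
    x <- min(max(roots[admissible][1], 0), J_LET)
  }

  y <- (A_BS - x * (P2 + P1)) / P1
  s <- x + y
  r <- if (alpha == 0 || alpha == 1 || fps %in% c(0, 1)) {
    rv <- r_from_psi(s)
    if (!is.finite(rv) || is.na(rv)) {
      # PSI constraint degenerate too; fall back on the PSII constraint
      if (alpha > 0 && alpha < 1) ((1 - alpha) / alpha) * x / (J_LET - x)
      else rv
    } else rv
  } else {
    ((1 - alpha) / alpha) * x / (J_LET - x)
  }

  u <- (J_LET - x) * (P2 + P1) / A_M
  v <- x * (P2 + P1) / A_BS
  beta <- y / (y + r * (J_CET - y))
  den_psii <- x / r + (J_LET - x)   # proportional to total PSII
  CxT <- (eff$Phi2LL / eff$Phi1LL) * (y / r + (J_CET - y)) / den_psii
  psi_psii_leaf <- (eff$Phi2LL / eff$Phi1LL) * (s / r + (J_tot - s)) / den_psii
  psi_psii_BS <- if (x == 0) Inf else (eff$Phi2LL / eff$Phi1LL) * s / x
  psi_psii_M <- (eff$Phi2LL / eff$Phi1LL) * (J_tot - s) / (J_LET - x)
  atp_BS <- x * eff$H_LET / eff$h + y * eff$H_CET / eff$h

  violations <- character(0)
  tol <- 1e-9
  if (!is.finite(r) || r <= 0) violations <- c(violations, "r <= 0")
  if (u < -tol || u > 1 + tol) violations <- c(violations, "u outside [0,1]")
  if (v < -tol || v > 1 + tol) violations <- c(violations, "v outside [0,1]")
  if (y < -tol || y > J_CET + tol)
    violations <- c(violations, "y outside [0, J_CET]")

  structure(list(
    x = x, y = y, s = s, r = r, u = u, v = v, beta = beta, CxT = CxT,
    psi_psii_leaf = psi_psii_leaf, psi_psii_BS = psi_psii_BS,
    psi_psii_M = psi_psii_M,
    photosys_BS_M = (optics$a_BS / optics$a_M) / r,
    f_CET_BS = y / s, f_CET_M = (J_CET - y) / (J_tot - s),
    e_flux_BS_M = s / (J_tot - s),
    cet_share_BS = if (J_CET > 0) y / J_CET else NaN,
    f_nadph_BS = x / J_LET,
    f_atp_BS = atp_BS / budget$A_req,
    atp_BS_from_CET = (y * eff$H_CET / eff$h) / atp_BS,
    A_BS = A_BS, A_M = A_M,
    feasible = length(violations) == 0, violations = violations
  ), class = "cell_type_solution")
}

#' @export
print.cell_type_solution <- function(x, ...) {
  cat("<cell_type_solution>\n")
  cat(sprintf("  x (LET in BS) = %.4f  y (CET in BS) = %.4f  r (k_BS:k_M) = %.3f\n",
              x$x, x$y, x$r))
  cat(sprintf("  u = %.3f  v = %.3f  beta = %.3f  Cx:T = %.3f\n",
              x$u, x$v, x$beta, x$CxT))
  cat(sprintf("  PSI:PSII leaf/BS/M = %.2f / %.2f / %.2f\n",
              x$psi_psii_leaf, x$psi_psii_BS, x$psi_psii_M))
  cat(sprintf("  f_nadph_BS = %.3f  f_atp_BS = %.3f\n",
              x$f_nadph_BS, x$f_atp_BS))
  if (!x$feasible)
    cat("  infeasible:", paste(x$violations, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten a cell-type solution to a one-row data frame
#'
#' @param sol A `cell_type_solution`.
#' @return One-row `data.frame` keyed by indicator names.
#' @export
celltype_record <- function(sol) {
  as.data.frame(sol[c("x", "y", "s", "r", "u", "v", "beta", "CxT",
                      "psi_psii_leaf", "psi_psii_BS", "psi_psii_M",
                      "photosys_BS_M", "f_CET_BS", "f_CET_M", "e_flux_BS_M",
                      "cet_share_BS", "f_nadph_BS", "f_atp_BS",
                      "atp_BS_from_CET", "feasible")])
}

#' Map the physiologically feasible range of alpha
#'
#' Evaluates [solve_cell_fluxes()] on a grid of alpha (the fraction of PSII
#' in BS cells) over \[0, 1\] and flags each point as feasible when a
#' solution exists with `0 <= u <= 1`, `0 <= v <= 1`, `0 <= y <= J_CET` and
#' `r > 0` (boundary points count as feasible). Returns the contiguous
#' feasible interval at grid resolution together with the analytic
#' boundaries where `v = 1` (hence `y = 0`) and where `u = 1`.
#'
#' @param budget A `whole_leaf_budget`.
#' @param optics An `optics_result`.
#' @param f_bsPSI Fraction of PSI in BS cells.
#' @param eff An [efficiency_stoichiometry()].
#' @param grid_step Grid resolution on alpha (default 0.005).
#' @return An object of class `alpha_scan`: `table` (one row per alpha),
#'   `feasible_min`/`feasible_max` (grid endpoints, NA when no feasible
#'   point), and `analytic` (alpha at the `v = 1` and `u = 1` boundaries,
#'   NA when outside \[0, 1\] or undefined).
#' @export
alpha_feasibility_scan <- function(budget, optics, f_bsPSI, eff,
                                   grid_step = 0.005) {
  stopifnot(grid_step > 0)
  grid <- seq(0, 1, by = grid_step)
  rows <- lapply(grid, function(a) {
    ps <- photosystem_distribution(a, f_bsPSI)
    sol <- tryCatch(solve_cell_fluxes(budget, optics, ps, eff),
                    error = function(e) NULL)
    if (is.null(sol)) {
      data.frame(alpha = a, feasible = FALSE, u = NA_real_, v = NA_real_,
                 x = NA_real_, y = NA_real_, r = NA_real_,
                 beta = NA_real_, CxT = NA_real_,
                 f_nadph_BS = NA_real_, f_atp_BS = NA_real_)
    } else {
      data.frame(alpha = a, feasible = sol$feasible, u = sol$u, v = sol$v,
                 x = sol$x, y = sol$y, r = sol$r,
                 beta = sol$beta, CxT = sol$CxT,
                 f_nadph_BS = sol$f_nadph_BS, f_atp_BS = sol$f_atp_BS)
    }
  })
  tab <- do.call(rbind, rows)
  feas <- which(tab$feasible)
  if (length(feas) == 0) {
    lo <- hi <- NA_real_
  } else {
    # contiguous run containing the first feasible point (runs are expected
    # to be unique; take the longest if not)
    runs <- split(feas, cumsum(c(1, diff(feas) != 1)))
    run <- runs[[which.max(lengths(runs))]]
    lo <- tab$alpha[run[1]]
    hi <- tab$alpha[run[length(run)]]
  }
  structure(list(table = tab, feasible_min = lo, feasible_max = hi,
                 analytic = alpha_scan_boundaries(budget, optics, f_bsPSI, eff),
                 grid_step = grid_step),
            class = "alpha_scan")
}

# closed-form alpha at the v = 1 (y = 0) and u = 1 boundaries
alpha_scan_boundaries <- function(budget, optics, f_bsPSI, eff) {
  P2 <- 1 / eff$Phi2LL; P1 <- 1 / eff$Phi1LL
  J_LET <- budget$J_LET; J_tot <- J_LET + budget$J_CET
  A_BS <- budget$photons * optics$a_BS / (optics$a_BS + optics$a_M)
  A_M <- budget$photons - A_BS
  alpha_at <- function(x) {
    if (x < 0 || x > J_LET) return(NA_real_)
    s <- eff$Phi1LL * A_BS - x * eff$Phi1LL / eff$Phi2LL
    if (s <= 0 || s >= J_tot) return(NA_real_)
    r <- ((1 - f_bsPSI) / f_bsPSI) * s / (J_tot - s)
    a <- (x / r) / (x / r + (J_LET - x))
    if (a < 0 || a > 1) NA_real_ else a
  }
  c(alpha_v1 = alpha_at(A_BS / (P1 + P2)),
    alpha_u1 = alpha_at(J_LET - A_M / (P1 + P2)))
}

#' @export
print.alpha_scan <- function(x, ...) {
  cat("<alpha_scan>\n")
  if (is.na(x$feasible_min)) {
    cat("  no feasible alpha on the grid\n")
  } else {
    cat(sprintf("  feasible alpha: %.3f - %.3f (grid step %.3f)\n",
                x$feasible_min, x$feasible_max, x$grid_step))
  }
  cat(sprintf("  analytic boundaries: v=1 at alpha = %.4f, u=1 at alpha = %.4f\n",
              x$analytic[["alpha_v1"]], x$analytic[["alpha_u1"]]))
  invisible(x)
}
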