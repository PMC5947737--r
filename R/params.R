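#' Leaf anatomy and pigment inputs
#'
#' Bundles the anatomical and pigment parameters that determine light
#' absorption in one interveinal unit of a C4 leaf: the fraction of the
#' interveinal distance occupied by the pure-mesophyll column (`m`), the
#' fraction of leaf depth occupied by the bundle-sheath section (`n_BS`),
#' leaf chlorophyll content, the fraction of chlorophyll residing in
#' bundle-sheath cells, and the Beer-Lambert extinction coefficient.
#'
#' @param m Fraction of one unit interveinal distance for the M1 section
#'   (dimensionless, open interval (0, 1)).
#' @param n_BS Fraction of one unit leaf depth for the BS section
#'   (dimensionless, open interval (0, 1)).
#' @param CHL Leaf chlorophyll content, umol Chl m-2 (> 0).
#' @param f_bsCHL Fraction of `CHL` in BS cells, in \[0, 1\].
#' @param k Light extinction coefficient, m2 (umol Chl)-1 (>= 0).
#'
#' @return An object of class `leaf_structure` (a named list).
#' @export
#' @examples
#' leaf_structure(m = 0.55, n_BS = 0.6, CHL = 475, f_bsCHL = 0.33, k = 0.005)
leaf_structure <- function(m, n_BS, CHL, f_bsCHL, k) {
  obj <- structure(
    list(m = m, n_BS = n_BS, CHL = CHL, f_bsCHL = f_bsCHL, k = k),
    class = "leaf_structure"
  )
  stop_on_violations(validate_leaf_structure(obj))
  obj
}

validate_leaf_structure <- function(x) {
  v <- character(0)
  v <- c(v, check_open_unit(x$m, "m"))
  v <- c(v, check_open_unit(x$n_BS, "n_BS"))
  if (!is_scalar_num(x$CHL) || x$CHL <= 0) v <- c(v, "CHL must be > 0")
  v <- c(v, check_fraction(x$f_bsCHL, "f_bsCHL"))
  if (!is_scalar_num(x$k) || x$k < 0) v <- c(v, "k must be >= 0")
  v
}

#' Photosystem distribution between cell types
#'
#' @param alpha Fraction of total PSII located in BS cells, in \[0, 1\].
#' @param f_bsPSI Fraction of total PSI located in BS cells, in \[0, 1\].
#'
#' @return An object of class `photosystem_distribution`.
#' @export
photosystem_distribution <- function(alpha, f_bsPSI) {
  obj <- structure(list(alpha = alpha, f_bsPSI = f_bsPSI),
                   class = "photosystem_distribution")
  stop_on_violations(validate_photosystem_distribution(obj))
  obj
}

validate_photosystem_distribution <- function(x) {
  c(check_fraction(x$alpha, "alpha"),
    check_fraction(x$f_bsPSI, "f_bsPSI"))
}

#' Photochemical efficiencies and proton stoichiometry
#'
#' Photosystem II efficiency under strictly limiting light (`Phi2LL`), the
#' PSII:PSI efficiency ratio (`ratio21` = Phi2LL/Phi1LL), the protons pumped
#' per electron by linear (`H_LET`) and cyclic (`H_CET`) electron transport,
#' and the protons required per ATP (`h`). Phi1LL is always derived as
#' `Phi2LL / ratio21` and never stored independently.
#'
#' @param Phi2LL PSII photochemical efficiency under limiting light,
#'   mol e- (mol photon)-1, in (0, 1\].
#' @param ratio21 Phi2LL / Phi1LL, dimensionless, in (0, 1\].
#' @param H_LET Protons per electron for LET (default 3, full Q-cycle).
#' @param H_CET Protons per electron for CET (default 2; 4 for the
#'   NDH-dependent pathway).
#' @param h Protons per ATP (default 4).
#'
#' @return An object of class `efficiency_stoichiometry`, with the derived
#'   `Phi1LL` included.
#' @export
efficiency_stoichiometry <- function(Phi2LL = 0.8, ratio21 = 0.85,
                                     H_LET = 3, H_CET = 2, h = 4) {
  obj <- structure(
    list(Phi2LL = Phi2LL, ratio21 = ratio21, Phi1LL = Phi2LL / ratio21,
         H_LET = H_LET, H_CET = H_CET, h = h),
    class = "efficiency_stoichiometry"
  )
  stop_on_violations(validate_efficiency_stoichiometry(obj))
  obj
}

validate_efficiency_stoichiometry <- function(x) {
  v <- character(0)
  if (!is_scalar_num(x$Phi2LL) || x$Phi2LL <= 0 || x$Phi2LL > 1)
    v <- c(v, "Phi2LL must be in (0, 1]")
  if (!is_scalar_num(x$ratio21) || x$ratio21 <= 0 || x$ratio21 > 1)
    v <- c(v, "ratio21 must be in (0, 1]")
  if (is_scalar_num(x$Phi2LL) && is_scalar_num(x$ratio21) &&
      x$ratio21 > 0 && x$Phi2LL / x$ratio21 > 1)
    v <- c(v, "Phi1LL > 1")
  for (nm in c("H_LET", "H_CET", "h"))
    if (!is_scalar_num(x[[nm]]) || x[[nm]] <= 0)
      v <- c(v, sprintf("%s must be > 0", nm))
  v
}

#' Assemble a full parameter preset
#'
#' @param name Text label for the preset.
#' @param leaf A [leaf_structure()].
#' @param photosystems A [photosystem_distribution()].
#' @param efficiency An [efficiency_stoichiometry()].
#'
#' @return An object of class `parameter_preset`.
#' @export
parameter_preset <- function(name, leaf, photosystems, efficiency) {
  structure(list(name = name, leaf = leaf, photosystems = photosystems,
                 efficiency = efficiency),
            class = "parameter_preset")
}

preset_dir <- function() system.file("extdata", "presets", package = "c4ebm")

#' List the packaged parameter presets
#'
#' @return Character vector of preset labels.
#' @export
preset_names <- function() {
  sort(sub("\\.json$", "", list.files(preset_dir(), pattern = "\\.json$")))
}

#' Load a packaged parameter preset
#'
#' `table1_default` carries the indicative whole-model defaults; `case_I` to
#' `case_IV` carry the species parameter sets for two NADP-ME species
#' (*Sorghum bicolor*, *Cenchrus ciliaris*) and two NAD-ME species
#' (*Panicum miliaceum*, *Panicum coloratum*), differing in leaf chlorophyll
#' content, f_bsCHL, f_bsPSI and alpha.
#'
#' @param name One of the labels returned by [preset_names()].
#'
#' @return A validated [parameter_preset()].
#' @export
#' @examples
#' p <- load_preset("case_I")
#' p$leaf$CHL            # 579
#' p$photosystems$alpha  # 0.01
load_preset <- function(name) {
  path <- file.path(preset_dir(), paste0(name, ".json"))
  if (!file.exists(path)) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 name, paste(preset_names(), collapse = ", ")), call. = FALSE)
  }
  preset_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Build a preset from a plain named list
#'
#' Accepts the flat documented key set (`m`, `n_BS`, `CHL`, `f_bsCHL`,
#' `f_bsPSI`, `alpha`, `k`, `Phi2LL`, `ratio21`, `H_LET`, `H_CET`, `h`,
#' optionally `name`), as read from a JSON or YAML file.
#'
#' @param x Named list of parameter values.
#' @return A validated [parameter_preset()].
#' @export
preset_from_list <- function(x) {
  need <- c("m", "n_BS", "CHL", "f_bsCHL", "f_bsPSI", "alpha", "k",
            "Phi2LL", "ratio21", "H_LET", "H_CET", "h")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0)
    stop("missing parameter keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  parameter_preset(
    name = if (is.null(x$name)) "custom" else x$name,
    leaf = leaf_structure(x$m, x$n_BS, x$CHL, x$f_bsCHL, x$k),
    photosystems = photosystem_distribution(x$alpha, x$f_bsPSI),
    efficiency = efficiency_stoichiometry(x$Phi2LL, x$ratio21,
                                          x$H_LET, x$H_CET, x$h)
  )
}

#' Flatten a preset to the documented key set
#'
#' Inverse of [preset_from_list()]; round-tripping reproduces all fields.
#'
#' @param preset A [parameter_preset()].
#' @return Named list with the flat documented keys.
#' @export
preset_to_list <- function(preset) {
  l <- preset$leaf; p <- preset$photosystems; e <- preset$efficiency
  list(name = preset$name,
       m = l$m, n_BS = l$n_BS, CHL = l$CHL, f_bsCHL = l$f_bsCHL, k = l$k,
       alpha = p$alpha, f_bsPSI = p$f_bsPSI,
       Phi2LL = e$Phi2LL, ratio21 = e$ratio21,
       H_LET = e$H_LET, H_CET = e$H_CET, h = e$h)
}

#' Report every violated parameter invariant
#'
#' Unlike the constructors, this never raises: it returns the full list of
#' violated invariants (empty when the preset is valid), including the check
#' that the derived Phi1LL = Phi2LL/ratio21 does not exceed 1.
#'
#' @param preset A `parameter_preset` (possibly built with invalid values via
#'   direct list construction).
#' @return Character vector of violation messages; `character(0)` when valid.
#' @export
validate_parameters <- function(preset) {
  c(validate_leaf_structure(preset$leaf),
    validate_photosystem_distribution(preset$photosystems),
    validate_efficiency_stoichiometry(preset$efficiency))
}

#' Fit the extinction coefficient to a target whole-leaf absorptance
#'
#' Monotone scalar root-solve for the extinction coefficient `k` such that
#' the whole-leaf absorptance of the serial Beer-Lambert cascade equals
#' `target_absorptance`. Absorptance saturates below 1 for finite k x CHL, so
#' unreachable targets raise an error.
#'
#' @param target_absorptance Target whole-leaf absorptance, in (0, 1).
#' @param leaf A [leaf_structure()]; its `k` field is ignored.
#' @param interval Search bracket for k (default `c(1e-10, 1)`).
#'
#' @return The fitted extinction coefficient (scalar).
#' @export
fit_k <- function(target_absorptance, leaf, interval = c(1e-10, 1)) {
  stopifnot(target_absorptance > 0, target_absorptance < 1)
  f <- function(k) {
    l2 <- leaf; l2$k <- k
    absorption_cascade(l2)$absorptance - target_absorptance
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo * hi > 0) {
    stop(sprintf(
      "no root: absorptance %.4f unreachable for k in [%g, %g]",
      target_absorptance, interval[1], interval[2]), call. = FALSE)
  }
  stats::uniroot(f, interval = interval, tol = 1e-12)$root
}

#' @export
print.parameter_preset <- function(x, ...) {
  cat(sprintf("<parameter_preset '%s'>\n", x$name))
  flat <- preset_to_list(x)
  flat$name <- NULL
  cat(paste0("  ", names(flat), " = ", unlist(flat), collapse = "\n"), "\n")
  invisible(x)
}

# ---- internal validation helpers ----

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

check_fraction <- function(x, nm) {
  if (!is_scalar_num(x) || x < 0 || x > 1)
    sprintf("%s: fraction out of [0,1]", nm) else character(0)
}

check_open_unit <- function(x, nm) {
  if (!is_scalar_num(x) || x <= 0 || x >= 1)
    sprintf("%s must be in the open interval (0,1)", nm) else character(0)
}

stop_on_violations <- function(v) {
  if (length(v) > 0)
    stop("invalid parameters: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(NULL)
}
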