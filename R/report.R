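#' Read a run configuration from JSON or YAML
#'
#' The configuration holds: either `preset` (one label or a vector of
#' labels) or an explicit `parameters` block (flat documented key set); a
#' `scenarios` list, each entry with `label`, `subtype` and any of
#' `phi_leak`, `gamma`, `eta`, `eta1`, `eta2`, `n_mito`, `phi_extra`,
#' `sinks_on`, `nu_oc`, `nu_nc`, `nu_rc`; and an `options` block
#' (`grid_step`, `rho_MDH`, `self_consistent`, `tol`, `max_iter`).
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  validate_run_config(raw)
}

#' Validate a run-configuration list
#'
#' @param config Named list as produced by [read_run_config()].
#' @return The list, classed `run_config`; raises on violations with field
#'   paths.
#' @export
validate_run_config <- function(config) {
  has_preset <- !is.null(config$preset)
  has_params <- !is.null(config$parameters)
  if (has_preset == has_params)
    stop("config: exactly one of 'preset' or 'parameters' must be given",
         call. = FALSE)
  if (has_preset) {
    bad <- setdiff(unlist(config$preset), preset_names())
    if (length(bad) > 0)
      stop("config$preset: unknown preset(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
  } else {
    preset_from_list(config$parameters)  # raises with missing keys
  }
  if (is.null(config$scenarios) || length(config$scenarios) == 0)
    stop("config$scenarios: at least one scenario required", call. = FALSE)
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    if (is.null(sc$subtype) || !sc$subtype %in% subtype_names())
      stop(sprintf("config$scenarios[[%d]]$subtype: must be one of %s", i,
                   paste(subtype_names(), collapse = ", ")), call. = FALSE)
    scenario_from_config(sc)  # raises on bad fields
  }
  structure(config, class = "run_config")
}

scenario_from_config <- function(sc) {
  sinks <- sink_ratios(sc$nu_oc %||% 0, sc$nu_nc %||% 0, sc$nu_rc %||% 0)
  demand_scenario(
    subtype = sc$subtype,
    phi_leak = sc$phi_leak %||% 0.16,
    gamma = sc$gamma %||% 0.5,
    eta = sc$eta, eta1 = sc$eta1, eta2 = sc$eta2,
    n_mito = sc$n_mito %||% 2.5,
    sinks = sinks,
    sinks_on = isTRUE(sc$sinks_on),
    phi_extra = sc$phi_extra %||% 2
  )
}

presets_from_config <- function(config) {
  if (!is.null(config$preset)) {
    lapply(unlist(config$preset), load_preset)
  } else {
    list(preset_from_list(config$parameters))
  }
}

#' Run the full report for a configuration
#'
#' For every preset x scenario combination, writes machine-readable tables:
#' \itemize{
#'   \item `budget.csv` — one whole-leaf budget row per combination;
#'   \item `celltype.csv` — the per-case cell-type indicator table (one row
#'     per indicator, one column per preset, per scenario);
#'   \item `alpha_scan_<preset>_<scenario>.csv` — the alpha feasibility
#'     scans (written when `options$alpha_scan` is not `FALSE`);
#'   \item `matching.csv` — production fractions, gamma by currency, eta by
#'     double mechanism and the triple-pathway solution per preset;
#'   \item `report.json` — all of the above plus derived constants and
#'     feasibility flags, as one JSON record.
#' }
#' Output is deterministic: fixed row and column order, fixed float
#' formatting; identical configs produce byte-identical files.
#'
#' @param config A `run_config` (or path to one).
#' @param outdir Output directory, created if absent.
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, the named character vector of files written.
#' @export
run_report <- function(config, outdir = ".", quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  presets <- presets_from_config(config)
  opts <- config$options %||% list()
  rho <- opts$rho_MDH %||% 0.39
  grid_step <- opts$grid_step %||% 0.005
  do_scan <- !isFALSE(opts$alpha_scan)

  budget_rows <- list(); ct_rows <- list(); match_rows <- list()
  files <- character(0)

  for (sc_cfg in config$scenarios) {
    label <- sc_cfg$label %||% sc_cfg$subtype
    scenario <- scenario_from_config(sc_cfg)
    for (preset in presets) {
      say("scenario %s x preset %s", label, preset$name)
      eff <- preset$efficiency
      optics <- absorption_cascade(preset$leaf)
      budget <- scenario_budget(scenario, eff)
      sol <- solve_cell_fluxes(budget, optics, preset$photosystems, eff)

      id <- data.frame(preset = preset$name, scenario = label,
                       stringsAsFactors = FALSE)
      budget_rows[[length(budget_rows) + 1]] <-
        cbind(id, budget_record(budget))
      ct_rows[[length(ct_rows) + 1]] <-
        cbind(id, ratio_BS_M = optics$ratio_BS_M, celltype_record(sol))

      if (do_scan) {
        scan <- alpha_feasibility_scan(budget, optics,
                                       preset$photosystems$f_bsPSI, eff,
                                       grid_step = grid_step)
        f <- file.path(outdir, sprintf("alpha_scan_%s_%s.csv",
                                       preset$name, label))
        write_table(cbind(id, scan$table), f)
        files[basename(f)] <- f
      }

      match_rows[[length(match_rows) + 1]] <-
        matching_row(id, scenario, sol, rho)
    }
  }

  out <- list(
    budget = do.call(rbind, budget_rows),
    celltype = do.call(rbind, ct_rows),
    matching = do.call(rbind, match_rows)
  )
  for (nm in names(out)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    write_table(out[[nm]], f)
    files[basename(f)] <- f
  }
  f <- file.path(outdir, "report.json")
  jsonlite::write_json(out, f, dataframe = "rows", digits = NA, pretty = TRUE)
  files["report.json"] <- f
  invisible(files)
}

# gamma by currency, eta for the mechanisms, triple solution, for one run
matching_row <- function(id, scenario, sol, rho) {
  g_of <- function(st, currency) {
    sc <- scenario; sc$subtype <- st
    if (st %in% c("NADPME_ASPMAL", "NADPME_PEPCK", "NADME_PEPCK") &&
        is.null(sc$eta)) sc$eta <- 1
    tryCatch(solve_gamma(sc, sol, currency)$gamma,
             error = function(e) NA_real_)
  }
  eta_of <- function(st) {
    sc <- scenario; sc$subtype <- st
    tryCatch(solve_eta_double(sc, sol)$eta, error = function(e) NA_real_)
  }
  sc_tri <- scenario; sc_tri$subtype <- "TRIPLE"
  tri <- tryCatch(solve_triple(sc_tri, sol, rho), error = function(e) NULL)
  st <- scenario$subtype
  base_st <- if (st %in% c("NADP_ME", "NADPME_ASPMAL", "NADPME_PEPCK",
                           "TRIPLE")) "NADP_ME" else
             if (st %in% c("NAD_ME", "NADME_PEPCK")) "NAD_ME" else st
  cbind(id, data.frame(
    f_nadph_BS = sol$f_nadph_BS, f_atp_BS = sol$f_atp_BS,
    gamma_nadph = g_of(base_st, "NADPH"),
    gamma_atp = g_of(base_st, "ATP"),
    eta_aspmal = eta_of("NADPME_ASPMAL"),
    eta_nadpme_pepck = eta_of("NADPME_PEPCK"),
    eta_nadme_pepck = eta_of("NADME_PEPCK"),
    eta1_triple = if (is.null(tri)) NA_real_ else tri$eta1,
    eta2_triple = if (is.null(tri)) NA_real_ else tri$eta2,
    gamma_triple = if (is.null(tri)) NA_real_ else tri$gamma,
    stringsAsFactors = FALSE
  ))
}

# deterministic CSV: fixed column order, fixed float formatting
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
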