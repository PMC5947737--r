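#' Section areas of one interveinal unit
#'
#' The interveinal unit is split into a pure-mesophyll column M1 of width `m`
#' and a vein column of width `1 - m` stacked, adaxial to abaxial, as
#' M2 / BS / M3, where the BS section occupies fraction `n_BS` of the depth
#' and M2, M3 split the remainder equally.
#'
#' @param leaf A [leaf_structure()].
#' @return A named list with `A_M1`, `A_M2`, `A_M3`, `A_BS`, `A_Mtot`
#'   (dimensionless areas summing, with `A_BS`, to 1).
#' @export
section_areas <- function(leaf) {
  m <- leaf$m; n_BS <- leaf$n_BS
  A_M2 <- (1 - m) * (1 - n_BS) / 2
  list(A_M1 = m, A_M2 = A_M2, A_M3 = A_M2,
       A_BS = (1 - m) * n_BS, A_Mtot = m + 2 * A_M2)
}

#' Partition leaf chlorophyll over the four sections
#'
#' BS cells receive `f_bsCHL * CHL`; the mesophyll remainder is split over
#' M1, M2 and M3 in proportion to their areas. All amounts are per unit
#' *leaf* area (umol m-2), so the four sections sum to `CHL`.
#'
#' @param leaf A [leaf_structure()].
#' @param areas Optional precomputed [section_areas()].
#' @return Named list `C_M1`, `C_M2`, `C_M3`, `C_BS`, `C_M` (the M total).
#' @export
#' @examples
#' partition_chlorophyll(load_preset("case_I")$leaf)
partition_chlorophyll <- function(leaf, areas = section_areas(leaf)) {
  C_BS <- leaf$f_bsCHL * leaf$CHL
  C_M <- (1 - leaf$f_bsCHL) * leaf$CHL
  list(C_M1 = C_M * areas$A_M1 / areas$A_Mtot,
       C_M2 = C_M * areas$A_M2 / areas$A_Mtot,
       C_M3 = C_M * areas$A_M3 / areas$A_Mtot,
       C_BS = C_BS, C_M = C_M)
}

#' Per-section light absorption by a serial Beer-Lambert cascade
#'
#' Illumination is adaxial-only and single-pass. The M1 column intercepts
#' fraction `m` of the incident light and absorbs with Beer-Lambert
#' absorptance `A(C) = 1 - exp(-k C)`, where `C` is the section's
#' chlorophyll per unit leaf area. The vein column intercepts the remaining
#' `1 - m` and is traversed in the order M2, BS, M3, each section absorbing
#' from what the sections above transmitted.
#'
#' @param leaf A [leaf_structure()].
#' @param chl Optional precomputed [partition_chlorophyll()] result.
#' @return An object of class `optics_result`: per-section absorbed fractions
#'   `a_M1`, `a_M2`, `a_M3`, `a_BS`, the mesophyll sum `a_M`, whole-leaf
#'   `absorptance`, `transmitted`, the BS:M absorptance ratio `ratio_BS_M`,
#'   and `degenerate` (TRUE when `k * CHL = 0`, in which case all
#'   absorptances are zero and the ratio is NaN).
#' @export
#' @examples
#' absorption_cascade(load_preset("case_III")$leaf)$ratio_BS_M  # ~0.92
absorption_cascade <- function(leaf, chl = partition_chlorophyll(leaf)) {
  k <- leaf$k
  A <- function(C) 1 - exp(-k * C)
  m <- leaf$m
  a_M1 <- m * A(chl$C_M1)
  t2 <- 1 - A(chl$C_M2)           # transmitted below M2 within the vein column
  a_M2 <- (1 - m) * A(chl$C_M2)
  a_BS <- (1 - m) * t2 * A(chl$C_BS)
  a_M3 <- (1 - m) * t2 * (1 - A(chl$C_BS)) * A(chl$C_M3)
  a_M <- a_M1 + a_M2 + a_M3
  degenerate <- (k * leaf$CHL) == 0
  structure(list(
    a_M1 = a_M1, a_M2 = a_M2, a_M3 = a_M3, a_BS = a_BS, a_M = a_M,
    absorptance = a_M + a_BS,
    transmitted = m * (1 - A(chl$C_M1)) +
      (1 - m) * t2 * (1 - A(chl$C_BS)) * (1 - A(chl$C_M3)),
    ratio_BS_M = if (degenerate) NaN else a_BS / a_M,
    degenerate = degenerate
  ), class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat("<optics_result>\n")
  cat(sprintf("  a_M = %.5f  a_BS = %.5f  absorptance = %.5f\n",
              x$a_M, x$a_BS, x$absorptance))
  cat(sprintf("  a_BS : a_M = %.4f%s\n", x$ratio_BS_M,
              if (x$degenerate) "  (degenerate: k*CHL = 0)" else ""))
  invisible(x)
}

#' Flatten an optics result to a one-row data frame
#'
#' @param optics An `optics_result`.
#' @return One-row `data.frame` keyed by the symbol names.
#' @export
optics_record <- function(optics) {
  as.data.frame(optics[c("a_M1", "a_M2", "a_M3", "a_BS", "a_M",
                         "absorptance", "transmitted", "ratio_BS_M")])
}
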