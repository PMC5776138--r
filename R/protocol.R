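#' Scale the EdU staining-solution recipe
#'
#' The reference recipe makes 3 mL of click-chemistry staining solution:
#' 2,241 uL 1X-PBS (pH 7.4), 600 uL 0.5 M L-ascorbic acid, 150 uL 2 M Tris
#' (pH 8.5), 6 uL 100 mM Alexa Fluor azide in DMSO and 3 uL 1 M copper
#' sulfate. All components scale proportionally; scaled volumes are
#' reported to 0.1 uL (pipettable precision), so component sums match the
#' total to within 0.5 uL.
#'
#' @param total_volume_ml Desired total volume in millilitres (> 0).
#' @return An object of class `edu_recipe`: data frame of `component` and
#'   `volume_ul`, with attribute `total_ul`.
#' @examples
#' scale_recipe(3)   # the reference table
#' scale_recipe(6)   # doubled
#' @export
scale_recipe <- function(total_volume_ml = 3) {
  if (!is.numeric(total_volume_ml) || length(total_volume_ml) != 1L ||
      !is.finite(total_volume_ml) || total_volume_ml <= 0) {
    stop("'total_volume_ml' must be a single positive number")
  }
  ref <- edu_recipe_reference()
  f <- total_volume_ml / 3
  out <- data.frame(component = ref$component,
                    volume_ul = round(ref$volume_ul * f, 1))
  structure(out, class = c("edu_recipe", "data.frame"),
            total_ul = total_volume_ml * 1000)
}

#' Reference 3 mL EdU staining-solution composition
#'
#' @return Data frame of the five components and their volumes in uL
#'   (summing to 3,000).
#' @export
edu_recipe_reference <- function() {
  data.frame(
    component = c("1X-PBS (pH 7.4)",
                  "0.5 M L-Ascorbic acid",
                  "2 M Tris buffer (pH 8.5)",
                  "100 mM Alexa Fluor azide (in DMSO)",
                  "1 M Copper sulfate (CuSO4)"),
    volume_ul = c(2241, 600, 150, 6, 3))
}

#' @export
print.edu_recipe <- function(x, ...) {
  cat(sprintf("EdU staining solution, %.4g mL total:\n",
              attr(x, "total_ul") / 1000))
  df <- data.frame(component = x$component,
                   volume_ul = sprintf("%.1f", x$volume_ul))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Molarity of a stock solution
#'
#' Concentration in mM of `mass_mg` of solute dissolved in `volume_ml`:
#' `mass_mg / (molar_mass_g_per_mol * volume_ml) * 1000`. For EdU
#' (molar mass 252.23 g/mol), 50 mg in 20 mL gives 9.91 mM, the working
#' "10 mM" stock.
#'
#' @param mass_mg Solute mass in milligrams.
#' @param volume_ml Solvent volume in millilitres.
#' @param molar_mass_g_per_mol Solute molar mass (default EdU, 252.23).
#' @return Concentration in mM.
#' @examples
#' stock_molarity(50, 20)  # 9.91 mM
#' @export
stock_molarity <- function(mass_mg, volume_ml, molar_mass_g_per_mol = 252.23) {
  if (any(c(mass_mg, volume_ml, molar_mass_g_per_mol) <= 0)) {
    stop("all inputs must be positive")
  }
  mass_mg / (molar_mass_g_per_mol * volume_ml) * 1000
}
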