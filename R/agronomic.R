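#' Convert available nitrogen from kg/ha to g/m^2
#'
#' @param kg_ha Available N in kg/ha (e.g., 180 for the high-N treatment,
#'   75 for low N).
#' @return Available N in g/m^2 (division by 10), keeping N use efficiency
#'   in kg dry matter per g N.
#' @export
n_input_g_m2 <- function(kg_ha) kg_ha / 10

#' Standardised agronomic and nitrogen-efficiency traits per plot
#'
#' Computes dry-matter yield and the N-efficiency traits from fresh tuber
#' yield, tuber dry-matter percentage, tuber N concentration, available N
#' and the area under the canopy cover curve:
#' `Y_DM = Y * DM% / 100` (kg/m^2), `NUpt = Y_DM * [N]` (g/m^2),
#' `NUE = Y_DM / N_input` (kg/g), `NUtE = Y_DM / NUpt` (kg/g),
#' `NUptE = NUpt / N_input` (g/g) and `SCYi = AUC / Y_DM` (%.td/(kg/m^2)).
#' Ratio traits with a zero denominator are returned as `NA`, never
#' infinite.
#'
#' @param fresh_yield Fresh tuber yield Y (kg/m^2), vectorised.
#' @param dm_pct Tuber dry-matter percentage in (0, 100).
#' @param n_conc Tuber N concentration (g/kg).
#' @param n_input Available N (g/m^2); see [n_input_g_m2()].
#' @param auc Area under the canopy cover curve (%.td).
#' @return Data frame with columns `Y_DM`, `NUpt`, `NUE`, `NUtE`, `NUptE`,
#'   `SCYi`.
#' @export
compute_agronomic <- function(fresh_yield, dm_pct, n_conc, n_input, auc) {
  stopifnot(all(fresh_yield >= 0, na.rm = TRUE),
            all(dm_pct > 0 & dm_pct < 100, na.rm = TRUE),
            all(n_conc >= 0, na.rm = TRUE),
            all(n_input > 0, na.rm = TRUE))
  y_dm <- fresh_yield * dm_pct / 100
  nupt <- y_dm * n_conc
  safe_div <- function(num, den) ifelse(is.na(den) | den == 0, NA_real_,
                                        num / den)
  data.frame(Y_DM = y_dm,
             NUpt = nupt,
             NUE = safe_div(y_dm, n_input),
             NUtE = safe_div(y_dm, nupt),
             NUptE = safe_div(nupt, n_input),
             SCYi = safe_div(auc, y_dm))
}
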