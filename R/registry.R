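# Reference summary statistics (median, mean, SD per cohort group) for the
# 28 immunologic parameters of the study population, plus recording
# conventions.  `decimals` is the recorded measurement precision on the raw
# scale: migrated/adhered neutrophils are counts, flow-cytometry lymphocyte
# percentages resolve to 0.1%, cytokine concentrations to 0.1 pg/ml, ELISA
# units and ratios to 0.01.  `carrier` marks the 11 parameters that the
# collinear preset treats as independent variance carriers; the remaining
# 17 are generated as linear blends of their latent factors.

reference_parameters <- local({
  txt <- "
name|display|unit|decimals|carrier|lop_median|lop_mean|lop_sd|eop_median|eop_mean|eop_sd|val_median|val_mean|val_sd
chemotaxis|Neutrophil chemotaxis|cells|0|FALSE|52.60|56.64|28.74|42.15|44.71|17.84|42.00|40.17|15.65
phagocytosis|Neutrophil phagocytosis|bacteria/100 cells|2|TRUE|4.27|4.83|3.25|2.84|6.89|17.95|4.33|4.91|2.32
adhesion|Leukocyte adhesion|cells|0|FALSE|71.19|71.76|7.77|60.41|60.22|19.24|70.20|69.20|8.33
CD3_pct|CD3 lymphocytes|%|1|TRUE|74.00|61.03|9.70|65.70|65.09|12.05|65.20|62.31|13.35
CD4_pct|CD4 lymphocytes|%|1|FALSE|39.00|41.63|7.51|36.60|37.28|10.98|39.40|38.16|9.26
CD8_pct|CD8 lymphocytes|%|1|FALSE|28.60|29.07|6.62|25.80|25.02|6.09|21.60|24.06|6.49
CD20_pct|CD20 lymphocytes|%|1|FALSE|12.30|16.38|9.33|9.95|13.13|4.41|10.90|11.08|7.82
CD4_CD8_ratio|CD4/CD8 ratio|ratio|2|FALSE|2.40|2.38|0.86|1.42|1.62|0.76|1.60|1.70|0.62
IL1|Monocytic IL-1 production|pg/ml|1|FALSE|3.50|5.32|3.83|99.00|436.72|897.76|114.50|422.38|813.33
IL2|Monocytic IL-2 production|pg/ml|1|TRUE|80.00|118.40|104.59|3.40|3.56|1.94|3.80|8.42|19.21
IL4|Monocytic IL-4 production|pg/ml|1|TRUE|3.90|4.30|3.88|7.80|9.01|6.70|7.70|7.93|2.25
IL6|Monocytic IL-6 production|pg/ml|1|TRUE|473.00|503.20|616.80|100.00|1957.74|4944.28|242.00|2089.50|4083.09
TNFa|Monocytic TNF-alpha production|pg/ml|1|TRUE|16.65|42.93|54.48|274.70|358.20|383.60|437.50|712.83|628.82
IFNg|Monocytic IFN-gamma production|pg/ml|1|FALSE|9.70|11.41|6.01|32.30|109.27|232.45|12.35|11.87|5.52
antiCD3_blastogenesis|T-cell blastogenesis (anti-CD3)|dpm x 1e-4|1|TRUE|13.90|15.96|3.14|8.90|12.96|11.63|13.50|13.54|5.79
PWM_blastogenesis|T-cell blastogenesis (PWM)|dpm x 1e-4|1|TRUE|6.50|7.48|4.59|5.60|8.39|7.65|8.60|9.77|6.36
IgG_Aa_Y4|IgG titer A.a. (Y4)|ELISA units|2|FALSE|0.57|0.67|2.51|0.33|0.43|1.12|-0.60|1.05|3.43
IgG_Aa_ATCC29523|IgG titer A.a. (ATCC29523)|ELISA units|2|FALSE|0.40|0.84|1.08|0.21|1.36|2.88|0.07|4.84|23.84
IgG_Aa_SUNY67|IgG titer A.a. (SUNY67)|ELISA units|2|FALSE|0.68|0.51|0.49|0.54|1.42|2.59|-0.18|0.21|0.84
IgG_Co_S3|IgG titer C.o. (S3)|ELISA units|2|FALSE|0.24|0.01|0.40|-0.09|0.11|0.45|1.00|0.76|5.96
IgG_Ec_ATCC23834|IgG titer E.c. (ATCC23834)|ELISA units|2|FALSE|0.08|0.22|0.48|0.45|1.04|1.95|-0.11|0.11|0.41
IgG_Fn_ATCC25586|IgG titer F.n. (ATCC25586)|ELISA units|2|FALSE|-0.06|0.68|4.74|0.33|3.70|9.71|-0.04|1.06|4.07
IgG_Pi_ATCC25611|IgG titer P.i. (ATCC25611)|ELISA units|2|FALSE|-0.17|-0.27|0.18|-0.15|0.41|1.61|-0.13|-0.01|0.46
IgG_Pn_ATCC33563|IgG titer P.n. (ATCC33563)|ELISA units|2|FALSE|0.60|0.26|1.16|0.15|0.53|1.56|0.45|0.30|0.95
IgG_Pg_FDC381|IgG titer P.g. (FDC381)|ELISA units|2|TRUE|1.59|4.19|4.90|2.98|7.84|218.07|1.54|6.31|12.73
IgG_Pg_SU63|IgG titer P.g. (SU63)|ELISA units|2|TRUE|0.52|2.23|4.35|1.41|6.41|19.58|1.01|2.18|4.65
IgG_Td_ATCC35405|IgG titer T.d. (ATCC35405)|ELISA units|2|FALSE|-0.05|0.12|0.39|0.23|0.93|1.85|1.27|0.63|1.60
IgG_Ws_ATCC29543|IgG titer W.s. (ATCC29543)|ELISA units|2|TRUE|0.37|0.88|0.99|0.33|14.72|56.08|0.35|5.60|14.31
"
  df <- utils::read.table(text = txt, sep = "|", header = TRUE,
                          stringsAsFactors = FALSE)
  df
})

#' Canonical parameter registry
#'
#' Returns the packaged registry of the 28 immunologic parameters: canonical
#' name, display name, measurement unit, recorded precision (decimal places
#' on the raw scale) and the per-group reference median, mean and standard
#' deviation used by the synthetic-cohort generator.
#'
#' @return A data frame with one row per parameter.
#' @export
parameter_registry <- function() reference_parameters

#' Map display names to canonical parameter names
#'
#' Cohort files may label columns with either canonical or display names;
#' this returns the named vector \code{c(display = canonical)} accepted by
#' the \code{rename} argument of \code{\link{read_cohort}}.
#'
#' @return Named character vector.
#' @export
display_name_map <- function() {
  stats::setNames(reference_parameters$name, reference_parameters$display)
}
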