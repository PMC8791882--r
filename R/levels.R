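# Canonical factor levels and schema constants shared across the package.

pt_levels <- list(
  gender          = c("female", "male"),
  smoking         = c("never", "former", "active"),
  diabetes        = c("no", "yes"),
  jaw             = c("maxilla", "mandible"),
  tooth_type      = c("anterior", "premolar", "molar"),
  furcation_class = c("single_rooted", "multi_no_FI", "multi_FI"),
  bone_loss_raw   = c("<=20", "21-40", "41-60", "61-80", ">80"),
  bone_loss_cat   = c("<=20", "21-40", "41-60", ">60"),
  infrabony       = c("shallow", "moderate", "deep"),
  abutment        = c("none", "fixed", "removable")
)

# ordinal variables get ordered factors so the split search respects order
pt_ordered <- c("furcation_class", "bone_loss_raw", "bone_loss_cat", "infrabony")

pt_patient_vars <- c("age", "gender", "smoking", "diabetes", "pcr")
pt_tooth_vars   <- c("jaw", "tooth_type", "furcation_class", "bone_loss_cat",
                     "infrabony", "abutment")

pt_csv_header <- c("patient_id", "tooth_id", "age", "gender", "smoking",
                   "diabetes", "pcr", "jaw", "tooth_type", "furcation_class",
                   "bone_loss_raw", "infrabony", "abutment", "lost_by_T2")

# FDI two-digit codes, third molars (x8) excluded
pt_fdi_codes <- as.character(outer(1:7, c(10, 20, 30, 40), "+"))

#' Variable level (patient vs tooth) for model covariates
#'
#' The bootstrap selection thresholds are asymmetric: tooth-level variables
#' need > 50% inclusion, patient-level variables > 25%, because patient-level
#' resampling limits the variability of patient characteristics.
#'
#' @param vars character vector of covariate names.
#' @return character vector, `"patient"` or `"tooth"` per variable.
#' @export
variable_level <- function(vars) {
  out <- ifelse(vars %in% pt_patient_vars, "patient",
                ifelse(vars %in% c(pt_tooth_vars, "bone_loss_raw"), "tooth", NA))
  if (anyNA(out)) {
    stop("unknown covariate(s): ", paste(vars[is.na(out)], collapse = ", "))
  }
  stats::setNames(out, vars)
}

#' Collapse raw bone-loss categories to the modelled scale
#'
#' The two most severe radiographic bone-loss increments (61-80% and >80%)
#' carry low counts and are merged into a single ">60" category for
#' modelling.
#'
#' @param bone_loss_raw factor or character with levels
#'   `<=20, 21-40, 41-60, 61-80, >80`.
#' @return ordered factor with levels `<=20, 21-40, 41-60, >60`.
#' @export
collapse_bone_loss <- function(bone_loss_raw) {
  raw <- as.character(bone_loss_raw)
  bad <- !is.na(raw) & !raw %in% pt_levels$bone_loss_raw
  if (any(bad)) {
    stop("invalid bone_loss_raw value(s): ",
         paste(unique(raw[bad]), collapse = ", "))
  }
  cat <- ifelse(raw %in% c("61-80", ">80"), ">60", raw)
  factor(cat, levels = pt_levels$bone_loss_cat, ordered = TRUE)
}

pt_make_factor <- function(x, var, ordered = var %in% pt_ordered) {
  factor(as.character(x), levels = pt_levels[[var]], ordered = ordered)
}
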