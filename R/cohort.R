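# Cohort container: one row per tooth nested in patients, with validation
# mirroring how the study data were coded (FDI numbering, third molars
# excluded, bone-loss categories pre-merged).

#' Construct a validated tooth-level cohort
#'
#' A cohort couples a patient table (one row per patient: age, gender,
#' smoking, diabetes, plaque control record) with a tooth table (one row per
#' tooth: jaw, tooth type, furcation class, interproximal bone loss,
#' infrabony defect depth, abutment status, and the binary 10-year loss
#' outcome). Structural invariants are enforced at construction: every tooth
#' resolves to exactly one patient, no patient carries more than 28 teeth or
#' a duplicated tooth code, third molars (FDI codes x8) are not admitted,
#' anterior teeth are single rooted, molars are multi rooted, and the merged
#' bone-loss category is consistent with the raw five-level coding.
#'
#' @param patients data.frame with columns `patient_id`, `age`, `gender`,
#'   `smoking`, `diabetes`, `pcr` (`pcr` may be `NA`).
#' @param teeth data.frame with columns `patient_id`, `tooth_id`, `jaw`,
#'   `tooth_type`, `furcation_class`, `bone_loss_raw`, `infrabony`,
#'   `abutment`, `lost_by_T2`. `bone_loss_cat` is derived.
#' @param provenance optional list of free-form metadata (source file,
#'   filters applied); carried along unmodified.
#' @return object of class `perio_cohort`: a list with elements `patients`,
#'   `teeth` and `provenance`.
#' @seealso [read_cohort_csv()], [generate_cohort()]
#' @export
perio_cohort <- function(patients, teeth, provenance = list()) {
  patients <- as.data.frame(patients)
  teeth <- as.data.frame(teeth)

  need_p <- c("patient_id", "age", "gender", "smoking", "diabetes", "pcr")
  need_t <- c("patient_id", "tooth_id", "jaw", "tooth_type", "furcation_class",
              "bone_loss_raw", "infrabony", "abutment", "lost_by_T2")
  miss <- setdiff(need_p, names(patients))
  if (length(miss)) stop("patients: missing column(s) ", paste(miss, collapse = ", "))
  miss <- setdiff(need_t, names(teeth))
  if (length(miss)) stop("teeth: missing column(s) ", paste(miss, collapse = ", "))

  patients$patient_id <- as.character(patients$patient_id)
  teeth$patient_id <- as.character(teeth$patient_id)
  teeth$tooth_id <- as.character(teeth$tooth_id)

  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patient table")
  }
  if (!all(teeth$patient_id %in% patients$patient_id)) {
    orphan <- setdiff(teeth$patient_id, patients$patient_id)
    stop("teeth reference unknown patient_id: ", paste(utils::head(orphan, 5), collapse = ", "))
  }

  patients$age <- as.numeric(patients$age)
  patients$pcr <- as.numeric(patients$pcr)
  if (any(is.na(patients$age) | patients$age <= 0)) {
    stop("age must be present and > 0 for every patient")
  }
  if (any(!is.na(patients$pcr) & (patients$pcr < 0 | patients$pcr > 100))) {
    stop("pcr must lie in [0, 100] when present")
  }
  for (v in c("gender", "smoking", "diabetes")) {
    patients[[v]] <- pt_validate_levels(patients[[v]], v, where = "patients")
  }
  for (v in c("jaw", "tooth_type", "furcation_class", "bone_loss_raw",
              "infrabony", "abutment")) {
    teeth[[v]] <- pt_validate_levels(teeth[[v]], v, where = "teeth")
  }
  teeth$lost_by_T2 <- as.integer(teeth$lost_by_T2)
  if (any(is.na(teeth$lost_by_T2) | !teeth$lost_by_T2 %in% 0:1)) {
    stop("lost_by_T2 must be 0 or 1 for every tooth")
  }
  teeth$bone_loss_cat <- collapse_bone_loss(teeth$bone_loss_raw)

  diag <- pt_row_diagnostics(teeth)
  if (length(diag)) {
    stop("invalid tooth rows:\n  ", paste(diag, collapse = "\n  "))
  }

  cnt <- table(teeth$patient_id)
  if (any(cnt > 28)) {
    stop("more than 28 teeth for patient(s): ",
         paste(names(cnt)[cnt > 28], collapse = ", "))
  }

  col_order <- c("patient_id", "tooth_id", "jaw", "tooth_type",
                 "furcation_class", "bone_loss_raw", "bone_loss_cat",
                 "infrabony", "abutment", "lost_by_T2")
  teeth <- teeth[, col_order]
  patients <- patients[, need_p]
  rownames(patients) <- rownames(teeth) <- NULL
  structure(list(patients = patients, teeth = teeth, provenance = provenance),
            class = "perio_cohort")
}

# case-insensitive header matching onto the canonical schema names
pt_canonical_names <- function(nms) {
  hit <- match(tolower(nms), tolower(pt_csv_header))
  ifelse(is.na(hit), tolower(nms), pt_csv_header[hit])
}

pt_validate_levels <- function(x, var, where) {
  chr <- as.character(x)
  bad <- which(!is.na(chr) & !chr %in% pt_levels[[var]])
  if (length(bad)) {
    stop(sprintf("%s: unknown level for '%s' in row(s) %s: %s",
                 where, var, paste(utils::head(bad, 5), collapse = ","),
                 paste(unique(chr[bad]), collapse = ", ")))
  }
  pt_make_factor(chr, var)
}

# per-row structural violations (reported with row indices)
pt_row_diagnostics <- function(teeth) {
  msgs <- character()
  third <- which(grepl("8$", teeth$tooth_id) | !teeth$tooth_id %in% pt_fdi_codes)
  for (i in third) {
    msgs <- c(msgs, sprintf("row %d: tooth_id '%s' is not a valid non-third-molar FDI code",
                            i, teeth$tooth_id[i]))
  }
  dup <- which(duplicated(teeth[, c("patient_id", "tooth_id")]))
  for (i in dup) {
    msgs <- c(msgs, sprintf("row %d: duplicate tooth %s for patient %s",
                            i, teeth$tooth_id[i], teeth$patient_id[i]))
  }
  ant <- which(!is.na(teeth$tooth_type) & !is.na(teeth$furcation_class) &
                 teeth$tooth_type == "anterior" &
                 teeth$furcation_class != "single_rooted")
  for (i in ant) {
    msgs <- c(msgs, sprintf("row %d: anterior tooth coded multi-rooted", i))
  }
  mol <- which(!is.na(teeth$tooth_type) & !is.na(teeth$furcation_class) &
                 teeth$tooth_type == "molar" &
                 teeth$furcation_class == "single_rooted")
  for (i in mol) {
    msgs <- c(msgs, sprintf("row %d: molar coded single-rooted", i))
  }
  msgs
}

#' @export
print.perio_cohort <- function(x, ...) {
  cat(sprintf("<perio_cohort> %d patients, %d teeth (%d lost, %.1f%%)\n",
              nrow(x$patients), nrow(x$teeth), sum(x$teeth$lost_by_T2),
              100 * mean(x$teeth$lost_by_T2)))
  if (length(x$provenance)) {
    cat("provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a cohort to one modelling row per tooth
#'
#' Joins the patient covariates onto the tooth table, giving the tooth-level
#' modelling frame used by the tree, bootstrap and cross-validation stages.
#'
#' @param cohort a [perio_cohort()].
#' @return data.frame with one row per tooth carrying tooth and patient
#'   covariates plus `lost_by_T2`.
#' @export
cohort_data <- function(cohort) {
  stopifnot(inherits(cohort, "perio_cohort"))
  idx <- match(cohort$teeth$patient_id, cohort$patients$patient_id)
  cbind(cohort$teeth,
        cohort$patients[idx, c("age", "gender", "smoking", "diabetes", "pcr"),
                        drop = FALSE],
        row.names = NULL)
}

#' Read a tooth-level cohort from CSV
#'
#' Expects one row per tooth with patient columns repeated (header:
#' `patient_id, tooth_id, age, gender, smoking, diabetes, pcr, jaw,
#' tooth_type, furcation_class, bone_loss_raw, infrabony, abutment,
#' lost_by_T2`; header matching is case-insensitive). An optional separate
#' patient-only CSV can be joined on `patient_id`. Missing values are empty
#' fields or the string `NA`. Rows that violate structural invariants
#' (third-molar codes, duplicated teeth, anterior/molar root-count
#' contradictions) are rejected with row-indexed diagnostics: an error by
#' default, or dropped with a warning when `drop_invalid = TRUE`.
#'
#' @param path path to the tooth-level CSV.
#' @param patients_path optional path to a patient-level CSV
#'   (`patient_id, age, gender, smoking, diabetes, pcr`).
#' @param drop_invalid drop invariant-violating tooth rows (with a warning
#'   listing them) instead of erroring.
#' @return a [perio_cohort()] with provenance recording the source files and
#'   any dropped rows.
#' @export
read_cohort_csv <- function(path, patients_path = NULL, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = c("", "NA"),
                         check.names = FALSE, strip.white = TRUE)
  names(raw) <- pt_canonical_names(names(raw))

  if (is.null(patients_path)) {
    need <- pt_csv_header
  } else {
    need <- setdiff(pt_csv_header, c("age", "gender", "smoking", "diabetes", "pcr"))
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("schema error: missing required column(s): ", paste(miss, collapse = ", "))
  }

  if (!is.null(patients_path)) {
    if (!file.exists(patients_path)) stop("file not found: ", patients_path)
    pat <- utils::read.csv(patients_path, colClasses = "character",
                           na.strings = c("", "NA"), check.names = FALSE,
                           strip.white = TRUE)
    names(pat) <- pt_canonical_names(names(pat))
    pmiss <- setdiff(c("patient_id", "age", "gender", "smoking", "diabetes", "pcr"),
                     names(pat))
    if (length(pmiss)) {
      stop("schema error: patient file missing column(s): ",
           paste(pmiss, collapse = ", "))
    }
    patients <- pat[!duplicated(pat$patient_id), ]
  } else {
    patients <- raw[!duplicated(raw$patient_id),
                    c("patient_id", "age", "gender", "smoking", "diabetes", "pcr")]
  }

  teeth <- raw[, c("patient_id", "tooth_id", "jaw", "tooth_type",
                   "furcation_class", "bone_loss_raw", "infrabony", "abutment",
                   "lost_by_T2")]

  dropped <- data.frame(row = integer(), reason = character())
  if (drop_invalid) {
    # validate levels first (errors are not row-droppable), then drop
    # rows failing structural checks
    tmp <- teeth
    for (v in c("jaw", "tooth_type", "furcation_class", "bone_loss_raw",
                "infrabony", "abutment")) {
      tmp[[v]] <- pt_validate_levels(tmp[[v]], v, where = "teeth")
    }
    diag <- pt_row_diagnostics(tmp)
    if (length(diag)) {
      rows <- as.integer(sub("^row (\\d+):.*$", "\\1", diag))
      dropped <- data.frame(row = rows, reason = sub("^row \\d+: ", "", diag))
      warning("dropping ", length(unique(rows)), " invalid tooth row(s):\n  ",
              paste(diag, collapse = "\n  "))
      teeth <- teeth[-unique(rows), , drop = FALSE]
    }
  }

  perio_cohort(patients, teeth,
               provenance = list(source = path,
                                 patients_source = patients_path,
                                 dropped_rows = dropped))
}

#' Write a cohort to the standard tooth-level CSV
#'
#' Inverse of [read_cohort_csv()]: one row per tooth, patient columns
#' repeated, missing values as empty fields. Reading the file back yields a
#' cohort equal to the input (up to provenance).
#'
#' @param cohort a [perio_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "perio_cohort"))
  dat <- cohort_data(cohort)
  out <- dat[, pt_csv_header]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Restrict a cohort to complete cases
#'
#' Removes teeth with missing values in the required tooth-level covariates
#' and all teeth of patients missing a required patient-level covariate,
#' then drops patients left without teeth. By default the plaque control
#' record is not required, so patients with a missing PCR are retained (the
#' modelled tree never used PCR, and requiring it would shrink the cohort).
#'
#' @param cohort a [perio_cohort()].
#' @param required_vars covariate names that must be observed; any of
#'   `age, gender, smoking, diabetes, pcr, jaw, tooth_type, furcation_class,
#'   bone_loss_cat, bone_loss_raw, infrabony, abutment`.
#' @return list with `cohort` (the filtered [perio_cohort()]) and `report`
#'   (data.frame: variable, level, n_teeth_removed, n_patients_removed).
#' @export
complete_case_filter <- function(cohort,
                                 required_vars = c(setdiff(pt_patient_vars, "pcr"),
                                                   pt_tooth_vars)) {
  stopifnot(inherits(cohort, "perio_cohort"))
  known <- c(pt_patient_vars, pt_tooth_vars, "bone_loss_raw")
  bad <- setdiff(required_vars, known)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))

  lvl <- variable_level(required_vars)
  teeth <- cohort$teeth
  patients <- cohort$patients

  report <- data.frame(variable = required_vars, level = unname(lvl),
                       n_teeth_removed = 0L, n_patients_removed = 0L)

  drop_tooth <- rep(FALSE, nrow(teeth))
  for (i in seq_along(required_vars)) {
    v <- required_vars[i]
    if (lvl[i] == "tooth") {
      miss <- is.na(teeth[[v]]) & !drop_tooth
      report$n_teeth_removed[i] <- sum(miss)
      drop_tooth <- drop_tooth | is.na(teeth[[v]])
    } else {
      miss_pat <- patients$patient_id[is.na(patients[[v]])]
      newly <- teeth$patient_id %in% miss_pat & !drop_tooth
      report$n_teeth_removed[i] <- sum(newly)
      report$n_patients_removed[i] <- length(miss_pat)
      drop_tooth <- drop_tooth | teeth$patient_id %in% miss_pat
    }
  }
  teeth <- teeth[!drop_tooth, , drop = FALSE]
  patients <- patients[patients$patient_id %in% teeth$patient_id, , drop = FALSE]
  if (nrow(teeth) == 0) {
    stop("complete-case filtering removed every tooth; check required_vars")
  }
  prov <- c(cohort$provenance,
            list(complete_case = list(required_vars = required_vars,
                                      removed_teeth = sum(drop_tooth))))
  out <- perio_cohort(patients, teeth[, setdiff(names(teeth), "bone_loss_cat")],
                      provenance = prov)
  list(cohort = out, report = report)
}

#' Descriptive patient- and tooth-level summary tables
#'
#' Reproduces the style of the study's descriptive tables: patient-level
#' counts and percentages per categorical level plus mean/SD for age and
#' PCR; tooth-level counts cross-tabulated against the 10-year outcome with
#' retention and loss percentages per level. Optionally a naive Pearson
#' chi-squared p-value per tooth-level variable is attached; it ignores the
#' clustering of teeth within patients and is flagged as such.
#'
#' @param cohort a [perio_cohort()].
#' @param chisq attach a naive (cluster-ignoring) Pearson chi-squared test
#'   per tooth-level variable.
#' @return list with data.frames `patients` (variable, level, n, percent,
#'   mean, sd) and `teeth` (variable, level, n, n_retained, pct_retained,
#'   n_lost, pct_lost, and `p_naive_chisq` when requested).
#' @export
descriptive_tables <- function(cohort, chisq = TRUE) {
  stopifnot(inherits(cohort, "perio_cohort"))
  if (nrow(cohort$teeth) == 0) stop("empty cohort")
  pat <- cohort$patients
  teeth <- cohort$teeth

  prow <- function(variable, level, n = NA, percent = NA, mean = NA, sd = NA) {
    data.frame(variable = variable, level = level, n = n, percent = percent,
               mean = mean, sd = sd)
  }
  ptab <- list(prow("n_patients", "", n = nrow(pat)))
  for (v in c("gender", "diabetes", "smoking")) {
    tab <- table(pat[[v]])
    ptab[[length(ptab) + 1L]] <-
      prow(v, names(tab), n = as.integer(tab),
           percent = round(100 * as.integer(tab) / sum(tab), 1))
  }
  for (v in c("age", "pcr")) {
    x <- pat[[v]]
    ptab[[length(ptab) + 1L]] <-
      prow(v, "", n = sum(!is.na(x)),
           mean = round(mean(x, na.rm = TRUE), 1),
           sd = round(stats::sd(x, na.rm = TRUE), 2))
  }
  ptab <- do.call(rbind, ptab)

  ttab <- list()
  for (v in c("jaw", "tooth_type", "furcation_class", "abutment",
              "bone_loss_raw", "infrabony")) {
    x <- droplevels(teeth[[v]])
    keep <- !is.na(x)
    tab <- table(x[keep], factor(teeth$lost_by_T2[keep], levels = 0:1))
    n <- rowSums(tab)
    row <- data.frame(variable = v, level = rownames(tab), n = as.integer(n),
                      n_retained = as.integer(tab[, "0"]),
                      pct_retained = round(100 * tab[, "0"] / pmax(n, 1), 2),
                      n_lost = as.integer(tab[, "1"]),
                      pct_lost = round(100 * tab[, "1"] / pmax(n, 1), 2),
                      n_missing = sum(!keep))
    if (chisq) {
      p <- if (nrow(tab) > 1 && all(rowSums(tab) > 0) && length(unique(teeth$lost_by_T2[keep])) > 1) {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      } else NA_real_
      row$p_naive_chisq <- p
    }
    ttab[[v]] <- row
  }
  ttab <- do.call(rbind, c(ttab, list(make.row.names = FALSE)))
  attr(ttab, "note") <-
    "chi-squared p-values ignore the clustered structure (teeth within patients)"
  list(patients = ptab, teeth = ttab)
}

#' Tooth-loss rate per patient per year
#'
#' Total teeth lost divided by (years of observation x number of patients).
#'
#' @param cohort a [perio_cohort()] with at least one patient.
#' @param years length of the observation window in years (default 10).
#' @return loss rate in teeth per patient per year.
#' @export
annual_loss_rate <- function(cohort, years = 10) {
  stopifnot(inherits(cohort, "perio_cohort"))
  if (!is.numeric(years) || years <= 0) stop("years must be > 0")
  n_pat <- nrow(cohort$patients)
  if (n_pat == 0) stop("cohort has no patients")
  sum(cohort$teeth$lost_by_T2) / (years * n_pat)
}
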