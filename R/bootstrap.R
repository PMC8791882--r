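# Patient-clustered bootstrap variable selection: resample patients with
# replacement (same number of patients, each copy a distinct cluster with
# all its teeth), fit one model-tree per replicate, count per-model variable
# occurrence, and apply the asymmetric inclusion thresholds (> 50% for
# tooth-level, > 25% for patient-level variables).

#' Draw a patient-level bootstrap sample of a cohort
#'
#' Patients are drawn with replacement so that the sample holds exactly the
#' original number of patients; every drawn copy receives a distinct cluster
#' identifier and carries all the patient's teeth. Duplicated patients are
#' therefore independent clusters in downstream mixed-model fits.
#'
#' @param cohort a [perio_cohort()].
#' @param seed integer seed for the draw.
#' @return a [perio_cohort()] with `n_patients` patient copies.
#' @export
bootstrap_sample <- function(cohort, seed) {
  stopifnot(inherits(cohort, "perio_cohort"))
  n <- nrow(cohort$patients)
  if (n < 1) stop("cohort has no patients")
  set.seed(seed)
  draw <- sample(cohort$patients$patient_id, n, replace = TRUE)
  new_id <- sprintf("%s.b%03d", draw, seq_len(n))
  pat <- cohort$patients[match(draw, cohort$patients$patient_id), ]
  pat$patient_id <- new_id
  teeth_split <- split(seq_len(nrow(cohort$teeth)), cohort$teeth$patient_id)
  idx <- unlist(teeth_split[draw], use.names = FALSE)
  reps <- vapply(teeth_split[draw], length, integer(1))
  teeth <- cohort$teeth[idx, ]
  teeth$patient_id <- rep(new_id, reps)
  teeth$bone_loss_cat <- NULL
  perio_cohort(pat, teeth,
               provenance = list(bootstrap_of = cohort$provenance$source,
                                 seed = seed))
}

#' Bootstrap variable selection
#'
#' Fits a model-tree on each of `n_boot` patient-level bootstrap samples and
#' records, per variable, the fraction of replicate models in which it
#' appears in at least one split (per-model occurrence, not split counts).
#' Tooth-level variables are selected when that fraction strictly exceeds
#' 0.5, patient-level variables when it strictly exceeds 0.25 — the lower
#' patient-level threshold compensates for patient-level resampling limiting
#' the variability of patient characteristics. Replicates whose fit fails
#' are recorded and excluded from the denominator; more than 10% failures is
#' an error.
#'
#' @param cohort a complete-case [perio_cohort()].
#' @param vars candidate variables (their level — patient or tooth — is
#'   derived with [variable_level()]).
#' @param n_boot number of bootstrap replicates (default 200).
#' @param fit_config a [fit_config()].
#' @param seed integer seed; replicate `r` uses `seed + r`.
#' @return object of class `selection_result`: `n_boot`, `n_failed`,
#'   `frequency` (named fractions), `selected`, `thresholds`,
#'   `replicate_vars` (per-replicate split-variable sets, for audit),
#'   `seed`.
#' @export
select_variables <- function(cohort, vars, n_boot = 200,
                             fit_config = periotree::fit_config(), seed = 1) {
  stopifnot(inherits(cohort, "perio_cohort"), n_boot >= 1)
  lvl <- variable_level(vars)
  rep_vars <- vector("list", n_boot)
  failed <- logical(n_boot)
  for (r in seq_len(n_boot)) {
    res <- tryCatch({
      boot <- bootstrap_sample(cohort, seed = seed + r)
      m <- fit_glmm_tree(boot, vars, fit_config)
      pt_tree_vars(m$root)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[r] <- TRUE
      rep_vars[[r]] <- NA
    } else {
      rep_vars[[r]] <- res
    }
  }
  n_fail <- sum(failed)
  if (n_fail > 0.1 * n_boot) {
    stop("bootstrap selection: ", n_fail, "/", n_boot, " replicate fits failed")
  }
  if (n_fail > 0) {
    warning(n_fail, " replicate fit(s) failed and were excluded from the denominator")
  }
  ok <- rep_vars[!failed]
  freq <- vapply(vars, function(v) {
    mean(vapply(ok, function(s) v %in% s, logical(1)))
  }, numeric(1))
  thr <- ifelse(lvl == "tooth", 0.5, 0.25)
  selected <- vars[freq > thr]            # strict: exactly at threshold is out
  structure(list(n_boot = n_boot, n_failed = n_fail,
                 frequency = freq,
                 selected = selected,
                 thresholds = stats::setNames(thr, vars),
                 levels = lvl,
                 replicate_vars = rep_vars,
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d replicates (%d failed)\n",
              x$n_boot, x$n_failed))
  df <- data.frame(variable = names(x$frequency), level = unname(x$levels),
                   frequency = round(unname(x$frequency), 3),
                   threshold = unname(x$thresholds),
                   selected = names(x$frequency) %in% x$selected)
  print(df[order(-df$frequency), ], row.names = FALSE)
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param selection a `selection_result`.
#' @param path optional output path; JSON string returned when `NULL`.
#' @return JSON string or `path` invisibly.
#' @export
selection_to_json <- function(selection, path = NULL) {
  doc <- list(n_boot = selection$n_boot, n_failed = selection$n_failed,
              frequency = as.list(selection$frequency),
              thresholds = as.list(selection$thresholds),
              selected = selection$selected,
              replicate_vars = selection$replicate_vars,
              seed = selection$seed)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Refit the tree on the full cohort with the selected variables
#'
#' @param cohort the full complete-case [perio_cohort()].
#' @param selection a `selection_result` with a nonempty selected set.
#' @param fit_config a [fit_config()].
#' @return a `glmm_tree` restricted to the selected partitioning variables.
#' @export
final_fit <- function(cohort, selection, fit_config = periotree::fit_config()) {
  stopifnot(inherits(selection, "selection_result"))
  if (length(selection$selected) == 0) {
    stop("no variable exceeded its selection threshold; ",
         "review thresholds or selection frequencies")
  }
  fit_glmm_tree(cohort, selection$selected, fit_config)
}
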