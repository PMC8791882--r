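# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: published patient- and tooth-level marginals, the
# structural constraints among tooth covariates, group-conditional 10-year
# loss rates driven by the published tree, and a patient random intercept
# on the logit scale.

#' Simulation configuration
#'
#' Defaults reproduce the study cohort: 110 patients, 10-28 teeth per
#' patient averaging about 23, patient marginals from the descriptive
#' patient table (61.8% female, 8.2% diabetic, smoking 45.5/24.5/30.0%
#' never/former/active, age 46.7 +/- 10.26 years, PCR 31.3 +/- 17.39% with
#' 7/110 missing) and tooth marginals from the descriptive tooth table.
#' Furcation class is sampled conditionally on tooth type (anterior teeth
#' are always single rooted, molars always multi rooted); the premolar
#' multi-rooted share and the furcation-involvement share among multi-rooted
#' teeth are derived from the published totals. The outcome mechanism is the
#' published eight-group tree: each tooth's loss probability is
#' `invlogit(eta_group + b_patient)` with `b_patient ~ N(0, sigma_b^2)` and
#' `eta_group` calibrated by [calibrate_offsets()] so the marginal rate of
#' each group matches its configured target (defaults: the published
#' lost/total ratios).
#'
#' `sigma_b` defaults to 0.5 — visible but moderate patient clustering; the
#' study reports no random-effect variance, so this is a free simulation
#' parameter. Covariates outside the published tree (gender, smoking, PCR,
#' jaw, tooth type, infrabony) are generated but carry no effect by
#' default; `effects` injects additional logit-scale effects for
#' selection-power experiments.
#'
#' @param n_patients number of patients (default 110).
#' @param seed integer seed used by [generate_cohort()].
#' @param teeth_per_patient list with `min`, `max`, `mean`; counts are drawn
#'   as `min + Binomial(max - min, (mean - min)/(max - min))`.
#' @param patient_marginals list: `gender`, `smoking`, `diabetes` level
#'   probabilities; `age_mean`, `age_sd`, `age_range`; `pcr_mean`, `pcr_sd`,
#'   `pcr_missing`.
#' @param tooth_marginals list: `jaw`, `tooth_type`, `bone_loss_raw`,
#'   `infrabony`, `abutment` level probabilities and `furcation` — a list of
#'   per-type probability vectors over
#'   `(single_rooted, multi_no_FI, multi_FI)`.
#' @param group_rates named numeric, target marginal 10-year loss
#'   probability per published group `"1"`..`"8"`.
#' @param sigma_b SD of the patient random intercept (logit scale, >= 0).
#' @param mechanism `"table3"` (published-tree groups) or `"constant"`
#'   (every tooth at `baseline_rate`; the null generator).
#' @param baseline_rate marginal loss probability under
#'   `mechanism = "constant"`.
#' @param effects optional named list of logit-scale additions: for a
#'   categorical covariate a named vector over its levels, for a numeric
#'   covariate a single slope applied to the centred value.
#' @param missing_rates optional named vector of per-variable missingness
#'   probabilities for tooth covariates (applied after outcome generation).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 110,
                       seed = 1,
                       teeth_per_patient = list(min = 10, max = 28, mean = 23.2),
                       patient_marginals = list(
                         gender = c(female = 68, male = 42) / 110,
                         smoking = c(never = 50, former = 27, active = 33) / 110,
                         diabetes = c(no = 101, yes = 9) / 110,
                         age_mean = 46.7, age_sd = 10.26, age_range = c(19, 90),
                         pcr_mean = 31.3, pcr_sd = 17.39, pcr_missing = 7 / 110
                       ),
                       tooth_marginals = list(
                         # count ratios from the published tooth table;
                         # premolar/molar root counts derived from its
                         # furcation totals (772 multi-rooted, 431 with FI)
                         jaw = c(maxilla = 1215, mandible = 1341) / 2556,
                         tooth_type = c(anterior = 1207, premolar = 733,
                                        molar = 616) / 2556,
                         furcation = list(
                           anterior = c(single_rooted = 1, multi_no_FI = 0,
                                        multi_FI = 0),
                           premolar = c(single_rooted = 577,
                                        multi_no_FI = 156 * 341 / 772,
                                        multi_FI = 156 * 431 / 772) / 733,
                           molar = c(single_rooted = 0, multi_no_FI = 341,
                                     multi_FI = 431) / 772
                         ),
                         bone_loss_raw = c("<=20" = 700, "21-40" = 1078,
                                           "41-60" = 531, "61-80" = 160,
                                           ">80" = 59) / 2528,
                         infrabony = c(shallow = 2260, moderate = 266,
                                       deep = 2) / 2528,
                         abutment = c(none = 2243, fixed = 232,
                                      removable = 67) / 2542
                       ),
                       group_rates = stats::setNames(
                         pt_published_groups$lost / pt_published_groups$total,
                         pt_published_groups$group_id),
                       sigma_b = 0.5,
                       mechanism = c("table3", "constant"),
                       baseline_rate = 0.1,
                       effects = NULL,
                       missing_rates = NULL) {
  mechanism <- match.arg(mechanism)
  cfg <- list(n_patients = n_patients, seed = seed,
              teeth_per_patient = teeth_per_patient,
              patient_marginals = patient_marginals,
              tooth_marginals = tooth_marginals,
              group_rates = group_rates, sigma_b = sigma_b,
              mechanism = mechanism, baseline_rate = baseline_rate,
              effects = effects, missing_rates = missing_rates)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    stop("n_patients must be a positive integer")
  }
  if (cfg$sigma_b < 0) stop("sigma_b must be >= 0")
  tp <- cfg$teeth_per_patient
  if (tp$min < 1 || tp$max > 28 || tp$mean < tp$min || tp$mean > tp$max) {
    stop("teeth_per_patient must satisfy 1 <= min <= mean <= max <= 28")
  }
  chk_probs <- function(p, what) {
    # tolerate sums off by rounding (<= 1e-3); anything worse is an error
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-3) {
      stop("probabilities for ", what, " must be in [0,1] and sum to 1")
    }
  }
  pm <- cfg$patient_marginals
  chk_probs(pm$gender, "gender"); chk_probs(pm$smoking, "smoking")
  chk_probs(pm$diabetes, "diabetes")
  tm <- cfg$tooth_marginals
  chk_probs(tm$jaw, "jaw"); chk_probs(tm$tooth_type, "tooth_type")
  chk_probs(tm$bone_loss_raw, "bone_loss_raw")
  chk_probs(tm$infrabony, "infrabony"); chk_probs(tm$abutment, "abutment")
  for (ty in names(tm$furcation)) chk_probs(tm$furcation[[ty]], paste("furcation", ty))
  if (tm$furcation$anterior[["multi_no_FI"]] > 0 ||
      tm$furcation$anterior[["multi_FI"]] > 0) {
    stop("configuration error: anterior teeth cannot be multi-rooted")
  }
  if (tm$furcation$molar[["single_rooted"]] > 0) {
    stop("configuration error: molars cannot be single-rooted")
  }
  if (cfg$mechanism == "table3") {
    if (length(cfg$group_rates) != 8 ||
        !setequal(names(cfg$group_rates), as.character(1:8))) {
      stop("group_rates must be named '1'..'8'")
    }
    if (any(cfg$group_rates <= 0 | cfg$group_rates >= 1)) {
      stop("group_rates must lie strictly in (0, 1)")
    }
  } else if (cfg$baseline_rate <= 0 || cfg$baseline_rate >= 1) {
    stop("baseline_rate must lie strictly in (0, 1)")
  }
  invisible(cfg)
}

# marginal P(y = 1) for logit offset eta under b ~ N(0, sigma^2)
pt_marginal_rate <- function(eta, sigma) {
  if (sigma < 1e-10) return(stats::plogis(eta))
  f <- function(b) stats::plogis(eta + b) * stats::dnorm(b, 0, sigma)
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

#' Calibrate logit offsets against a patient random intercept
#'
#' For each target marginal probability `p` solves for the logit-scale
#' offset `eta` such that `E[invlogit(eta + b)] = p` with
#' `b ~ N(0, sigma_b^2)` (Gaussian quadrature plus root finding, absolute
#' tolerance 1e-8). With `sigma_b = 0` this reduces to `eta = logit(p)`;
#' with `sigma_b > 0` the offset is pushed away from zero because the
#' logistic-normal mean shrinks toward 1/2.
#'
#' @param group_rates named numeric vector of target marginal probabilities,
#'   each strictly in (0, 1).
#' @param sigma_b random-intercept SD (>= 0).
#' @return named numeric vector of offsets (class `group_offsets`).
#' @export
calibrate_offsets <- function(group_rates, sigma_b) {
  if (any(group_rates <= 0 | group_rates >= 1)) {
    stop("rates must lie strictly in (0, 1); offsets are undefined at 0 or 1")
  }
  if (sigma_b < 0) stop("sigma_b must be >= 0")
  eta <- vapply(group_rates, function(p) {
    if (sigma_b < 1e-10) return(stats::qlogis(p))
    stats::uniroot(function(e) pt_marginal_rate(e, sigma_b) - p,
                   interval = stats::qlogis(p) + c(-1, 1) * (1 + 3 * sigma_b),
                   extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
  structure(eta, class = "group_offsets", sigma_b = sigma_b)
}

pt_rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

pt_sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort
#'
#' Draws patients and teeth from the marginals in the configuration, assigns
#' FDI tooth codes as within-patient labels (sampled from the 28 valid
#' non-third-molar positions, independent of the jaw/type covariates), and
#' generates the 10-year loss outcome from
#' `Bernoulli(invlogit(eta + effects + b_patient))`, where `eta` is the
#' calibrated offset of the tooth's published risk group (or of the constant
#' baseline under the null mechanism) and `b_patient ~ N(0, sigma_b^2)`.
#' Reproducible: the configured seed fully determines the cohort.
#'
#' @param config a [sim_config()].
#' @return a [perio_cohort()]; provenance records the configuration, the
#'   seed, and each tooth's generating group and linear predictor is
#'   attached as attribute `truth` (data.frame with `group_id`, `eta`,
#'   `b_patient`, `p_true`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  pm <- config$patient_marginals
  tm <- config$tooth_marginals
  n <- as.integer(config$n_patients)

  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(pt_rnorm_trunc(n, pm$age_mean, pm$age_sd,
                               pm$age_range[1], pm$age_range[2]), 1),
    gender = pt_sample_levels(n, pm$gender),
    smoking = pt_sample_levels(n, pm$smoking),
    diabetes = pt_sample_levels(n, pm$diabetes),
    pcr = round(pt_rnorm_trunc(n, pm$pcr_mean, pm$pcr_sd, 0, 100), 1)
  )
  patients$pcr[stats::runif(n) < pm$pcr_missing] <- NA_real_

  tp <- config$teeth_per_patient
  span <- tp$max - tp$min
  n_teeth <- tp$min + stats::rbinom(n, span, (tp$mean - tp$min) / span)

  pid <- rep(patients$patient_id, n_teeth)
  tooth_id <- unlist(lapply(n_teeth, function(k) sample(pt_fdi_codes, k)),
                     use.names = FALSE)
  m <- length(pid)

  tooth_type <- pt_sample_levels(m, tm$tooth_type)
  furcation <- character(m)
  for (ty in names(tm$furcation)) {
    idx <- tooth_type == ty
    if (any(idx)) furcation[idx] <- pt_sample_levels(sum(idx), tm$furcation[[ty]])
  }
  teeth <- data.frame(
    patient_id = pid, tooth_id = tooth_id,
    jaw = pt_sample_levels(m, tm$jaw),
    tooth_type = tooth_type,
    furcation_class = furcation,
    bone_loss_raw = pt_sample_levels(m, tm$bone_loss_raw),
    infrabony = pt_sample_levels(m, tm$infrabony),
    abutment = pt_sample_levels(m, tm$abutment)
  )

  # linear predictor: calibrated group/baseline offset + injected effects
  page <- patients$age[match(pid, patients$patient_id)]
  pdia <- patients$diabetes[match(pid, patients$patient_id)]
  if (config$mechanism == "table3") {
    eta_g <- calibrate_offsets(config$group_rates, config$sigma_b)
    grp <- assign_group(collapse_bone_loss(teeth$bone_loss_raw),
                        teeth$furcation_class, teeth$abutment, page, pdia)
    eta <- unname(eta_g[as.character(grp$group_id)])
    group_id <- grp$group_id
  } else {
    eta0 <- calibrate_offsets(c(base = config$baseline_rate), config$sigma_b)
    eta <- rep(unname(eta0), m)
    group_id <- rep(NA_integer_, m)
  }
  if (!is.null(config$effects)) {
    dat <- cbind(teeth,
                 patients[match(pid, patients$patient_id),
                          c("age", "gender", "smoking", "diabetes", "pcr")])
    dat$bone_loss_cat <- as.character(collapse_bone_loss(dat$bone_loss_raw))
    for (v in names(config$effects)) {
      ef <- config$effects[[v]]
      if (!v %in% names(dat)) stop("effects: unknown covariate ", v)
      if (is.null(names(ef))) {
        eta <- eta + ef[1] * (dat[[v]] - mean(dat[[v]], na.rm = TRUE))
      } else {
        add <- ef[as.character(dat[[v]])]
        if (anyNA(add)) stop("effects for ", v, " must cover all levels")
        eta <- eta + unname(add)
      }
    }
  }

  b <- stats::rnorm(n, 0, config$sigma_b)
  b_tooth <- b[match(pid, patients$patient_id)]
  p_true <- stats::plogis(eta + b_tooth)
  teeth$lost_by_T2 <- stats::rbinom(m, 1, p_true)

  if (!is.null(config$missing_rates)) {
    for (v in names(config$missing_rates)) {
      teeth[[v]][stats::runif(m) < config$missing_rates[[v]]] <- NA
    }
  }

  out <- perio_cohort(patients, teeth,
                      provenance = list(generator = "periotree::generate_cohort",
                                        seed = config$seed,
                                        config = unclass(config)))
  attr(out, "truth") <- data.frame(group_id = group_id, eta = eta,
                                   b_patient = b_tooth, p_true = p_true)
  out
}

#' Save / load a simulation configuration
#'
#' Flat JSON serialization of a [sim_config()]. Named probability vectors
#' are written as JSON objects so level names survive the round trip.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `save_sim_config` returns `path` invisibly; `load_sim_config`
#'   returns the restored [sim_config()].
#' @export
save_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  to_listy <- function(x) {
    if (is.list(x)) lapply(x, to_listy)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(to_listy(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_sim_config
#' @export
load_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unl <- function(x) if (is.list(x)) unlist(x) else x
  for (v in c("gender", "smoking", "diabetes")) {
    raw$patient_marginals[[v]] <- unl(raw$patient_marginals[[v]])
  }
  for (v in c("jaw", "tooth_type", "bone_loss_raw", "infrabony", "abutment")) {
    raw$tooth_marginals[[v]] <- unl(raw$tooth_marginals[[v]])
  }
  raw$tooth_marginals$furcation <- lapply(raw$tooth_marginals$furcation, unl)
  raw$group_rates <- unl(raw$group_rates)
  if (!is.null(raw$effects)) raw$effects <- lapply(raw$effects, unl)
  if (!is.null(raw$missing_rates)) raw$missing_rates <- unl(raw$missing_rates)
  args <- raw[!vapply(raw, is.null, logical(1))]
  do.call(sim_config, args)
}
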