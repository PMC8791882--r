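test_that("offset calibration matches closed forms and a Monte-Carlo oracle", {
  # sigma = 0: plain logit
  expect_equal(as.numeric(calibrate_offsets(c(g = 0.223), 0)), qlogis(0.223),
               tolerance = 1e-10)
  # symmetry: rate 1/2 needs offset 0 at any sigma
  expect_equal(as.numeric(calibrate_offsets(c(g = 0.5), 1)), 0,
               tolerance = 1e-8)
  # sigma = 1, rate 0.223: verify by Monte-Carlo integration
  eta <- as.numeric(calibrate_offsets(c(g = 0.223), 1))
  set.seed(42)
  mc <- mean(plogis(eta + rnorm(1e6)))
  expect_equal(mc, 0.223, tolerance = 2e-3)   # ~3 MC standard errors
  # quadrature itself is tight
  expect_equal(periotree:::pt_marginal_rate(eta, 1), 0.223, tolerance = 1e-8)
  expect_error(calibrate_offsets(c(g = 0), 1), "strictly in")
  expect_error(calibrate_offsets(c(g = 1), 0.5), "strictly in")
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_patients = 25, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$teeth, b$teeth)
})

test_that("generated cohorts satisfy the structural tooth invariants", {
  co <- generate_cohort(sim_config(n_patients = 200, seed = 17))
  teeth <- co$teeth
  expect_true(all(teeth$furcation_class[teeth$tooth_type == "anterior"] ==
                    "single_rooted"))
  expect_true(all(teeth$furcation_class[teeth$tooth_type == "molar"] %in%
                    c("multi_no_FI", "multi_FI")))
  expect_equal(teeth$bone_loss_cat, collapse_bone_loss(teeth$bone_loss_raw))
  expect_false(any(grepl("8$", teeth$tooth_id)))
  expect_true(all(table(teeth$patient_id) <= 28))
  expect_false(anyDuplicated(teeth[, c("patient_id", "tooth_id")]) > 0)
})

test_that("categorical marginals are recovered within 3 binomial SEs at n = 2000", {
  cfg <- sim_config(n_patients = 2000, seed = 4)
  co <- generate_cohort(cfg)
  m <- nrow(co$teeth)
  chk <- function(x, probs) {
    obs <- table(factor(x, levels = names(probs))) / length(x)
    for (lv in names(probs)) {
      se <- sqrt(probs[[lv]] * (1 - probs[[lv]]) / length(x))
      expect_lt(abs(obs[[lv]] - probs[[lv]]), 3 * se + 1e-9)
    }
  }
  chk(co$teeth$tooth_type, cfg$tooth_marginals$tooth_type)
  chk(co$teeth$jaw, cfg$tooth_marginals$jaw)
  chk(co$teeth$bone_loss_raw, cfg$tooth_marginals$bone_loss_raw)
  chk(co$teeth$abutment, cfg$tooth_marginals$abutment)
  chk(co$patients$gender, cfg$patient_marginals$gender)
  chk(co$patients$diabetes, cfg$patient_marginals$diabetes)
  # furcation is specified conditionally on tooth type
  for (ty in c("premolar", "molar")) {
    chk(co$teeth$furcation_class[co$teeth$tooth_type == ty],
        cfg$tooth_marginals$furcation[[ty]])
  }
  expect_equal(mean(co$patients$age), cfg$patient_marginals$age_mean,
               tolerance = 0.02)
})

test_that("with sigma_b = 0 group-wise loss rates converge to their targets", {
  cfg <- sim_config(n_patients = 3000, seed = 8, sigma_b = 0)
  co <- generate_cohort(cfg)
  truth <- attr(co, "truth")
  for (g in names(cfg$group_rates)) {
    idx <- truth$group_id == as.integer(g)
    n <- sum(idx)
    if (n < 200) next    # tiny groups carry no power
    p <- cfg$group_rates[[g]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(co$teeth$lost_by_T2[idx]) - p), 3 * se + 1e-9)
  }
})

test_that("a larger random-intercept SD raises within-patient outcome correlation", {
  icc <- function(co) {
    y <- co$teeth$lost_by_T2
    g <- factor(co$teeth$patient_id)
    fit <- stats::aov(y ~ g)
    ms <- summary(fit)[[1]]$`Mean Sq`
    k <- mean(table(g))
    (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  }
  co0 <- generate_cohort(sim_config(n_patients = 800, seed = 21, sigma_b = 0,
                                    mechanism = "constant"))
  co2 <- generate_cohort(sim_config(n_patients = 800, seed = 22, sigma_b = 2,
                                    mechanism = "constant"))
  expect_gt(icc(co2), icc(co0))
})

test_that("injected covariate effects shift loss rates in the configured direction", {
  delta <- qlogis(0.30) - qlogis(0.05)
  cfg <- sim_config(n_patients = 600, seed = 31, sigma_b = 0,
                    mechanism = "constant", baseline_rate = 0.05,
                    effects = list(abutment = c(none = 0, fixed = delta,
                                                removable = delta)))
  co <- generate_cohort(cfg)
  dat <- cohort_data(co)
  r_none <- mean(dat$lost_by_T2[dat$abutment == "none"])
  r_abut <- mean(dat$lost_by_T2[dat$abutment != "none"])
  expect_lt(abs(r_none - 0.05), 0.01)
  expect_lt(abs(r_abut - 0.30), 0.04)
})

test_that("simulation configs survive a save/load round trip", {
  cfg <- sim_config(n_patients = 42, seed = 7, sigma_b = 1.25)
  f <- withr::local_tempfile(fileext = ".json")
  save_sim_config(cfg, f)
  back <- load_sim_config(f)
  expect_equal(back$n_patients, 42)
  expect_equal(back$sigma_b, 1.25)
  expect_equal(back$group_rates, cfg$group_rates, tolerance = 1e-12)
  expect_identical(generate_cohort(back)$teeth, generate_cohort(cfg)$teeth)
})

test_that("infeasible marginal configurations are rejected", {
  expect_error(sim_config(tooth_marginals = within(
    sim_config()$tooth_marginals,
    furcation <- list(anterior = c(single_rooted = 0.8, multi_no_FI = 0.1,
                                   multi_FI = 0.1),
                      premolar = c(single_rooted = 1, multi_no_FI = 0, multi_FI = 0),
                      molar = c(single_rooted = 0, multi_no_FI = 0.5, multi_FI = 0.5))
  )), "anterior")
  expect_error(sim_config(sigma_b = -1), "sigma_b")
})
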