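# The model-tree learner: recovery of known generating structure,
# partition properties, determinism, serialization.

test_that("a single effective binary covariate yields exactly one split with correct leaf rates", {
  delta <- qlogis(0.30) - qlogis(0.05)
  cfg <- sim_config(n_patients = 1000, seed = 12, sigma_b = 0,
                    mechanism = "constant", baseline_rate = 0.05,
                    patient_marginals = within(sim_config()$patient_marginals,
                                               diabetes <- c(no = 0.5, yes = 0.5)),
                    effects = list(diabetes = c(no = 0, yes = delta)))
  co <- generate_cohort(cfg)
  m <- fit_glmm_tree(co, c("diabetes", "jaw", "gender", "smoking"))
  expect_equal(tree_vars_used(m), "diabetes")
  leaves <- periotree:::pt_collect_betas(m$root)
  expect_length(leaves, 2)
  dat <- cohort_data(co)
  for (lv in c("no", "yes")) {
    idx <- dat$diabetes == lv
    p_true <- if (lv == "no") 0.05 else 0.30
    se <- sqrt(p_true * (1 - p_true) / sum(idx))
    p_leaf <- plogis(unname(periotree:::pt_collect_betas(m$root)[
      as.character(unique(periotree:::pt_route(m$root, dat[idx, , drop = FALSE])))]))
    expect_lt(abs(p_leaf - p_true), 2 * se + 0.01)
  }
})

test_that("leaves partition the covariate space", {
  co <- generate_cohort(sim_config(n_patients = 200, seed = 13))
  m <- fit_glmm_tree(co, model_vars)
  grid <- calculator_grid()
  grid$bone_loss_cat <- factor(grid$bone_loss_cat,
                               levels = c("<=20", "21-40", "41-60", ">60"),
                               ordered = TRUE)
  grid$furcation_class <- factor(grid$furcation_class,
                                 levels = c("single_rooted", "multi_no_FI",
                                            "multi_FI"), ordered = TRUE)
  assign <- periotree:::pt_route(m$root, grid)
  expect_length(assign, nrow(grid))
  expect_true(all(assign %in% periotree:::pt_leaf_ids(m$root)))
  # child counts add up to parents throughout the tree
  walk <- function(nd) {
    if (is.null(nd$split)) return(invisible())
    expect_equal(nd$left$n_teeth + nd$right$n_teeth, nd$n_teeth)
    walk(nd$left); walk(nd$right)
  }
  walk(m$root)
})

test_that("refitting with identical inputs is deterministic", {
  co <- generate_cohort(sim_config(n_patients = 80, seed = 14))
  m1 <- fit_glmm_tree(co, model_vars)
  m2 <- fit_glmm_tree(co, model_vars)
  expect_equal(m1$root, m2$root, tolerance = 0)
  expect_identical(m1$sigma_b_hat, m2$sigma_b_hat)
})

test_that("JSON serialization round-trips predictions bit for bit", {
  co <- generate_cohort(sim_config(n_patients = 80, seed = 15))
  m <- fit_glmm_tree(co, model_vars)
  back <- model_from_json(model_to_json(m))
  expect_identical(predict(back, co, mode = "marginal"),
                   predict(m, co, mode = "marginal"))
  expect_identical(predict(back, co, mode = "conditional"),
                   predict(m, co, mode = "conditional"))
  f <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, f)
  expect_identical(predict(model_from_json(f), co), predict(m, co))
})

test_that("marginal predictions average conditional ones over the random intercept", {
  co <- generate_cohort(sim_config(n_patients = 120, seed = 16, sigma_b = 0.8))
  m <- fit_glmm_tree(co, model_vars)
  betas <- periotree:::pt_collect_betas(m$root)
  b0 <- unname(betas[1])
  set.seed(1)
  mc <- mean(plogis(b0 + rnorm(1e6, 0, m$sigma_b_hat)))
  expect_equal(unname(marginal_prob(b0, m$sigma_b_hat)), mc, tolerance = 1e-3)
})

test_that("conditional predictions use BLUPs for known patients and fall back otherwise", {
  co <- generate_cohort(sim_config(n_patients = 60, seed = 18, sigma_b = 1))
  m <- fit_glmm_tree(co, model_vars)
  dat <- cohort_data(co)
  cond <- predict(m, co, mode = "conditional")
  marg <- predict(m, co, mode = "marginal")
  betas <- periotree:::pt_collect_betas(m$root)
  assign <- periotree:::pt_route(m$root, dat)
  hand <- plogis(unname(betas[as.character(assign)]) +
                   unname(m$patient_effects[dat$patient_id]))
  expect_equal(cond, hand, tolerance = 1e-12)
  # unseen patient: falls back to the marginal value
  new_dat <- dat[1, , drop = FALSE]
  new_dat$patient_id <- "UNSEEN"
  expect_equal(predict(m, new_dat, mode = "conditional"),
               predict(m, new_dat, mode = "marginal"))
  # unknown categorical level is a routing error naming the variable
  bad <- dat[1, , drop = FALSE]
  bad$bone_loss_cat <- "99%"
  expect_error(predict(m, bad), "bone_loss_cat")
})

test_that("a constant-outcome cohort yields a root-only model with a warning", {
  co <- generate_cohort(sim_config(n_patients = 20, seed = 19))
  co$teeth$lost_by_T2 <- 0L
  expect_warning(m <- fit_glmm_tree(co, model_vars), "identical")
  expect_null(m$root$split)
  expect_lt(predict(m, co)[1], 1e-5)
})
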