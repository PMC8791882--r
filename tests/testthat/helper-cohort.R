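# Fixture builders used across the suite. All fixtures are constructed in
# code; no binary data.

fdi_codes <- periotree:::pt_fdi_codes

# Two patients, four teeth; exercises every column of the CSV schema.
toy_cohort <- function() {
  patients <- data.frame(
    patient_id = c("p1", "p2"),
    age = c(45, 67),
    gender = c("female", "male"),
    smoking = c("never", "active"),
    diabetes = c("no", "yes"),
    pcr = c(25.5, NA)
  )
  teeth <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2"),
    tooth_id = c("11", "16", "36", "47"),
    jaw = c("maxilla", "maxilla", "mandible", "mandible"),
    tooth_type = c("anterior", "molar", "molar", "molar"),
    furcation_class = c("single_rooted", "multi_FI", "multi_no_FI", "multi_FI"),
    bone_loss_raw = c("<=20", "61-80", "21-40", ">80"),
    infrabony = c("shallow", "moderate", "shallow", "deep"),
    abutment = c("none", "fixed", "none", "removable"),
    lost_by_T2 = c(0L, 1L, 0L, 1L)
  )
  perio_cohort(patients, teeth)
}

# Cohort with exact per-block tooth counts and loss counts; used to encode
# printed contingency tables. Unspecified covariates take safe defaults.
make_block_cohort <- function(blocks, teeth_per_patient = 23) {
  defaults <- list(jaw = "maxilla", tooth_type = "anterior",
                   furcation_class = "single_rooted", bone_loss_raw = "<=20",
                   infrabony = "shallow", abutment = "none",
                   age = 50, diabetes = "no")
  rows <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    b <- as.list(blocks[i, ])
    for (v in names(defaults)) if (is.null(b[[v]])) b[[v]] <- defaults[[v]]
    data.frame(jaw = b$jaw, tooth_type = b$tooth_type,
               furcation_class = b$furcation_class,
               bone_loss_raw = b$bone_loss_raw, infrabony = b$infrabony,
               abutment = b$abutment, age = b$age, diabetes = b$diabetes,
               lost_by_T2 = rep(c(1L, 0L), c(b$n_lost, b$n - b$n_lost)))
  }))
  n_pat <- ceiling(nrow(rows) / teeth_per_patient)
  pat_idx <- rep(seq_len(n_pat), each = teeth_per_patient)[seq_len(nrow(rows))]
  first <- !duplicated(pat_idx)   # pat_idx is nondecreasing
  patients <- data.frame(
    patient_id = sprintf("F%04d", seq_len(n_pat)),
    age = rows$age[first],
    gender = "female", smoking = "never",
    diabetes = as.character(rows$diabetes)[first],
    pcr = 30
  )
  teeth <- rows[, c("jaw", "tooth_type", "furcation_class", "bone_loss_raw",
                    "infrabony", "abutment", "lost_by_T2")]
  teeth$patient_id <- patients$patient_id[pat_idx]
  teeth$tooth_id <- unlist(lapply(split(seq_along(pat_idx), pat_idx),
                                  function(k) fdi_codes[seq_along(k)]),
                           use.names = FALSE)
  perio_cohort(patients, teeth)
}

# Cohort for annual-rate arithmetic: n_patients patients, n_lost lost teeth.
make_rate_cohort <- function(n_patients, n_lost, teeth_per_patient = 23) {
  total <- n_patients * teeth_per_patient
  make_block_cohort(data.frame(n = total, n_lost = n_lost),
                    teeth_per_patient = teeth_per_patient)
}

# Exhaustive covariate grid of the published calculator's input space.
calculator_grid <- function() {
  expand.grid(bone_loss_cat = c("<=20", "21-40", "41-60", ">60"),
              furcation_class = c("single_rooted", "multi_no_FI", "multi_FI"),
              abutment = c("none", "fixed", "removable"),
              age = c(45, 70),
              diabetes = c("no", "yes"),
              stringsAsFactors = FALSE)
}

# The published tree structure hand-encoded as a glmm_tree, for the
# cross-module equivalence check against assign_group().
published_tree_model <- function() {
  r <- periotree::published_groups()
  beta <- stats::qlogis(r$rate_pct / 100)
  leaf <- function(id, g) list(node_id = id, n_teeth = r$total[g],
                               n_lost = r$lost[g], split = NULL,
                               beta = beta[g], group_id = g)
  split_ord <- function(var, left_levels) {
    list(variable = var, kind = "ordinal", threshold = NULL,
         left_levels = left_levels)
  }
  root <- list(
    node_id = 1L, n_teeth = sum(r$total), n_lost = sum(r$lost),
    split = split_ord("bone_loss_cat", c("<=20", "21-40", "41-60")),
    left = list(
      node_id = 2L, n_teeth = 0L, n_lost = 0L,
      split = split_ord("furcation_class", c("single_rooted", "multi_no_FI")),
      left = list(
        node_id = 3L, n_teeth = 0L, n_lost = 0L,
        split = list(variable = "abutment", kind = "nominal",
                     threshold = NULL, left_levels = "none"),
        left = list(
          node_id = 4L, n_teeth = 0L, n_lost = 0L,
          split = split_ord("bone_loss_cat", c("<=20", "21-40")),
          left = list(
            node_id = 5L, n_teeth = 0L, n_lost = 0L,
            split = list(variable = "diabetes", kind = "nominal",
                         threshold = NULL, left_levels = "no"),
            left = leaf(6L, 1), right = leaf(7L, 2)),
          right = leaf(8L, 3)),
        right = list(
          node_id = 9L, n_teeth = 0L, n_lost = 0L,
          split = list(variable = "age", kind = "numeric", threshold = 61,
                       left_levels = NULL),
          left = leaf(10L, 4), right = leaf(11L, 5))),
      right = list(
        node_id = 12L, n_teeth = 0L, n_lost = 0L,
        split = split_ord("bone_loss_cat", c("<=20", "21-40")),
        left = leaf(13L, 6), right = leaf(14L, 7))),
    right = leaf(15L, 8))
  structure(list(root = root, sigma_b_hat = 0,
                 patient_effects = stats::setNames(numeric(0), character(0)),
                 fit_info = list(iterations = 0L, converged = TRUE),
                 partitioning_vars = c("bone_loss_cat", "furcation_class",
                                       "abutment", "age", "diabetes"),
                 var_kinds = NULL, config = periotree::fit_config()),
            class = "glmm_tree")
}

# Brute-force AUC oracle: mean over all positive-negative pairs, ties as 1/2.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

tree_vars_used <- function(model) periotree:::pt_tree_vars(model$root)

model_vars <- c("bone_loss_cat", "furcation_class", "abutment", "age",
                "diabetes")
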