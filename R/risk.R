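# The published eight-group prognosis calculator: a fixed encoding of the
# final mixed-model tree, mapping five covariates to a risk group and its
# reported 10-year loss rate.

# Printed group counts (teeth lost / total) and rates. Note: group totals
# sum to 2529 while the complete-case text count is 2528, and group losses
# sum to 161 of 166 lost teeth overall; the rows are reproduced verbatim and
# the discrepancy is surfaced, not resolved, here.
pt_published_groups <- data.frame(
  group_id = 1:8,
  lost  = c(28L, 6L, 21L, 9L, 11L, 14L, 23L, 49L),
  total = c(1279L, 105L, 366L, 179L, 22L, 221L, 137L, 220L),
  rate_pct = c(2.2, 5.7, 5.7, 5.0, 50.0, 6.3, 16.8, 22.3),
  label = c(
    "BL <=40% & no FI & no abutment & no diabetes",
    "BL <=40% & no FI & no abutment & diabetic",
    "BL 41-60% & no FI & no abutment",
    "BL <=60% & no FI & abutment & age <=61",
    "BL <=60% & no FI & abutment & age >61",
    "BL <=40% & multi-rooted with FI",
    "BL 41-60% & multi-rooted with FI",
    "BL >60%"
  )
)

#' The published risk groups
#'
#' The eight terminal groups of the final prognostic tree with their
#' reported teeth-lost/total counts and 10-year loss rates. The printed
#' group totals sum to 2529 teeth (vs 2528 complete-case teeth in the text)
#' and group losses to 161 (vs 166 lost overall); the rows are reported as
#' printed and this discrepancy is deliberately left visible.
#'
#' @return data.frame with columns `group_id`, `lost`, `total`, `rate_pct`,
#'   `label`.
#' @export
published_groups <- function() pt_published_groups

#' Percent loss rate from lost/total counts
#'
#' `100 * lost / total`, rounded half-up to one decimal place — the rounding
#' used in the published group table.
#'
#' @param lost number of teeth lost (0 <= lost <= total).
#' @param total total number of teeth (> 0).
#' @return percent at one decimal place.
#' @export
group_rate_from_counts <- function(lost, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(lost < 0 | lost > total)) stop("need 0 <= lost <= total")
  floor(1000 * lost / total + 0.5) / 10
}

#' Assign teeth to the published risk groups
#'
#' Routes each tooth through the fixed final tree: bone loss > 60% first
#' (group 8); otherwise multi-rooted teeth with furcation involvement split
#' on bone loss 41-60% vs <= 40% (groups 7/6); otherwise abutment teeth
#' (fixed or removable) split on patient age > 61 vs <= 61 (groups 5/4);
#' otherwise non-abutment teeth with bone loss 41-60% form group 3, and with
#' bone loss <= 40% split on diabetes (groups 2/1). Age exactly 61 routes to
#' the lower-risk branch. Groups 4 and 5 are reachable for any bone loss
#' <= 60%, as in the published table. All arguments are vectorised.
#'
#' @param bone_loss_cat merged bone-loss category
#'   (`<=20, 21-40, 41-60, >60`).
#' @param furcation_class `single_rooted`, `multi_no_FI` or `multi_FI`.
#' @param abutment `none`, `fixed` or `removable`.
#' @param age_years patient age in years (> 0); dichotomised at 61
#'   internally.
#' @param diabetes `no` or `yes`.
#' @return data.frame with `group_id`, `rate_pct` (the printed rate),
#'   `lost`, `total`, and `path` (the split decisions taken, `" & "`
#'   separated).
#' @export
assign_group <- function(bone_loss_cat, furcation_class, abutment, age_years,
                         diabetes) {
  bl <- pt_make_factor(as.character(bone_loss_cat), "bone_loss_cat")
  fi <- pt_make_factor(as.character(furcation_class), "furcation_class")
  ab <- pt_make_factor(as.character(abutment), "abutment")
  db <- pt_make_factor(as.character(diabetes), "diabetes")
  age <- as.numeric(age_years)
  n <- max(length(bl), length(fi), length(ab), length(age), length(db))
  if (any(c(length(bl), length(fi), length(ab), length(age), length(db)) != n)) {
    stop("arguments must have equal length")
  }
  if (anyNA(bl) || anyNA(fi) || anyNA(ab) || anyNA(db)) {
    stop("invalid or missing categorical level(s) in input")
  }
  if (any(is.na(age) | age <= 0)) stop("age_years must be > 0")

  blh <- bl == ">60"                 # bone loss > 60%
  bl46 <- bl == "41-60"
  fiy <- fi == "multi_FI"
  aby <- ab %in% c("fixed", "removable")
  old <- age > 61
  dby <- db == "yes"

  gid <- integer(n)
  path <- character(n)
  gid[blh] <- 8L
  path[blh] <- "BL >60%"
  i <- !blh & fiy
  gid[i & bl46] <- 7L
  path[i & bl46] <- "BL <=60% & multi-rooted with FI & BL 41-60%"
  gid[i & !bl46] <- 6L
  path[i & !bl46] <- "BL <=60% & multi-rooted with FI & BL <=40%"
  j <- !blh & !fiy & aby
  gid[j & old] <- 5L
  path[j & old] <- "BL <=60% & no FI & abutment & age >61"
  gid[j & !old] <- 4L
  path[j & !old] <- "BL <=60% & no FI & abutment & age <=61"
  k <- !blh & !fiy & !aby
  gid[k & bl46] <- 3L
  path[k & bl46] <- "BL <=60% & no FI & no abutment & BL 41-60%"
  gid[k & !bl46 & dby] <- 2L
  path[k & !bl46 & dby] <- "BL <=60% & no FI & no abutment & BL <=40% & diabetic"
  gid[k & !bl46 & !dby] <- 1L
  path[k & !bl46 & !dby] <- "BL <=60% & no FI & no abutment & BL <=40% & no diabetes"

  m <- match(gid, pt_published_groups$group_id)
  data.frame(group_id = gid,
             rate_pct = pt_published_groups$rate_pct[m],
             lost = pt_published_groups$lost[m],
             total = pt_published_groups$total[m],
             path = path)
}

#' Score a cohort with the published calculator
#'
#' Batch interface: routes every tooth of a cohort through [assign_group()]
#' and returns the tooth table with `group_id`, `rate_pct` and `path`
#' appended.
#'
#' @param cohort a [perio_cohort()]; furcation, bone loss, abutment and
#'   diabetes must be observed (apply [complete_case_filter()] first if
#'   needed).
#' @return data.frame: the flattened cohort with assignment columns.
#' @export
predict_published <- function(cohort) {
  dat <- cohort_data(cohort)
  g <- assign_group(dat$bone_loss_cat, dat$furcation_class, dat$abutment,
                    dat$age, dat$diabetes)
  cbind(dat, g[, c("group_id", "rate_pct", "path")])
}
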