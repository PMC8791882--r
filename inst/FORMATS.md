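# File formats

## Cohort CSV (input and output of `simulate`, input to all other stages)

One row per tooth, patient columns repeated. Header (case-insensitive):

    patient_id, tooth_id, age, gender, smoking, diabetes, pcr,
    jaw, tooth_type, furcation_class, bone_loss_raw, infrabony,
    abutment, lost_by_T2

- `patient_id` — opaque patient identifier (string).
- `tooth_id` — FDI two-digit code; third molars (codes ending in 8) are
  rejected at read time.
- `age` — years at start of therapy, > 0.
- `gender` — `female` / `male`.
- `smoking` — `never` / `former` / `active`.
- `diabetes` — `no` / `yes`.
- `pcr` — plaque control record, percent in [0, 100]; may be missing.
- `jaw` — `maxilla` / `mandible`.
- `tooth_type` — `anterior` / `premolar` / `molar`.
- `furcation_class` — `single_rooted` / `multi_no_FI` / `multi_FI`.
- `bone_loss_raw` — `<=20` / `21-40` / `41-60` / `61-80` / `>80`
  (percent interproximal bone loss). The merged modelling category
  (`>60` pools the top two levels) is derived, never stored.
- `infrabony` — `shallow` / `moderate` / `deep`.
- `abutment` — `none` / `fixed` / `removable`.
- `lost_by_T2` — 0/1, tooth lost within the 10-year window.

Missing values: empty field or `NA`. An optional separate patient-level
CSV (`patient_id, age, gender, smoking, diabetes, pcr`) can be joined on
`patient_id`.

## Model JSON (`fit` output, `predict --model` input)

Nested node records: internal nodes carry `split` (`variable`, `kind` =
`numeric`/`ordinal`/`nominal`, `threshold` or `left_levels`) plus `left`
and `right`; leaves carry the leaf logit `beta`, `n_teeth`, `n_lost`.
Top-level fields: `sigma_b_hat` (random-intercept SD), `patient_effects`
(BLUPs by patient), `fit_info`, `partitioning_vars`, `config`. Numbers are
written with 17 significant digits so parsing reproduces predictions bit
for bit.

## Selection JSON (`select` output)

`n_boot`, `n_failed`, `frequency` (per-variable fraction of replicate
models using the variable in at least one split), `thresholds` (0.5 for
tooth-level, 0.25 for patient-level variables), `selected`,
`replicate_vars` (per-replicate audit trail), `seed`.

## Cross-validation JSON (`validate` output)

`k`, `n_patients`, `seed`, `threshold_policy`, `level`, `mean`
(auc/sensitivity/specificity over folds), `ci` (Wilson lower/upper with
n = number of independent patients), `folds` (per-fold rows).

## Scored CSV (`predict` output)

The flattened cohort plus `group_id`, `rate_pct`, `path` (published tree)
or `p_loss` (fitted model, marginal probability).

## Report (plain text, `report` output)

Indented rendering of the final tree (left, lower-risk child first),
bootstrap selection frequencies against their thresholds, and CV metrics
with Wilson intervals.
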