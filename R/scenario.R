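# Remediation scenarios: sweeps over removal depth / cover thickness, the
# search for the smallest action meeting an annual dose limit, and the
# end-to-end report runner.

#' Remediation action
#'
#' Normalized form: `amount_cm == 0` iff `kind == "none"`.
#'
#' @param kind `"none"`, `"remove"` (excavate the top `amount_cm` of
#'   sediment) or `"add"` (cover with `amount_cm` of clean soil).
#' @param amount_cm Action magnitude in cm, `>= 0`.
#' @return An object of class `remediation_action`.
#' @export
remediation_action <- function(kind = c("none", "remove", "add"), amount_cm = 0) {
  kind <- match.arg(kind)
  if (length(amount_cm) != 1 || is.na(amount_cm) || amount_cm < 0) {
    stop("amount_cm must be a single number >= 0")
  }
  if (amount_cm == 0) kind <- "none"
  if (kind == "none" && amount_cm != 0) stop("kind 'none' requires amount_cm == 0")
  structure(list(kind = kind, amount_cm = amount_cm), class = "remediation_action")
}

#' Apply a remediation action to a profile
#'
#' @param profile A `site_profile`.
#' @param action A `remediation_action`.
#' @return The remediated `site_profile`.
#' @export
apply_action <- function(profile, action) {
  stopifnot(inherits(action, "remediation_action"))
  switch(action$kind,
         none = profile,
         remove = remove_top(profile, action$amount_cm),
         add = add_cover(profile, action$amount_cm))
}

# Per-tissue doses for both sexes covering the union of the weighting tissues
# and the mapped organs; returns list(male=, female=) named vectors.
scenario_tissue_doses <- function(profile, inputs, age, duration_years,
                                  outdoor_fraction) {
  tissues <- union(names(inputs$weights), unique(inputs$site_map$tissue))
  lapply(stats::setNames(c("male", "female"), c("male", "female")), function(sx) {
    tissue_doses(profile, inputs$table, tissues, age, sx,
                 duration_years, outdoor_fraction, inputs$nuclides)
  })
}

#' Assemble the input bundle for scenario evaluation
#'
#' @param table A `coeff_table`.
#' @param weights Tissue weights.
#' @param params Risk parameter table.
#' @param lt A `life_table`.
#' @param site_map Site-to-tissue mapping.
#' @param nuclides Nuclide registry.
#' @return A named list of validated inputs.
#' @export
scenario_inputs <- function(table, weights, params, lt,
                            site_map = default_site_organ_map(),
                            nuclides = nuclide_registry()) {
  list(table = table, weights = tissue_weights(weights), params = params,
       lt = lt, site_map = site_map, nuclides = nuclides)
}

#' Sweep remediation actions
#'
#' Evaluates effective dose and total LAR for each action and age; the
#' baseline (no action) is always evaluated and the per-age dose reduction
#' fraction `1 - E/E_baseline` is reported against it.
#'
#' @param profile A `site_profile` (uncovered baseline).
#' @param inputs Bundle from [scenario_inputs()].
#' @param actions List of `remediation_action`s.
#' @param ages Ages at start of exposure to evaluate.
#' @param duration_years,outdoor_fraction Scenario parameters.
#' @param a_max LAR upper integration limit.
#' @return data.frame `kind, amount_cm, age, E_mSv, lar_total_male,
#'   lar_total_female, dose_reduction_fraction`.
#' @export
remediation_sweep <- function(profile, inputs, actions, ages = 20,
                              duration_years = 1, outdoor_fraction = 1,
                              a_max = 110) {
  if (!any(vapply(actions, function(a) a$kind == "none", logical(1)))) {
    actions <- c(list(remediation_action("none")), actions)
  }
  rows <- list()
  baseline_E <- stats::setNames(rep(NA_real_, length(ages)), ages)
  # evaluate baseline first so reductions are always available
  ord <- order(vapply(actions, function(a) a$kind != "none", logical(1)))
  for (act in actions[ord]) {
    p <- apply_action(profile, act)
    for (age in ages) {
      H <- scenario_tissue_doses(p, inputs, age, duration_years, outdoor_fraction)
      E <- effective_dose(H$male, H$female, inputs$weights)
      lar <- vapply(c("male", "female"), function(sx) {
        doses <- stats::setNames(as.list(H[[sx]][inputs$site_map$tissue]),
                                 inputs$site_map$site)
        total_lar(doses, age, sx, inputs$params, inputs$lt, a_max)$total
      }, numeric(1))
      if (act$kind == "none") baseline_E[[as.character(age)]] <- E
      E0 <- baseline_E[[as.character(age)]]
      rows[[length(rows) + 1]] <- data.frame(
        kind = act$kind, amount_cm = act$amount_cm, age = age,
        E_mSv = E * 1e3,
        lar_total_male = lar[["male"]], lar_total_female = lar[["female"]],
        dose_reduction_fraction = if (is.na(E0) || E0 <= 0) 0 else 1 - E / E0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$kind, out$amount_cm, out$age), , drop = FALSE]
}

#' Smallest remediation depth meeting a dose limit
#'
#' Finds the smallest depth on the grid `seq(0, max_depth_cm, resolution_cm)`
#' whose annual weighted dose is at or below `limit_mSv`, by monotone
#' bisection on the grid (dose is non-increasing in both removal depth and
#' cover thickness, so bisection is exact on the grid).
#'
#' @param profile A `site_profile`.
#' @param inputs Bundle from [scenario_inputs()].
#' @param action_kind `"remove"` or `"add"`.
#' @param limit_mSv Annual dose limit in mSv (e.g. the Swedish free-release
#'   criterion 0.1 mSv).
#' @param age Age at start of exposure used for the comparison (default
#'   adult, the regulatory convention; use `age = 0` with `sex = "average"`
#'   for the most conservative receptor).
#' @param sex `"average"` for the effective dose, or a single sex.
#' @param duration_years,outdoor_fraction Scenario parameters.
#' @param resolution_cm Grid resolution (cm).
#' @param max_depth_cm Largest depth evaluated; exceeding it raises an error
#'   reporting the residual dose.
#' @return Depth in cm (0 when the baseline already meets the limit).
#' @export
depth_to_meet_limit <- function(profile, inputs, action_kind = c("remove", "add"),
                                limit_mSv = 0.1, age = 20, sex = "average",
                                duration_years = 1, outdoor_fraction = 1,
                                resolution_cm = 1, max_depth_cm = 100) {
  action_kind <- match.arg(action_kind)
  stopifnot(limit_mSv > 0, resolution_cm > 0, max_depth_cm > 0)
  E_at <- function(x) {
    p <- apply_action(profile, remediation_action(
      if (x == 0) "none" else action_kind, x))
    1e3 * weighted_dose(p, inputs$table, inputs$weights, age, sex,
                        duration_years, outdoor_fraction, inputs$nuclides)
  }
  grid <- seq(0, max_depth_cm, by = resolution_cm)
  if (grid[length(grid)] < max_depth_cm) grid <- c(grid, max_depth_cm)
  if (E_at(0) <= limit_mSv) return(0)
  E_max <- E_at(grid[length(grid)])
  if (E_max > limit_mSv) {
    stop(sprintf("dose limit %g mSv not reached within %g cm (residual %.4g mSv)",
                 limit_mSv, max_depth_cm, E_max))
  }
  lo <- 1L; hi <- length(grid)  # E(grid[lo]) > limit, E(grid[hi]) <= limit
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (E_at(grid[mid]) <= limit_mSv) hi <- mid else lo <- mid
  }
  grid[hi]
}
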