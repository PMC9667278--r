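# Cumulative-depth external dose-rate coefficient tables.
#
# A coefficient h(d) is the dose rate (Sv/y) to a tissue of a receptor of a
# given reference age and sex, per unit activity concentration (Bq/kg wet
# weight) of soil uniformly contaminated from the surface down to depth d.
# Tables carry the FGR-15 depth grid {1, 5, 15, Inf} cm and the six reference
# ages {newborn, 1, 5, 10, 15, adult}; h(0) = 0 is implicit (empty source).

REF_AGE_LEVELS <- c("newborn", "1", "5", "10", "15", "adult")
REF_AGE_YEARS <- c(newborn = 0, `1` = 1, `5` = 5, `10` = 10, `15` = 15, adult = 20)
DEPTH_KNOTS <- c(1, 5, 15, Inf)

coeff_key <- function(nuclide, tissue, sex, ref_age) {
  paste(nuclide, tissue, sex, ref_age, sep = "\r")
}

#' Construct a dose-rate coefficient table
#'
#' Validates the long-format coefficient data and builds a keyed lookup.
#' Validation enforces `h >= 0`, monotone non-decreasing `h` with source
#' depth, and completeness: all four depths for every
#' (nuclide, tissue, sex, ref_age) and all six reference ages for every
#' (nuclide, tissue, sex).
#'
#' @param df data.frame with columns `nuclide, tissue, sex, ref_age,
#'   depth_cm, h_Sv_per_y_per_Bq_kg`; `depth_cm` in `{1, 5, 15, Inf}`
#'   (`"INF"` accepted), `ref_age` in
#'   `{newborn, 1, 5, 10, 15, adult}`, `sex` in `{male, female}`.
#' @param interpolation Depth-interpolation scheme between tabulated depths:
#'   `"shortfall"` (default) interpolates the shortfall `h(Inf) - h(d)`
#'   log-linearly in depth (exact for an exponential kernel); `"linear"`
#'   interpolates `h` piecewise-linearly with the infinite-depth value
#'   anchored at 45 cm.
#' @return An object of class `coeff_table`.
#' @export
coefficient_table <- function(df, interpolation = c("shortfall", "linear")) {
  interpolation <- match.arg(interpolation)
  required <- c("nuclide", "tissue", "sex", "ref_age", "depth_cm",
                "h_Sv_per_y_per_Bq_kg")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("coefficient table missing column(s): ",
                            paste(missing, collapse = ", "))
  df <- df[, required, drop = FALSE]
  if (is.character(df$depth_cm)) {
    df$depth_cm <- ifelse(toupper(df$depth_cm) %in% c("INF", "INFINITE"),
                          Inf, suppressWarnings(as.numeric(df$depth_cm)))
  }
  df$ref_age <- as.character(df$ref_age)
  bad_age <- setdiff(unique(df$ref_age), REF_AGE_LEVELS)
  if (length(bad_age)) stop("unknown ref_age value(s): ", paste(bad_age, collapse = ", "))
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex)) stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  bad_depth <- setdiff(unique(df$depth_cm), DEPTH_KNOTS)
  if (length(bad_depth)) stop("depth_cm must be one of 1, 5, 15, INF; found: ",
                              paste(bad_depth, collapse = ", "))
  if (anyNA(df$h_Sv_per_y_per_Bq_kg) || any(!is.finite(df$h_Sv_per_y_per_Bq_kg)) ||
      any(df$h_Sv_per_y_per_Bq_kg < 0)) {
    stop("coefficients must be finite and >= 0")
  }

  # completeness of the six reference ages per (nuclide, tissue, sex)
  triples <- unique(df[, c("nuclide", "tissue", "sex")])
  bad <- character(0)
  for (i in seq_len(nrow(triples))) {
    sub <- df[df$nuclide == triples$nuclide[i] & df$tissue == triples$tissue[i] &
                df$sex == triples$sex[i], ]
    have <- unique(sub$ref_age)
    if (!all(REF_AGE_LEVELS %in% have)) {
      bad <- c(bad, paste0(triples$nuclide[i], "/", triples$tissue[i], "/",
                           triples$sex[i], " missing age(s): ",
                           paste(setdiff(REF_AGE_LEVELS, have), collapse = ", ")))
    }
  }
  if (length(bad)) stop("incomplete reference ages:\n  ", paste(bad, collapse = "\n  "))

  # completeness of depth grid and monotonicity per key
  idx <- list()
  keys <- unique(df[, c("nuclide", "tissue", "sex", "ref_age")])
  bad <- character(0)
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$nuclide == keys$nuclide[i] & df$tissue == keys$tissue[i] &
                df$sex == keys$sex[i] & df$ref_age == keys$ref_age[i], ]
    label <- paste(keys$nuclide[i], keys$tissue[i], keys$sex[i], keys$ref_age[i], sep = "/")
    if (!setequal(sub$depth_cm, DEPTH_KNOTS) || nrow(sub) != 4) {
      bad <- c(bad, paste0(label, ": depth grid must be exactly {1, 5, 15, INF}"))
      next
    }
    h <- sub$h_Sv_per_y_per_Bq_kg[match(DEPTH_KNOTS, sub$depth_cm)]
    if (is.unsorted(h)) {
      bad <- c(bad, paste0(label, ": h(d) not monotone non-decreasing in depth"))
      next
    }
    idx[[coeff_key(keys$nuclide[i], keys$tissue[i], keys$sex[i], keys$ref_age[i])]] <- h
  }
  if (length(bad)) stop("invalid coefficient entries:\n  ", paste(bad, collapse = "\n  "))

  structure(list(data = df, index = idx, interpolation = interpolation),
            class = "coeff_table")
}

#' Read a dose-rate coefficient table from CSV
#'
#' Schema: `nuclide,tissue,sex,ref_age,depth_cm,h_Sv_per_y_per_Bq_kg` with
#' `depth_cm` in `{1,5,15,INF}`. A loader for genuine FGR-15 exports can be
#' written by mapping onto this schema.
#'
#' @inheritParams coefficient_table
#' @param path CSV path.
#' @return A `coeff_table`.
#' @export
read_coefficient_table <- function(path, interpolation = c("shortfall", "linear")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(depth_cm = "character"))
  coefficient_table(df, interpolation = match.arg(interpolation))
}

#' Write a coefficient table to CSV
#' @param table A `coeff_table`.
#' @param path Output CSV path.
#' @export
write_coefficient_table <- function(table, path) {
  df <- table$data
  df$depth_cm <- ifelse(is.infinite(df$depth_cm), "INF", as.character(df$depth_cm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

lookup_h <- function(table, nuclide, tissue, sex, ref_age) {
  h <- table$index[[coeff_key(nuclide, tissue, sex, ref_age)]]
  if (is.null(h)) {
    stop("no coefficients for key ", paste(nuclide, tissue, sex, ref_age, sep = "/"))
  }
  h
}

# Interpolate the cumulative coefficient at arbitrary depth from the four
# tabulated values hv = (h1, h5, h15, hInf). The shortfall s(d) = hInf - h(d)
# of photon kerma behind a thickening source column falls off roughly
# exponentially, so log-linear interpolation of s is used between knots
# (including d = 0 where s = hInf) and log-linear extrapolation with the
# (5, 15] segment slope beyond 15 cm. Exact for an exponential kernel.
interp_h <- function(hv, depth, mode) {
  h_inf <- hv[4]
  vapply(depth, function(d) {
    if (d <= 0) return(0)
    if (is.infinite(d)) return(h_inf)
    if (h_inf <= 0) return(0)
    if (mode == "linear") {
      dk <- c(0, 1, 5, 15, 45)
      hk <- c(0, hv[1], hv[2], hv[3], h_inf)
      if (d >= 45) return(h_inf)
      return(stats::approx(dk, hk, xout = d)$y)
    }
    dk <- c(0, 1, 5, 15)
    s <- c(h_inf, pmax(h_inf - hv[1:3], 0))
    if (d >= 15) {
      s1 <- s[3]; s2 <- s[4]
      if (s2 <= 0 || s1 <= 0) return(h_inf)
      k <- log(s2 / s1) / 10
      return(h_inf - s2 * exp(k * (d - 15)))
    }
    i <- findInterval(d, dk)
    s1 <- s[i]; s2 <- s[i + 1]
    t <- (d - dk[i]) / (dk[i + 1] - dk[i])
    if (s1 <= 0) return(h_inf)
    sd <- if (s2 <= 0) s1 * (1 - t) else s1 * (s2 / s1)^t
    h_inf - sd
  }, numeric(1))
}

#' Cumulative-depth coefficient at arbitrary depth
#'
#' Returns the dose-rate coefficient for soil uniformly contaminated from the
#' surface down to `depth_cm`, using the table's interpolation scheme between
#' tabulated depths. `h(0) = 0`; tabulated depths reproduce the table exactly;
#' `h(d)` approaches `h(Inf)` as `d` grows.
#'
#' @param table A `coeff_table`.
#' @param nuclide,tissue,sex,ref_age Key of the coefficient set.
#' @param depth_cm Depth(s) in cm, `>= 0` (may be `Inf`).
#' @return Coefficient(s) in Sv/y per Bq/kg.
#' @export
h_cumulative <- function(table, nuclide, tissue, sex, ref_age, depth_cm) {
  if (any(depth_cm < 0)) stop("depth_cm must be >= 0")
  hv <- lookup_h(table, nuclide, tissue, sex, ref_age)
  interp_h(hv, depth_cm, table$interpolation)
}

#' Coefficient for a unit-concentration slab source
#'
#' The slab occupying `[a_cm, b_cm)` has coefficient `h(b) - h(a)`, which is
#' non-negative by monotonicity of the cumulative coefficient.
#'
#' @inheritParams h_cumulative
#' @param a_cm,b_cm Slab bounds in cm, `0 <= a_cm <= b_cm` (`b_cm` may be `Inf`).
#' @return Coefficient in Sv/y per Bq/kg.
#' @export
slab_coefficient <- function(table, nuclide, tissue, sex, ref_age, a_cm, b_cm) {
  if (any(a_cm > b_cm)) stop("slab requires a_cm <= b_cm")
  h_cumulative(table, nuclide, tissue, sex, ref_age, b_cm) -
    h_cumulative(table, nuclide, tissue, sex, ref_age, a_cm)
}

age_bracket <- function(age_years) {
  # weights over the six reference-age knots {0,1,5,10,15,20}; adult plateau
  if (age_years < 0) stop("age_years must be >= 0")
  knots <- unname(REF_AGE_YEARS)
  if (age_years >= 20) return(list(i = c(6L, 6L), w = c(1, 0)))
  i <- findInterval(age_years, knots)
  if (knots[i] == age_years) return(list(i = c(i, i), w = c(1, 0)))
  t <- (age_years - knots[i]) / (knots[i + 1] - knots[i])
  list(i = c(i, i + 1L), w = c(1 - t, t))
}

#' Age-interpolated cumulative coefficient
#'
#' Piecewise-linear interpolation across the reference ages mapped to
#' \{0, 1, 5, 10, 15, 20\} years, with the adult value for ages >= 20. Depth
#' interpolation (see [h_cumulative()]) is applied within each bracketing
#' reference age before the linear mix, so the result is continuous in both
#' age and depth.
#'
#' @param table A `coeff_table`.
#' @param nuclide,tissue,sex Key of the coefficient set.
#' @param depth_cm Depth(s) in cm.
#' @param age_years Receptor age in years, `>= 0`.
#' @return Coefficient(s) in Sv/y per Bq/kg.
#' @export
age_interpolated_h <- function(table, nuclide, tissue, sex, depth_cm, age_years) {
  br <- age_bracket(age_years)
  a1 <- REF_AGE_LEVELS[br$i[1]]
  h1 <- h_cumulative(table, nuclide, tissue, sex, a1, depth_cm)
  if (br$w[2] == 0) return(h1)
  a2 <- REF_AGE_LEVELS[br$i[2]]
  h2 <- h_cumulative(table, nuclide, tissue, sex, a2, depth_cm)
  br$w[1] * h1 + br$w[2] * h2
}

# Per-nuclide slab sums of the profile at each of the six reference ages:
# PS[n, k] = sum over layers of nuclide n of C * (h(bottom+cover) - h(top+cover))
# evaluated with the k-th reference age. Because age interpolation is linear
# over the same knots for every key, any age's dose rate is the linear
# interpolation of these columns.
profile_slab_sums <- function(profile, table, tissue, sex) {
  ly <- profile$layers
  nucs <- unique(ly$nuclide)
  ps <- matrix(0, nrow = length(nucs), ncol = length(REF_AGE_LEVELS),
               dimnames = list(nucs, REF_AGE_LEVELS))
  for (nuc in nucs) {
    sub <- ly[ly$nuclide == nuc, , drop = FALSE]
    a <- sub$top_cm + profile$cover_cm
    b <- sub$bottom_cm + profile$cover_cm
    for (k in seq_along(REF_AGE_LEVELS)) {
      hv <- lookup_h(table, nuc, tissue, sex, REF_AGE_LEVELS[k])
      coefs <- interp_h(hv, b, table$interpolation) -
        interp_h(hv, a, table$interpolation)
      ps[nuc, k] <- sum(sub$conc_Bq_per_kg * coefs)
    }
  }
  ps
}

#' Instantaneous dose rate from a layered profile
#'
#' Sums, over nuclides and layers, concentration times the age-interpolated
#' slab coefficient of the layer's effective depth interval
#' `[top + cover, bottom + cover)`. Linear in every concentration.
#'
#' @param profile A `site_profile`.
#' @param table A `coeff_table` covering every nuclide in the profile.
#' @param tissue,sex Receptor tissue and sex.
#' @param age_years Receptor age in years.
#' @return Dose rate in Sv/y.
#' @export
profile_dose_rate <- function(profile, table, tissue, sex, age_years) {
  if (nrow(profile$layers) == 0) return(0)
  ps <- profile_slab_sums(profile, table, tissue, sex)
  br <- age_bracket(age_years)
  tot <- colSums(ps)
  sum(br$w * tot[br$i])
}
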