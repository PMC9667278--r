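#' Sediment core sample
#'
#' A single-nuclide activity depth profile measured on one sediment core.
#' Depths are in cm measured downward from the sediment surface; slices are
#' half-open intervals `[top_cm, bottom_cm)`, contiguous from depth 0.
#' Concentrations are Bq/kg wet weight at the sample's reference date.
#'
#' @param location_id Identifier of the coring location.
#' @param nuclide Nuclide name (e.g. `"Co-60"`).
#' @param slices data.frame with columns `top_cm`, `bottom_cm`,
#'   `conc_Bq_per_kg`.
#' @param reference_date Date (or ISO-8601 string) of activity quantification.
#' @return An object of class `core_sample`.
#' @export
core_sample <- function(location_id, nuclide, slices, reference_date) {
  stopifnot(is.data.frame(slices))
  required <- c("top_cm", "bottom_cm", "conc_Bq_per_kg")
  missing <- setdiff(required, names(slices))
  if (length(missing)) stop("slices missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(slices) == 0) stop("a core sample needs at least one slice")
  slices <- slices[order(slices$top_cm), required, drop = FALSE]
  rownames(slices) <- NULL
  check_contiguous(slices$top_cm, slices$bottom_cm,
                   what = paste0("core ", location_id, " (", nuclide, ")"))
  if (any(slices$conc_Bq_per_kg < 0)) stop("concentrations must be >= 0")
  structure(
    list(location_id = as.character(location_id),
         nuclide = as.character(nuclide),
         slices = slices,
         reference_date = as.Date(reference_date)),
    class = "core_sample"
  )
}

# Shared geometry check: half-open [top, bottom) intervals, contiguous from 0.
check_contiguous <- function(top, bottom, what = "profile") {
  if (any(bottom <= top)) stop(what, ": slice bottoms must exceed tops")
  if (abs(top[1]) > 1e-12) stop(what, ": first slice must start at depth 0")
  n <- length(top)
  if (n > 1 && any(abs(top[-1] - bottom[-n]) > 1e-9)) {
    stop(what, ": slices must be contiguous and non-overlapping")
  }
  invisible(TRUE)
}

#' Layered site activity profile
#'
#' Piecewise-constant activity concentration versus depth, possibly for
#' several nuclides, with an optional thickness of clean (uncontaminated)
#' cover soil on top. Stored layer coordinates are relative to the top of the
#' contaminated material; the cover shifts the layers' effective depths as
#' seen by the dose-rate kernels.
#'
#' @param layers data.frame with columns `nuclide`, `top_cm`, `bottom_cm`,
#'   `conc_Bq_per_kg`. Zero rows are allowed (fully remediated site). The
#'   deepest layer's `bottom_cm` may be `Inf`.
#' @param cover_cm Clean-cover thickness in cm, `>= 0`.
#' @param reference_date Date the concentrations refer to.
#' @return An object of class `site_profile`.
#' @export
site_profile <- function(layers, cover_cm = 0, reference_date) {
  required <- c("nuclide", "top_cm", "bottom_cm", "conc_Bq_per_kg")
  missing <- setdiff(required, names(layers))
  if (length(missing)) stop("layers missing column(s): ", paste(missing, collapse = ", "))
  layers <- layers[, required, drop = FALSE]
  layers <- layers[order(layers$nuclide, layers$top_cm), , drop = FALSE]
  rownames(layers) <- NULL
  if (nrow(layers) > 0) {
    if (any(layers$conc_Bq_per_kg < 0)) stop("concentrations must be >= 0")
    for (nuc in unique(layers$nuclide)) {
      sub <- layers[layers$nuclide == nuc, , drop = FALSE]
      check_contiguous(sub$top_cm, sub$bottom_cm, what = paste0("profile (", nuc, ")"))
    }
  }
  if (length(cover_cm) != 1 || !is.finite(cover_cm) || cover_cm < 0) {
    stop("cover_cm must be a single number >= 0")
  }
  structure(
    list(layers = layers, cover_cm = cover_cm,
         reference_date = as.Date(reference_date)),
    class = "site_profile"
  )
}

#' @export
print.site_profile <- function(x, ...) {
  cat("<site_profile> ", nrow(x$layers), " layer(s), cover ", x$cover_cm,
      " cm, reference date ", format(x$reference_date), "\n", sep = "")
  if (nrow(x$layers)) print(x$layers)
  invisible(x)
}

#' Apply physical decay up to a target date
#'
#' Multiplies every concentration by `exp(-lambda * dt)` with `dt` the elapsed
#' time in years and `lambda` the nuclide's decay constant. Back-decay
#' (a target date before the reference date) is refused.
#'
#' @param x A `site_profile` or `core_sample`.
#' @param target_date Date to decay to (must be `>=` the reference date).
#' @param nuclides Nuclide registry (see [nuclide_registry()]).
#' @return Object of the same class with decayed concentrations and updated
#'   reference date; geometry unchanged.
#' @export
decay_to_date <- function(x, target_date, nuclides = nuclide_registry()) {
  UseMethod("decay_to_date")
}

#' @export
decay_to_date.site_profile <- function(x, target_date, nuclides = nuclide_registry()) {
  dt <- years_between(x$reference_date, target_date)
  if (dt < 0) stop("target_date precedes the profile reference date; no back-decay")
  if (nrow(x$layers)) {
    lam <- decay_constants(x$layers$nuclide, nuclides)
    x$layers$conc_Bq_per_kg <- x$layers$conc_Bq_per_kg * exp(-lam * dt)
  }
  x$reference_date <- as.Date(target_date)
  x
}

#' @export
decay_to_date.core_sample <- function(x, target_date, nuclides = nuclide_registry()) {
  dt <- years_between(x$reference_date, target_date)
  if (dt < 0) stop("target_date precedes the sample reference date; no back-decay")
  lam <- decay_constants(x$nuclide, nuclides)
  x$slices$conc_Bq_per_kg <- x$slices$conc_Bq_per_kg * exp(-lam * dt)
  x$reference_date <- as.Date(target_date)
  x
}

#' Conservative site profile from several core samples
#'
#' For each depth bin (the union of all slice boundaries) and nuclide, takes
#' the maximum concentration over all cores covering that bin: the simplest
#' envelope dominating every measured profile. Shallower cores do not
#' constrain bins below their deepest slice. All samples must share a common
#' reference date (decay them first).
#'
#' @param samples List of `core_sample` objects.
#' @param below Treatment of depths below the deepest sampled slice:
#'   `"zero"` (default; profile ends there) or `"extend"` (the deepest bin of
#'   each nuclide is extended to infinite depth — a deliberately conservative
#'   assumption for cores that did not reach clean sediment).
#' @return A `site_profile` with `cover_cm = 0`.
#' @export
build_conservative_profile <- function(samples, below = c("zero", "extend")) {
  below <- match.arg(below)
  if (!length(samples)) stop("need at least one core sample")
  if (!all(vapply(samples, inherits, logical(1), "core_sample"))) {
    stop("samples must be core_sample objects")
  }
  dates <- unique(vapply(samples, function(s) format(s$reference_date), character(1)))
  if (length(dates) > 1) {
    stop("samples have mixed reference dates (", paste(dates, collapse = ", "),
         "); decay them to a common date first")
  }
  nucs <- unique(vapply(samples, function(s) s$nuclide, character(1)))
  out <- list()
  for (nuc in nucs) {
    sub <- Filter(function(s) s$nuclide == nuc, samples)
    bounds <- sort(unique(unlist(lapply(sub, function(s) c(s$slices$top_cm, s$slices$bottom_cm)))))
    tops <- bounds[-length(bounds)]
    bots <- bounds[-1]
    conc <- vapply(seq_along(tops), function(i) {
      mid <- (tops[i] + bots[i]) / 2
      vals <- unlist(lapply(sub, function(s) {
        j <- which(s$slices$top_cm <= mid & mid < s$slices$bottom_cm)
        if (length(j)) s$slices$conc_Bq_per_kg[j] else NULL
      }))
      if (length(vals)) max(vals) else 0
    }, numeric(1))
    if (below == "extend") bots[length(bots)] <- Inf
    out[[nuc]] <- data.frame(nuclide = nuc, top_cm = tops, bottom_cm = bots,
                             conc_Bq_per_kg = conc, stringsAsFactors = FALSE)
  }
  site_profile(do.call(rbind, out), cover_cm = 0,
               reference_date = samples[[1]]$reference_date)
}

#' Remove the top layer of contaminated sediment
#'
#' Deletes the uppermost `x_cm` of contaminated material; the remaining layers
#' shift upward so the new surface is at depth 0 (partial layers are
#' truncated). Removal is refused when clean cover is present: the remediation
#' scenarios treat removal and covering as mutually exclusive actions.
#'
#' @param profile A `site_profile`.
#' @param x_cm Thickness to remove, cm `>= 0`.
#' @return The remediated `site_profile`.
#' @export
remove_top <- function(profile, x_cm) {
  if (length(x_cm) != 1 || is.na(x_cm) || x_cm < 0) stop("x_cm must be a single number >= 0")
  if (x_cm == 0) return(profile)
  if (profile$cover_cm > 0) {
    stop("cannot remove sediment from a covered profile; removal and cover are exclusive")
  }
  ly <- profile$layers
  ly <- ly[ly$bottom_cm > x_cm, , drop = FALSE]
  if (nrow(ly)) {
    ly$top_cm <- pmax(ly$top_cm, x_cm) - x_cm
    ly$bottom_cm <- ly$bottom_cm - x_cm
  }
  profile$layers <- ly
  # revalidate geometry via the constructor
  site_profile(ly, cover_cm = profile$cover_cm,
               reference_date = profile$reference_date)
}

#' Add clean soil cover on top of the profile
#'
#' Increases the clean-cover thickness; contaminated layers keep their stored
#' coordinates but their effective depths, as seen by the dose-rate kernels,
#' shift down by the cover thickness. The cover is assumed radiologically
#' equivalent to the reference soil of the coefficient tables, so its
#' shielding is realized purely by this depth shift.
#'
#' @param profile A `site_profile`.
#' @param x_cm Cover thickness to add, cm `>= 0`.
#' @return The covered `site_profile`.
#' @export
add_cover <- function(profile, x_cm) {
  if (length(x_cm) != 1 || is.na(x_cm) || x_cm < 0) stop("x_cm must be a single number >= 0")
  profile$cover_cm <- profile$cover_cm + x_cm
  profile
}

#' Read core samples from a profile CSV
#'
#' Schema: `location_id,nuclide,top_cm,bottom_cm,conc_Bq_per_kg,reference_date`
#' (ISO-8601 dates). One file may hold many cores and nuclides.
#'
#' @param path CSV path.
#' @return A list of `core_sample` objects.
#' @export
read_core_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("location_id", "nuclide", "top_cm", "bottom_cm",
                "conc_Bq_per_kg", "reference_date")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("profile CSV missing column(s): ", paste(missing, collapse = ", "))
  keys <- unique(df[, c("location_id", "nuclide")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$location_id == keys$location_id[i] & df$nuclide == keys$nuclide[i], ]
    dates <- unique(sub$reference_date)
    if (length(dates) > 1) {
      stop("core ", keys$location_id[i], "/", keys$nuclide[i],
           " has multiple reference dates")
    }
    core_sample(keys$location_id[i], keys$nuclide[i],
                sub[, c("top_cm", "bottom_cm", "conc_Bq_per_kg")], dates)
  })
}

#' Write core samples to a profile CSV
#'
#' @param samples List of `core_sample` objects.
#' @param path Output CSV path.
#' @export
write_core_samples <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    data.frame(location_id = s$location_id, nuclide = s$nuclide,
               top_cm = s$slices$top_cm, bottom_cm = s$slices$bottom_cm,
               conc_Bq_per_kg = s$slices$conc_Bq_per_kg,
               reference_date = format(s$reference_date),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
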