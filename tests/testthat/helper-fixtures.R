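# Shared analytic fixtures. The exponential kernel
#   h(d) = h_inf * age_factor * (1 - exp(-d / rho))
# has closed forms for every quantity downstream, so most oracles below are
# one-line formulas evaluated independently of the package's interpolation
# and quadrature paths.

flat_ages <- c(newborn = 1, `1` = 1, `5` = 1, `10` = 1, `15` = 1, adult = 1)

# single-nuclide, single-tissue exponential-kernel config; age factors and
# tissue factor default to 1 so closed forms are bare exponentials
oracle_config <- function(seed = 1, h_inf = 1e-6, rho = 10,
                          age_factors = flat_ages,
                          surf = 1000, sigma = 0, relax = 10,
                          nuclide = "Co-60") {
  kern_hinf <- stats::setNames(h_inf, nuclide)
  synthetic_config(
    seed = seed,
    nuclides = data.frame(name = nuclide, surf_min = surf, surf_max = surf,
                          relaxation_cm = relax, sigma = sigma,
                          clip_min = 0, clip_max = Inf,
                          stringsAsFactors = FALSE),
    kernel = list(h_inf = kern_hinf, relaxation_cm = rho,
                  age_factors = age_factors,
                  tissues = "colon", tissue_factors = c(colon = 1)))
}

oracle_table <- function(...) gen_coefficient_table(oracle_config(...))

# uniform semi-infinite (or finite) single-nuclide profile
uniform_profile <- function(conc = 1000, bottom = Inf, cover = 0,
                            nuclide = "Co-60", date = "2020-01-01") {
  site_profile(data.frame(nuclide = nuclide, top_cm = 0, bottom_cm = bottom,
                          conc_Bq_per_kg = conc, stringsAsFactors = FALSE),
               cover_cm = cover, reference_date = date)
}

# closed form of the exponential kernel: cumulative coefficient at depth d
h_closed <- function(d, h_inf = 1e-6, rho = 10) h_inf * (1 - exp(-d / rho))

# constant-hazard life table (S = exp(-mu a)) with constant baseline rates
const_hazard_lt <- function(mu = 0.01, rate = 0.001, sites = "stomach") {
  ages <- 0:110
  surv <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    data.frame(age = ages, sex = sx, S = exp(-mu * ages))
  }))
  rates <- do.call(rbind, lapply(sites, function(s) {
    do.call(rbind, lapply(c("male", "female"), function(sx) {
      data.frame(site = s, sex = sx, age = ages, rate_per_year = rate)
    }))
  }))
  life_table(surv, rates)
}

# degenerate parameter row making M(D, e, a) constant: M = D * beta * lambda
const_rate_params <- function(beta = 1, sites = "stomach", latency = 5) {
  risk_params(do.call(rbind, lapply(sites, function(s) {
    do.call(rbind, lapply(c("male", "female"), function(sx) {
      data.frame(site = s, sex = sx, beta_err = beta, beta_ear = 0,
                 gamma = 0, eta = 0, w = 1, ddref = 1, latency_y = latency,
                 stringsAsFactors = FALSE)
    }))
  })))
}

# a long-lived pseudo-nuclide so exposure-time decay is negligible
stable_registry <- function(nuclide = "Co-60") {
  data.frame(name = nuclide, half_life_years = 1e9, stringsAsFactors = FALSE)
}

# registry with a chosen decay constant (1/y)
lambda_registry <- function(lambda, nuclide = "Co-60") {
  data.frame(name = nuclide, half_life_years = log(2) / lambda,
             stringsAsFactors = FALSE)
}

# brute-force microslab dose rate under the closed-form exponential kernel:
# independent oracle for profile_dose_rate (age factors interpolated with
# stats::approx over the reference-age knots)
microslab_rate <- function(profile, h_inf, rho, age, age_factors = flat_ages,
                           step = 0.1, max_depth = 200) {
  fac <- stats::approx(c(0, 1, 5, 10, 15, 20), unname(age_factors),
                       xout = min(age, 20), rule = 2)$y
  total <- 0
  for (i in seq_len(nrow(profile$layers))) {
    row <- profile$layers[i, ]
    a <- row$top_cm + profile$cover_cm
    b <- min(row$bottom_cm + profile$cover_cm, max_depth)
    if (b <= a) next
    edges <- seq(a, b, by = step)
    if (edges[length(edges)] < b) edges <- c(edges, b)
    h <- h_closed(edges, h_inf, rho) * fac
    total <- total + row$conc_Bq_per_kg * sum(diff(h))
  }
  total
}

# full synthetic input bundle for scenario-level tests
synthetic_bundle <- function(seed = 1, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  profile <- build_conservative_profile(gen_core_samples(cfg))
  inputs <- scenario_inputs(gen_coefficient_table(cfg), icrp103_weights(),
                            gen_risk_params(cfg), gen_life_table(cfg))
  list(cfg = cfg, profile = profile, inputs = inputs)
}
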