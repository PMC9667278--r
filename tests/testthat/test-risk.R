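test_that("excess rate evaluates the mixed ERR/EAR form and is linear in dose", {
  par <- risk_params(data.frame(site = "stomach", sex = "male",
                                beta_err = 0.5, beta_ear = 0, gamma = 0,
                                eta = 0, w = 1, ddref = 1.5, latency_y = 5))
  expect_equal(excess_rate(0, 30, 50, par, 0.002), 0)
  expect_equal(excess_rate(0.2, 30, 50, par, 0.002),
               2 * excess_rate(0.1, 30, 50, par, 0.002))
  expect_equal(excess_rate(0.1, 30, 50, par, 0.002), 0.1 / 1.5 * 0.5 * 0.002,
               tolerance = 1e-12)
  expect_error(excess_rate(-0.1, 30, 50, par, 0.002), ">= 0")
  expect_error(excess_rate(0.1, 50, 30, par, 0.002), "attained age")

  # exposure-age and attained-age modifiers enter as exp(gamma e*) (a/60)^eta
  par2 <- risk_params(data.frame(site = "stomach", sex = "male",
                                 beta_err = 0.5, beta_ear = 2e-4, gamma = -0.3,
                                 eta = -1.4, w = 0.7, ddref = 1.5, latency_y = 5))
  e <- 20; a <- 50; lam <- 0.003; D <- 0.05
  phi <- exp(-0.3 * (min(e, 30) - 30) / 10) * (a / 60)^-1.4
  expect_equal(excess_rate(D, e, a, par2, lam),
               D / 1.5 * (0.7 * 0.5 * phi * lam + 0.3 * 2e-4 * phi),
               tolerance = 1e-12)
  # exposure-age modifier saturates at e = 30
  expect_equal(excess_rate(D, 30, a, par2, lam), excess_rate(D, 45, a, par2, lam))
})

test_that("site LAR matches the constant-hazard closed form", {
  lt <- const_hazard_lt(mu = 0.01, rate = 0.001)
  par <- const_rate_params(beta = 1)  # M = D * lambda_base = 0.001 at D = 1
  lar <- site_lar(1, 30, "male", "stomach", par, lt)
  closed <- 0.001 * (1 - exp(-0.01 * (110 - 35))) / 0.01
  expect_equal(lar, closed, tolerance = 1e-6)
  expect_equal(site_lar(0, 30, "male", "stomach", par, lt), 0)

  # immortal cohort: LAR = m * (110 - e - L) exactly
  lt1 <- const_hazard_lt(mu = 0, rate = 0.001)
  expect_equal(site_lar(1, 30, "male", "stomach", par, lt1),
               0.001 * (110 - 35), tolerance = 1e-12)

  # empty integration range warns and returns 0
  expect_warning(z <- site_lar(1, 106, "male", "stomach", par, lt), "empty")
  expect_equal(z, 0)
})

test_that("LAR quadrature agrees with a 0.01-year trapezoid brute force", {
  set.seed(7)
  for (k in 1:20) {
    gomp <- k %% 2 == 0
    cfg <- synthetic_config(
      seed = k,
      life = if (gomp) list(model = "gompertz", alpha = 5e-5, beta = 0.09)
      else list(model = "constant", mu = runif(1, 0.005, 0.02)),
      baseline = list(rate = runif(1, 5e-4, 5e-3), power = sample(0:2, 1)))
    lt <- gen_life_table(cfg, sites = "stomach")
    par <- risk_params(data.frame(
      site = "stomach", sex = "female",
      beta_err = runif(1, 0, 1), beta_ear = runif(1, 0, 1e-3),
      gamma = runif(1, -0.5, 0), eta = runif(1, -2, 1),
      w = runif(1), ddref = runif(1, 1, 2),
      latency_y = sample(c(2, 5), 1)))
    e <- sample(0:80, 1)
    D <- runif(1, 0.001, 0.1)
    got <- site_lar(D, e, "female", "stomach", par, lt)
    lower <- e + par$latency_y
    a <- seq(lower, 110, by = 0.01)
    f <- excess_rate(D, e, a, par, baseline_rate_at(lt, "stomach", "female", a)) *
      survival_at(lt, "female", a) / survival_at(lt, "female", lower)
    oracle <- sum((f[-1] + f[-length(f)]) / 2) * 0.01
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("LAR is scale-free in survival and linear in dose", {
  lt <- const_hazard_lt(mu = 0.012, rate = 0.002)
  par <- const_rate_params(beta = 0.4)
  base <- site_lar(0.05, 25, "male", "stomach", par, lt)

  scaled <- lt
  surv <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    data.frame(age = 0:110, sex = sx, S = 0.5 * exp(-0.012 * (0:110)))
  }))
  lt_scaled <- life_table(surv, lt$rates, strict = FALSE)
  expect_equal(site_lar(0.05, 25, "male", "stomach", par, lt_scaled), base,
               tolerance = 1e-12)

  expect_equal(site_lar(0.1, 25, "male", "stomach", par, lt), 2 * base,
               tolerance = 1e-12)
})

test_that("total LAR sums sites and demands a dose for every site", {
  lt <- const_hazard_lt(sites = c("stomach", "colon"))
  par <- const_rate_params(sites = c("stomach", "colon"))
  res <- total_lar(list(stomach = 0.01, colon = 0.01), 30, "male", par, lt)
  expect_equal(res$total, sum(res$by_site$LAR), tolerance = 1e-12)
  expect_equal(res$by_site$LAR[1], res$by_site$LAR[2])  # identical inputs
  zero <- total_lar(list(stomach = 0, colon = 0), 30, "male", par, lt)
  expect_equal(zero$total, 0)
  one <- total_lar(list(stomach = 0.01, colon = 0), 30, "male", par, lt)
  expect_equal(one$total, one$by_site$LAR[one$by_site$site == "stomach"])
  expect_error(total_lar(list(stomach = 0.01), 30, "male", par, lt),
               "no organ dose")
})

test_that("LAR by age reflects risk-model structure through the pipeline", {
  tab <- oracle_table()
  p <- uniform_profile(1000)
  lt <- const_hazard_lt(sites = "colon")
  map <- data.frame(site = "colon", tissue = "colon")

  zero_tab <- lar_by_age_and_sex(uniform_profile(0), tab,
                                 const_rate_params(sites = "colon"), lt,
                                 site_map = map, ages = c(20, 50),
                                 nuclides = stable_registry())
  expect_true(all(zero_tab$LAR == 0))

  # declining excess rates with exposure age: LAR(70) < LAR(20)
  par <- risk_params(do.call(rbind, lapply(c("male", "female"), function(sx) {
    data.frame(site = "colon", sex = sx, beta_err = 0.5, beta_ear = 0,
               gamma = -0.3, eta = -1.4, w = 1, ddref = 1.5, latency_y = 5)
  })))
  res <- lar_by_age_and_sex(p, tab, par, lt, site_map = map, ages = c(20, 70),
                            nuclides = stable_registry())
  m <- res[res$sex == "male", ]
  expect_lt(m$LAR[m$age_at_exposure == 70], m$LAR[m$age_at_exposure == 20])

  # female beta = 1.2 x male with all else equal: ratio 1.2 at every age
  par12 <- par
  par12$beta_err[par12$sex == "female"] <- 0.5 * 1.2
  res12 <- lar_by_age_and_sex(p, tab, par12, lt, site_map = map,
                              ages = c(10, 40, 70), nuclides = stable_registry())
  for (a in c(10, 40, 70)) {
    fm <- res12$LAR[res12$age_at_exposure == a & res12$sex == "female"]
    ml <- res12$LAR[res12$age_at_exposure == a & res12$sex == "male"]
    expect_equal(fm / ml, 1.2, tolerance = 1e-9)
  }
})

test_that("life table and risk parameter validation reject bad input", {
  ages <- 0:110
  surv <- data.frame(age = ages, sex = "male", S = exp(-0.01 * ages))
  rates <- data.frame(site = "stomach", sex = "male", age = ages,
                      rate_per_year = 0.001)
  expect_silent(life_table(surv, rates))
  inc <- surv; inc$S[50] <- inc$S[40]  # increase at age 49 -> 50? make increasing
  inc$S[50] <- 1.5 * inc$S[49]
  expect_error(life_table(inc, rates), "non-increasing|\\(0, 1\\]")
  s0 <- surv; s0$S <- 0.9 * s0$S
  expect_error(life_table(s0, rates), "S\\(0\\)")
  expect_silent(life_table(s0, rates, strict = FALSE))
  badr <- rates; badr$rate_per_year[3] <- -1
  expect_error(life_table(surv, badr), ">= 0")

  expect_error(risk_params(data.frame(site = "a", sex = "male", beta_err = 1,
                                      beta_ear = 0, gamma = 0, eta = 0, w = 2,
                                      ddref = 1, latency_y = 5)), "w must")
  expect_error(risk_params(data.frame(site = "a", sex = "male", beta_err = 1,
                                      beta_ear = 0, gamma = 0, eta = 0, w = 1,
                                      ddref = 0.5, latency_y = 5)), "ddref")
})
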