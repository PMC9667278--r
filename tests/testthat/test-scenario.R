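oracle_inputs <- function(cfg) {
  scenario_inputs(gen_coefficient_table(cfg), tissue_weights(c(colon = 1)),
                  const_rate_params(sites = "colon"),
                  const_hazard_lt(sites = "colon"),
                  site_map = data.frame(site = "colon", tissue = "colon"),
                  nuclides = stable_registry())
}

test_that("remediation actions normalize and apply correctly", {
  expect_equal(remediation_action("remove", 0)$kind, "none")
  expect_error(remediation_action("none", 3), "amount_cm == 0")
  expect_error(remediation_action("add", -1), ">= 0")
  p <- uniform_profile(100, bottom = 20)
  expect_identical(apply_action(p, remediation_action("none")), p)
  expect_equal(apply_action(p, remediation_action("add", 7))$cover_cm, 7)
  expect_equal(nrow(apply_action(p, remediation_action("remove", 30))$layers), 0)
})

test_that("sweep reductions follow the closed form of the exponential kernel", {
  cfg <- oracle_config()
  inputs <- oracle_inputs(cfg)
  p <- uniform_profile(1000)  # infinite uniform source
  sw <- remediation_sweep(p, inputs, list(remediation_action("add", 10)),
                          ages = 30)
  none <- sw[sw$kind == "none", ]
  expect_equal(none$dose_reduction_fraction, 0)
  add10 <- sw[sw$kind == "add", ]
  expect_equal(add10$dose_reduction_fraction, 1 - exp(-1), tolerance = 1e-8)
  # removing at least the whole contaminated depth empties the source
  p_fin <- uniform_profile(1000, bottom = 20)
  sw_fin <- remediation_sweep(p_fin, inputs,
                              list(remediation_action("remove", 25)), ages = 30)
  gone <- sw_fin[sw_fin$kind == "remove", ]
  expect_equal(gone$E_mSv, 0)
  expect_equal(gone$dose_reduction_fraction, 1)
  expect_equal(gone$lar_total_male, 0)
  # consistency: sweep E equals evaluating the remediated profile directly
  E_direct <- 1e3 * weighted_dose(add_cover(p, 10), inputs$table, inputs$weights,
                                  30, "average", nuclides = stable_registry())
  expect_equal(add10$E_mSv, E_direct, tolerance = 1e-12)
})

test_that("dose and LAR are monotone in remediation depth on synthetic sites", {
  amounts <- c(0, 5, 10, 20, 30)
  for (seed in 1:4) {
    bun <- synthetic_bundle(seed = seed, n_cores = 3)
    actions <- c(lapply(amounts[-1], function(x) remediation_action("remove", x)),
                 lapply(amounts[-1], function(x) remediation_action("add", x)))
    sw <- remediation_sweep(bun$profile, bun$inputs, actions, ages = 30)
    for (kind in c("remove", "add")) {
      sub <- sw[sw$kind %in% c("none", kind), ]
      sub <- sub[order(sub$amount_cm), ]
      expect_true(all(diff(sub$E_mSv) <= 1e-12))
      expect_true(all(diff(sub$lar_total_male) <= 1e-12))
      expect_true(all(diff(sub$lar_total_female) <= 1e-12))
      expect_true(all(sub$dose_reduction_fraction >= 0 &
                        sub$dose_reduction_fraction <= 1))
    }
  }
})

test_that("limit search matches the analytic cover depth and the grid scan", {
  cfg <- oracle_config(h_inf = 7.6e-6)  # baseline E = 7.6 mSv
  inputs <- oracle_inputs(cfg)
  p <- uniform_profile(1000)
  for (res in c(1, 0.5)) {
    found <- depth_to_meet_limit(p, inputs, "add", limit_mSv = 0.1, age = 30,
                                 resolution_cm = res, max_depth_cm = 60)
    exact <- 10 * log(7.6 / 0.1)
    expect_lte(found - exact, res)
    expect_gte(found, exact - 1e-9)
    # exhaustive scan oracle
    grid <- seq(0, 60, by = res)
    E <- vapply(grid, function(x) {
      1e3 * weighted_dose(add_cover(p, x), inputs$table, inputs$weights, 30,
                          "average", nuclides = stable_registry())
    }, numeric(1))
    expect_equal(found, grid[which(E <= 0.1)[1]])
  }
  # removal only helps when activity declines with depth: use the noise-free
  # exponential sediment profile and check against the exhaustive scan
  p_exp <- build_conservative_profile(gen_core_samples(cfg))
  found_rm <- depth_to_meet_limit(p_exp, inputs, "remove", limit_mSv = 0.1,
                                  age = 30, resolution_cm = 1, max_depth_cm = 60)
  grid_rm <- seq(0, 60, by = 1)
  E_rm <- vapply(grid_rm, function(x) {
    1e3 * weighted_dose(remove_top(p_exp, x), inputs$table, inputs$weights, 30,
                        "average", nuclides = stable_registry())
  }, numeric(1))
  expect_equal(found_rm, grid_rm[which(E_rm <= 0.1)[1]])

  # baseline already below the limit
  expect_equal(depth_to_meet_limit(p, inputs, "add", limit_mSv = 50, age = 30), 0)
  # unreachable limit reports the residual dose
  expect_error(depth_to_meet_limit(p, inputs, "add", limit_mSv = 1e-9, age = 30,
                                   max_depth_cm = 20), "not reached")
})

test_that("limit search agrees with exhaustive scan on synthetic fixtures", {
  for (seed in 1:3) {
    bun <- synthetic_bundle(seed = seed, n_cores = 3)
    for (kind in c("remove", "add")) {
      found <- depth_to_meet_limit(bun$profile, bun$inputs, kind,
                                   limit_mSv = 0.1, age = 20,
                                   resolution_cm = 2, max_depth_cm = 80)
      grid <- seq(0, 80, by = 2)
      E <- vapply(grid, function(x) {
        p <- apply_action(bun$profile,
                          remediation_action(if (x == 0) "none" else kind, x))
        1e3 * weighted_dose(p, bun$inputs$table, bun$inputs$weights, 20, "average")
      }, numeric(1))
      expect_equal(found, grid[which(E <= 0.1)[1]])
    }
  }
})

test_that("the report runner is deterministic and handles edge configs", {
  dir <- withr::local_tempdir()
  quick <- list(synthetic = list(seed = 11, n_cores = 3),
                scenario = list(lar_ages = c(0, 30, 60),
                                sweep_amounts_cm = c(0, 10, 20),
                                limit_max_depth_cm = 80))
  paths <- run_report(quick, out_dir = file.path(dir, "a"))
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 0))
  snap <- lapply(paths, function(p) readBin(p, "raw", file.size(p)))
  paths2 <- run_report(quick, out_dir = file.path(dir, "a"))
  for (i in seq_along(paths2)) {
    expect_identical(readBin(paths2[i], "raw", file.size(paths2[i])), snap[[i]])
  }
  man <- jsonlite::read_json(paths[["manifest.json"]])
  expect_equal(man$seed, 11)
  expect_equal(man$package, "sedidose")

  # zero-activity site: all dose and LAR tables are zero
  zero <- list(synthetic = list(
    seed = 1, n_cores = 2,
    nuclides = data.frame(name = "Co-60", surf_min = 0, surf_max = 0,
                          relaxation_cm = 10, sigma = 0,
                          clip_min = 0, clip_max = 0)),
    scenario = list(lar_ages = c(0, 30), sweep_amounts_cm = c(0, 10)))
  pz <- run_report(zero, out_dir = file.path(dir, "z"))
  expect_true(all(read.csv(pz[["dose_by_age.csv"]])$E_Sv == 0))
  expect_true(all(read.csv(pz[["lar_by_age_sex.csv"]])$LAR == 0))
})

test_that("a YAML config file drives the report", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.yaml")
  writeLines(c("synthetic:", "  seed: 21", "  n_cores: 2",
               "scenario:", "  lar_ages: [30]", "  sweep_amounts_cm: [0, 10]",
               "output:", paste0("  dir: ", file.path(dir, "out"))), cfg_path)
  paths <- run_report(cfg_path)
  expect_true(file.exists(paths[["dose_by_age.csv"]]))
  expect_equal(jsonlite::read_json(paths[["manifest.json"]])$seed, 21)
})
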