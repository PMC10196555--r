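test_that("fitness table composes dominance, cost and incomplete resistance", {
  ft <- fitness_table(h = 0.79, cost = 0.36, incomplete_resistance = 0.49,
                      w_ss_bt = 0)
  ref <- ft[ft$habitat == "refuge", ]
  bt <- ft[ft$habitat == "bt_cotton", ]
  expect_equal(ref$w_ss, 1)
  expect_equal(ref$w_rs, 1)
  expect_equal(ref$w_rr, 0.64)
  expect_equal(bt$w_rr, 0.3136)
  expect_equal(bt$w_rs, 0.247744)
  expect_equal(bt$w_ss, 0)

  # degenerate corners: fully recessive / fully dominant, no cost
  rec <- fitness_table(h = 0, cost = 0, incomplete_resistance = 1)
  expect_equal(unname(unlist(rec[rec$habitat == "bt_cotton",
                                 c("w_ss", "w_rs", "w_rr")])), c(0, 0, 1))
  dom <- fitness_table(h = 1, cost = 0, incomplete_resistance = 1)
  expect_equal(unname(unlist(dom[dom$habitat == "bt_cotton",
                                 c("w_ss", "w_rs", "w_rr")])), c(0, 1, 1))

  expect_error(fitness_table(h = 1.2), "h")
  expect_error(fitness_table(cost = -0.1), "cost")

  # the alternative reading takes incomplete resistance as rr fitness on Bt
  alt <- fitness_table(mode = "absolute")
  expect_equal(alt$w_rr[alt$habitat == "bt_cotton"], 0.49)
})

test_that("habitat fitness is the refuge-weighted linear mixture", {
  ft <- paper_fitness()
  expect_equal(unname(habitat_fitness(ft, 1)), c(1, 1, 0.64))
  expect_equal(unname(habitat_fitness(ft, 0)), c(0, 0.247744, 0.3136))
  expect_equal(unname(habitat_fitness(ft, 0.5)), c(0.5, 0.623872, 0.4768))
  expect_error(habitat_fitness(ft, 1.5), "refuge_fraction")
})

test_that("one-generation recursion matches hand values and errors on extinction", {
  expect_equal(advance_generation(0.5, c(1, 1, 1)), 0.5)
  w_bt <- c(0, 0.247744, 0.3136)
  expect_equal(advance_generation(0.5, w_bt), 0.6938, tolerance = 1e-4)
  expect_equal(advance_generation(0.001, w_bt), 0.5003, tolerance = 1e-4)
  expect_error(advance_generation(0.5, c(0, 0, 0)), "extinct")
  # p = 0 with w_ss = 0 is also an extinct population
  expect_error(advance_generation(0, w_bt), "extinct")
})

test_that("recursion agrees with the genotype-enumeration oracle", {
  set.seed(42)
  for (i in 1:200) {
    p <- runif(1)
    w <- runif(3)
    wbar <- p^2 * w[3] + 2 * p * (1 - p) * w[2] + (1 - p)^2 * w[1]
    if (wbar <= 0) next
    expect_lt(abs(advance_generation(p, w) -
                    oracle_advance(p, w[1], w[2], w[3])), 1e-12)
  }
})

test_that("selection recursion keeps p in [0,1], is neutral-invariant and monotone", {
  set.seed(7)
  for (i in 1:100) {
    p <- runif(1)
    # neutrality: equal fitnesses leave p unchanged to machine precision
    wc <- runif(1, 0.1, 1)
    expect_equal(advance_generation(p, rep(wc, 3)), p, tolerance = 1e-15)
    # conservation
    w <- runif(3, 0.05, 1)
    p2 <- advance_generation(p, w)
    expect_gte(p2, 0)
    expect_lte(p2, 1)
    # monotone selection: w_rr >= w_rs >= w_ss with a strict step raises p
    w_mono <- sort(runif(3, 0.05, 1))
    if (w_mono[3] > w_mono[1] && p > 0 && p < 1) {
      expect_gt(advance_generation(p, w_mono), p)
    }
  }
})

test_that("overdominance equilibrium matches closed form and long iteration", {
  expect_true(is.na(overdominance_equilibrium(c(1, 1, 1))))
  expect_equal(overdominance_equilibrium(c(0.9, 1.0, 0.8)), 1 / 3,
               tolerance = 1e-10)

  w90 <- habitat_fitness(paper_fitness(), 0.90)
  expect_equal(overdominance_equilibrium(w90), 0.0724, tolerance = 1e-3)

  for (w in list(c(0.9, 1.0, 0.8), unname(w90),
                 unname(habitat_fitness(paper_fitness(), 0.85)))) {
    pstar <- overdominance_equilibrium(w)
    expect_lt(abs(oracle_equilibrium_by_iteration(w) - pstar), 1e-6)
    # equilibrium is a fixed point of the recursion
    expect_equal(advance_generation(pstar, w), pstar, tolerance = 1e-12)
  }
})

test_that("trajectories honour the scenario contract", {
  # pure refuge without cost: no selection at all, p stays at p0
  flat <- simulate_trajectory(scenario(
    refuge = 1, fitness = fitness_table(cost = 0)))
  expect_equal(flat$p, rep(0.001, nrow(flat)))
  expect_equal(flat$year, 2006:2020)

  # no refuge with the empirical parameters: past 0.75 entering 2007
  no_ref <- simulate_trajectory(scenario(refuge = 0))
  expect_equal(no_ref$p[no_ref$year == 2006], 0.001)
  expect_gte(no_ref$p[no_ref$year == 2007], 0.75)
  expect_true(all(no_ref$p >= 0 & no_ref$p <= 1))

  # missing refuge years are a configuration error naming the year
  expect_error(
    scenario(refuge = tibble::tibble(year = 2006:2010, refuge = 0.5)),
    "2011"
  )
})

test_that("full-refuge trajectory is slower than no-refuge every year", {
  series <- refuge_series_from_regression(2006:2019)
  full <- simulate_trajectory(scenario(refuge = series))
  none <- simulate_trajectory(scenario(refuge = 0))
  after <- full$year > 2006
  expect_true(all(full$p[after] < none$p[after]))
})

test_that("run_scenarios is deterministic, ordered, and monotone in cost", {
  series <- refuge_series_from_regression(2006:2019)
  configs <- list(
    no_refuge = scenario(refuge = 0),
    cotton_only = scenario(refuge = 0.05),
    effective_refuge = scenario(refuge = series)
  )
  tab1 <- run_scenarios(configs)
  tab2 <- run_scenarios(configs)
  expect_identical(tab1, tab2)

  y75 <- tab1 |>
    dplyr::group_by(scenario) |>
    dplyr::summarise(first = first_year_above(dplyr::pick(dplyr::everything())))
  first_of <- setNames(y75$first, y75$scenario)
  expect_lte(first_of[["no_refuge"]], first_of[["cotton_only"]])
  expect_true(is.na(first_of[["effective_refuge"]]) ||
                first_of[["effective_refuge"]] >= first_of[["cotton_only"]])

  # sensitivity sweep: higher recessive cost, lower final frequency
  finals <- vapply(c(0.18, 0.36, 0.54), function(cost) {
    tr <- simulate_trajectory(scenario(
      refuge = series, fitness = fitness_table(cost = cost)))
    tr$p[[nrow(tr)]]
  }, numeric(1))
  expect_true(all(diff(finals) <= 0))

  expect_error(run_scenarios(list()), "named list")
})

test_that("observed frequencies join onto the scenario table", {
  obs <- tibble::tibble(year = c(2006, 2016, 2020),
                        observed = c(0.001, 0.10, 0.10))
  tab <- run_scenarios(list(no_refuge = scenario(refuge = 0)), observed = obs)
  expect_equal(tab$observed[tab$year == 2016], 0.10)
  expect_true(is.na(tab$observed[tab$year == 2010]))
})

test_that("scenario round-trips through YAML and JSON config files", {
  cfg <- list(
    h = 0.79, cost = 0.36, incomplete_resistance = 0.49, w_ss_bt = 0,
    p0 = 0.001, start_year = 2006, end_year = 2009,
    generations_per_year = 3,
    refuge = list(`2006` = 0.5, `2007` = 0.55, `2008` = 0.6)
  )
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  sy <- read_scenario(yml)
  sj <- read_scenario(jsn)
  expect_equal(simulate_trajectory(sy)$p, simulate_trajectory(sj)$p)
  expect_equal(sy$refuge$refuge, c(0.5, 0.55, 0.6))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(simulate_trajectory(sy), out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(back$p, simulate_trajectory(sy)$p)
})
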