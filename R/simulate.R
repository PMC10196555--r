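#' One generation of the Hardy-Weinberg selection recursion
#'
#' Advances the resistance-allele frequency `p` through one generation of
#' viability selection in a randomly mating population. With genotype
#' fitness `w = (w_ss, w_rs, w_rr)` and `q = 1 - p`,
#' \deqn{p' = \frac{p (p\,w_{rr} + q\,w_{rs})}
#'                 {p^2 w_{rr} + 2pq\,w_{rs} + q^2 w_{ss}}.}
#'
#' @param p Resistance-allele frequency before selection, in \[0, 1\].
#'   May be a vector.
#' @param w Genotype fitness triple `(w_ss, w_rs, w_rr)`, all finite and
#'   non-negative, e.g. from [habitat_fitness()].
#' @return Allele frequency after selection, same length as `p`.
#' @examples
#' w <- habitat_fitness(fitness_table(), refuge_fraction = 0)
#' advance_generation(0.001, w)
#' @export
advance_generation <- function(p, w) {
  check_fraction(p, "p", allow_vector = TRUE)
  if (!is.numeric(w) || length(w) != 3L || anyNA(w) || any(!is.finite(w)) ||
      any(w < 0)) {
    abort("`w` must be three finite, non-negative fitness values (w_ss, w_rs, w_rr).")
  }
  q <- 1 - p
  w_bar <- p^2 * w[[3]] + 2 * p * q * w[[2]] + q^2 * w[[1]]
  if (any(w_bar <= 0)) {
    abort("Mean fitness is zero: the population is extinct under these fitness values.")
  }
  pmin(1, pmax(0, p * (p * w[[3]] + q * w[[2]]) / w_bar))
}

#' Define a refuge scenario for the resistance simulator
#'
#' Bundles the initial condition, time span, within-year generation count,
#' fitness table and yearly refuge series that define one deterministic
#' simulation of resistance-allele frequency.
#'
#' The refuge series must provide a refuge fraction for every year from
#' `start_year` to `end_year - 1`; the frequency reported for a year is the
#' frequency entering that year, so the final year's refuge value is never
#' used. A scalar `refuge` is recycled to all years.
#'
#' @param refuge Either a single refuge fraction applied to every year, or
#'   a data frame with columns `year` and `refuge` (fractions in \[0, 1\]),
#'   e.g. from [refuge_series_from_regression()].
#' @param p0 Initial resistance-allele frequency at the start of
#'   `start_year`. Default 0.001, the observed 2006 frequency of the T92C
#'   mutation in northern China.
#' @param start_year,end_year First and last simulated years (defaults
#'   2006 and 2020).
#' @param generations_per_year Number of selected generations per year
#'   (default 3, the generations the cotton bollworm spends on cotton in
#'   northern China).
#' @param fitness A [fitness_table()].
#' @return An object of class `refuge_scenario`.
#' @examples
#' scen <- scenario(refuge = 0)
#' simulate_trajectory(scen)
#' @export
scenario <- function(refuge, p0 = 0.001, start_year = 2006, end_year = 2020,
                     generations_per_year = 3, fitness = fitness_table()) {
  check_fraction(p0, "p0")
  start_year <- check_count(start_year, "start_year")
  end_year <- check_count(end_year, "end_year")
  if (start_year > end_year) abort("`start_year` must be <= `end_year`.")
  generations_per_year <- check_count(generations_per_year,
                                      "generations_per_year", min = 1L)
  stopifnot(inherits(fitness, "fitness_table"))

  years_needed <- if (start_year == end_year) integer() else
    seq(start_year, end_year - 1L)
  if (is.numeric(refuge) && length(refuge) == 1L) {
    check_fraction(refuge, "refuge")
    refuge <- tibble::tibble(year = years_needed, refuge = refuge)
  }
  if (!is.data.frame(refuge) || !all(c("year", "refuge") %in% names(refuge))) {
    abort("`refuge` must be a fraction or a data frame with columns `year` and `refuge`.")
  }
  check_fraction(refuge$refuge, "refuge$refuge", allow_vector = TRUE)
  missing_years <- setdiff(years_needed, refuge$year)
  if (length(missing_years) > 0) {
    abort(sprintf("Refuge series is missing year(s): %s.",
                  paste(missing_years, collapse = ", ")))
  }

  structure(
    list(
      p0 = p0, start_year = start_year, end_year = end_year,
      generations_per_year = generations_per_year,
      fitness = fitness,
      refuge = tibble::as_tibble(refuge[c("year", "refuge")])
    ),
    class = "refuge_scenario"
  )
}

#' @export
print.refuge_scenario <- function(x, ...) {
  cat(sprintf(
    "Refuge scenario: %d-%d, p0 = %g, %d generation(s)/year, refuge %s\n",
    x$start_year, x$end_year, x$p0, x$generations_per_year,
    if (length(unique(x$refuge$refuge)) == 1L && nrow(x$refuge) > 0)
      sprintf("constant at %g", x$refuge$refuge[[1]])
    else sprintf("varying over %d year(s)", nrow(x$refuge))
  ))
  invisible(x)
}

#' Read a scenario from a YAML or JSON configuration file
#'
#' Expected keys: `h`, `cost`, `incomplete_resistance`, `w_ss_bt`, `p0`,
#' `start_year`, `end_year`, `generations_per_year`, and `refuge`, a
#' mapping from year to refuge fraction (or a single number). Missing keys
#' fall back to the defaults of [scenario()] and [fitness_table()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `refuge_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("Scenario file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  scenario_from_list(cfg)
}

scenario_from_list <- function(cfg) {
  ft_args <- cfg[intersect(names(cfg),
                           c("h", "cost", "incomplete_resistance", "w_ss_bt", "mode"))]
  ft <- do.call(fitness_table, ft_args)
  refuge <- cfg$refuge
  if (is.list(refuge) || (is.numeric(refuge) && !is.null(names(refuge)))) {
    refuge <- tibble::tibble(
      year = as.integer(names(refuge)),
      refuge = as.numeric(unlist(refuge))
    )
  }
  sc_args <- cfg[intersect(names(cfg),
                           c("p0", "start_year", "end_year", "generations_per_year"))]
  do.call(scenario, c(list(refuge = refuge, fitness = ft), sc_args))
}

#' Simulate a yearly resistance-allele trajectory
#'
#' Runs the deterministic one-locus, two-allele recursion of
#' [advance_generation()] for the span of a [scenario()]. Each simulated
#' year applies that year's habitat-weighted fitness
#' ([habitat_fitness()]) for `generations_per_year` generations. The
#' reported frequency for a year is the frequency entering that year, so
#' the first entry equals `p0` at `start_year`.
#'
#' @param config A `refuge_scenario` from [scenario()] or [read_scenario()].
#' @return A `resistance_trajectory`: a tibble with columns `year`,
#'   `refuge` (the fraction applied during that year; `NA` for the final
#'   year) and `p`.
#' @examples
#' simulate_trajectory(scenario(refuge = 0, end_year = 2009))
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "refuge_scenario"))
  years <- seq(config$start_year, config$end_year)
  refuge_of <- setNames(config$refuge$refuge, config$refuge$year)
  p <- numeric(length(years))
  p[[1]] <- config$p0
  cur <- config$p0
  for (i in seq_along(years)[-length(years)]) {
    w <- habitat_fitness(config$fitness, refuge_of[[as.character(years[[i]])]])
    for (g in seq_len(config$generations_per_year)) {
      cur <- advance_generation(cur, w)
    }
    p[[i + 1L]] <- cur
  }
  out <- tibble::tibble(
    year = years,
    refuge = c(unname(refuge_of[as.character(head(years, -1L))]), NA_real_)[seq_along(years)],
    p = p
  )
  structure(out, class = c("resistance_trajectory", class(out)),
            scenario = config)
}

#' @describeIn simulate_trajectory One-row summary of a trajectory:
#'   `n_years`, `p_start`, `p_final`, and `first_year_above` — the first
#'   year in which the frequency exceeds `threshold` (`NA` if never).
#' @param x A `resistance_trajectory`.
#' @param threshold Frequency threshold for `first_year_above`
#'   (default 0.75).
#' @param ... Unused.
#' @method glance resistance_trajectory
#' @export
glance.resistance_trajectory <- function(x, threshold = 0.75, ...) {
  above <- x$year[x$p > threshold]
  tibble::tibble(
    n_years = nrow(x),
    p_start = x$p[[1]],
    p_final = x$p[[nrow(x)]],
    threshold = threshold,
    first_year_above = if (length(above)) min(above) else NA_integer_
  )
}

#' Year at which a trajectory first exceeds a frequency threshold
#'
#' @param trajectory A `resistance_trajectory` (or any data frame with
#'   `year` and `p`).
#' @param threshold Frequency threshold (default 0.75).
#' @return The first year with `p > threshold`, or `NA` if never reached.
#' @export
first_year_above <- function(trajectory, threshold = 0.75) {
  check_fraction(threshold, "threshold")
  above <- trajectory$year[trajectory$p > threshold]
  if (length(above)) min(above) else NA_integer_
}

#' Run and tabulate several refuge scenarios
#'
#' @param configs Named list of `refuge_scenario` objects.
#' @param observed Optional data frame with columns `year` and `observed`
#'   (e.g. field estimates of the allele frequency) joined onto every
#'   scenario's trajectory.
#' @return A tibble with columns `scenario`, `year`, `p` and, when
#'   supplied, `observed`. Identical inputs give identical tables.
#' @examples
#' run_scenarios(list(no_refuge = scenario(refuge = 0, end_year = 2008),
#'                    pure_refuge = scenario(refuge = 1, end_year = 2008)))
#' @export
run_scenarios <- function(configs, observed = NULL) {
  if (!is.list(configs) || length(configs) == 0 ||
      is.null(names(configs)) || any(names(configs) == "")) {
    abort("`configs` must be a non-empty named list of scenarios.")
  }
  out <- purrr::map(configs, simulate_trajectory) |>
    purrr::map(~ tibble::as_tibble(.x)[c("year", "p")]) |>
    purrr::list_rbind(names_to = "scenario")
  if (!is.null(observed)) {
    stopifnot(all(c("year", "observed") %in% names(observed)))
    out <- dplyr::left_join(out, observed[c("year", "observed")], by = "year")
  }
  out
}

#' Balanced-polymorphism equilibrium under overdominance
#'
#' When the heterozygote is fitter than both homozygotes, selection
#' maintains a stable polymorphism at
#' \deqn{p^* = \frac{w_{rs} - w_{ss}}{2 w_{rs} - w_{ss} - w_{rr}}.}
#' In a refuge landscape this arises when strong selection for resistance
#' on Bt cotton is balanced by the weaker selection against resistance
#' (fitness cost) in a large refuge.
#'
#' @inheritParams advance_generation
#' @return The equilibrium frequency `p*`, or `NA_real_` when the fitness
#'   triple is not overdominant.
#' @examples
#' overdominance_equilibrium(c(0.9, 1, 0.8))
#' overdominance_equilibrium(habitat_fitness(fitness_table(), 0.9))
#' @export
overdominance_equilibrium <- function(w) {
  if (!is.numeric(w) || length(w) != 3L || anyNA(w)) {
    abort("`w` must be three fitness values (w_ss, w_rs, w_rr).")
  }
  if (w[[2]] > max(w[[1]], w[[3]])) {
    unname((w[[2]] - w[[1]]) / (2 * w[[2]] - w[[1]] - w[[3]]))
  } else {
    NA_real_
  }
}

#' Write scenario trajectories to a TSV file
#'
#' @param trajectories Output of [run_scenarios()] or a single trajectory.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  df <- tibble::as_tibble(trajectories)
  if (!"scenario" %in% names(df)) df <- dplyr::mutate(df, scenario = "scenario", .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}
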