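#' Genotype fitness on Bt cotton and in refuges
#'
#' Builds the relative-fitness table for the three genotypes at a biallelic
#' resistance locus (`ss` susceptible homozygote, `rs` heterozygote, `rr`
#' resistant homozygote) in the two habitats of a refuge landscape: Bt
#' cotton and non-Bt refuge host plants. Fitness is scaled so that the
#' susceptible homozygote in the refuge has fitness 1.
#'
#' The table is composed from three field-estimable parameters:
#'
#' * `h` — dominance of resistance on Bt cotton; the heterozygote sits at
#'   `w_rs_bt = w_ss_bt + h * (w_rr_bt - w_ss_bt)` (`h = 0` fully
#'   recessive, `h = 1` fully dominant).
#' * `cost` — recessive fitness cost of resistance on non-Bt hosts: only
#'   the resistant homozygote pays it, `w_rr_ref = 1 - cost`.
#' * `incomplete_resistance` — reduced performance of resistant homozygotes
#'   on Bt cotton relative to non-Bt hosts. Under the default
#'   `mode = "ratio"` it is the ratio of `rr` fitness on Bt cotton to `rr`
#'   fitness on non-Bt hosts, so `w_rr_bt = incomplete_resistance *
#'   (1 - cost)`. Under `mode = "absolute"` it is taken as the fitness of
#'   `rr` on Bt cotton outright (`w_rr_bt = incomplete_resistance`).
#'
#' The defaults are the empirical estimates for the cotton bollworm T92C
#' mutation: `h = 0.79`, `cost = 0.36`, `incomplete_resistance = 0.49`,
#' and complete mortality of susceptible homozygotes on Bt cotton
#' (`w_ss_bt = 0`).
#'
#' @param h Dominance of resistance on Bt cotton, in \[0, 1\].
#' @param cost Recessive fitness cost on non-Bt hosts, in \[0, 1\].
#' @param incomplete_resistance Incomplete-resistance parameter, in \[0, 1\].
#' @param w_ss_bt Fitness of susceptible homozygotes on Bt cotton, in
#'   \[0, 1\]. Default 0 (complete mortality).
#' @param mode How `incomplete_resistance` enters the Bt-cotton fitness of
#'   `rr`: `"ratio"` (default) or `"absolute"`; see Details.
#' @return A `fitness_table`: a tibble with one row per habitat
#'   (`"refuge"`, `"bt_cotton"`) and columns `w_ss`, `w_rs`, `w_rr`, with
#'   the input parameters stored as attributes.
#' @examples
#' fitness_table()
#' fitness_table(h = 0, cost = 0, incomplete_resistance = 1)
#' @seealso [habitat_fitness()], [simulate_trajectory()]
#' @export
fitness_table <- function(h = 0.79, cost = 0.36, incomplete_resistance = 0.49,
                          w_ss_bt = 0, mode = c("ratio", "absolute")) {
  mode <- match.arg(mode)
  check_fraction(h, "h")
  check_fraction(cost, "cost")
  check_fraction(incomplete_resistance, "incomplete_resistance")
  check_fraction(w_ss_bt, "w_ss_bt")

  w_rr_ref <- 1 - cost
  w_rr_bt <- switch(mode,
    ratio    = incomplete_resistance * w_rr_ref,
    absolute = incomplete_resistance
  )
  w_rs_bt <- w_ss_bt + h * (w_rr_bt - w_ss_bt)

  out <- tibble::tibble(
    habitat = c("refuge", "bt_cotton"),
    w_ss = c(1, w_ss_bt),
    w_rs = c(1, w_rs_bt),
    w_rr = c(w_rr_ref, w_rr_bt)
  )
  structure(out,
    class = c("fitness_table", class(out)),
    h = h, cost = cost, incomplete_resistance = incomplete_resistance,
    w_ss_bt = w_ss_bt, mode = mode
  )
}

#' @export
print.fitness_table <- function(x, ...) {
  cat(sprintf(
    "Genotype fitness table (h = %g, cost = %g, incomplete resistance = %g, %s)\n",
    attr(x, "h"), attr(x, "cost"), attr(x, "incomplete_resistance"),
    attr(x, "mode")
  ))
  NextMethod()
}

#' @describeIn fitness_table Long-format view: one row per habitat and
#'   genotype with columns `habitat`, `genotype`, `fitness`.
#' @param x A `fitness_table`.
#' @param ... Unused.
#' @method tidy fitness_table
#' @export
tidy.fitness_table <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), cols = c("w_ss", "w_rs", "w_rr"),
                      names_to = "genotype", values_to = "fitness",
                      names_prefix = "w_")
}

#' Habitat-weighted marginal genotype fitness
#'
#' Mixes refuge and Bt-cotton genotype fitness according to the effective
#' refuge fraction. Under random mating across habitats (panmixia), the
#' marginal fitness of genotype g is
#' `w_g = R * w_g_refuge + (1 - R) * w_g_bt`, where `R` is the fraction of
#' the selection habitat made up of non-Bt host plants.
#'
#' @param table A [fitness_table()].
#' @param refuge_fraction Effective refuge fraction `R`, in \[0, 1\].
#' @return Named numeric vector `c(w_ss, w_rs, w_rr)`.
#' @examples
#' habitat_fitness(fitness_table(), refuge_fraction = 0.85)
#' @export
habitat_fitness <- function(table, refuge_fraction) {
  stopifnot(inherits(table, "fitness_table"))
  check_fraction(refuge_fraction, "refuge_fraction")
  ref <- table[table$habitat == "refuge", ]
  bt <- table[table$habitat == "bt_cotton", ]
  R <- refuge_fraction
  c(
    w_ss = R * ref$w_ss + (1 - R) * bt$w_ss,
    w_rs = R * ref$w_rs + (1 - R) * bt$w_rs,
    w_rr = R * ref$w_rr + (1 - R) * bt$w_rr
  )
}
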