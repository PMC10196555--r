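#' Synthetic data generators with known ground truth
#'
#' @description
#' Generators that emulate every input the monitoring pipeline consumes —
#' Hardy-Weinberg moth pools, dual-tagged pooled amplicon read pairs,
#' diagnostic-dose bioassay outcomes and crop-area tables — so that every
#' stage of the analysis can be tested against a known truth without any
#' external data. All generators are deterministic under a fixed seed.
#'
#' @name synthetic
NULL

#' Synthetic amplicon reference fragment
#'
#' A random 204-nt fragment carrying the susceptible base at the variant
#' position. The variant position is a free design choice for synthetic
#' data; it is placed mid-fragment by default and recorded in the FASTA
#' header written by [write_reference_fasta()].
#'
#' @param length Fragment length (default 204).
#' @param variant_pos 1-based variant position (default 102).
#' @param susceptible_base,resistant_base Alleles at the variant position.
#' @param seed Optional integer seed.
#' @return A list with `sequence`, `variant_pos`, `susceptible_base`,
#'   `resistant_base`.
#' @export
synthetic_reference <- function(length = 204L, variant_pos = 102L,
                                susceptible_base = "T", resistant_base = "C",
                                seed = NULL) {
  length <- check_count(length, "length", min = 1L)
  variant_pos <- check_count(variant_pos, "variant_pos", min = 1L)
  if (variant_pos > length) abort("`variant_pos` must lie within the fragment.")
  draw <- function() sample(c("A", "C", "G", "T"), length, replace = TRUE)
  bases <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  bases[variant_pos] <- susceptible_base
  list(
    sequence = paste(bases, collapse = ""),
    variant_pos = variant_pos,
    susceptible_base = susceptible_base,
    resistant_base = resistant_base
  )
}

#' Write/read the synthetic reference fragment as FASTA
#'
#' The header records the variant position and alleles
#' (`variant_pos=<i> susceptible=<base> resistant=<base>`), so the
#' reference file is self-describing.
#'
#' @param reference A list from [synthetic_reference()].
#' @param path FASTA path.
#' @return `path` (write) or the reference list (read).
#' @export
write_reference_fasta <- function(reference, path) {
  header <- sprintf("amplicon_reference variant_pos=%d susceptible=%s resistant=%s",
                    reference$variant_pos, reference$susceptible_base,
                    reference$resistant_base)
  x <- Biostrings::DNAStringSet(reference$sequence)
  names(x) <- header
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("Reference FASTA not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  header <- names(x)[[1]]
  grab <- function(key, default) {
    m <- regmatches(header, regexpr(sprintf("%s=\\S+", key), header))
    if (length(m)) sub(sprintf("%s=", key), "", m) else default
  }
  list(
    sequence = as.character(x[[1]]),
    variant_pos = as.integer(grab("variant_pos", NA)),
    susceptible_base = grab("susceptible", "T"),
    resistant_base = grab("resistant", "C")
  )
}

#' Generate a tag scheme of unique 6-bp site tags
#'
#' @param sites Character vector of site ids.
#' @param n_legs Pool size per site (recycled).
#' @param year Collection year per site (recycled).
#' @param tag_length Tag length (default 6).
#' @param seed Optional integer seed.
#' @return A tibble with columns `site`, `forward_tag`, `reverse_tag`,
#'   `n_legs`, `year`.
#' @export
make_tag_scheme <- function(sites, n_legs, year, tag_length = 6L,
                            seed = NULL) {
  stopifnot(length(sites) >= 1, !anyDuplicated(sites))
  draw <- function() {
    tags <- character(0)
    while (length(tags) < 2 * length(sites)) {
      cand <- paste(sample(c("A", "C", "G", "T"), tag_length, replace = TRUE),
                    collapse = "")
      if (!cand %in% tags) tags <- c(tags, cand)
    }
    tags
  }
  tags <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  scheme <- tibble::tibble(
    site = as.character(sites),
    forward_tag = tags[seq_along(sites)],
    reverse_tag = tags[length(sites) + seq_along(sites)],
    n_legs = as.integer(rep_len(n_legs, length(sites))),
    year = as.integer(rep_len(year, length(sites)))
  )
  validate_tag_scheme(scheme, tag_length = tag_length)
  scheme
}

#' Write a tag scheme to CSV
#'
#' @param scheme Tag scheme tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tag_scheme <- function(scheme, path) {
  validate_tag_scheme(scheme)
  readr::write_csv(scheme, path)
  invisible(path)
}

#' Draw a Hardy-Weinberg moth pool
#'
#' Samples `n` diploid genotypes at genotype probabilities
#' `(q^2, 2pq, p^2)` for resistance-allele frequency `p`, emulating a pool
#' of field-collected moths from a randomly mating population.
#'
#' @param p True resistance-allele frequency.
#' @param n Number of individuals (>= 1).
#' @param seed Optional integer seed.
#' @return A one-row tibble with columns `ss`, `rs`, `rr`.
#' @examples
#' simulate_moth_pool(0.1, 100, seed = 1)
#' @export
simulate_moth_pool <- function(p, n, seed = NULL) {
  check_fraction(p, "p")
  n <- check_count(n, "n", min = 1L)
  q <- 1 - p
  draw <- function() rmultinom(1, n, prob = c(q^2, 2 * p * q, p^2))
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(ss = counts[1, 1], rs = counts[2, 1], rr = counts[3, 1])
}

#' Simulate dual-tagged pooled amplicon read pairs
#'
#' Builds paired-end reads for one site pool: each read pair covers one
#' 216-bp amplicon (forward tag + 204-bp fragment + reverse-complemented
#' reverse tag) drawn from the pool's allele copies (two per moth), with
#' the resistant base substituted at the variant position for resistant
#' allele copies. Uniform per-base substitution errors are applied to each
#' read independently (no indels, no quality model).
#'
#' Reads are allocated to alleles either multinomially (default), or
#' proportionally (`allocation = "proportional"`, deterministic rounding
#' of `depth * allele fraction`), which permits exact recovery checks.
#'
#' @param tally One-row genotype tally (`ss`, `rs`, `rr`) from
#'   [simulate_moth_pool()].
#' @param site Site id; must be present in `scheme`.
#' @param scheme Tag scheme (see [make_tag_scheme()]).
#' @param reference Reference list from [synthetic_reference()].
#' @param depth Total read pairs to generate (default 10000).
#' @param error_rate Per-base substitution error probability per read
#'   (default 0.001; must be <= 0.1).
#' @param read_length Length of each read (default 150; the pair must
#'   span the 216-bp amplicon).
#' @param allocation `"multinomial"` (default) or `"proportional"`.
#' @param seed Optional integer seed.
#' @return A list with character vectors `r1` and `r2` (named by read id)
#'   and the true resistant-allele read fraction `truth`.
#' @export
simulate_pooled_reads <- function(tally, site, scheme, reference,
                                  depth = 10000L, error_rate = 0.001,
                                  read_length = 150L,
                                  allocation = c("multinomial", "proportional"),
                                  seed = NULL) {
  allocation <- match.arg(allocation)
  stopifnot(is.data.frame(tally), all(c("ss", "rs", "rr") %in% names(tally)),
            nrow(tally) == 1)
  validate_tag_scheme(scheme)
  depth <- check_count(depth, "depth", min = 1L)
  if (error_rate < 0 || error_rate > 0.1) abort("`error_rate` must lie in [0, 0.1].")
  idx <- match(site, scheme$site)
  if (is.na(idx)) abort(sprintf("Site '%s' is missing from the tag scheme.", site))

  frag_len <- nchar(reference$sequence)
  amp_len <- frag_len + 2L * nchar(scheme$forward_tag[[idx]])
  if (2L * read_length < amp_len) {
    abort(sprintf("Read pairs of length %d cannot span a %d-bp amplicon.",
                  read_length, amp_len))
  }

  r_alleles <- 2 * tally$rr + tally$rs
  total_alleles <- 2 * (tally$ss + tally$rs + tally$rr)
  p_r <- r_alleles / total_alleles

  run <- function() {
    n_r <- switch(allocation,
      multinomial = rbinom(1, depth, p_r),
      proportional = round(depth * p_r)
    )
    is_r <- c(rep(TRUE, n_r), rep(FALSE, depth - n_r))

    fragment <- rep(reference$sequence, depth)
    substr(fragment, reference$variant_pos, reference$variant_pos) <-
      ifelse(is_r, reference$resistant_base, reference$susceptible_base)
    amplicon <- paste0(scheme$forward_tag[[idx]], fragment,
                       reverse_complement(scheme$reverse_tag[[idx]]))
    r1 <- substr(amplicon, 1L, read_length)
    r2 <- substr(reverse_complement(amplicon), 1L, read_length)
    if (error_rate > 0) {
      r1 <- apply_substitution_errors(r1, error_rate)
      r2 <- apply_substitution_errors(r2, error_rate)
    }
    ids <- sprintf("%s_read%06d", site, seq_len(depth))
    list(r1 = setNames(r1, ids), r2 = setNames(r2, ids), truth = p_r)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Independent per-base substitution errors; a hit base is replaced by one
# of the three other bases uniformly.
apply_substitution_errors <- function(reads, error_rate) {
  width <- nchar(reads[[1]])
  n_bases <- length(reads) * width
  hits <- which(runif(n_bases) < error_rate)
  if (length(hits) == 0) return(reads)
  read_i <- ((hits - 1L) %/% width) + 1L
  pos <- ((hits - 1L) %% width) + 1L
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(hits)) {
    old <- substr(reads[[read_i[k]]], pos[k], pos[k])
    new <- sample(setdiff(bases, old), 1)
    substr(reads[[read_i[k]]], pos[k], pos[k]) <- new
  }
  reads
}

#' Simulate a diagnostic-dose bioassay
#'
#' Draws `n` larvae from a Hardy-Weinberg population at resistance-allele
#' frequency `p` and applies genotype-specific survival probabilities at
#' the diagnostic toxin concentration. The expected survivor fraction is
#' `q^2 s_ss + 2pq s_rs + p^2 s_rr`. The default susceptible survival is
#' 0, matching complete mortality of susceptibles at the diagnostic dose.
#'
#' @param p True resistance-allele frequency.
#' @param n Number of larvae tested (>= 1).
#' @param survival Named numeric vector `c(ss=, rs=, rr=)` of survival
#'   probabilities at the diagnostic dose.
#' @param site,year Identifiers carried into the output record.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `site`, `year`, `n_tested`, `n_surviving`.
#' @examples
#' simulate_bioassay(0.1, 1000, seed = 1)
#' @export
simulate_bioassay <- function(p, n, survival = c(ss = 0, rs = 0.8, rr = 0.9),
                              site = "site1", year = NA_integer_,
                              seed = NULL) {
  check_fraction(p, "p")
  n <- check_count(n, "n", min = 1L)
  check_fraction(survival, "survival", allow_vector = TRUE)
  stopifnot(length(survival) == 3)
  draw <- function() {
    counts <- rmultinom(1, n, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))[, 1]
    sum(rbinom(3, counts, survival))
  }
  surv <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(site = site, year = as.integer(year),
                 n_tested = n, n_surviving = surv)
}

#' Build a validated crop-area table
#'
#' Assembles per-year crop records (areas, Bt fractions, production
#' weights) into the tabular form consumed by
#' [effective_refuge_percentage()], validating every field. The table
#' round-trips bit-identically through [write_crop_table()] /
#' [read_crop_table()].
#'
#' @param ... Data frames (or one list of data frames), each with columns
#'   `year`, `crop`, `area_ha`, `bt_fraction`, `production_weight`.
#' @return A validated tibble of crop records sorted by year then crop.
#' @examples
#' make_crop_table(tibble::tibble(
#'   year = 2019, crop = c("cotton", "corn"), area_ha = c(6.4e5, 1.2e7),
#'   bt_fraction = c(0.95, 0), production_weight = c(1, 0.4)
#' ))
#' @export
make_crop_table <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  if (length(parts) == 0) abort("No crop records supplied.")
  records <- dplyr::bind_rows(parts)
  validate_crop_records(records)
  dplyr::arrange(tibble::as_tibble(records), .data$year, .data$crop)
}

#' Crop table whose refuge series follows a straight line
#'
#' Convenience generator: a two-crop landscape (Bt cotton plus one
#' aggregate non-Bt host) whose yearly effective refuge percentage equals
#' `slope * year + intercept`, with constant total host area. Useful for
#' regression round-trip checks.
#'
#' @inheritParams refuge_series_from_regression
#' @param total_area_ha Constant total host area per year.
#' @param production_weight Production weight of the aggregate non-Bt host.
#' @return A crop-record tibble spanning `years`.
#' @export
make_linear_refuge_crops <- function(years, slope = 2.85, intercept = -5667,
                                     total_area_ha = 2.7e7,
                                     production_weight = 1) {
  series <- refuge_series_from_regression(years, slope, intercept, clamp = TRUE)
  purrr::map(seq_along(series$year), function(i) {
    R <- series$refuge[[i]]
    # weighted refuge area w*a_ref and Bt area a_bt chosen so that
    # w*a_ref / (w*a_ref + a_bt) = R with a_ref + a_bt = total.
    a_bt <- total_area_ha * (1 - R) /
      ((1 - R) + R / production_weight)
    a_ref <- total_area_ha - a_bt
    tibble::tibble(
      year = series$year[[i]],
      crop = c("Bt cotton", "non-Bt hosts"),
      area_ha = c(a_bt, a_ref),
      bt_fraction = c(1, 0),
      production_weight = c(1, production_weight)
    )
  }) |>
    make_crop_table()
}
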