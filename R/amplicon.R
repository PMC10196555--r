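#' Pooled-amplicon allele-frequency estimation
#'
#' @description
#' Functions for estimating the frequency of a resistance allele from
#' pooled, dual-tagged amplicon sequencing. One leg per moth is pooled per
#' collection site; amplicons of 216 bp carry a 204-bp genomic fragment
#' flanked by site-specific 6-bp tags on both primers. After
#' demultiplexing by exact tag match and merging of read pairs, identical
#' sequences are collapsed, sequences rarer than `1/(2n)` (n = legs in the
#' pool, the theoretical minimum allele frequency) are removed as likely
#' sequencing errors, and reads are classified by the base at the variant
#' position.
#'
#' @name amplicon
NULL

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a site tag scheme from CSV
#'
#' Expects the header `site,forward_tag,reverse_tag,n_legs,year`. Tags are
#' 6-mers over A/C/G/T and the (forward, reverse) pair must be unique
#' across sites.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_tag_scheme <- function(path) {
  if (!file.exists(path)) abort(sprintf("Tag scheme not found: %s", path))
  scheme <- readr::read_csv(
    path,
    col_types = readr::cols(
      site = readr::col_character(),
      forward_tag = readr::col_character(),
      reverse_tag = readr::col_character(),
      n_legs = readr::col_integer(),
      year = readr::col_integer()
    )
  )
  validate_tag_scheme(scheme)
  scheme
}

validate_tag_scheme <- function(scheme, tag_length = 6L) {
  required <- c("site", "forward_tag", "reverse_tag", "n_legs")
  if (!is.data.frame(scheme) || !all(required %in% names(scheme)) ||
      nrow(scheme) == 0) {
    abort(sprintf("Tag scheme needs columns: %s.", paste(required, collapse = ", ")))
  }
  tags <- c(scheme$forward_tag, scheme$reverse_tag)
  if (any(nchar(tags) != tag_length) || any(grepl("[^ACGT]", tags))) {
    abort(sprintf("All tags must be %d-mers over A/C/G/T.", tag_length))
  }
  key <- paste(scheme$forward_tag, scheme$reverse_tag)
  if (anyDuplicated(key)) abort("Tag pairs (forward, reverse) must be unique across sites.")
  if (any(scheme$n_legs < 1)) abort("`n_legs` must be >= 1 for every site.")
  invisible(scheme)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTQ file
#'
#' Writes plain-text FASTQ with a constant quality character (the
#' generators in this package do not model qualities).
#'
#' @param sequences Character vector of sequences (names become read ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sequences, path) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("read", seq_along(sequences))
  x <- Biostrings::DNAStringSet(unname(sequences))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Demultiplex and merge dual-tagged paired-end amplicon reads
#'
#' Reconstructs each 216-bp amplicon from its read pair (forward read +
#' reverse-complemented reverse read, which must agree over their
#' overlap), assigns it to a site by exact match of both 6-bp tags at the
#' amplicon ends, and strips the tags. Pairs with an overlap disagreement,
#' an unexpected length, or tags matching no site are rejected; assigned
#' plus rejected always equals the number of input pairs.
#'
#' @param r1,r2 Forward/reverse reads: FASTQ file paths or character
#'   vectors of equal length.
#' @param scheme Tag scheme (see [read_tag_scheme()]): columns `site`,
#'   `forward_tag`, `reverse_tag`, `n_legs` (and optionally `year`).
#' @param reference_length Length of the genomic fragment between the
#'   tags (default 204).
#' @param tag_length Tag length (default 6).
#' @return A list with `reads`, a tibble of columns `site` and `sequence`
#'   (tag-stripped, `reference_length` nt), and `n_rejected`.
#' @export
demultiplex_reads <- function(r1, r2, scheme, reference_length = 204L,
                              tag_length = 6L) {
  validate_tag_scheme(scheme, tag_length = tag_length)
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) r1 <- read_fastq(r1)
  if (is.character(r2) && length(r2) == 1L && file.exists(r2)) r2 <- read_fastq(r2)
  if (length(r1) != length(r2)) abort("`r1` and `r2` must contain the same number of reads.")
  n <- length(r1)
  if (n == 0) {
    return(list(reads = tibble::tibble(site = character(), sequence = character()),
                n_rejected = 0L))
  }
  r1 <- unname(toupper(r1))
  r2 <- unname(toupper(r2))
  amp_len <- reference_length + 2L * tag_length
  len1 <- nchar(r1)
  len2 <- nchar(r2)

  ok <- len1 <= amp_len & len2 <= amp_len & (len1 + len2) >= amp_len &
    !grepl("[^ACGT]", r1) & !grepl("[^ACGT]", r2)
  amplicon <- rep(NA_character_, n)
  if (any(ok)) {
    rc2 <- reverse_complement(r2[ok])
    l1 <- len1[ok]
    l2 <- len2[ok]
    # rc2 spans amplicon positions (amp_len - l2 + 1)..amp_len; the region
    # shared with r1 must match exactly, otherwise the pair is rejected.
    ov1 <- substr(r1[ok], amp_len - l2 + 1L, l1)
    ov2 <- substr(rc2, 1L, l1 - (amp_len - l2))
    agree <- ov1 == ov2
    amplicon[which(ok)[agree]] <- paste0(
      r1[ok][agree],
      substr(rc2[agree], (l1 - (amp_len - l2) + 1L)[agree], l2[agree])
    )
  }

  fwd <- substr(amplicon, 1L, tag_length)
  rev_rc <- substr(amplicon, amp_len - tag_length + 1L, amp_len)
  key <- paste(fwd, rev_rc)
  site_key <- paste(scheme$forward_tag, reverse_complement(scheme$reverse_tag))
  site <- scheme$site[match(key, site_key)]
  assigned <- !is.na(amplicon) & !is.na(site)

  list(
    reads = tibble::tibble(
      site = site[assigned],
      sequence = substr(amplicon[assigned], tag_length + 1L,
                        amp_len - tag_length)
    ),
    n_rejected = as.integer(n - sum(assigned))
  )
}

#' Tally alleles in a site pool with the 1/(2n) rare-sequence filter
#'
#' Collapses identical sequences, removes distinct sequences whose
#' frequency among the pool's reads is strictly below `1/(2 * n_legs)` —
#' the smallest allele frequency a pool of `n_legs` diploid individuals
#' can contain, so rarer sequences are attributed to sequencing error —
#' and classifies the surviving reads by the base at the variant position.
#'
#' @param sequences Character vector of tag-stripped amplicon sequences
#'   for one site, all the same length as `reference`.
#' @param n_legs Number of legs (individuals) in the pool (>= 1).
#' @param reference Reference fragment sequence (defines the expected
#'   length).
#' @param variant_pos 1-based position of the biallelic variant within the
#'   fragment.
#' @param resistant_base,susceptible_base Bases defining the resistant and
#'   susceptible alleles at `variant_pos`.
#' @return A one-row tibble: `n_legs`, `n_reads_in`, `threshold`
#'   (`1/(2 n_legs)`), `n_reads_surviving`, `n_distinct_surviving`,
#'   `r_count`, `s_count`, `other_count`.
#' @examples
#' ref <- strrep("A", 10)
#' seqs <- c(rep("AAAAATAAAA", 6), rep("AAAAACAAAA", 4))
#' count_alleles(seqs, n_legs = 5, reference = ref, variant_pos = 6,
#'               resistant_base = "C", susceptible_base = "T")
#' @export
count_alleles <- function(sequences, n_legs, reference, variant_pos,
                          resistant_base = "C", susceptible_base = "T") {
  n_legs <- check_count(n_legs, "n_legs", min = 1L)
  variant_pos <- check_count(variant_pos, "variant_pos", min = 1L)
  if (variant_pos > nchar(reference)) {
    abort(sprintf("`variant_pos` (%d) is beyond the reference length (%d).",
                  variant_pos, nchar(reference)))
  }
  if (length(sequences) == 0) abort("No sequences to tally.")
  if (any(nchar(sequences) != nchar(reference))) {
    abort("All sequences must have the same length as the reference.")
  }

  threshold <- 1 / (2 * n_legs)
  tab <- dplyr::count(tibble::tibble(sequence = sequences), .data$sequence,
                      name = "reads")
  tab <- dplyr::filter(tab, .data$reads / length(sequences) >= threshold)
  base <- substr(tab$sequence, variant_pos, variant_pos)

  tibble::tibble(
    n_legs = n_legs,
    n_reads_in = length(sequences),
    threshold = threshold,
    n_reads_surviving = sum(tab$reads),
    n_distinct_surviving = nrow(tab),
    r_count = sum(tab$reads[base == resistant_base]),
    s_count = sum(tab$reads[base == susceptible_base]),
    other_count = sum(tab$reads[base != resistant_base &
                                  base != susceptible_base])
  )
}

#' Per-site allele counts for demultiplexed reads
#'
#' Applies [count_alleles()] to every site in the output of
#' [demultiplex_reads()], using each site's pool size from the tag scheme.
#'
#' @param reads Tibble with columns `site` and `sequence` (from
#'   [demultiplex_reads()]).
#' @param scheme Tag scheme with `site`, `n_legs` and optionally `year`.
#' @inheritParams count_alleles
#' @return A tibble with one row per site present in `reads`, columns
#'   `site` (and `year` if in the scheme) plus the [count_alleles()]
#'   columns.
#' @export
count_alleles_by_site <- function(reads, scheme, reference, variant_pos,
                                  resistant_base = "C",
                                  susceptible_base = "T") {
  stopifnot(is.data.frame(reads), all(c("site", "sequence") %in% names(reads)))
  validate_tag_scheme(scheme)
  out <- reads |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(d, g) {
      n_legs <- scheme$n_legs[match(g$site, scheme$site)]
      if (is.na(n_legs)) abort(sprintf("Site '%s' is missing from the tag scheme.", g$site))
      count_alleles(d$sequence, n_legs = n_legs, reference = reference,
                    variant_pos = variant_pos,
                    resistant_base = resistant_base,
                    susceptible_base = susceptible_base)
    }) |>
    dplyr::ungroup()
  if ("year" %in% names(scheme)) {
    out <- dplyr::mutate(out,
      year = scheme$year[match(.data$site, scheme$site)], .after = "site")
  }
  out
}

#' Per-site allele frequency from filtered counts
#'
#' The site frequency is the number of surviving reads carrying the
#' resistant base divided by all surviving reads (reads with a
#' non-canonical base at the variant position stay in the denominator).
#'
#' @param counts Output of [count_alleles()] or [count_alleles_by_site()].
#' @return `counts` with an added `frequency` column.
#' @export
site_frequency <- function(counts) {
  required <- c("r_count", "s_count", "other_count")
  stopifnot(is.data.frame(counts), all(required %in% names(counts)))
  total <- counts$r_count + counts$s_count + counts$other_count
  if (any(total <= 0)) {
    bad <- if ("site" %in% names(counts)) {
      paste(counts$site[total <= 0], collapse = ", ")
    } else "input"
    abort(sprintf("No surviving reads for: %s.", bad))
  }
  dplyr::mutate(tibble::as_tibble(counts), frequency = .data$r_count / total)
}

#' Annual mean allele frequency with a site-level bootstrap interval
#'
#' Unweighted mean of per-site frequencies for one year, with a percentile
#' bootstrap confidence interval obtained by resampling sites with
#' replacement (1000 repetitions by default). Weighting sites by the
#' square root of the number of pooled legs is available but off by
#' default, matching the reporting convention for this assay.
#'
#' @param site_frequencies Numeric vector of per-site frequencies, or a
#'   data frame with a `frequency` column (and `n_legs` when weighting).
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for a reproducible interval.
#' @param confidence Confidence level (default 0.95).
#' @param weighting `"none"` (default) or `"sqrt_legs"`.
#' @return A one-row tibble: `n_sites`, `mean`, `lower`, `upper`, `reps`.
#' @examples
#' annual_mean_bootstrap(c(0.08, 0.12, 0.10, 0.09), seed = 1)
#' @export
annual_mean_bootstrap <- function(site_frequencies, reps = 1000, seed = NULL,
                                  confidence = 0.95,
                                  weighting = c("none", "sqrt_legs")) {
  weighting <- match.arg(weighting)
  weights <- NULL
  if (is.data.frame(site_frequencies)) {
    stopifnot("frequency" %in% names(site_frequencies))
    if (weighting == "sqrt_legs") {
      stopifnot("n_legs" %in% names(site_frequencies))
      weights <- sqrt(site_frequencies$n_legs)
    }
    site_frequencies <- site_frequencies$frequency
  }
  if (length(site_frequencies) == 0) abort("No site frequencies supplied.")
  check_fraction(site_frequencies, "site_frequencies", allow_vector = TRUE)
  reps <- check_count(reps, "reps", min = 1L)

  site_mean <- function(idx) {
    if (is.null(weights)) mean(site_frequencies[idx])
    else sum(site_frequencies[idx] * weights[idx]) / sum(weights[idx])
  }
  n <- length(site_frequencies)
  draw <- function() {
    means <- vapply(seq_len(reps),
                    function(i) site_mean(sample.int(n, replace = TRUE)),
                    numeric(1))
    quantile(means, probs = c((1 - confidence) / 2, 1 - (1 - confidence) / 2),
             names = FALSE)
  }
  ci <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(
    n_sites = n, mean = site_mean(seq_len(n)),
    lower = ci[[1]], upper = ci[[2]], reps = reps
  )
}
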