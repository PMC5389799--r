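#' Natural abundance of +1-mass-unit heavy isotopes
#'
#' Default per-element abundances of the heavy isotope one mass unit above
#' the principal isotope, as fractions: 13C, 2H, 15N, 17O and 29Si. These
#' drive the natural-abundance correction of selected-ion-monitoring (SIM)
#' heavy/light peak-area ratios for tBDMS amino-acid derivatives.
#'
#' @return Named numeric vector (element symbol -> M+1 abundance fraction).
#' @examples
#' default_abundance_table()
#' @export
default_abundance_table <- function() {
  c(C = 0.0110, H = 0.00015, N = 0.0037, O = 0.0004, Si = 0.047)
}

validate_abundance_table <- function(table) {
  if (is.null(names(table)) || any(!nzchar(names(table)))) {
    stop("abundance table must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(table)) || any(table <= 0) || any(table >= 0.1)) {
    stop("heavy-isotope abundances must lie in (0, 0.1)", call. = FALSE)
  }
  invisible(table)
}

#' Parse an elemental composition string
#'
#' Parses strings such as `"C16H21N1O2Si2"` (element symbol followed by an
#' optional count; a missing count means 1) into a named integer vector.
#'
#' @param x Composition string.
#' @return Named integer vector of atom counts.
#' @examples
#' parse_composition("C16H21N1O2Si2")
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("[[:space:]_]", "", x)
  if (!nzchar(x)) stop("empty composition", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse composition string: ", x, call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(sub("^[A-Za-z]+", "", paste0(tokens, "")))
  counts[is.na(counts)] <- 1L
  comp <- tapply(counts, elems, sum)
  out <- as.integer(comp)
  names(out) <- names(comp)
  validate_composition(out)
  out
}

validate_composition <- function(composition) {
  if (length(composition) == 0L || sum(composition) < 1L) {
    stop("composition must contain at least one atom", call. = FALSE)
  }
  if (any(composition < 0L) || any(composition > 200L)) {
    stop("atom counts must be in [0, 200]", call. = FALSE)
  }
  invisible(composition)
}

#' Natural-abundance M+1 correction factor from an elemental composition
#'
#' Computes the expected heavy/light (M+1 over M) SIM peak-area ratio due to
#' naturally occurring heavy isotopes alone. The `"linear"` method is the
#' first-order sum over elements, atom count times M+1 abundance; it is the
#' convention used to derive the packaged correction factors (e.g. 0.278 for
#' the m/z 331/330 glutamate fragment). The `"exact"` method evaluates
#' P(M+1)/P(M0) for single heavy substitution from the full isotope-pattern
#' product, i.e. the sum of n_e * p_e / (1 - p_e).
#'
#' @param composition Named integer vector of atom counts, or a composition
#'   string accepted by [parse_composition()].
#' @param table Abundance table as from [default_abundance_table()].
#' @param method `"linear"` (default) or `"exact"`.
#' @return Correction factor as a fraction (e.g. 0.278, i.e. 27.8%).
#' @examples
#' mplus1_fraction("C16H21N1O2Si2") # ~0.278
#' @export
mplus1_fraction <- function(composition, table = default_abundance_table(),
                            method = c("linear", "exact")) {
  method <- match.arg(method)
  if (is.character(composition)) composition <- parse_composition(composition)
  validate_composition(composition)
  validate_abundance_table(table)
  missing <- setdiff(names(composition)[composition > 0L], names(table))
  if (length(missing)) {
    stop("no heavy-isotope abundance for element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- table[names(composition)]
  switch(method,
    linear = sum(composition * p),
    exact  = sum(composition * p / (1 - p))
  )
}

#' Fractional biological 13C enrichment from a SIM ion-pair ratio
#'
#' Converts an observed heavy/light peak-area ratio to biological fractional
#' 13C enrichment, after subtracting the natural-abundance contribution:
#' E = (A/B - C) / (1 + (A/B - C)), where A is the heavy-ion and B the
#' light-ion peak area and C the natural-abundance correction factor.
#' Ratios below C give a (retained, not truncated) negative enrichment; use
#' `A/B < C` to flag such below-baseline points.
#'
#' @param area_heavy Heavy-ion (M+1) peak area, >= 0. Vectorized.
#' @param area_light Light-ion (M) peak area, > 0. Vectorized.
#' @param correction Correction factor C in (0, 1).
#' @return Numeric vector of fractional enrichments (always < 1).
#' @examples
#' fractional_enrichment(127.8, 100, 0.278) # 0.5
#' @export
fractional_enrichment <- function(area_heavy, area_light, correction) {
  if (any(!is.finite(area_light)) || any(area_light <= 0)) {
    stop("light-ion peak area must be positive", call. = FALSE)
  }
  if (any(area_heavy < 0)) {
    stop("heavy-ion peak area must be non-negative", call. = FALSE)
  }
  if (any(correction <= 0) || any(correction >= 1)) {
    stop("correction factor must lie in (0, 1)", call. = FALSE)
  }
  x <- area_heavy / area_light - correction
  if (any(1 + x <= 0)) {
    stop("degenerate ratio: 1 + (A/B - C) <= 0", call. = FALSE)
  }
  x / (1 + x)
}

#' Forward model: SIM peak areas from a true enrichment
#'
#' Inverse of [fractional_enrichment()]: generates a heavy/light peak-area
#' pair whose noiseless ratio is A/B = C + E/(1 - E). With `cv > 0`, both
#' areas are multiplied by independent mean-one lognormal factors with the
#' given coefficient of variation (reproducible under the caller's RNG
#' state, i.e. via `set.seed()`).
#'
#' @param enrichment True fractional enrichment E in [0, 1).
#' @param correction Correction factor C in (0, 1).
#' @param area_light Noiseless light-ion peak area scale (default 1e5).
#' @param cv Coefficient of variation of the multiplicative area noise.
#' @return A tibble with columns `area_heavy`, `area_light`.
#' @examples
#' simulate_peak_areas(0.5, 0.278, area_light = 100) # A = 127.8
#' @export
simulate_peak_areas <- function(enrichment, correction, area_light = 1e5,
                                cv = 0) {
  if (any(enrichment >= 1)) {
    stop("true enrichment must be < 1", call. = FALSE)
  }
  if (any(enrichment < 0)) {
    stop("true enrichment must be >= 0", call. = FALSE)
  }
  stopifnot(cv >= 0)
  n <- max(length(enrichment), length(area_light))
  ratio <- correction + enrichment / (1 - enrichment)
  a <- rep_len(area_light * ratio, n)
  b <- rep_len(area_light, n)
  if (cv > 0) {
    a <- a * rlnorm_cv(n, cv)
    b <- b * rlnorm_cv(n, cv)
  }
  tibble::tibble(area_heavy = a, area_light = b)
}

# mean-one lognormal multiplicative noise with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Average the enrichment over concordant ion pairs
#'
#' The reported enrichment for an analyte/fraction is the arithmetic mean of
#' the enrichments from its ion pairs covering the same carbon span (for
#' tBDMS-GLU, m/z 331/330 and 273/272). Pairs are expected to agree within
#' +/- 1% absolute enrichment; a larger spread raises a discordance flag but
#' the mean is still returned.
#'
#' @param enrichments Numeric vector of per-ion-pair enrichments.
#' @param carbons Optional character vector of carbon-span labels (e.g.
#'   `"C2-C5"`); mixing spans is an error.
#' @param tol Absolute concordance tolerance (default 0.01).
#' @return List with `enrichment` (mean), `discordant` (logical) and
#'   `spread` (max - min).
#' @export
mean_ion_pair_enrichment <- function(enrichments, carbons = NULL, tol = 0.01) {
  if (length(enrichments) < 1L) {
    stop("at least one ion-pair enrichment is required", call. = FALSE)
  }
  if (!is.null(carbons) && length(unique(carbons)) > 1L) {
    stop("ion pairs cover different carbon spans: ",
         paste(unique(carbons), collapse = ", "), call. = FALSE)
  }
  spread <- max(enrichments) - min(enrichments)
  list(enrichment = mean(enrichments),
       discordant = spread > tol,
       spread = spread)
}
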