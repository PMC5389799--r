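#' Packaged SIM ion-pair definitions for tBDMS-GLU and tBDMS-pyroGLU
#'
#' One row per light/heavy ion pair monitored for the tBDMS derivative of
#' extracellular glutamate ("GLU") and of glutamine-derived pyroglutamate
#' ("GLN"; glutamine is cyclized to pyroglutamate because tBDMS-glutamine is
#' unstable). `correction_factor` is the authoritative natural-abundance
#' heavy/light ratio for the fragment; `composition` is a plausible fragment
#' elemental composition whose linear M+1 sum reproduces the factor to
#' within 0.01 (useful as a cross-check; when both are present the explicit
#' factor wins). `use_for_mean` marks the C2-C5 pairs averaged into the
#' reported enrichment.
#'
#' The m/z 330 glutamate fragment is recorded with composition
#' C16H21N1O2Si2; note its nominal mass (315) suggests the hydrogen count is
#' understated (H36 gives mass 330), but both H counts give the same 27.8%
#' factor at the reported precision because hydrogen contributes < 0.006.
#'
#' @return Tibble: `analyte`, `pair`, `light_mz`, `heavy_mz`, `carbons`,
#'   `composition`, `correction_factor`, `use_for_mean`.
#' @examples
#' default_ion_pairs()
#' @export
default_ion_pairs <- function() {
  pairs <- tibble::tribble(
    ~analyte, ~light_mz, ~heavy_mz, ~carbons, ~composition,     ~correction_factor, ~use_for_mean,
    "GLU",    432L,      433L,      "C1-C5",  "C19H40N1O4Si3",  0.362,              FALSE,
    "GLU",    330L,      331L,      "C2-C5",  "C16H21N1O2Si2",  0.278,              TRUE,
    "GLU",    272L,      273L,      "C2-C5",  "C12H26N1O2Si2",  0.234,              TRUE,
    "GLN",    300L,      301L,      "C1-C5",  "C13H26N1O3Si2",  0.245,              FALSE,
    "GLN",    272L,      273L,      "C2-C5",  "C12H26N1O2Si2",  0.234,              TRUE,
    "GLN",    198L,      199L,      "C2-C5",  "C10H20N1O1Si1",  0.161,              TRUE
  )
  pairs$pair <- paste0(pairs$heavy_mz, "/", pairs$light_mz)
  validate_ion_pairs(pairs)
}

validate_ion_pairs <- function(pairs) {
  required <- c("analyte", "pair", "light_mz", "heavy_mz", "carbons",
                "correction_factor")
  missing <- setdiff(required, names(pairs))
  if (length(missing)) {
    stop("ion-pair table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(pairs$heavy_mz != pairs$light_mz + 1L)) {
    stop("heavy m/z must equal light m/z + 1", call. = FALSE)
  }
  if (any(pairs$correction_factor <= 0 | pairs$correction_factor >= 1)) {
    stop("correction factors must lie in (0, 1)", call. = FALSE)
  }
  pairs
}

#' Read an ion-pair definition CSV
#'
#' Columns: `analyte`, `light_mz`, `heavy_mz`, `carbons`, optional
#' `composition` (string such as `"C16H21N1O2Si2"`), optional
#' `correction_factor`. When `correction_factor` is missing for a row it is
#' derived from the composition with [mplus1_fraction()] (linear method);
#' when both are present the explicit factor wins.
#'
#' @param path CSV path.
#' @param table Abundance table used when deriving missing factors.
#' @return Ion-pair tibble as [default_ion_pairs()].
#' @export
read_ion_pairs <- function(path, table = default_abundance_table()) {
  pairs <- readr::read_csv(path, show_col_types = FALSE)
  if (!"correction_factor" %in% names(pairs)) pairs$correction_factor <- NA_real_
  derive <- is.na(pairs$correction_factor)
  if (any(derive)) {
    if (!"composition" %in% names(pairs) || anyNA(pairs$composition[derive])) {
      stop("rows without correction_factor need a composition", call. = FALSE)
    }
    pairs$correction_factor[derive] <-
      vapply(pairs$composition[derive],
             function(x) mplus1_fraction(x, table), numeric(1))
  }
  if (!"pair" %in% names(pairs)) {
    pairs$pair <- paste0(pairs$heavy_mz, "/", pairs$light_mz)
  }
  if (!"use_for_mean" %in% names(pairs)) {
    pairs$use_for_mean <- pairs$carbons == "C2-C5"
  }
  validate_ion_pairs(tibble::as_tibble(pairs))
}
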