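#' @keywords internal
"_PACKAGE"

# Conversion factors to micromolar. Concentrations are always carried as a
# numeric value plus an explicit unit string; nothing is converted silently.
.conc_units <- c(M = 1e6, mM = 1e3, uM = 1, nM = 1e-3, pM = 1e-6)

#' Convert a concentration between units
#'
#' All internal binding algebra is done in a single unit chosen per call;
#' this helper performs the only unit conversions in the package.
#'
#' @param value numeric vector of concentrations.
#' @param from,to unit strings, one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_conc(50, "nM", "uM") # 0.05
#' @export
convert_conc <- function(value, from = "uM", to = "uM") {
  from <- match.arg(from, names(.conc_units))
  to <- match.arg(to, names(.conc_units))
  value * .conc_units[[from]] / .conc_units[[to]]
}

#' Fraction of a reference set that was detected
#'
#' Coverage bookkeeping for proteome-scale experiments: the share of a
#' reference database (e.g. a 20,358-entry proteome FASTA) detected with
#' quantifiable peptides.
#'
#' @param n_detected number of detected entries.
#' @param n_reference size of the reference set.
#' @param percent report as percent (default) or as a fraction.
#' @return coverage as a percentage (or fraction).
#' @examples
#' proteome_coverage(6516, 20358) # ~32
#' @export
proteome_coverage <- function(n_detected, n_reference, percent = TRUE) {
  stopifnot(n_reference > 0, n_detected >= 0, n_detected <= n_reference)
  frac <- n_detected / n_reference
  if (percent) 100 * frac else frac
}

#' Concentration after dilution
#'
#' @param conc starting concentration (any unit).
#' @param fold dilution factor (> 0); extracts prepared from cells are
#'   typically treated as ~100-fold diluted relative to cellular
#'   concentrations.
#' @return diluted concentration in the same unit.
#' @examples
#' dilute_conc(100, 100) # 100 nM complex in a 100-fold diluted extract -> 1 nM
#' @export
dilute_conc <- function(conc, fold) {
  stopifnot(is.numeric(conc), is.numeric(fold), all(fold > 0))
  conc / fold
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never perturbs user RNG streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-component child seed from a root seed so that adding one
# generator call does not perturb the streams of the others. Kept below
# 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647
}
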