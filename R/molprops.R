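# Molecular properties derived from assigned CHONSP formulas.

#' IUPAC monoisotopic atomic masses used throughout the package
#'
#' Masses (Da) of the six elements considered during formula assignment of
#' negative-mode FTICR-MS dissolved organic matter data: C, H, N, O, S, P.
#'
#' @format Named numeric vector of length 6.
#' @export
ATOMIC_MASSES <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

ELEMENTS <- names(ATOMIC_MASSES)

#' Neutral monoisotopic mass of a molecular formula
#'
#' Computes the exact neutral monoisotopic mass from CHONSP element counts
#' using [ATOMIC_MASSES]. Vectorised over rows when given a data frame.
#'
#' @param C,H,N,O,S,P Non-negative integer element counts. `C` may instead be
#'   a data frame holding columns named `C`, `H`, `N`, `O`, `S`, `P` (missing
#'   columns are treated as zero), in which case the remaining arguments are
#'   ignored.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass(C = 1, H = 4)           # methane, 16.0313
#' monoisotopic_mass(C = 3, H = 5, N = 1, O = 1, S = 1)  # cysteine residue
#' @export
monoisotopic_mass <- function(C = 0, H = 0, N = 0, O = 0, S = 0, P = 0) {
  if (is.data.frame(C)) {
    df <- C
    counts <- sapply(ELEMENTS, function(el) {
      if (el %in% names(df)) {
        v <- df[[el]]
        v[is.na(v)] <- 0
        as.numeric(v)
      } else {
        rep(0, nrow(df))
      }
    })
    counts <- matrix(counts, nrow = nrow(df), dimnames = list(NULL, ELEMENTS))
  } else {
    counts <- cbind(C = C, H = H, N = N, O = O, S = S, P = P)
  }
  if (any(counts < 0, na.rm = TRUE)) {
    stop("element counts must be non-negative")
  }
  as.numeric(counts %*% ATOMIC_MASSES[colnames(counts)])
}

#' Derived molecular properties of assigned formulas
#'
#' For each formula-assigned peak, computes the derived statistics that span
#' the molecular-characteristics trait space:
#' \describe{
#'   \item{DBE}{double-bond equivalents, `1 + (2C - H + N + P)/2`}
#'   \item{AImod}{modified aromaticity index (Koch & Dittmar),
#'     `(1 + C - 0.5 O - S - 0.5 H) / (C - 0.5 O - N - S - P)`, set to 0 when
#'     the numerator or denominator is non-positive and clamped to `[0, 1]`}
#'   \item{NOSC}{nominal oxidation state of carbon (LaRowe & Van Cappellen),
#'     `4 - (4C + H - 3N - 2O + 5P - 2S)/C` for the neutral molecule}
#'   \item{gibbs}{standard Gibbs free energy of carbon oxidation,
#'     `60.3 - 28.5 * NOSC` (kJ per mol C)}
#'   \item{kdef}{CH2-based Kendrick mass defect: Kendrick mass is
#'     `mass * 14 / 14.01565`; the defect is `nominal(mass) - Kendrick mass`,
#'     with nominal mass by nearest-integer rounding (default) or `floor`}
#' }
#'
#' @param x A `peak_table` (only formula-assigned peaks are used) or a data
#'   frame with columns `C`, `H` and optionally `N`, `O`, `S`, `P` and `mass`.
#' @param mass Optional numeric vector of neutral monoisotopic masses; when
#'   omitted, taken from `x$mass` if present, otherwise recomputed from the
#'   formula via [monoisotopic_mass()].
#' @param kendrick_rounding `"round"` (default) or `"floor"`: how the nominal
#'   mass entering the Kendrick defect is obtained.
#' @return Data frame with one row per formula-assigned peak: `peak_id` (when
#'   available), the six element counts, `mass`, `DBE`, `AImod`, `NOSC`,
#'   `gibbs` and `kdef`.
#' @examples
#' compute_properties(data.frame(C = 6, H = 12, O = 6))  # glucose: NOSC 0
#' @export
compute_properties <- function(x, mass = NULL,
                               kendrick_rounding = c("round", "floor")) {
  kendrick_rounding <- match.arg(kendrick_rounding)
  if (inherits(x, "peak_table")) {
    pk <- x$peaks
    keep <- !is.na(pk$C)
    df <- pk[keep, , drop = FALSE]
  } else {
    df <- as.data.frame(x)
  }
  n <- nrow(df)
  counts <- sapply(ELEMENTS, function(el) {
    if (el %in% names(df)) {
      v <- as.numeric(df[[el]])
      v[is.na(v)] <- 0
      v
    } else {
      rep(0, n)
    }
  })
  counts <- matrix(counts, nrow = n, dimnames = list(NULL, ELEMENTS))
  if (is.null(mass)) {
    mass <- if ("mass" %in% names(df)) as.numeric(df$mass) else
      monoisotopic_mass(as.data.frame(counts))
  }
  C <- counts[, "C"]; H <- counts[, "H"]; N <- counts[, "N"]
  O <- counts[, "O"]; S <- counts[, "S"]; P <- counts[, "P"]
  if (any(C == 0)) {
    bad <- which(C == 0)
    stop("NOSC undefined for formulas without carbon (row ",
         paste(bad, collapse = ", "), ")")
  }

  dbe <- 1 + (2 * C - H + N + P) / 2
  ai_num <- 1 + C - 0.5 * O - S - 0.5 * H
  ai_den <- C - 0.5 * O - N - S - P
  aimod <- ifelse(ai_num <= 0 | ai_den <= 0, 0, ai_num / ai_den)
  aimod <- pmin(pmax(aimod, 0), 1)
  nosc <- 4 - (4 * C + H - 3 * N - 2 * O + 5 * P - 2 * S) / C
  gibbs <- 60.3 - 28.5 * nosc
  kmass <- mass * 14 / 14.01565
  nominal <- if (kendrick_rounding == "round") round(mass) else floor(mass)
  kdef <- nominal - kmass

  out <- data.frame(counts, mass = mass, DBE = dbe, AImod = aimod,
                    NOSC = nosc, gibbs = gibbs, kdef = kdef)
  if ("peak_id" %in% names(df)) {
    out <- cbind(peak_id = df$peak_id, out)
    rownames(out) <- df$peak_id
  }
  out
}

#' Write a per-peak molecular property table
#'
#' @param props Data frame from [compute_properties()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(props, path) {
  utils::write.csv(props, path, row.names = FALSE)
  invisible(path)
}
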