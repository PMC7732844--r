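# Synthetic CHONSP formula universes and assemblages under controlled
# assembly regimes, for validation without any external data download.

# transformations used to chain new formulas off existing ones, so the
# mass-difference network is non-trivially connected
CHAIN_NAMES <- c("CH2", "H2O", "O", "CO2", "C2H4O2 (acetic acid)",
                 "NH3", "glycine (C2H3NO)", "alanine (C3H5NO)",
                 "C2H2O (acetyl)", "C6H10O5 (hexose)")

formula_ok <- function(f, mass_range) {
  with(as.list(f), {
    if (C < 4 || C > 50 || H < 1 || H > 2 * C + 2) return(FALSE)
    if (O > C + 2 || N > 4 || S > 2 || P > 1) return(FALSE)
    dbe <- 1 + (2 * C - H + N + P) / 2
    if (dbe < 0) return(FALSE)
    m <- monoisotopic_mass(C, H, N, O, S, P)
    m >= mass_range[1] && m <= mass_range[2]
  })
}

random_formula <- function(mass_range) {
  for (tries in 1:500) {
    f <- c(C = sample(4:50, 1), H = 0, N = sample(0:4, 1),
           O = 0, S = sample(0:2, 1), P = sample(0:1, 1))
    f["H"] <- sample.int(2 * f["C"] + 2, 1)
    f["O"] <- sample(0:(f["C"] + 2), 1)
    if (formula_ok(f, mass_range)) return(f)
  }
  stop("could not sample a formula satisfying the constraints")
}

#' Generate a synthetic CHONSP formula universe
#'
#' Samples `n` molecular formulas with realistic elemental bounds
#' (C 4-50, H <= 2C+2, O <= C+2, N <= 4, S <= 2, P <= 1), rejecting any with
#' negative double-bond equivalents or a monoisotopic mass outside
#' `mass_range`. With probability `p_chain`, a new formula is instead created
#' by adding a biochemical transformation (CH2, water, amino-acid residue,
#' sugar, ...) to an already-accepted formula, so that the resulting peak
#' list carries a connected mass-difference network the way real dissolved
#' organic matter does.
#'
#' @param n Number of peaks (>= 10).
#' @param seed Optional integer seed.
#' @param p_chain Probability of deriving a formula from an existing one.
#' @param mass_range Allowed neutral mass window in Da (default 200-900).
#' @return Data frame: `peak_id`, `mass`, `C`, `H`, `N`, `O`, `S`, `P`.
#' @export
gen_formula_universe <- function(n, seed = NULL, p_chain = 0.5,
                                 mass_range = c(200, 900)) {
  if (n < 10) stop("n must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  db <- transformation_database()
  chain <- db[db$name %in% CHAIN_NAMES, , drop = FALSE]
  acc <- matrix(0, n, 6, dimnames = list(NULL, ELEMENTS))
  ids <- character(n)
  k <- 0
  while (k < n) {
    f <- NULL
    if (k >= 1 && stats::runif(1) < p_chain) {
      parent <- acc[sample.int(k, 1), ]
      tr <- chain[sample.int(nrow(chain), 1), ]
      cand <- parent + unlist(tr[ELEMENTS])
      if (formula_ok(cand, mass_range)) f <- cand
    }
    if (is.null(f)) f <- random_formula(mass_range)
    m <- monoisotopic_mass(f["C"], f["H"], f["N"], f["O"], f["S"], f["P"])
    id <- format_peak_id(m)
    if (id %in% ids[seq_len(k)]) next  # mass collision at 4 d.p.: resample
    k <- k + 1
    acc[k, ] <- f[ELEMENTS]
    ids[k] <- id
  }
  out <- data.frame(acc, mass = monoisotopic_mass(as.data.frame(acc)))
  out$peak_id <- ids
  out <- out[order(out$mass), c("peak_id", "mass", ELEMENTS)]
  rownames(out) <- NULL
  out
}

#' Define a simulation scenario
#'
#' A scenario fixes the habitat structure (sample groups with optional NOSC
#' trait windows), the assembly regime, and the per-sample richness used by
#' [gen_assemblages()].
#'
#' Regimes: `neutral` draws every sample from shared lognormal occupancy
#' weights; `homogeneous_selection` restricts all samples to the first
#' habitat's trait window; `variable_selection` restricts each habitat to its
#' own (disjoint) window; `mixing` copies one template assemblage and
#' resamples each present peak with probability `perturb`.
#'
#' @param regime One of `"neutral"`, `"homogeneous_selection"`,
#'   `"variable_selection"`, `"mixing"`.
#' @param n_samples Samples per habitat.
#' @param richness Peaks detected per sample.
#' @param habitats List of `list(name =, window = c(lo, hi))`; `window` is a
#'   NOSC interval or `NULL`. Default: two habitats (`"surface"`, `"pore"`)
#'   without windows.
#' @param perturb Per-peak resampling probability for the mixing regime.
#' @param seed Optional integer seed.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(regime = c("neutral", "homogeneous_selection",
                                    "variable_selection", "mixing"),
                         n_samples = 10, richness = 60,
                         habitats = NULL, perturb = 0.05, seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(habitats)) {
    habitats <- list(list(name = "surface", window = NULL),
                     list(name = "pore", window = NULL))
  }
  structure(list(regime = regime, n_samples = n_samples, richness = richness,
                 habitats = habitats, perturb = perturb, seed = seed),
            class = "sim_scenario")
}

#' Default disjoint NOSC trait windows for a universe
#'
#' Splits the universe's NOSC distribution at its 40% and 60% quantiles and
#' returns the reduced (left) and oxidised (right) tails as two disjoint
#' habitat windows, each holding 40% of the peaks. Used by the
#' variable-selection scenario; for homogeneous selection the central window
#' between the 30% and 70% quantiles is returned instead.
#'
#' @param universe Data frame from [gen_formula_universe()].
#' @param type `"disjoint"` (two windows) or `"central"` (one window).
#' @return List of numeric `c(lo, hi)` windows.
#' @export
nosc_windows <- function(universe, type = c("disjoint", "central")) {
  type <- match.arg(type)
  nosc <- compute_properties(universe)$NOSC
  if (type == "disjoint") {
    q <- stats::quantile(nosc, c(0.4, 0.6), names = FALSE)
    list(c(-4, q[1]), c(q[2], 4))
  } else {
    q <- stats::quantile(nosc, c(0.3, 0.7), names = FALSE)
    list(c(q[1], q[2]))
  }
}

#' Generate sample-by-peak assemblages under a scenario
#'
#' @param universe Data frame from [gen_formula_universe()].
#' @param scenario A [sim_scenario()]. For the selection regimes, habitats
#'   without explicit windows get default NOSC windows via [nosc_windows()].
#' @return List: `incidence` (binary samples x peaks matrix over the whole
#'   universe), `sample_meta` (sample_id, group), `truth` (regime, windows,
#'   occupancy weights).
#' @export
gen_assemblages <- function(universe, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n_peaks <- nrow(universe)
  richness <- scenario$richness
  if (richness > n_peaks) stop("richness exceeds universe size")
  habs <- scenario$habitats
  regime <- scenario$regime

  if (regime %in% c("homogeneous_selection", "variable_selection") &&
      any(vapply(habs, function(h) is.null(h$window), TRUE))) {
    win <- if (regime == "variable_selection") {
      nosc_windows(universe, "disjoint")
    } else {
      rep(nosc_windows(universe, "central"), length(habs))
    }
    if (length(win) < length(habs)) stop("more habitats than trait windows")
    for (i in seq_along(habs)) habs[[i]]$window <- win[[i]]
  }
  nosc <- compute_properties(universe)$NOSC
  weights <- stats::rlnorm(n_peaks)  # shared occupancy weights

  pool_for <- function(h) {
    if (is.null(h$window)) return(seq_len(n_peaks))
    p <- which(nosc >= h$window[1] & nosc <= h$window[2])
    if (length(p) < richness) {
      stop("trait window [", h$window[1], ", ", h$window[2], "] holds ",
           length(p), " peaks, fewer than the per-sample richness ", richness)
    }
    p
  }

  sample_ids <- character(0); groups <- character(0)
  inc <- NULL
  draw <- function(pool) {
    idx <- pool[sample.int(length(pool), richness, prob = weights[pool])]
    v <- integer(n_peaks); v[idx] <- 1L
    v
  }
  if (regime == "mixing") {
    template <- draw(seq_len(n_peaks))
  }
  for (h in habs) {
    pool <- switch(regime,
      neutral = seq_len(n_peaks),
      mixing = seq_len(n_peaks),
      homogeneous_selection = pool_for(list(window = habs[[1]]$window)),
      variable_selection = pool_for(h))
    for (r in seq_len(scenario$n_samples)) {
      v <- if (regime == "mixing") {
        vv <- template
        present <- which(vv == 1L)
        flip <- present[stats::runif(length(present)) < scenario$perturb]
        if (length(flip)) {
          absent <- which(vv == 0L)
          repl <- absent[sample.int(length(absent), length(flip),
                                    prob = weights[absent])]
          vv[flip] <- 0L; vv[repl] <- 1L
        }
        vv
      } else {
        draw(pool)
      }
      inc <- rbind(inc, v)
      sample_ids <- c(sample_ids, paste0(h$name, "_", r))
      groups <- c(groups, h$name)
    }
  }
  dimnames(inc) <- list(sample_ids, universe$peak_id)
  list(incidence = inc,
       sample_meta = data.frame(sample_id = sample_ids, group = groups,
                                stringsAsFactors = FALSE),
       truth = list(regime = regime,
                    windows = lapply(habs, `[[`, "window"),
                    weights = weights))
}

#' Write a simulated dataset in the package's input CSV formats
#'
#' Produces the same file layout [read_peak_table()] consumes (peak CSV with
#' `Mass`, element counts and per-sample intensity columns; sample metadata
#' CSV) plus a ground-truth JSON sidecar, guaranteeing a lossless round trip
#' from simulation to ingestion.
#'
#' @param universe Data frame from [gen_formula_universe()].
#' @param assemblages List from [gen_assemblages()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(universe, assemblages, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peaks_path <- file.path(dir, "peaks.csv")
  meta_path <- file.path(dir, "sample_metadata.csv")
  truth_path <- file.path(dir, "truth.json")
  tab <- data.frame(Mass = universe$mass, universe[ELEMENTS],
                    t(assemblages$incidence), check.names = FALSE)
  utils::write.csv(tab, peaks_path, row.names = FALSE)
  utils::write.csv(assemblages$sample_meta, meta_path, row.names = FALSE)
  jsonlite::write_json(assemblages$truth[c("regime", "windows")], truth_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(peaks = peaks_path, metadata = meta_path, truth = truth_path))
}
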