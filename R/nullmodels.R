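# Ecological null models: NRI/NTI, beta-MNTD/beta-NTI, Raup-Crick, and
# assembly-process classification.

#' Null-model configuration
#'
#' @param n_null_alpha Randomisations for NRI/NTI (default 999).
#' @param n_null_beta Randomisations for beta-NTI (default 999).
#' @param n_null_rc Null draws per pair for Raup-Crick (default 9999).
#' @param seed Optional integer seed; when set, results are bit-reproducible.
#' @return List of class `null_config`.
#' @export
null_config <- function(n_null_alpha = 999, n_null_beta = 999,
                        n_null_rc = 9999, seed = NULL) {
  counts <- c(n_null_alpha, n_null_beta, n_null_rc)
  if (any(counts < 99)) stop("null draw counts must be at least 99")
  structure(list(n_null_alpha = as.integer(n_null_alpha),
                 n_null_beta = as.integer(n_null_beta),
                 n_null_rc = as.integer(n_null_rc),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 shuffle_scheme = "tip_shuffle"),
            class = "null_config")
}

set_seed_if_any <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
}

prepare_null_inputs <- function(m, d, what = "dendrogram") {
  if (inherits(m, "peak_table")) m <- m$incidence
  d <- check_square(d)
  m <- align_matrix_to_ids(m, rownames(d), what)
  d <- d[colnames(m), colnames(m)]
  list(m = m, d = d)
}

# standardized effect size of a per-sample alpha metric against tip-shuffled
# nulls. metric_fun(d, idx) -> scalar. Tip shuffling relabels the dendrogram
# leaves, which is equivalent to permuting the distance-matrix labels.
ses_alpha <- function(m, d, cfg, metric_fun, negate) {
  set_seed_if_any(cfg)
  n <- ncol(m)
  idx_list <- apply(m > 0, 1, which, simplify = FALSE)
  obs <- vapply(idx_list, function(i) metric_fun(d, i), numeric(1))
  nulls <- matrix(NA_real_, cfg$n_null_alpha, nrow(m))
  for (b in seq_len(cfg$n_null_alpha)) {
    p <- sample.int(n)
    nulls[b, ] <- vapply(idx_list, function(i) metric_fun(d, p[i]), numeric(1))
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  degenerate <- !is.na(null_sd) & null_sd < 1e-12
  z <- (obs - null_mean) / null_sd
  if (negate) z <- -z
  z[degenerate] <- NA_real_
  data.frame(sample = rownames(m), richness = lengths(idx_list),
             observed = obs, null_mean = null_mean, null_sd = null_sd,
             z = z, degenerate = degenerate, row.names = NULL)
}

mpd_idx <- function(d, idx) {
  s <- length(idx)
  if (s < 2) return(NA_real_)
  sum(d[idx, idx]) / (s * (s - 1))
}

mntd_idx <- function(d, idx) {
  if (length(idx) < 2) return(NA_real_)
  sub <- d[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  mean(row_mins(sub))
}

#' Net relatedness index (NRI) per sample
#'
#' Standardised effect size of MPD against tip-shuffled null assemblages,
#' multiplied by -1 so that positive values indicate clustering within the
#' dendrogram and negative values overdispersion.
#'
#' @param m Binary incidence matrix or `peak_table`.
#' @param d Cophenetic distance matrix of the dendrogram.
#' @param cfg A [null_config()].
#' @return Data frame: `sample`, `richness`, `observed`, `null_mean`,
#'   `null_sd`, `z` (the index; NA when degenerate), `degenerate`.
#' @export
nri <- function(m, d, cfg = null_config()) {
  inp <- prepare_null_inputs(m, d)
  out <- ses_alpha(inp$m, inp$d, cfg, mpd_idx, negate = TRUE)
  names(out)[names(out) == "z"] <- "nri"
  out
}

#' Nearest taxon index (NTI) per sample
#'
#' As [nri()] but for MNTD, capturing tip-level clustering.
#'
#' @inheritParams nri
#' @return Data frame as in [nri()] with column `nti`.
#' @export
nti <- function(m, d, cfg = null_config()) {
  inp <- prepare_null_inputs(m, d)
  out <- ses_alpha(inp$m, inp$d, cfg, mntd_idx, negate = TRUE)
  names(out)[names(out) == "z"] <- "nti"
  out
}

bmntd_idx <- function(d, a, b) {
  if (!length(a) || !length(b)) return(NA_real_)
  sub <- d[a, b, drop = FALSE]
  (mean(row_mins(sub)) + mean(row_mins(t(sub)))) / 2
}

#' Between-sample mean nearest taxon distance (beta-MNTD)
#'
#' For each sample pair, the average (over the two directions) of each
#' detected peak's minimum cophenetic distance to any peak detected in the
#' other sample; abundance-unweighted.
#'
#' @param m Binary incidence matrix or `peak_table`.
#' @param d Cophenetic distance matrix (or a `phylo`, from which it is
#'   computed).
#' @return Symmetric matrix of beta-MNTD values (zero diagonal).
#' @export
bmntd <- function(m, d) {
  if (inherits(d, "phylo")) d <- stats::cophenetic(d)
  inp <- prepare_null_inputs(m, d)
  idx <- apply(inp$m > 0, 1, which, simplify = FALSE)
  ns <- nrow(inp$m)
  out <- matrix(0, ns, ns, dimnames = list(rownames(inp$m), rownames(inp$m)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      out[i, j] <- out[j, i] <- bmntd_idx(inp$d, idx[[i]], idx[[j]])
    }
  }
  out
}

#' Beta nearest taxon index (beta-NTI) for all sample pairs
#'
#' Standardised effect size of beta-MNTD against null assemblages generated
#' by shuffling the tips of the whole dendrogram. The default sign convention
#' is `z = (obs - null_mean) / null_sd`, so `z > 2` marks pairs driven apart
#' by deterministic processes (variable selection) and `z < -2` pairs driven
#' together (homogeneous selection); `|z| < 2` is consistent with stochastic
#' assembly. `sign_convention = "negated"` returns `-z` instead for
#' compatibility with formulations that carry an explicit -1 factor.
#'
#' @param m Binary incidence matrix or `peak_table`.
#' @param tree `phylo` dendrogram or a cophenetic distance matrix.
#' @param cfg A [null_config()].
#' @param sign_convention `"ses"` (default) or `"negated"`.
#' @return Object of class `mme_bnti`: list with symmetric matrices
#'   `observed`, `null_mean`, `null_sd`, `z`, logical `degenerate`, plus the
#'   draw count and sign convention.
#' @export
bnti <- function(m, tree, cfg = null_config(),
                 sign_convention = c("ses", "negated")) {
  sign_convention <- match.arg(sign_convention)
  d <- if (inherits(tree, "phylo")) stats::cophenetic(tree) else tree
  inp <- prepare_null_inputs(m, d)
  set_seed_if_any(cfg)
  m2 <- inp$m; d2 <- inp$d
  n <- ncol(m2); ns <- nrow(m2)
  idx <- apply(m2 > 0, 1, which, simplify = FALSE)
  pairs <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  np <- nrow(pairs)

  obs <- vapply(seq_len(np), function(k) {
    bmntd_idx(d2, idx[[pairs[k, 1]]], idx[[pairs[k, 2]]])
  }, numeric(1))

  nulls <- matrix(NA_real_, cfg$n_null_beta, np)
  for (b in seq_len(cfg$n_null_beta)) {
    p <- sample.int(n)
    nulls[b, ] <- vapply(seq_len(np), function(k) {
      bmntd_idx(d2, p[idx[[pairs[k, 1]]]], p[idx[[pairs[k, 2]]]])
    }, numeric(1))
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  degenerate <- !is.na(null_sd) & null_sd < 1e-12
  z <- (obs - null_mean) / null_sd
  if (sign_convention == "negated") z <- -z
  z[degenerate] <- NA_real_

  to_mat <- function(v, diag_val = 0) {
    mt <- matrix(diag_val, ns, ns, dimnames = list(rownames(m2), rownames(m2)))
    mt[pairs] <- v
    mt[pairs[, c(2, 1), drop = FALSE]] <- v
    mt
  }
  structure(list(observed = to_mat(obs), null_mean = to_mat(null_mean),
                 null_sd = to_mat(null_sd, 0), z = to_mat(z),
                 degenerate = to_mat(degenerate, FALSE) > 0,
                 n_null = cfg$n_null_beta, sign_convention = sign_convention),
            class = "mme_bnti")
}

#' @export
print.mme_bnti <- function(x, ...) {
  z <- x$z[upper.tri(x$z)]
  cat("beta-NTI over", nrow(x$z), "samples (", length(z), "pairs,",
      x$n_null, "null draws )\n")
  cat("  z range:", round(min(z, na.rm = TRUE), 2), "to",
      round(max(z, na.rm = TRUE), 2), "; |z| > 2 in",
      sum(abs(z) > 2, na.rm = TRUE), "pair(s)\n")
  invisible(x)
}

sorensen_pair <- function(s1_in_s2, n1, n2) {
  1 - 2 * s1_in_s2 / (n1 + n2)
}

#' Raup-Crick dissimilarity deviation for all sample pairs
#'
#' For each sample pair, null assemblages are generated by drawing each
#' sample's observed richness from the regional pool (the union of peaks
#' detected anywhere in the matrix) without replacement, with probability
#' proportional to each peak's occupancy frequency across samples (or
#' uniformly with `weighting = "uniform"`). The observed Sorensen
#' dissimilarity is located within the null distribution; ties count half
#' (mid-P). The resulting probability is rescaled to `[-1, 1]`:
#' `RC = 2 * ((n_less + 0.5 * n_equal) / n_null - 0.5)`.
#'
#' @param m Binary incidence matrix or `peak_table`.
#' @param cfg A [null_config()] (`n_null_rc` draws per pair).
#' @param weighting `"occupancy"` (default) or `"uniform"`.
#' @return Symmetric matrix of RC values in `[-1, 1]` (zero diagonal).
#' @export
raup_crick <- function(m, cfg = null_config(),
                       weighting = c("occupancy", "uniform")) {
  weighting <- match.arg(weighting)
  if (inherits(m, "peak_table")) m <- m$incidence
  m <- as.matrix(m) > 0
  if (nrow(m) < 2) stop("need at least 2 samples")
  pool <- which(colSums(m) > 0)
  npool <- length(pool)
  occ <- colSums(m)[pool]
  w <- if (weighting == "occupancy") occ / sum(occ) else rep(1 / npool, npool)
  s <- rowSums(m)
  if (any(s > npool)) stop("a sample is richer than the regional pool")
  set_seed_if_any(cfg)

  ns <- nrow(m)
  nn <- cfg$n_null_rc
  member <- logical(npool)
  out <- matrix(0, ns, ns, dimnames = list(rownames(m), rownames(m)))
  msub <- m[, pool, drop = FALSE]
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      n1 <- s[i]; n2 <- s[j]
      obs <- sorensen_pair(sum(msub[i, ] & msub[j, ]), n1, n2)
      less <- 0; equal <- 0
      for (b in seq_len(nn)) {
        a <- sample.int(npool, n1, prob = w)
        bb <- sample.int(npool, n2, prob = w)
        member[a] <- TRUE
        shared <- sum(member[bb])
        member[a] <- FALSE
        nullv <- sorensen_pair(shared, n1, n2)
        if (nullv < obs - 1e-12) less <- less + 1
        else if (nullv <= obs + 1e-12) equal <- equal + 1
      }
      out[i, j] <- out[j, i] <- 2 * ((less + 0.5 * equal) / nn - 0.5)
    }
  }
  out
}

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated", "undominated_unresolved")

#' Classify assembly processes from beta-NTI and Raup-Crick values
#'
#' Applies the standard two-stage decision rule per sample pair:
#' `z > 2` variable selection; `z < -2` homogeneous selection; otherwise
#' `RC > 0.95` dispersal limitation, `RC < -0.95` homogenizing dispersal,
#' else undominated. A pair with `|z| < 2` but missing RC is labelled
#' `undominated_unresolved`.
#'
#' @param bnti An `mme_bnti` object or a symmetric matrix of beta-NTI values.
#' @param rc Symmetric matrix of RC values (or `NULL`).
#' @param bnti_threshold,rc_threshold Decision thresholds (defaults 2, 0.95).
#' @return Data frame of class `process_classification`: `sample_1`,
#'   `sample_2`, `bnti`, `rc`, `process` (factor).
#' @export
classify_processes <- function(bnti, rc = NULL, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  z <- if (inherits(bnti, "mme_bnti")) bnti$z else check_square(as.matrix(bnti))
  samples <- rownames(z)
  if (!is.null(rc)) {
    rc <- check_square(as.matrix(rc), "rc")
    rc <- rc[samples, samples]
  }
  idx <- which(upper.tri(z), arr.ind = TRUE)
  zi <- z[idx]
  rci <- if (is.null(rc)) rep(NA_real_, nrow(idx)) else rc[idx]
  proc <- ifelse(zi > bnti_threshold, "variable_selection",
          ifelse(zi < -bnti_threshold, "homogeneous_selection",
          ifelse(is.na(rci), "undominated_unresolved",
          ifelse(rci > rc_threshold, "dispersal_limitation",
          ifelse(rci < -rc_threshold, "homogenizing_dispersal",
                 "undominated")))))
  proc[is.na(zi)] <- NA
  out <- data.frame(sample_1 = samples[idx[, 1]],
                    sample_2 = samples[idx[, 2]],
                    bnti = zi, rc = rci,
                    process = factor(proc, levels = PROCESS_LEVELS))
  attr(out, "thresholds") <- c(bnti = bnti_threshold, rc = rc_threshold)
  class(out) <- c("process_classification", "data.frame")
  out
}

#' Summarise process classifications as percentages
#'
#' @param cls A `process_classification` data frame.
#' @param groups Optional named vector mapping sample -> group; when given,
#'   percentages are computed per group-pair block (e.g. pore-vs-surface).
#' @return Data frame with columns `block`, `process`, `n`, `percent`
#'   (percentages sum to 100 within each block).
#' @export
process_summary <- function(cls, groups = NULL) {
  block <- rep("all", nrow(cls))
  if (!is.null(groups)) {
    g1 <- groups[cls$sample_1]; g2 <- groups[cls$sample_2]
    block <- ifelse(is.na(g1) | is.na(g2), "all",
                    paste(pmin(g1, g2), pmax(g1, g2), sep = " vs "))
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(cls)), block), function(i) {
    tab <- table(cls$process[i])
    data.frame(block = block[i[1]], process = names(tab),
               n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(i),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
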