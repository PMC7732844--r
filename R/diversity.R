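# Alpha- and beta-diversity over binary metabolite assemblages.

row_mins <- function(m) {
  # fast row minima via max.col on the negated matrix
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

align_matrix_to_ids <- function(m, ids, what = "dendrogram") {
  m <- as.matrix(m)
  common <- intersect(colnames(m), ids)
  dropped <- ncol(m) - length(common)
  if (!length(common)) stop("no peaks shared with the ", what)
  if (dropped > 0) {
    warning("dropping ", dropped, " peak(s) absent from the ", what)
  }
  m[, common, drop = FALSE]
}

# edge-by-tip incidence: logical [n_edge x n_tip], TRUE when the tip lies
# below the edge. Postorder traversal so child edges are filled first.
edge_tip_incidence <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nnode <- max(edge)
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  inc <- below[edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(tree = tree, incidence = inc, lengths = tree$edge.length)
}

#' Metabolite richness per sample
#'
#' @param m Binary incidence matrix (samples x peaks) or a `peak_table`.
#' @return Named integer vector of per-sample peak counts.
#' @export
richness <- function(m) {
  if (inherits(m, "peak_table")) m <- m$incidence
  rowSums(as.matrix(m) > 0)
}

#' Dendrogram diversity (Faith-type branch-length sum) per sample
#'
#' Sums the branch lengths of the minimal subtree connecting the peaks
#' detected in a sample. With `include_root = TRUE` (default) the path up to
#' the dendrogram root is included, so even a single detected peak has a
#' positive diversity equal to its root-path length.
#'
#' @param m Binary incidence matrix (samples x peaks) or `peak_table`.
#' @param tree `phylo` dendrogram; peaks absent from the tree are dropped
#'   with a warning.
#' @param include_root Include the root path above the detected peaks' most
#'   recent common ancestor?
#' @return Named numeric vector (NA for samples with no peak on the tree).
#' @export
dendrogram_diversity <- function(m, tree, include_root = TRUE) {
  if (inherits(m, "peak_table")) m <- m$incidence
  m <- align_matrix_to_ids(m, tree$tip.label)
  et <- edge_tip_incidence(tree)
  inc <- et$incidence[, colnames(m), drop = FALSE]  # edges x kept tips
  # per edge and sample: number of detected descendants
  ndesc <- inc %*% t(m)
  s <- rowSums(m)
  dd <- vapply(seq_len(nrow(m)), function(k) {
    if (s[k] < 1) return(NA_real_)
    use <- ndesc[, k] > 0
    if (!include_root) use <- use & ndesc[, k] < s[k]
    sum(et$lengths[use])
  }, numeric(1))
  names(dd) <- rownames(m)
  dd
}

#' Mean pairwise distance (MPD) per sample
#'
#' Average cophenetic distance over all pairs of peaks detected in a sample
#' (abundance-unweighted, self-comparisons excluded).
#'
#' @param m Binary incidence matrix (samples x peaks) or `peak_table`.
#' @param d Cophenetic (or any symmetric) distance matrix with peak_id
#'   dimnames.
#' @return Named numeric vector; NA for samples with fewer than 2 peaks.
#' @export
mpd <- function(m, d) {
  if (inherits(m, "peak_table")) m <- m$incidence
  d <- check_square(d)
  m <- align_matrix_to_ids(m, rownames(d))
  d <- d[colnames(m), colnames(m)]
  out <- vapply(seq_len(nrow(m)), function(k) {
    idx <- which(m[k, ] > 0)
    s <- length(idx)
    if (s < 2) return(NA_real_)
    sum(d[idx, idx]) / (s * (s - 1))
  }, numeric(1))
  names(out) <- rownames(m)
  out
}

#' Mean nearest taxon distance (MNTD) per sample
#'
#' Average, over the peaks detected in a sample, of each peak's distance to
#' its nearest co-detected peak.
#'
#' @inheritParams mpd
#' @return Named numeric vector; NA for samples with fewer than 2 peaks.
#' @export
mntd <- function(m, d) {
  if (inherits(m, "peak_table")) m <- m$incidence
  d <- check_square(d)
  m <- align_matrix_to_ids(m, rownames(d))
  d <- d[colnames(m), colnames(m)]
  diag(d) <- Inf
  out <- vapply(seq_len(nrow(m)), function(k) {
    idx <- which(m[k, ] > 0)
    if (length(idx) < 2) return(NA_real_)
    mean(row_mins(d[idx, idx, drop = FALSE]))
  }, numeric(1))
  names(out) <- rownames(m)
  out
}

#' Alpha-diversity summary table
#'
#' Richness plus the three dendrogram-based alpha metrics for one dendrogram.
#'
#' @param m Binary incidence matrix or `peak_table`.
#' @param tree `phylo` dendrogram.
#' @param include_root Passed to [dendrogram_diversity()].
#' @return Data frame: `sample`, `richness`, `DD`, `MPD`, `MNTD`.
#' @export
alpha_diversity <- function(m, tree, include_root = TRUE) {
  if (inherits(m, "peak_table")) m <- m$incidence
  d <- stats::cophenetic(tree)
  data.frame(sample = rownames(m),
             richness = richness(m),
             DD = dendrogram_diversity(m, tree, include_root),
             MPD = suppressWarnings(mpd(m, d)),
             MNTD = suppressWarnings(mntd(m, d)),
             row.names = NULL)
}

#' Jaccard dissimilarity between samples
#'
#' Presence/absence Jaccard dissimilarity, `1 - |A intersect B|/|A union B|`,
#' via [vegan::vegdist()].
#'
#' @param m Binary incidence matrix or `peak_table`.
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
jaccard <- function(m) {
  if (inherits(m, "peak_table")) m <- m$incidence
  as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
}

#' Unweighted UniFrac between samples
#'
#' Fraction of dendrogram branch length leading exclusively to one sample's
#' detected peaks, out of the branch length leading to either sample's peaks.
#'
#' @param m Binary incidence matrix or `peak_table`.
#' @param tree `phylo` dendrogram.
#' @return Symmetric dissimilarity matrix in `[0, 1]`; rows for empty samples
#'   are NA.
#' @export
unifrac_unweighted <- function(m, tree) {
  if (inherits(m, "peak_table")) m <- m$incidence
  m <- align_matrix_to_ids(m, tree$tip.label)
  et <- edge_tip_incidence(tree)
  inc <- et$incidence[, colnames(m), drop = FALSE] * 1
  present <- (inc %*% t(m)) > 0          # edges x samples
  shared <- t(present * et$lengths) %*% present
  total <- colSums(present * et$lengths)
  union <- outer(total, total, "+") - shared
  u <- 1 - shared / union
  u[union == 0] <- 0
  diag(u) <- 0
  empty <- rowSums(m) == 0
  u[empty, ] <- NA_real_; u[, empty] <- NA_real_
  dimnames(u) <- list(rownames(m), rownames(m))
  u
}

#' Spearman-based Mantel correlation between two dissimilarity matrices
#'
#' Wrapper around [vegan::mantel()] with Spearman rank correlation; the
#' permutation p-value is `(count >= observed + 1) / (n_perm + 1)`.
#'
#' @param x,y Symmetric dissimilarity matrices over the same samples.
#' @param n_perm Number of permutations (>= 99).
#' @return List with `statistic` (Spearman r) and `p_value`.
#' @export
mantel_spearman <- function(x, y, n_perm = 999) {
  x <- check_square(x, "x"); y <- check_square(y, "y")
  if (nrow(x) < 4) stop("need at least 4 samples for a Mantel permutation test")
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (!identical(sort(rownames(x)), sort(rownames(y)))) {
    stop("x and y must cover the same samples")
  }
  y <- y[rownames(x), rownames(x)]
  fit <- vegan::mantel(stats::as.dist(x), stats::as.dist(y),
                       method = "spearman", permutations = n_perm)
  list(statistic = unname(fit$statistic), p_value = fit$signif,
       n_perm = n_perm)
}

#' Write diversity results as tidy long-format CSV
#'
#' @param values Named vector (alpha) or symmetric matrix (beta).
#' @param metric Metric name recorded in the output.
#' @param dendrogram Dendrogram name recorded in the output ("" if none).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diversity <- function(values, metric, dendrogram, path) {
  if (is.matrix(values)) {
    idx <- which(lower.tri(values), arr.ind = TRUE)
    out <- data.frame(sample_1 = rownames(values)[idx[, 2]],
                      sample_2 = rownames(values)[idx[, 1]],
                      metric = metric, dendrogram = dendrogram,
                      value = values[idx])
  } else {
    out <- data.frame(sample = names(values), metric = metric,
                      dendrogram = dendrogram, value = unname(values))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
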