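# The three relational dendrograms: MCD, TD, TWCD.

# Default trait columns for the molecular-characteristics distance: elemental
# composition plus double-bond equivalents, modified aromaticity index and
# Kendrick defect. NOSC/gibbs can be added via the `columns` argument.
MCD_DEFAULT_COLUMNS <- c("C", "H", "N", "O", "S", "P", "DBE", "AImod", "kdef")

check_square <- function(d, arg = "d") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(arg, " must be square")
  if (is.null(rownames(d))) stop(arg, " must carry ids as dimnames")
  if (max(abs(d - t(d))) > 1e-8) stop(arg, " must be symmetric")
  if (any(!is.finite(d))) stop(arg, " must be finite")
  d
}

#' Molecular-characteristics distance (MCD input)
#'
#' Pairwise Euclidean distance between formula-assigned peaks in the
#' molecular property space. No column scaling is applied by default, in
#' keeping with a plain Euclidean distance over the property table; set
#' `standardize = TRUE` to z-score columns first (counts and Kendrick defect
#' live on different scales).
#'
#' @param props Property table from [compute_properties()] with rownames or a
#'   `peak_id` column identifying peaks.
#' @param columns Property columns to use; default [MCD_DEFAULT_COLUMNS].
#' @param standardize Z-score columns before computing distances?
#' @return Symmetric distance matrix with peak_id dimnames.
#' @export
mcd_distance <- function(props, columns = MCD_DEFAULT_COLUMNS,
                         standardize = FALSE) {
  props <- as.data.frame(props)
  ids <- if ("peak_id" %in% names(props)) as.character(props$peak_id) else
    rownames(props)
  missing_cols <- setdiff(columns, names(props))
  if (length(missing_cols)) {
    stop("property columns not found: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(props[, columns, drop = FALSE])
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite property for peak ", paste(unique(ids[bad[, 1]]),
                                                collapse = ", "))
  }
  if (standardize) x <- scale(x)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(ids, ids)
  d
}

#' Transformation-network distance (TD input)
#'
#' Restricts the transformation network to its largest connected component
#' (any peak outside it is discarded; ties broken toward the component
#' containing the lexicographically smallest peak id), measures the stepwise
#' distance between every pair of peaks (minimum number of transformations
#' connecting them), and standardises the matrix to `[0, 1]` by dividing by
#' its maximum.
#'
#' @param net A `transformation_network` with at least one edge.
#' @return Symmetric distance matrix over the largest component, values in
#'   `[0, 1]` with maximum exactly 1.
#' @export
td_distance <- function(net) {
  stopifnot(inherits(net, "transformation_network"))
  if (!nrow(net$edges)) stop("transformation network has no edges")
  memb <- net$membership
  sizes <- table(memb)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1) {
    # tie: component holding the smallest peak id
    first_id <- vapply(best, function(b) min(names(memb)[memb == b]), "")
    best <- best[which.min(first_id)]
  }
  keep <- sort(names(memb)[memb == best])
  if (length(keep) < 3) {
    stop("largest connected component has fewer than 3 peaks; ",
         "dendrogram would be degenerate")
  }
  pairs <- unique(net$edges[, c("peak_1", "peak_2")])
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  sub <- igraph::induced_subgraph(g, keep)
  d <- igraph::distances(sub, algorithm = "unweighted")
  d <- d[keep, keep]
  d / max(d)
}

#' Transformation-weighted characteristics distance (TWCD input)
#'
#' Combines the molecular-characteristics matrix with the standardised
#' transformation matrix by their entrywise product on the peaks common to
#' both (formula-assigned and inside the largest network component). Because
#' the transformation matrix lies in `[0, 1]`, realised molecular
#' characteristic differences are down-weighted: the result never exceeds
#' the molecular-characteristics distance.
#'
#' @param mcd Matrix from [mcd_distance()].
#' @param td Standardised matrix from [td_distance()].
#' @return Symmetric distance matrix over the shared peak ids.
#' @export
twcd_distance <- function(mcd, td) {
  mcd <- check_square(mcd, "mcd")
  td <- check_square(td, "td")
  ids <- sort(intersect(rownames(mcd), rownames(td)))
  if (length(ids) < 3) {
    stop("fewer than 3 peaks shared between the molecular-characteristics ",
         "and transformation matrices")
  }
  mcd[ids, ids] * td[ids, ids]
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering. Ids are sorted
#' lexicographically before clustering so tie-breaking is deterministic
#' across runs. The returned tree is rooted, ultrametric, and its cophenetic
#' (leaf-to-leaf) distances equal the average-linkage merge distances; node
#' heights are half the merge distance.
#'
#' @param d Symmetric distance matrix with id dimnames (>= 3 ids).
#' @return An [ape::read.tree()]-style `phylo` object.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(d)
#' cophenetic(tr)["A", "C"]  # 4
#' @export
upgma <- function(d) {
  d <- check_square(d)
  if (nrow(d) < 3) stop("need at least 3 ids")
  ids <- sort(rownames(d))
  d <- d[ids, ids]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  tr
}

#' Prune a dendrogram to a subset of leaves
#'
#' Removes all leaves outside `keep`, collapsing the freed internal nodes and
#' summing branch lengths, so cophenetic distances among the kept leaves are
#' unchanged.
#'
#' @param tree A `phylo` dendrogram.
#' @param keep Character vector of leaf labels to retain (>= 2, all present
#'   in the tree).
#' @return Pruned `phylo`.
#' @export
prune_dendrogram <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2) stop("need at least 2 leaves to keep")
  ape::keep.tip(tree, keep)
}

#' Write / read dendrograms as Newick
#'
#' Thin wrappers around [ape::write.tree()] / [ape::read.tree()] so every
#' dendrogram round-trips through plain text with branch lengths.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `read_newick` a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a distance matrix as square CSV
#'
#' @param d Symmetric matrix with id dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(as.matrix(d)), path, row.names = TRUE)
  invisible(path)
}

#' Build the selected relational dendrograms for a peak table
#'
#' Convenience wrapper running the full dendrogram stage: molecular
#' properties -> MCD; transformation matching -> TD; their combination ->
#' TWCD; each converted to a UPGMA tree.
#'
#' @param table A `peak_table`.
#' @param which Subset of `c("MCD", "TD", "TWCD")`.
#' @param db Transformation database (for TD/TWCD).
#' @param tol_mode,tol_value Matching tolerance, see [match_transformations()].
#' @param columns MCD property columns.
#' @return Named list with, per selected dendrogram, `tree` (`phylo`),
#'   `distance` (matrix) and `n_peaks`; plus `network` and `properties` when
#'   computed.
#' @export
build_dendrograms <- function(table, which = c("MCD", "TD", "TWCD"),
                              db = transformation_database(),
                              tol_mode = "ppm", tol_value = 1,
                              columns = MCD_DEFAULT_COLUMNS) {
  which <- match.arg(which, c("MCD", "TD", "TWCD"), several.ok = TRUE)
  out <- list()
  mcd <- td <- NULL
  if (any(c("MCD", "TWCD") %in% which)) {
    props <- compute_properties(table)
    out$properties <- props
    mcd <- mcd_distance(props, columns = columns)
  }
  if (any(c("TD", "TWCD") %in% which)) {
    net <- match_transformations(table, db = db, tol_mode = tol_mode,
                                 tol_value = tol_value)
    out$network <- net
    td <- td_distance(net)
  }
  if ("MCD" %in% which) {
    out$MCD <- list(tree = upgma(mcd), distance = mcd, n_peaks = nrow(mcd))
  }
  if ("TD" %in% which) {
    out$TD <- list(tree = upgma(td), distance = td, n_peaks = nrow(td))
  }
  if ("TWCD" %in% which) {
    twcd <- twcd_distance(mcd, td)
    out$TWCD <- list(tree = upgma(twcd), distance = twcd, n_peaks = nrow(twcd))
  }
  out
}
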