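# Putative biochemical transformation networks from exact mass differences.

# name = label used on edges; formula = CHONSP counts the mass is computed from.
BUILTIN_TRANSFORMATIONS <- list(
  # small gains/losses
  list("H2",                      c(C = 0, H = 2)),
  list("CH2",                     c(C = 1, H = 2)),
  list("C2H2",                    c(C = 2, H = 2)),
  list("C2H4",                    c(C = 2, H = 4)),
  list("C3H6",                    c(C = 3, H = 6)),
  list("C4H8",                    c(C = 4, H = 8)),
  list("C5H8 (isoprene)",         c(C = 5, H = 8)),
  list("O",                       c(O = 1)),
  list("H2O",                     c(H = 2, O = 1)),
  list("CO",                      c(C = 1, O = 1)),
  list("CO2",                     c(C = 1, O = 2)),
  list("CH2O (formaldehyde)",     c(C = 1, H = 2, O = 1)),
  list("CH2O2 (formic acid)",     c(C = 1, H = 2, O = 2)),
  list("CH4O (methanol)",         c(C = 1, H = 4, O = 1)),
  list("C2H2O (acetyl)",          c(C = 2, H = 2, O = 1)),
  list("C2H2O2 (glyoxal)",        c(C = 2, H = 2, O = 2)),
  list("C2H4O2 (acetic acid)",    c(C = 2, H = 4, O = 2)),
  list("C3H4O2 (acrylic acid)",   c(C = 3, H = 4, O = 2)),
  list("C3H2O3 (malonyl)",        c(C = 3, H = 2, O = 3)),
  list("C3H4O3 (pyruvic acid)",   c(C = 3, H = 4, O = 3)),
  list("C4H4O3 (succinyl)",       c(C = 4, H = 4, O = 3)),
  list("C3H6O2 (glycerol-H2O)",   c(C = 3, H = 6, O = 2)),
  # nitrogen groups
  list("NH",                      c(N = 1, H = 1)),
  list("NH3",                     c(N = 1, H = 3)),
  list("NH4",                     c(N = 1, H = 4)),
  list("CH3N (methylimine)",      c(C = 1, H = 3, N = 1)),
  list("CH5N (methylamine)",      c(C = 1, H = 5, N = 1)),
  list("C2H5N (aziridine)",       c(C = 2, H = 5, N = 1)),
  list("C2H5NO (acetamide)",      c(C = 2, H = 5, N = 1, O = 1)),
  list("CH4N2O (urea)",           c(C = 1, H = 4, N = 2, O = 1)),
  # sulfur / phosphorus groups
  list("S",                       c(S = 1)),
  list("H2S",                     c(H = 2, S = 1)),
  list("SO2",                     c(S = 1, O = 2)),
  list("SO3 (sulfonate)",         c(S = 1, O = 3)),
  list("H2SO4 (sulfate)",         c(H = 2, S = 1, O = 4)),
  list("CH2S",                    c(C = 1, H = 2, S = 1)),
  list("CH4S (methanethiol)",     c(C = 1, H = 4, S = 1)),
  list("HPO3 (phosphate)",        c(H = 1, P = 1, O = 3)),
  list("H3PO4 (phosphoric acid)", c(H = 3, P = 1, O = 4)),
  # sugars (condensation residues)
  list("C5H8O4 (pentose)",        c(C = 5, H = 8, O = 4)),
  list("C6H10O4 (deoxyhexose)",   c(C = 6, H = 10, O = 4)),
  list("C6H10O5 (hexose)",        c(C = 6, H = 10, O = 5)),
  list("C6H8O6 (glucuronic)",     c(C = 6, H = 8, O = 6)),
  # amino-acid residues (amino acid minus water); Leu/Ile are isobaric
  list("glycine (C2H3NO)",        c(C = 2, H = 3, N = 1, O = 1)),
  list("alanine (C3H5NO)",        c(C = 3, H = 5, N = 1, O = 1)),
  list("serine (C3H5NO2)",        c(C = 3, H = 5, N = 1, O = 2)),
  list("proline (C5H7NO)",        c(C = 5, H = 7, N = 1, O = 1)),
  list("valine (C5H9NO)",         c(C = 5, H = 9, N = 1, O = 1)),
  list("threonine (C4H7NO2)",     c(C = 4, H = 7, N = 1, O = 2)),
  list("cysteine (C3H5NOS)",      c(C = 3, H = 5, N = 1, O = 1, S = 1)),
  list("leucine/isoleucine (C6H11NO)", c(C = 6, H = 11, N = 1, O = 1)),
  list("asparagine (C4H6N2O2)",   c(C = 4, H = 6, N = 2, O = 2)),
  list("aspartate (C4H5NO3)",     c(C = 4, H = 5, N = 1, O = 3)),
  list("glutamine (C5H8N2O2)",    c(C = 5, H = 8, N = 2, O = 2)),
  list("lysine (C6H12N2O)",       c(C = 6, H = 12, N = 2, O = 1)),
  list("glutamate (C5H7NO3)",     c(C = 5, H = 7, N = 1, O = 3)),
  list("methionine (C5H9NOS)",    c(C = 5, H = 9, N = 1, O = 1, S = 1)),
  list("histidine (C6H7N3O)",     c(C = 6, H = 7, N = 3, O = 1)),
  list("phenylalanine (C9H9NO)",  c(C = 9, H = 9, N = 1, O = 1)),
  list("arginine (C6H12N4O)",     c(C = 6, H = 12, N = 4, O = 1)),
  list("tyrosine (C9H9NO2)",      c(C = 9, H = 9, N = 1, O = 2)),
  list("tryptophan (C11H10N2O)",  c(C = 11, H = 10, N = 2, O = 1)),
  # nucleobases and cofactor fragments
  list("uracil (C4H4N2O2)",       c(C = 4, H = 4, N = 2, O = 2)),
  list("cytosine (C4H5N3O)",      c(C = 4, H = 5, N = 3, O = 1)),
  list("thymine (C5H6N2O2)",      c(C = 5, H = 6, N = 2, O = 2)),
  list("adenine (C5H5N5)",        c(C = 5, H = 5, N = 5)),
  list("guanine (C5H5N5O)",       c(C = 5, H = 5, N = 5, O = 1)),
  list("glutathione (C10H17N3O6S)", c(C = 10, H = 17, N = 3, O = 6, S = 1))
)

#' Built-in biochemical transformation database
#'
#' Returns the package's transformation database: named exact mass differences
#' corresponding to common biochemical gains/losses (amino-acid residues,
#' sugars, CH2 homologues, water, ammonia, carboxylation, methylation,
#' phosphate, sulfonate, nucleobases, common cofactor fragments). Every mass
#' is computed from CHONSP counts via [monoisotopic_mass()], so the database
#' is exact by construction; it is a reconstruction of the transformation
#' lists commonly used for FTICR-MS mass-difference analysis, not a copy of
#' any particular deposited list.
#'
#' @return Data frame of class `transformation_database` with columns `name`,
#'   `mass` (Da) and the six element-count columns.
#' @examples
#' db <- transformation_database()
#' db[db$name == "NH4", "mass"]   # 18.03437 Da
#' @export
transformation_database <- function() {
  rows <- lapply(BUILTIN_TRANSFORMATIONS, function(e) {
    counts <- sapply(ELEMENTS, function(el) {
      v <- e[[2]][el]
      if (is.na(v)) 0 else as.numeric(v)
    })
    data.frame(name = e[[1]], t(counts),
               mass = monoisotopic_mass(as.data.frame(t(counts))))
  })
  db <- do.call(rbind, rows)
  db <- db[order(db$mass), c("name", "mass", ELEMENTS)]
  rownames(db) <- NULL
  validate_transformation_db(db)
}

validate_transformation_db <- function(db) {
  if (!nrow(db)) stop("empty transformation database")
  if (any(db$mass <= 0)) stop("transformation masses must be positive")
  if (anyDuplicated(db$name)) stop("duplicate transformation names")
  key <- round(db$mass, 4)
  if (anyDuplicated(key)) {
    dup <- db$name[key %in% key[duplicated(key)]]
    stop("transformation masses not unique to 4 decimals: ",
         paste(dup, collapse = ", "))
  }
  class(db) <- c("transformation_database", "data.frame")
  db
}

#' Read a user transformation database from CSV
#'
#' Columns `Name` and `Mass` (Da); a user-supplied database overrides the
#' built-in one throughout the pipeline.
#'
#' @param path CSV path.
#' @return `transformation_database` data frame with columns `name`, `mass`.
#' @export
read_transformation_database <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("name", "mass") %in% names(raw))) {
    stop("transformation database CSV needs columns 'Name' and 'Mass'")
  }
  validate_transformation_db(data.frame(name = raw$name,
                                        mass = as.numeric(raw$mass)))
}

#' Match pairwise peak mass differences to a transformation database
#'
#' For every unordered peak pair, the absolute mass difference is compared
#' with every database entry; a pair is linked when the difference falls
#' within the tolerance of the entry's expected mass. The default tolerance
#' is 1 ppm of the transformation mass, the window ultrahigh-resolution
#' FTICR-MS supports; an absolute-Da window is also available, as fixed
#' windows are common in released mass-difference pipelines. All entries
#' matching the same pair annotate a single undirected edge.
#'
#' @param peaks A `peak_table`, or a data frame with columns `peak_id` and
#'   `mass`, or a named numeric vector of masses.
#' @param db A transformation database (default [transformation_database()]).
#' @param tol_mode `"ppm"` (tolerance = `tol_value` ppm of the transformation
#'   mass) or `"absolute"` (tolerance = `tol_value` Da).
#' @param tol_value Positive tolerance value (default 1, i.e. 1 ppm).
#' @return Object of class `transformation_network`: list with `nodes` (all
#'   peak ids supplied), `edges` (data frame `peak_1`, `peak_2`,
#'   `transformation`, `delta_mass`, `error`; one row per matched entry, so a
#'   pair matched by several entries contributes several rows), `membership`
#'   (named component id per node present in the edge set) and the tolerance
#'   settings.
#' @export
match_transformations <- function(peaks, db = transformation_database(),
                                  tol_mode = c("ppm", "absolute"),
                                  tol_value = 1) {
  tol_mode <- match.arg(tol_mode)
  if (!is.null(db) && nrow(db) == 0) stop("empty transformation database")
  if (tol_value <= 0) stop("tol_value must be positive")
  if (inherits(peaks, "peak_table")) {
    ids <- peaks$peaks$peak_id
    mass <- peaks$peaks$mass
  } else if (is.data.frame(peaks)) {
    ids <- as.character(peaks$peak_id)
    mass <- as.numeric(peaks$mass)
  } else {
    mass <- as.numeric(peaks)
    ids <- names(peaks)
    if (is.null(ids)) ids <- format_peak_id(mass)
  }
  if (length(mass) < 2) stop("need at least two peaks")

  ord <- order(mass)
  ids <- ids[ord]; mass <- mass[ord]
  n <- length(mass)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  delta <- mass[jj] - mass[ii]  # >= 0 since sorted

  tol <- if (tol_mode == "ppm") tol_value * 1e-6 * db$mass else
    rep(tol_value, nrow(db))
  hits <- lapply(seq_len(nrow(db)), function(k) {
    sel <- which(abs(delta - db$mass[k]) <= tol[k])
    if (!length(sel)) return(NULL)
    data.frame(peak_1 = ids[ii[sel]], peak_2 = ids[jj[sel]],
               transformation = db$name[k],
               delta_mass = delta[sel],
               error = delta[sel] - db$mass[k],
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, hits)
  if (is.null(edges)) {
    edges <- data.frame(peak_1 = character(), peak_2 = character(),
                        transformation = character(), delta_mass = numeric(),
                        error = numeric(), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$peak_1, edges$peak_2, edges$transformation), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  membership <- integer(0)
  if (nrow(edges)) {
    pairs <- unique(edges[, c("peak_1", "peak_2")])
    g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                       vertices = data.frame(name = ids))
    comp <- igraph::components(g)
    membership <- comp$membership
  }
  structure(list(nodes = ids, edges = edges, membership = membership,
                 tol_mode = tol_mode, tol_value = tol_value),
            class = "transformation_network")
}

#' @export
print.transformation_network <- function(x, ...) {
  pairs <- unique(x$edges[, c("peak_1", "peak_2")])
  cat("transformation_network:", length(x$nodes), "peaks,", nrow(pairs),
      "edges (", nrow(x$edges), "annotations ), tolerance", x$tol_value,
      x$tol_mode, "\n")
  if (length(x$membership)) {
    sizes <- table(x$membership)
    cat("  components:", length(sizes), "( largest", max(sizes), ")\n")
  }
  invisible(x)
}

#' Per-peak transformation counts
#'
#' Counts, for every peak in `universe`, the number of transformations it is
#' involved in: one count per matched database annotation incident to the
#' peak (a pair matched by two entries contributes two to each end). Peaks
#' absent from the network score zero.
#'
#' @param net A `transformation_network`.
#' @param universe Character vector of peak ids (default: the network nodes).
#' @return Named integer vector over `universe`.
#' @export
transformation_counts <- function(net, universe = net$nodes) {
  stopifnot(inherits(net, "transformation_network"))
  if (!all(net$nodes %in% universe)) {
    stop("universe must contain every network node")
  }
  counts <- integer(length(universe))
  names(counts) <- universe
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$peak_1, net$edges$peak_2))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Partition peaks by putative biochemical activity
#'
#' Peaks involved in more than `threshold_hi` transformations are labelled
#' active; peaks involved in none are labelled inactive; everything in
#' between belongs to neither class. The default threshold of 40 follows the
#' convention of treating the upper tail of the transformation-count
#' distribution as putatively active material.
#'
#' @param counts Named integer vector from [transformation_counts()].
#' @param threshold_hi Activity threshold (default 40).
#' @return List of class `activity_partition`: `active`, `inactive`
#'   (character vectors of peak ids), `threshold_hi`.
#' @export
partition_by_activity <- function(counts, threshold_hi = 40) {
  if (!length(counts)) stop("empty transformation counts")
  structure(list(active = names(counts)[counts > threshold_hi],
                 inactive = names(counts)[counts == 0],
                 threshold_hi = threshold_hi),
            class = "activity_partition")
}

#' Write the transformation edge list to CSV
#'
#' @param net A `transformation_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}
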