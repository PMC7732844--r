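# Independent brute-force oracles used to validate the implementation on
# small instances. Deliberately naive and written from first principles.

# Textbook UPGMA: returns the cophenetic matrix implied by average-linkage
# agglomeration with size-weighted cluster distances.
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  ids <- rownames(d)
  clusters <- as.list(ids)
  dist_c <- d
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1) {
    n <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (dist_c[i, j] < best[1] - 1e-12) best <- c(dist_c[i, j], i, j)
    }
    i <- best[2]; j <- best[3]; h <- best[1]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- h
    }
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    newd <- (ni * dist_c[i, ] + nj * dist_c[j, ]) / (ni + nj)
    dist_c <- rbind(cbind(dist_c, new = newd), new = c(newd, 0))
    dist_c <- dist_c[-c(i, j), -c(i, j), drop = FALSE]
    clusters <- c(clusters[-c(i, j)], list(c(clusters[[i]], clusters[[j]])))
  }
  coph
}

# Exhaustive triple loop over (pair, database entry).
oracle_edge_set <- function(ids, masses, db, tol_mode = "ppm", tol_value = 1) {
  rows <- list()
  n <- length(masses)
  for (i in 1:(n - 1)) for (j in (i + 1):n) for (k in seq_len(nrow(db))) {
    delta <- abs(masses[i] - masses[j])
    tol <- if (tol_mode == "ppm") tol_value * 1e-6 * db$mass[k] else tol_value
    if (abs(delta - db$mass[k]) <= tol) {
      a <- ids[i]; b <- ids[j]
      if (masses[i] > masses[j]) { a <- ids[j]; b <- ids[i] }
      rows[[length(rows) + 1]] <- data.frame(
        peak_1 = a, peak_2 = b, transformation = db$name[k])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(peak_1 = character(), peak_2 = character(),
                      transformation = character()))
  }
  out <- out[order(out$peak_1, out$peak_2, out$transformation), ]
  rownames(out) <- NULL
  out
}

oracle_mpd <- function(d, present) {
  s <- length(present)
  tot <- 0
  for (i in present) for (j in present) if (i != j) tot <- tot + d[i, j]
  tot / (s * (s - 1))
}

oracle_mntd <- function(d, present) {
  mean(sapply(present, function(i) {
    min(sapply(setdiff(present, i), function(j) d[i, j]))
  }))
}

oracle_bmntd <- function(d, a, b) {
  one <- mean(sapply(a, function(i) min(d[i, b])))
  two <- mean(sapply(b, function(j) min(d[j, a])))
  (one + two) / 2
}

# Faith-type diversity by explicit root-path union on an ape tree.
oracle_dd <- function(tree, present, include_root = TRUE) {
  n <- length(tree$tip.label)
  tip_idx <- match(present, tree$tip.label)
  edges_used <- integer(0)
  for (t in tip_idx) {
    node <- t
    while (TRUE) {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      edges_used <- union(edges_used, e)
      node <- tree$edge[e, 1]
    }
  }
  if (!include_root) {
    # drop edges below which ALL present tips lie
    keep <- sapply(edges_used, function(e) {
      below <- geiger_tips(tree, tree$edge[e, 2])
      !all(present %in% below)
    })
    edges_used <- edges_used[keep]
  }
  sum(tree$edge.length[edges_used])
}

geiger_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, geiger_tips, tree = tree))
}

# Shared fixtures -------------------------------------------------------

# hand example: d(A,B) = 2, d(A,C) = d(B,C) = 4; A,B merge at node height 1,
# root at height 2.
t1_distance <- function() {
  matrix(c(0, 2, 4,
           2, 0, 4,
           4, 4, 0), 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

random_distance <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n)
  rownames(x) <- sprintf("p%02d", seq_len(n))
  as.matrix(dist(x))
}

random_assemblage <- function(n_samples, n_peaks, prob = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_samples * n_peaks, 1, prob), n_samples,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("p%02d", seq_len(n_peaks))))
  # guarantee >= 2 peaks per sample
  for (i in seq_len(n_samples)) {
    if (sum(m[i, ]) < 2) m[i, sample.int(n_peaks, 2)] <- 1
  }
  m
}

write_peak_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
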