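# One-call assembly inference: beta-NTI + Raup-Crick + classification,
# returned as a classed object with print/summary/plot methods.

#' Fit the assembly-process model to a metabolite assemblage
#'
#' Runs the complete null-model inference for one dendrogram: beta-MNTD and
#' its tip-shuffled standardised effect (beta-NTI), the Raup-Crick deviation,
#' and the per-pair assembly-process classification. This is the package's
#' central fitting function; the result is an `mme_assembly` object.
#'
#' @param m Binary incidence matrix (samples x peaks) or a `peak_table`.
#' @param tree `phylo` dendrogram over (a subset of) the peaks.
#' @param groups Optional named character vector mapping sample -> group
#'   (taken from the `peak_table` metadata when available).
#' @param config A [null_config()].
#' @param rc_weighting Passed to [raup_crick()].
#' @param dendrogram Label stored with the fit (e.g. `"MCD"`).
#' @return Object of class `mme_assembly` with elements `bnti` (`mme_bnti`),
#'   `rc` (matrix), `classification` (`process_classification`), `groups`,
#'   `config`, `dendrogram`, `n_peaks`, `call`.
#' @seealso [bnti()], [raup_crick()], [classify_processes()]
#' @export
mme_assembly <- function(m, tree, groups = NULL, config = null_config(),
                         rc_weighting = "occupancy", dendrogram = "dendrogram") {
  cl <- match.call()
  if (inherits(m, "peak_table")) {
    if (is.null(groups)) {
      groups <- stats::setNames(m$sample_meta$group, m$sample_meta$sample_id)
    }
    m <- m$incidence
  }
  b <- bnti(m, tree, config)
  # RC uses the same peak coverage as the dendrogram-based comparison
  mm <- align_matrix_to_ids(m, if (inherits(tree, "phylo")) tree$tip.label else
    rownames(tree))
  rc <- raup_crick(mm, config, weighting = rc_weighting)
  cls <- classify_processes(b, rc)
  structure(list(bnti = b, rc = rc, classification = cls, groups = groups,
                 config = config, dendrogram = dendrogram,
                 n_peaks = ncol(mm), call = cl),
            class = "mme_assembly")
}

#' @export
print.mme_assembly <- function(x, ...) {
  cat("Meta-metabolome assembly model (", x$dendrogram, ")\n", sep = "")
  cat("  ", nrow(x$rc), " samples, ", x$n_peaks, " peaks, ",
      x$config$n_null_beta, " beta-NTI / ", x$config$n_null_rc,
      " Raup-Crick null draws\n", sep = "")
  tab <- table(x$classification$process)
  tab <- tab[tab > 0]
  for (p in names(tab)) {
    cat(sprintf("  %-24s %4d pairs (%.1f%%)\n", p, tab[[p]],
                100 * tab[[p]] / nrow(x$classification)))
  }
  invisible(x)
}

#' @export
summary.mme_assembly <- function(object, ...) {
  out <- process_summary(object$classification, object$groups)
  out$dendrogram <- object$dendrogram
  class(out) <- c("summary.mme_assembly", "data.frame")
  out
}

#' @export
print.summary.mme_assembly <- function(x, ...) {
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' @export
coef.mme_assembly <- function(object, ...) {
  cls <- object$classification
  stats::setNames(cls$bnti, paste(cls$sample_1, cls$sample_2, sep = ":"))
}

#' Plot method for assembly fits
#'
#' Boxplots of per-pair beta-NTI by group-pair block (or a histogram when no
#' groups are available), with the +/-2 significance thresholds marked.
#'
#' @param x An `mme_assembly` object.
#' @param ... Passed to the underlying base plotting call.
#' @export
plot.mme_assembly <- function(x, ...) {
  cls <- x$classification
  if (!is.null(x$groups)) {
    g1 <- x$groups[cls$sample_1]; g2 <- x$groups[cls$sample_2]
    block <- paste(pmin(g1, g2), pmax(g1, g2), sep = " vs ")
    graphics::boxplot(cls$bnti ~ block, xlab = "sample-pair block",
                      ylab = expression(beta * "NTI"),
                      main = x$dendrogram, ...)
    graphics::abline(h = c(-2, 2), lty = 2, col = "grey40")
  } else {
    graphics::hist(cls$bnti, xlab = expression(beta * "NTI"),
                   main = x$dendrogram, ...)
    graphics::abline(v = c(-2, 2), lty = 2, col = "grey40")
  }
  invisible(x)
}
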