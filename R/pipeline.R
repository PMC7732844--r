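# End-to-end pipeline: peak table -> dendrograms -> diversity -> null models
# -> process classification, with provenance stamping.

#' Assemble a pipeline run configuration
#'
#' @param peak_table_path Input peak CSV (see [read_peak_table()]).
#' @param sample_meta_path Sample metadata CSV (`sample_id`, `group`) or NULL.
#' @param output_dir Output directory.
#' @param dendrograms Subset of `c("MCD", "TD", "TWCD")`.
#' @param db_path Optional transformation database CSV overriding the builtin.
#' @param mass_column Name of the mass column in the peak CSV.
#' @param mz_min,mz_max Peak mass filter window (Da).
#' @param property_columns MCD property columns.
#' @param tol_mode,tol_value Transformation-matching tolerance.
#' @param n_null_alpha,n_null_beta,n_null_rc Null-model draw counts.
#' @param activity_threshold Transformation-count threshold for "active".
#' @param seed Integer seed recorded in all outputs.
#' @return List of class `run_config`.
#' @export
run_config <- function(peak_table_path, sample_meta_path = NULL,
                       output_dir = "mmeco_out",
                       dendrograms = c("MCD", "TD", "TWCD"),
                       db_path = NULL, mass_column = "Mass",
                       mz_min = 200, mz_max = 900,
                       property_columns = MCD_DEFAULT_COLUMNS,
                       tol_mode = "ppm", tol_value = 1,
                       n_null_alpha = 999, n_null_beta = 999,
                       n_null_rc = 9999,
                       activity_threshold = 40, seed = 1) {
  dendrograms <- match.arg(dendrograms, c("MCD", "TD", "TWCD"),
                           several.ok = TRUE)
  if (!length(dendrograms)) stop("select at least one dendrogram")
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

stage <- function(name, manifest_env, expr) {
  message("[mmeco] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e),
         "\n  outputs written so far: ",
         paste(get("files", manifest_env), collapse = ", "),
         call. = FALSE)
  })
}

#' Run the full meta-metabolome ecology pipeline
#'
#' Executes every stage for the selected dendrograms -- ingestion and
#' filtering, molecular properties, transformation network and activity
#' partition, dendrogram construction, alpha- and beta-diversity, beta-NTI
#' and Raup-Crick null models, and assembly-process classification -- and
#' writes all results (CSV/Newick/JSON) plus a provenance file into the
#' output directory.
#'
#' @param cfg A [run_config()].
#' @return The output directory path, invisibly; side effect: output files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(); env$files <- character(0)
  out <- function(name) {
    p <- file.path(cfg$output_dir, name)
    env$files <- c(env$files, name)
    p
  }
  t0 <- Sys.time()

  pt <- stage("read", env, {
    read_peak_table(cfg$peak_table_path, mass_column = cfg$mass_column,
                    sample_meta = cfg$sample_meta_path)
  })
  pt <- stage("filter", env, {
    filter_peaks(pt, cfg$mz_min, cfg$mz_max)
  })
  message("[mmeco]   peaks after filter: ", nrow(pt$peaks),
          " (formula-assigned: ", sum(!is.na(pt$peaks$C)), ")")

  db <- stage("database", env, {
    if (is.null(cfg$db_path)) transformation_database() else
      read_transformation_database(cfg$db_path)
  })

  need_net <- any(c("TD", "TWCD") %in% cfg$dendrograms)
  net <- NULL
  if (need_net) {
    net <- stage("transformation_network", env, {
      match_transformations(pt, db = db, tol_mode = cfg$tol_mode,
                            tol_value = cfg$tol_value)
    })
    stage("activity", env, {
      counts <- transformation_counts(net, universe = pt$peaks$peak_id)
      part <- partition_by_activity(counts, cfg$activity_threshold)
      utils::write.csv(
        data.frame(peak_id = names(counts), transformations = counts,
                   class = ifelse(names(counts) %in% part$active, "active",
                           ifelse(names(counts) %in% part$inactive,
                                  "inactive", "intermediate"))),
        out("transformation_counts.csv"), row.names = FALSE)
      write_edge_list(net, out("transformation_edges.csv"))
    })
  }

  dend <- stage("dendrograms", env, {
    res <- list()
    mcd <- td <- NULL
    if (any(c("MCD", "TWCD") %in% cfg$dendrograms)) {
      props <- compute_properties(pt)
      write_property_table(props, out("molecular_properties.csv"))
      mcd <- mcd_distance(props, columns = cfg$property_columns)
    }
    if (need_net) td <- td_distance(net)
    if ("MCD" %in% cfg$dendrograms) res$MCD <- upgma(mcd)
    if ("TD" %in% cfg$dendrograms) res$TD <- upgma(td)
    if ("TWCD" %in% cfg$dendrograms) res$TWCD <- upgma(twcd_distance(mcd, td))
    res
  })
  for (nm in names(dend)) write_newick(dend[[nm]], out(paste0(nm, ".nwk")))
  message("[mmeco]   dendrogram peak counts: ",
          paste(names(dend), vapply(dend, function(t) length(t$tip.label), 1L),
                sep = "=", collapse = ", "))

  m <- pt$incidence
  groups <- stats::setNames(pt$sample_meta$group, pt$sample_meta$sample_id)
  stage("jaccard", env, {
    write_distance_matrix(jaccard(m), out("jaccard.csv"))
  })

  cfg_null <- null_config(cfg$n_null_alpha, cfg$n_null_beta, cfg$n_null_rc,
                          seed = cfg$seed)
  for (nm in names(dend)) {
    tree <- dend[[nm]]
    stage(paste0("alpha_", nm), env, {
      utils::write.csv(suppressWarnings(alpha_diversity(m, tree)),
                       out(paste0("alpha_", nm, ".csv")), row.names = FALSE)
      d <- stats::cophenetic(tree)
      utils::write.csv(suppressWarnings(nri(m, d, cfg_null)),
                       out(paste0("nri_", nm, ".csv")), row.names = FALSE)
      utils::write.csv(suppressWarnings(nti(m, d, cfg_null)),
                       out(paste0("nti_", nm, ".csv")), row.names = FALSE)
    })
    stage(paste0("beta_", nm), env, {
      write_distance_matrix(suppressWarnings(unifrac_unweighted(m, tree)),
                            out(paste0("unifrac_", nm, ".csv")))
      fit <- suppressWarnings(
        mme_assembly(m, tree, groups = groups, config = cfg_null,
                     dendrogram = nm))
      write_distance_matrix(fit$bnti$z, out(paste0("bnti_", nm, ".csv")))
      write_distance_matrix(fit$rc, out(paste0("rc_", nm, ".csv")))
      utils::write.csv(fit$classification,
                       out(paste0("classification_", nm, ".csv")),
                       row.names = FALSE)
      utils::write.csv(summary(fit),
                       out(paste0("process_summary_", nm, ".csv")),
                       row.names = FALSE)
    })
  }

  stage("provenance", env, {
    prov <- list(
      package = "mmeco",
      version = as.character(utils::packageVersion("mmeco")),
      r_version = R.version.string,
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
      seed = cfg$seed,
      tolerance = list(mode = cfg$tol_mode, value = cfg$tol_value),
      null_draws = list(alpha = cfg$n_null_alpha, beta = cfg$n_null_beta,
                        raup_crick = cfg$n_null_rc),
      mass_window = c(cfg$mz_min, cfg$mz_max),
      dendrogram_peak_counts = lapply(dend, function(t) length(t$tip.label)),
      outputs = env$files)
    jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                         digits = NA)
  })
  message("[mmeco] done in ",
          round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), "s")
  invisible(cfg$output_dir)
}
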