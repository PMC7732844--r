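# Peak tables: reading, validation, filtering, binary incidence.

format_peak_id <- function(mass) {
  formatC(mass, format = "f", digits = 4)
}

#' Construct a peak table
#'
#' The master input object: a set of peaks (neutral monoisotopic masses with
#' optional CHONSP formula assignments), a binary sample-by-peak incidence
#' matrix, and per-sample metadata. Peak identity is the mass printed to four
#' decimals, matching FTICR-MS reporting precision; intensities are reduced to
#' presence/absence because a peak's absence is defined as falling below the
#' limit of detection.
#'
#' @param peaks Data frame with columns `mass` (positive, Da) and optionally
#'   `C`, `H`, `N`, `O`, `S`, `P` (`NA` throughout a row = unassigned) and
#'   `isotopologue` (logical).
#' @param incidence Numeric matrix, samples in rows, peaks in columns; any
#'   positive value is treated as detected. Column count must equal
#'   `nrow(peaks)`.
#' @param sample_meta Data frame with columns `sample_id`, `group`, or `NULL`
#'   (a single group `"all"` is assumed).
#' @return An object of class `peak_table` with elements `peaks` (data frame,
#'   sorted by mass, with `peak_id`), `incidence` (binary integer matrix with
#'   sample rownames and peak_id colnames) and `sample_meta`.
#' @export
peak_table <- function(peaks, incidence, sample_meta = NULL) {
  peaks <- as.data.frame(peaks)
  if (!"mass" %in% names(peaks)) stop("'peaks' needs a 'mass' column")
  mass <- suppressWarnings(as.numeric(peaks$mass))
  if (anyNA(mass)) {
    stop("non-numeric mass in row ", paste(which(is.na(mass)), collapse = ", "))
  }
  if (any(mass <= 0)) stop("masses must be positive")
  peaks$mass <- mass
  peaks$peak_id <- format_peak_id(mass)
  if (anyDuplicated(peaks$peak_id)) {
    dup <- unique(peaks$peak_id[duplicated(peaks$peak_id)])
    stop("duplicate peak mass after 4-decimal rounding: ",
         paste(dup, collapse = ", "))
  }
  if (!"isotopologue" %in% names(peaks)) peaks$isotopologue <- FALSE
  peaks$isotopologue <- as.logical(peaks$isotopologue) %in% TRUE
  for (el in ELEMENTS) if (!el %in% names(peaks)) peaks[[el]] <- NA_real_
  assigned <- !is.na(peaks$C)
  if (any(assigned & (peaks$C < 1 | peaks$H < 1), na.rm = TRUE)) {
    stop("assigned formulas must have C >= 1 and H >= 1")
  }

  incidence <- as.matrix(incidence)
  if (ncol(incidence) != nrow(peaks)) {
    stop("incidence must have one column per peak")
  }
  storage.mode(incidence) <- "double"
  incidence <- (incidence > 0) * 1L
  colnames(incidence) <- peaks$peak_id
  if (is.null(rownames(incidence))) {
    rownames(incidence) <- paste0("S", seq_len(nrow(incidence)))
  }

  ord <- order(peaks$mass)
  peaks <- peaks[ord, c("peak_id", "mass", ELEMENTS, "isotopologue"),
                 drop = FALSE]
  rownames(peaks) <- NULL
  incidence <- incidence[, peaks$peak_id, drop = FALSE]

  empty <- rowSums(incidence) == 0
  if (any(empty)) {
    warning("dropping sample(s) with no detected peaks: ",
            paste(rownames(incidence)[empty], collapse = ", "))
    incidence <- incidence[!empty, , drop = FALSE]
  }

  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = rownames(incidence), group = "all",
                              stringsAsFactors = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta)
  if (!all(c("sample_id", "group") %in% names(sample_meta))) {
    stop("sample_meta needs columns 'sample_id' and 'group'")
  }
  missing_meta <- setdiff(rownames(incidence), sample_meta$sample_id)
  if (length(missing_meta)) {
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  }
  sample_meta <- sample_meta[match(rownames(incidence), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL

  structure(list(peaks = peaks, incidence = incidence,
                 sample_meta = sample_meta),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  n_assigned <- sum(!is.na(x$peaks$C))
  cat("peak_table:", nrow(x$peaks), "peaks (", n_assigned,
      "formula-assigned ),", nrow(x$incidence), "samples\n")
  cat("  mass range:", format_peak_id(min(x$peaks$mass)), "-",
      format_peak_id(max(x$peaks$mass)), "Da\n")
  cat("  groups:", paste(unique(x$sample_meta$group), collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned peak table from CSV
#'
#' Reads a comma-separated, headered file in which rows are aligned peaks. One
#' column holds the neutral monoisotopic mass; a configurable set of columns
#' holds per-sample intensities (binarised: any value strictly greater than
#' zero counts as detected); optional columns hold element counts and an
#' isotopologue flag.
#'
#' @param path CSV path.
#' @param sample_columns Character vector of intensity column names. Default
#'   `NULL`: every column other than the mass, formula and isotope columns.
#' @param mass_column Name of the mass column (default `"Mass"`).
#' @param formula_columns Named or plain character vector of the element count
#'   columns, in order C, H, N, O, S, P; default picks up columns literally
#'   named `C`, `H`, `N`, `O`, `S`, `P` when all are present.
#' @param isotope_column Optional name of a logical/0-1 column flagging
#'   isotopologue peaks (instrument software flags these upstream; they are
#'   not re-detected here).
#' @param sample_meta Data frame or CSV path with columns `sample_id`,
#'   `group`; `NULL` assigns every sample to group `"all"`.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, sample_columns = NULL, mass_column = "Mass",
                            formula_columns = NULL, isotope_column = NULL,
                            sample_meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!mass_column %in% names(raw)) {
    stop("mass column '", mass_column, "' not found")
  }
  if (is.null(formula_columns) && all(ELEMENTS %in% names(raw))) {
    formula_columns <- ELEMENTS
  }
  reserved <- c(mass_column, formula_columns, isotope_column)
  if (is.null(sample_columns)) {
    sample_columns <- setdiff(names(raw), reserved)
  }
  missing_cols <- setdiff(sample_columns, names(raw))
  if (length(missing_cols)) {
    stop("sample columns not found: ", paste(missing_cols, collapse = ", "))
  }

  mass <- suppressWarnings(as.numeric(raw[[mass_column]]))
  if (anyNA(mass)) {
    stop("non-numeric mass in row ", paste(which(is.na(mass)), collapse = ", "))
  }
  peaks <- data.frame(mass = mass)
  if (!is.null(formula_columns)) {
    if (length(formula_columns) != 6) {
      stop("formula_columns must name six columns (C, H, N, O, S, P)")
    }
    for (i in seq_along(ELEMENTS)) {
      peaks[[ELEMENTS[i]]] <- suppressWarnings(as.numeric(raw[[formula_columns[i]]]))
    }
    # a formula is assigned only when all six counts are defined
    part <- rowSums(is.na(peaks[ELEMENTS])) %in% seq_len(5)
    peaks[part, ELEMENTS] <- NA_real_
  }
  if (!is.null(isotope_column)) {
    peaks$isotopologue <- raw[[isotope_column]] %in% c(TRUE, 1, "1", "TRUE", "yes")
  }
  inc <- t(as.matrix(raw[, sample_columns, drop = FALSE]))
  rownames(inc) <- sample_columns
  if (is.character(sample_meta)) {
    sample_meta <- read_sample_metadata(sample_meta)
  }
  peak_table(peaks, inc, sample_meta)
}

#' Read sample metadata (sample_id, group) from CSV
#'
#' @param path CSV path with columns `sample_id` and `group`.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata must have columns 'sample_id' and 'group'")
  }
  meta
}

#' Filter peaks by mass window and isotopologue flag
#'
#' Retains peaks whose neutral mass lies within `[mz_min, mz_max]` (default
#' 200-900 Da, the instrument window commonly analysed for dissolved organic
#' matter) and, optionally, drops peaks flagged as isotopologues. Incidence
#' columns are pruned consistently; filtering is idempotent.
#'
#' @param table A [peak_table()].
#' @param mz_min,mz_max Mass window bounds in Da (`mz_min < mz_max`).
#' @param drop_isotopologues Drop peaks carrying the isotopologue flag?
#' @return A filtered `peak_table`.
#' @export
filter_peaks <- function(table, mz_min = 200, mz_max = 900,
                         drop_isotopologues = TRUE) {
  stopifnot(inherits(table, "peak_table"))
  if (!(mz_min < mz_max)) stop("mz_min must be less than mz_max")
  keep <- table$peaks$mass >= mz_min & table$peaks$mass <= mz_max
  if (drop_isotopologues) keep <- keep & !table$peaks$isotopologue
  if (!any(keep)) {
    stop("no peaks left after filtering; check the mass range [",
         mz_min, ", ", mz_max, "]")
  }
  peaks <- table$peaks[keep, , drop = FALSE]
  inc <- table$incidence[, peaks$peak_id, drop = FALSE]
  suppressWarnings(
    pt <- peak_table(peaks, inc, table$sample_meta)
  )
  empty <- setdiff(rownames(table$incidence), rownames(pt$incidence))
  if (length(empty)) {
    warning("sample(s) lost all peaks during filtering: ",
            paste(empty, collapse = ", "))
  }
  pt
}

#' Binary incidence matrix of a peak table
#'
#' @param table A [peak_table()].
#' @return Integer 0/1 matrix, samples in rows, peak_ids in columns.
#' @export
assemblage_matrix <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  table$incidence
}
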