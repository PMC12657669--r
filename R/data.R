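#' Build a validated correlation-matrix meta-analytic dataset
#'
#' Takes a long-format data frame with one row per correlation coefficient per
#' independent sample (samples nested in primary studies) and returns a
#' validated, canonically ordered dataset ready for pooling. Each row holds a
#' Pearson correlation between two named variables ("cells" of the correlation
#' matrix), the sample size it was computed from, and the identifiers of the
#' sample and study it belongs to. Extra columns are carried through as
#' moderators.
#'
#' Validation enforces the model's requirements: correlations strictly inside
#' (-1, 1); sample sizes of at least 5 (the Fisher-z variance 1/(n-3) and the
#' large-sample covariance formulas need this); each sample belonging to
#' exactly one study; a constant n within a sample; and at most one
#' correlation per (sample, cell) pair. Incomplete matrices (missing cells) are
#' legal and simply contribute fewer rows.
#'
#' Cell labels are canonicalized to "A–B" (en dash) with A preceding B in
#' the declared variable order, so that reversed Var1/Var2 inputs name the same
#' cell (a correlation is symmetric in its variables).
#'
#' @param df Data frame with columns for study, sample, the two variable
#'   names, the correlation and the sample size. Default column names follow
#'   the common layout `StudyID`, `SampleID`, `ESID`, `Var1`, `Var2`, `Cell`,
#'   `Correlation`, `N`; override via `column_map`. `ESID` and `Cell` are
#'   optional (regenerated). All other columns are treated as moderators.
#' @param variable_order Character vector declaring the variable roster order.
#'   Defaults to order of first appearance in `Var1`/`Var2`.
#' @param column_map Named character vector mapping internal roles
#'   (`study`, `sample`, `es_id`, `var1`, `var2`, `cell`, `r`, `n`) to column
#'   names in `df`. Only roles that deviate from the defaults need to be given.
#' @return A tibble of class `cor_data`, sorted by study, sample within study,
#'   then cell roster order, with columns `study_id`, `sample_id`, `es_id`,
#'   `var_a`, `var_b`, `cell`, `r`, `n` plus any moderator columns. The
#'   variable roster and the cell roster (all I(I-1)/2 unordered pairs) are
#'   attached as attributes `variables` and `cells`.
#' @examples
#' toy <- tibble::tibble(
#'   StudyID = c(1, 1, 1, 2, 2, 2, 2, 2, 2),
#'   SampleID = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
#'   Var1 = rep(c("A", "A", "B"), 3),
#'   Var2 = rep(c("B", "C", "C"), 3),
#'   Correlation = c(.3, .4, .5, .2, .3, .4, .25, .35, .45),
#'   N = c(100, 100, 100, 200, 200, 200, 150, 150, 150)
#' )
#' dat <- cor_data(toy)
#' summarize_cor_data(dat)
#' @export
cor_data <- function(df, variable_order = NULL, column_map = NULL) {
  map <- .resolve_column_map(df, column_map)
  dat <- tibble::tibble(
    study_id  = as.character(df[[map["study"]]]),
    sample_id = as.character(df[[map["sample"]]]),
    var_a     = as.character(df[[map["var1"]]]),
    var_b     = as.character(df[[map["var2"]]]),
    r         = as.numeric(df[[map["r"]]]),
    n         = as.numeric(df[[map["n"]]])
  )
  used <- unname(map[c("study", "sample", "var1", "var2", "r", "n")])
  # ESID / Cell are regenerated; drop originals rather than carry stale copies
  used <- c(used, unname(map[c("es_id", "cell")]), "es_id", "cell")
  moderators <- setdiff(names(df), used)
  for (m in moderators) dat[[m]] <- df[[m]]

  if (anyNA(dat$r) || anyNA(dat$n)) {
    stop("correlation and sample-size columns must parse as numeric without NA",
         call. = FALSE)
  }
  if (nrow(dat) > 0 && any(abs(dat$r) >= 1)) {
    bad <- which(abs(dat$r) >= 1)
    stop("correlations must lie strictly in (-1, 1); offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(dat) > 0 && any(dat$n < 5)) {
    bad <- which(dat$n < 5)
    stop("sample sizes must be at least 5; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(dat) > 0 && any(dat$var_a == dat$var_b)) {
    stop("a cell must involve two distinct variables", call. = FALSE)
  }

  vars <- if (is.null(variable_order)) {
    unique(c(rbind(dat$var_a, dat$var_b)))
  } else {
    as.character(variable_order)
  }
  unknown <- setdiff(unique(c(dat$var_a, dat$var_b)), vars)
  if (length(unknown) > 0) {
    stop("variables not in declared order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  # canonical orientation: var_a before var_b in the roster
  ia <- match(dat$var_a, vars)
  ib <- match(dat$var_b, vars)
  flip <- ia > ib
  if (any(flip)) {
    tmp <- dat$var_a[flip]
    dat$var_a[flip] <- dat$var_b[flip]
    dat$var_b[flip] <- tmp
    tmp <- ia[flip]; ia[flip] <- ib[flip]; ib[flip] <- tmp
  }
  dat$cell <- cell_label(dat$var_a, dat$var_b)

  cells <- cell_roster(vars)

  # one study per sample, constant n per sample
  per_sample <- dplyr::summarise(
    dplyr::group_by(dat, .data$sample_id),
    n_studies = dplyr::n_distinct(.data$study_id),
    n_sizes = dplyr::n_distinct(.data$n),
    .groups = "drop"
  )
  if (any(per_sample$n_studies > 1)) {
    stop("sample(s) span more than one study: ",
         paste(per_sample$sample_id[per_sample$n_studies > 1], collapse = ", "),
         call. = FALSE)
  }
  if (any(per_sample$n_sizes > 1)) {
    stop("sample size n must be constant within a sample; offending sample(s): ",
         paste(per_sample$sample_id[per_sample$n_sizes > 1], collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(dat[c("sample_id", "cell")])
  if (any(dup)) {
    key <- paste0(dat$sample_id[dup], " / ", dat$cell[dup])
    stop("duplicate (sample, cell) rows: ", paste(unique(key), collapse = "; "),
         call. = FALSE)
  }

  # total, deterministic vectorization order
  dat$..cell_idx <- match(dat$cell, cells$label)
  ord <- order(.natural_key(dat$study_id), .natural_key(dat$sample_id),
               dat$..cell_idx)
  dat <- dat[ord, , drop = FALSE]
  dat$..cell_idx <- NULL
  dat$es_id <- if (nrow(dat) > 0) seq_len(nrow(dat)) else integer(0)
  dat <- dat[c("study_id", "sample_id", "es_id", "var_a", "var_b", "cell",
               "r", "n", moderators)]

  structure(dat,
            class = c("cor_data", class(tibble::tibble())),
            variables = vars, cells = cells, moderators = moderators)
}

#' Read a correlation dataset from CSV
#'
#' Thin wrapper around [readr::read_csv()] + [cor_data()]. The expected layout
#' is one row per correlation with header columns `StudyID`, `SampleID`,
#' `Var1`, `Var2`, `Correlation`, `N` (plus optional `ESID`, `Cell` and any
#' moderator columns).
#'
#' @inheritParams cor_data
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A `cor_data` tibble; see [cor_data()].
#' @export
read_cor_data <- function(path, variable_order = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cor_data(df, variable_order = variable_order, column_map = column_map)
}

#' Write a correlation dataset to CSV
#'
#' Writes the normalized long format (the same schema [read_cor_data()]
#' accepts), so that a write/read round trip reproduces the dataset.
#'
#' @param data A `cor_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cor_data <- function(data, path) {
  stopifnot(inherits(data, "cor_data"))
  out <- tibble::as_tibble(data)
  names(out)[match(c("study_id", "sample_id", "es_id", "var_a", "var_b",
                     "cell", "r", "n"), names(out))] <-
    c("StudyID", "SampleID", "ESID", "Var1", "Var2", "Cell", "Correlation", "N")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarize a correlation dataset
#'
#' Descriptive statistics at the three levels of the hierarchy: rows
#' (correlation coefficients), samples (independent correlation matrices) and
#' primary studies. Participant totals and sample-size statistics are computed
#' over distinct samples, not rows; matrices-per-study statistics over studies.
#'
#' @param data A `cor_data` object.
#' @return A list of class `cor_data_summary` with elements `counts` (one-row
#'   tibble: `n_records`, `n_samples`, `n_studies`, `total_participants`),
#'   `sample_size` and `matrices_per_study` (one-row tibbles with
#'   mean/sd/median/min/max; all-`NA` when the dataset is empty).
#' @export
summarize_cor_data <- function(data) {
  stopifnot(inherits(data, "cor_data"))
  samples <- dplyr::distinct(tibble::as_tibble(data),
                             .data$study_id, .data$sample_id, .data$n)
  per_study <- dplyr::count(samples, .data$study_id)
  stat5 <- function(x) {
    if (length(x) == 0) {
      tibble::tibble(mean = NA_real_, sd = NA_real_, median = NA_real_,
                     min = NA_real_, max = NA_real_)
    } else {
      tibble::tibble(mean = mean(x), sd = stats::sd(x),
                     median = stats::median(x), min = min(x), max = max(x))
    }
  }
  structure(list(
    counts = tibble::tibble(
      n_records = nrow(data),
      n_samples = nrow(samples),
      n_studies = nrow(per_study),
      total_participants = if (nrow(samples) == 0) 0 else sum(samples$n)
    ),
    sample_size = stat5(samples$n),
    matrices_per_study = stat5(as.numeric(per_study$n))
  ), class = "cor_data_summary")
}

#' @export
print.cor_data_summary <- function(x, ...) {
  cat("Correlation-matrix meta-analytic dataset\n")
  cat(sprintf("  %d correlations from %d samples in %d studies (total N = %s)\n",
              x$counts$n_records, x$counts$n_samples, x$counts$n_studies,
              format(x$counts$total_participants, big.mark = ",")))
  if (!is.na(x$sample_size$mean)) {
    cat(sprintf("  per-sample n: M = %.1f, SD = %.1f, Mdn = %s, range [%s, %s]\n",
                x$sample_size$mean, x$sample_size$sd,
                format(x$sample_size$median), format(x$sample_size$min),
                format(x$sample_size$max)))
    cat(sprintf("  matrices per study: M = %.1f, Mdn = %s, max = %s\n",
                x$matrices_per_study$mean, format(x$matrices_per_study$median),
                format(x$matrices_per_study$max)))
  }
  invisible(x)
}

#' Vectorize a correlation dataset
#'
#' Flattens the dataset into the effect-size vector y and an index frame that
#' is the single source of truth for aligning the sampling covariance matrix,
#' design matrices and random-effect indicators. The row order is the
#' dataset's total order (study, sample within study, cell roster order), so
#' shuffling input rows never changes the result.
#'
#' @param data A `cor_data` object.
#' @return List with `y` (numeric vector of correlations) and `index` (tibble
#'   with `row`, `es_id`, `study_id`, `sample_id`, `cell`, `cell_idx`, `n`).
#' @export
cor_vectorize <- function(data) {
  stopifnot(inherits(data, "cor_data"))
  cells <- attr(data, "cells")
  idx <- tibble::tibble(
    row = seq_len(nrow(data)),
    es_id = data$es_id,
    study_id = data$study_id,
    sample_id = data$sample_id,
    cell = data$cell,
    cell_idx = match(data$cell, cells$label),
    n = data$n
  )
  list(y = data$r, index = idx)
}

#' Canonical cell labels for variable pairs
#'
#' @param var_a,var_b Variable names (vectors of equal length).
#' @return Character vector "a–b" (en dash separator).
#' @export
cell_label <- function(var_a, var_b) paste0(var_a, "–", var_b)

#' All cells for a variable roster
#'
#' @param variables Ordered character vector of variable names.
#' @return Tibble with `var_a`, `var_b`, `label`: the I(I-1)/2 unordered pairs
#'   in roster order (a before b).
#' @export
cell_roster <- function(variables) {
  if (length(variables) < 2) {
    return(tibble::tibble(var_a = character(), var_b = character(),
                          label = character()))
  }
  pairs <- utils::combn(variables, 2)
  tibble::tibble(var_a = pairs[1, ], var_b = pairs[2, ],
                 label = cell_label(pairs[1, ], pairs[2, ]))
}

.default_column_map <- c(study = "StudyID", sample = "SampleID", es_id = "ESID",
                         var1 = "Var1", var2 = "Var2", cell = "Cell",
                         r = "Correlation", n = "N")

.resolve_column_map <- function(df, column_map) {
  map <- .default_column_map
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad) > 0) {
      stop("unknown column-map roles: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  required <- map[c("study", "sample", "var1", "var2", "r", "n")]
  missing <- required[!required %in% names(df)]
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  map
}

# sort key that orders numeric-looking ids numerically, others lexically
.natural_key <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) {
    rank(num, ties.method = "min")
  } else {
    rank(x, ties.method = "min")
  }
}

# shared getters
.cells_of <- function(data) attr(data, "cells")
.vars_of <- function(data) attr(data, "variables")
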