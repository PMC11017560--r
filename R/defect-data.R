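#' @useDynLib mvdefect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats plogis qlogis rnorm runif rbinom rbeta rcauchy rpois sd
#'   quantile median dnorm dgamma dcauchy dbeta dbinom setNames
NULL

# canonical component orders used throughout the package and its tables
REGION_LABELS <- c("cervical", "middle", "incisal")
DEFECT_LABELS <- c("EH", "OP", "PEB", "DC")
NA_TOKENS <- c("", "NA")

default_labels <- function(axis_kind) {
  switch(axis_kind, regions = REGION_LABELS, defects = DEFECT_LABELS)
}

#' Construct a defect outcome panel
#'
#' A defect panel holds one binary outcome per subject and outcome component,
#' where the component axis is either the three horizontal tooth regions of
#' the primary maxillary central incisors (cervical, middle, incisal) or the
#' four defect types scored within a single region (enamel hypoplasia EH,
#' opacity OP, post-eruptive breakdown PEB, dental caries DC). Missing cells
#' are allowed and tracked by an observation mask; the model likelihood skips
#' masked cells.
#'
#' @param data A data frame with one column per component label containing
#'   0/1/NA values, plus an optional `subject_id` column.
#' @param axis_kind Either `"regions"` (3 components) or `"defects"`
#'   (4 components).
#' @param labels Component names in order. Defaults to the canonical order
#'   `c("cervical", "middle", "incisal")` or `c("EH", "OP", "PEB", "DC")`.
#' @return An object of class `defect_panel` with elements `y` (n x d binary
#'   matrix, `NA` where unobserved), `observed` (logical mask), `subject_ids`,
#'   `axis_kind`, and `labels`.
#' @export
#' @examples
#' defect_panel(data.frame(cervical = c(0, 1), middle = c(1, NA),
#'                         incisal = c(0, 0)))
defect_panel <- function(data, axis_kind = c("regions", "defects"),
                         labels = NULL) {
  axis_kind <- match.arg(axis_kind)
  if (is.null(labels)) labels <- default_labels(axis_kind)
  d_expect <- if (axis_kind == "regions") 3L else 4L
  if (length(labels) != d_expect) {
    stop(sprintf("axis_kind '%s' requires %d component labels, got %d",
                 axis_kind, d_expect, length(labels)), call. = FALSE)
  }
  data <- as.data.frame(data)
  missing_cols <- setdiff(labels, names(data))
  if (length(missing_cols) > 0) {
    stop("panel is missing component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  subject_ids <- if ("subject_id" %in% names(data)) {
    as.character(data$subject_id)
  } else {
    as.character(seq_len(nrow(data)))
  }
  y <- as.matrix(data[labels])
  storage.mode(y) <- "double"
  bad <- which(!is.na(y) & !(y %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("outcome cell outside {0, 1, NA} at row %d, column '%s' (value %s)",
                 bad[1, 1], labels[bad[1, 2]], format(y[bad[1, , drop = FALSE]])),
         call. = FALSE)
  }
  if (nrow(y) < 1) stop("panel must contain at least one subject", call. = FALSE)
  structure(
    list(y = y, observed = !is.na(y), subject_ids = subject_ids,
         axis_kind = axis_kind, labels = labels),
    class = "defect_panel"
  )
}

#' @export
print.defect_panel <- function(x, ...) {
  cat(sprintf("<defect_panel> %d subjects x %d components (%s)\n",
              nrow(x$y), ncol(x$y), x$axis_kind))
  cat("  components:", paste(x$labels, collapse = ", "), "\n")
  cat(sprintf("  observed cells: %d / %d\n", sum(x$observed), length(x$observed)))
  invisible(x)
}

#' @export
as.data.frame.defect_panel <- function(x, ...) {
  out <- as.data.frame(x$y)
  names(out) <- x$labels
  cbind(subject_id = x$subject_ids, out)
}

#' Read a defect panel from a delimited text file
#'
#' Expects a UTF-8 CSV with a header row containing one column per component
#' label; empty cells and the token `NA` are treated as missing. Row order is
#' preserved.
#'
#' @inheritParams defect_panel
#' @param path Path to a CSV file.
#' @return A [defect_panel()].
#' @export
read_defect_panel <- function(path, axis_kind = c("regions", "defects"),
                              labels = NULL) {
  axis_kind <- match.arg(axis_kind)
  if (is.null(labels)) labels <- default_labels(axis_kind)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = NA_TOKENS, progress = FALSE)
  missing_cols <- setdiff(labels, names(raw))
  if (length(missing_cols) > 0) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- raw
  for (lab in labels) {
    cell <- raw[[lab]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & (is.na(num) | !(num %in% c(0, 1))))
    if (length(bad) > 0) {
      stop(sprintf("invalid outcome value '%s' at row %d, column '%s' (must be 0, 1 or NA)",
                   cell[bad[1]], bad[1], lab), call. = FALSE)
    }
    parsed[[lab]] <- num
  }
  defect_panel(as.data.frame(parsed), axis_kind = axis_kind, labels = labels)
}

#' Write a defect panel to CSV
#'
#' Inverse of [read_defect_panel()]: masked cells are written as empty fields.
#'
#' @param panel A [defect_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_defect_panel <- function(panel, path) {
  stopifnot(inherits(panel, "defect_panel"))
  readr::write_csv(as.data.frame(panel), path, na = "")
  invisible(path)
}

#' Drop subjects with no observed outcome
#'
#' By default the likelihood skips masked outcome cells so partially observed
#' subjects contribute through their observed components. This helper removes
#' subjects with every component missing (the only rows that carry no outcome
#' information), or optionally any row with a missing component.
#'
#' @param panel A [defect_panel()].
#' @param which `"all_missing"` drops only fully unobserved subjects;
#'   `"any_missing"` drops every subject with at least one masked component.
#' @return A filtered [defect_panel()].
#' @export
drop_unobserved <- function(panel, which = c("all_missing", "any_missing")) {
  which <- match.arg(which)
  keep <- if (which == "all_missing") {
    rowSums(panel$observed) > 0
  } else {
    rowSums(panel$observed) == ncol(panel$y)
  }
  if (!any(keep)) stop("no subjects left after filtering", call. = FALSE)
  structure(
    list(y = panel$y[keep, , drop = FALSE],
         observed = panel$observed[keep, , drop = FALSE],
         subject_ids = panel$subject_ids[keep],
         axis_kind = panel$axis_kind, labels = panel$labels),
    class = "defect_panel"
  )
}

#' Per-component defect prevalence
#'
#' Counts defect presence per outcome component over observed cells only, so
#' denominators differ across components when missingness differs.
#'
#' @param panel A [defect_panel()].
#' @return A tibble with columns `component`, `n_present`, `n_observed`, and
#'   `percent` (100 * n_present / n_observed; `NA` when nothing is observed).
#' @export
#' @examples
#' p <- defect_panel(data.frame(cervical = c(1, 0, NA), middle = c(0, 0, 0),
#'                              incisal = c(1, 1, 0)))
#' summarize_prevalence(p)
summarize_prevalence <- function(panel) {
  stopifnot(inherits(panel, "defect_panel"))
  n_obs <- colSums(panel$observed)
  n_present <- colSums(panel$y == 1, na.rm = TRUE)
  tibble::tibble(
    component = panel$labels,
    n_present = as.integer(unname(n_present)),
    n_observed = as.integer(unname(n_obs)),
    percent = unname(ifelse(n_obs > 0, 100 * n_present / n_obs, NA_real_))
  )
}

#' Declare predictor columns and their kinds
#'
#' The model distinguishes continuous predictors, binary predictors, and
#' three-level categorical predictors (the vitamin-D binding protein genotype
#' with levels 1s/1f/2 is the motivating example). Categorical predictors are
#' dummy-encoded with the first declared level as the reference.
#'
#' @param columns Character vector of predictor column names.
#' @param kinds Character vector, same length, each one of `"continuous"`,
#'   `"binary"`, `"categorical3"`.
#' @param levels Named list giving the three ordered levels of each
#'   `categorical3` column (first level = reference).
#' @return A tibble describing the schema, class `predictor_schema`.
#' @export
predictor_schema <- function(columns, kinds, levels = list()) {
  kinds <- match.arg(kinds, c("continuous", "binary", "categorical3"),
                     several.ok = TRUE)
  if (length(columns) != length(kinds)) {
    stop("`columns` and `kinds` must have the same length", call. = FALSE)
  }
  cat3 <- columns[kinds == "categorical3"]
  for (col in cat3) {
    lv <- levels[[col]]
    if (is.null(lv) || length(lv) != 3) {
      stop("categorical3 column '", col, "' needs exactly 3 declared levels",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(column = columns, kind = kinds,
                        levels = lapply(columns, function(cl) levels[[cl]]))
  class(out) <- c("predictor_schema", class(out))
  out
}

encode_predictors <- function(data, schema, race = NULL) {
  n <- nrow(data)
  cols <- list()
  mask <- list()
  meta <- list()
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    kind <- schema$kind[i]
    if (!col %in% names(data)) {
      stop("predictor column '", col, "' not found in data", call. = FALSE)
    }
    v <- data[[col]]
    if (kind == "continuous") {
      num <- if (is.character(v)) suppressWarnings(as.numeric(ifelse(v %in% NA_TOKENS, NA, v))) else as.numeric(v)
      bad <- which(!is.na(v) & !(as.character(v) %in% NA_TOKENS) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value '%s' at row %d in continuous column '%s'",
                     as.character(v[bad[1]]), bad[1], col), call. = FALSE)
      }
      if (all(is.na(num))) {
        warning("continuous column '", col, "' is entirely missing", call. = FALSE)
      }
      cols[[col]] <- num
      mask[[col]] <- !is.na(num)
      meta[[length(meta) + 1]] <- tibble::tibble(predictor = col, column = col, kind = kind)
    } else if (kind == "binary") {
      num <- if (is.character(v)) suppressWarnings(as.numeric(ifelse(v %in% NA_TOKENS, NA, v))) else as.numeric(v)
      bad <- which(!is.na(num) & !(num %in% c(0, 1)))
      if (length(bad) > 0) {
        stop(sprintf("binary column '%s' has non 0/1 value %s at row %d",
                     col, format(num[bad[1]]), bad[1]), call. = FALSE)
      }
      cols[[col]] <- num
      mask[[col]] <- !is.na(num)
      meta[[length(meta) + 1]] <- tibble::tibble(predictor = col, column = col, kind = kind)
    } else { # categorical3 -> two dummies, reference = first declared level
      lv <- schema$levels[[i]]
      chr <- as.character(v)
      chr[chr %in% NA_TOKENS] <- NA
      bad <- which(!is.na(chr) & !(chr %in% lv))
      if (length(bad) > 0) {
        stop(sprintf("level '%s' at row %d of categorical column '%s' is not one of {%s}",
                     chr[bad[1]], bad[1], col, paste(lv, collapse = ", ")), call. = FALSE)
      }
      for (j in 2:3) {
        dcol <- paste0(col, "_", lv[j])
        cols[[dcol]] <- as.numeric(chr == lv[j])
        mask[[dcol]] <- !is.na(chr)
        meta[[length(meta) + 1]] <- tibble::tibble(predictor = col, column = dcol,
                                                   kind = kind)
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  list(x = x, observed = do.call(cbind, mask), column_meta = dplyr::bind_rows(meta))
}

#' Construct a predictor table
#'
#' Dummy-encodes predictors according to a [predictor_schema()] and tracks
#' missingness per cell. Continuous columns stay on their native scale.
#' An optional 3-level maternal-race column is carried alongside; it is used
#' only by the multinomial-regression imputation model for the categorical
#' genotype predictor, never as a model predictor itself.
#'
#' @param data Data frame with one column per declared predictor (plus
#'   optionally the race column).
#' @param schema A [predictor_schema()].
#' @param race_column Optional name of the maternal-race column in `data`
#'   (at most 3 levels).
#' @return An object of class `predictor_table` with elements `x`
#'   (n x p numeric matrix after dummy-encoding), `observed` (mask),
#'   `column_meta`, `schema`, and `race` (factor or `NULL`).
#' @export
predictor_table <- function(data, schema, race_column = NULL) {
  stopifnot(inherits(schema, "predictor_schema"))
  data <- as.data.frame(data)
  enc <- encode_predictors(data, schema)
  race <- NULL
  if (!is.null(race_column)) {
    if (!race_column %in% names(data)) {
      stop("race column '", race_column, "' not found in data", call. = FALSE)
    }
    rv <- as.character(data[[race_column]])
    rv[rv %in% NA_TOKENS] <- NA
    race <- factor(rv)
    if (nlevels(race) > 3) {
      stop("race column must have at most 3 levels, found ", nlevels(race),
           call. = FALSE)
    }
  }
  structure(
    list(x = enc$x, observed = enc$observed, column_meta = enc$column_meta,
         schema = schema, race = race),
    class = "predictor_table"
  )
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("<predictor_table> %d subjects x %d encoded columns (%d predictors)\n",
              nrow(x$x), ncol(x$x), nrow(x$schema)))
  miss <- sum(!x$observed)
  if (miss > 0) cat(sprintf("  missing cells: %d\n", miss))
  invisible(x)
}

#' Read a predictor table from a delimited text file
#'
#' @param path Path to a UTF-8 CSV with header row; empty cells and `NA` are
#'   treated as missing.
#' @inheritParams predictor_table
#' @return A [predictor_table()].
#' @export
read_predictor_table <- function(path, schema, race_column = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = NA_TOKENS, progress = FALSE)
  predictor_table(as.data.frame(raw), schema, race_column = race_column)
}

#' Fraction of missing cells per predictor column
#'
#' @param predictors A [predictor_table()].
#' @return A tibble with `column`, `kind`, `n_missing`, `fraction_missing`.
#' @export
missingness_summary <- function(predictors) {
  stopifnot(inherits(predictors, "predictor_table"))
  tibble::tibble(
    column = colnames(predictors$x),
    kind = predictors$column_meta$kind,
    n_missing = unname(colSums(!predictors$observed)),
    fraction_missing = unname(colMeans(!predictors$observed))
  )
}
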