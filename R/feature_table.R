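#' Read a samples-by-features table from CSV
#'
#' Reads a comma-separated feature table (header row; rows are samples,
#' columns are features such as taxon counts or clr-transformed abundances),
#' drops declared metadata columns, and validates that everything that
#' remains is numeric. Metadata removal is always explicit: nothing is
#' inferred from column content.
#'
#' If the first column of the file is non-numeric and not listed in
#' `drop_columns` it is taken as the sample identifier column; otherwise
#' samples are labelled `S1`, `S2`, ... in file order.
#'
#' @param path Path to a CSV file with a header row.
#' @param drop_columns Character vector of metadata column names to remove
#'   before validation.
#' @param transpose If `TRUE`, the file is feature-by-sample and is
#'   transposed after reading (the first column then holds feature ids).
#' @return A feature table: a tibble whose first column is `sample_id`
#'   (character, unique) followed by one numeric column per feature.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(sample = c("S1", "S2"), a = 1:2, b = c(3, 5)), path)
#' read_feature_table(path)
#' @export
read_feature_table <- function(path, drop_columns = character(), transpose = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Feature table file not found: '%s'.", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  if (transpose) {
    ids <- raw[[1L]]
    m <- t(as.matrix(raw[, -1L, drop = FALSE]))
    raw <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE), rownames = "sample")
    names(raw) <- c("sample", ids)
  }
  missing_drops <- setdiff(drop_columns, names(raw))
  if (length(missing_drops) > 0L) {
    abort(sprintf("drop_columns not present in file: %s.",
                  paste(sQuote(missing_drops), collapse = ", ")))
  }
  raw <- raw[, !(names(raw) %in% drop_columns), drop = FALSE]
  if (ncol(raw) == 0L) {
    abort("No columns remain after dropping metadata columns.")
  }

  first_numeric <- !anyNA(suppressWarnings(as.numeric(raw[[1L]])))
  if (!first_numeric) {
    sample_ids <- raw[[1L]]
    values <- raw[, -1L, drop = FALSE]
  } else {
    sample_ids <- paste0("S", seq_len(nrow(raw)))
    values <- raw
  }
  if (anyDuplicated(sample_ids)) {
    abort("Duplicate sample identifiers in the first column.")
  }
  if (anyDuplicated(names(values))) {
    dup <- unique(names(values)[duplicated(names(values))])
    abort(sprintf("Duplicate feature names: %s.", paste(sQuote(dup), collapse = ", ")))
  }
  if (ncol(values) == 0L) {
    abort("The table contains no feature columns.")
  }

  parsed <- lapply(names(values), function(col) {
    x <- values[[col]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Non-numeric value %s at row %d, column '%s'; drop metadata columns explicitly via `drop_columns`.",
        sQuote(ifelse(is.na(x[bad[1L]]), "NA", x[bad[1L]])), bad[1L], col))
    }
    num
  })
  names(parsed) <- names(values)
  out <- tibble(sample_id = as.character(sample_ids))
  out[names(parsed)] <- parsed
  out
}

#' Standardize feature names to X1, X2, ...
#'
#' Replaces feature names by `X1` ... `Xp` in original column order and
#' returns the bijective name map needed to recover the originals, which is
#' useful when long taxonomy strings make plots unreadable.
#'
#' @param table A feature table (first column `sample_id`).
#' @return A list with `table` (features renamed) and `name_map`, a tibble
#'   with columns `standardized` and `original`.
#' @examples
#' ft <- tibble::tibble(sample_id = c("S1", "S2"),
#'                      g__Bacteroides = c(1, 2), g__Lactobacillus = c(3, 4))
#' map_columns(ft)$name_map
#' @export
map_columns <- function(table) {
  features <- feature_ids(table)
  if (length(features) == 0L) {
    abort("Feature table has no features.")
  }
  std <- paste0("X", seq_along(features))
  out <- table
  names(out)[match(features, names(out))] <- std
  list(
    table = out,
    name_map = tibble(standardized = std, original = features)
  )
}

#' Restore original feature names from a name map
#'
#' @param table A feature table whose features carry standardized names.
#' @param name_map The `name_map` tibble produced by [map_columns()].
#' @return The table with original feature names.
#' @export
unmap_columns <- function(table, name_map) {
  idx <- match(names(table), name_map$standardized)
  names(table)[!is.na(idx)] <- name_map$original[idx[!is.na(idx)]]
  table
}

#' Centered log-ratio transform
#'
#' Applies the clr transform row-wise: each sample's values become
#' `log(x + pseudocount) - mean(log(x + pseudocount))`, mapping non-negative
#' compositional data onto an unconstrained scale where every row sums to
#' zero. The transform is never applied implicitly by any other function in
#' the package.
#'
#' @param table A feature table with non-negative values.
#' @param pseudocount Positive offset added before taking logs (default 1,
#'   the usual choice for count tables).
#' @return The transformed feature table.
#' @examples
#' ft <- tibble::tibble(sample_id = "S1", a = 1, b = 3)
#' clr_transform(ft)
#' @export
clr_transform <- function(table, pseudocount = 1) {
  assert_scalar_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) {
    abort("`pseudocount` must be > 0.")
  }
  m <- feature_matrix(table)
  if (any(m < 0)) {
    abort("clr_transform requires non-negative values.")
  }
  lg <- log(m + pseudocount)
  clr <- lg - rowMeans(lg)
  out <- table
  out[, colnames(m)] <- as.data.frame(clr)
  out
}

#' Write a result table to CSV
#'
#' UTF-8, comma-delimited, header row, no row-name column; numeric values
#' are written with enough digits to round-trip losslessly.
#'
#' @param rows A data frame (possibly zero-row, in which case only the
#'   header is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(as_tibble(rows), path, progress = FALSE)
  invisible(path)
}

# --- internal helpers -------------------------------------------------------

feature_ids <- function(table) {
  setdiff(names(table), "sample_id")
}

# n x p numeric matrix with sample ids as rownames; validates the contract.
feature_matrix <- function(table) {
  if (!is.data.frame(table)) {
    abort("Expected a feature table (data frame with a `sample_id` column).")
  }
  feats <- feature_ids(table)
  if (length(feats) == 0L) {
    abort("Feature table has no features.")
  }
  m <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  if (!is.numeric(m)) {
    abort("Feature columns must all be numeric.")
  }
  if (anyNA(m)) {
    abort("Feature table contains missing values.")
  }
  rownames(m) <- if ("sample_id" %in% names(table)) table$sample_id else NULL
  m
}
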