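#' Phenotype table with variable kinds
#'
#' A `pheno_table` is a data.frame of participants (rows) by named variables
#' (columns) carrying an explicit declaration of each variable's kind:
#' `"continuous"`, `"ordinal"` or `"categorical"`.  Missing entries are plain
#' `NA` — no sentinel values.  Row names are subject identifiers.
#'
#' @param data data.frame of phenotype values (numeric or factor columns).
#' @param kinds named character vector mapping every column of `data` to one
#'   of `"continuous"`, `"ordinal"`, `"categorical"`.  Unnamed scalar input is
#'   recycled to all columns.
#' @return An object of class `pheno_table` (inherits from `data.frame`).
#' @export
pheno_table <- function(data, kinds = "continuous") {
  data <- as.data.frame(data)
  if (is.null(names(kinds)) && length(kinds) == 1L) {
    kinds <- stats::setNames(rep(kinds, ncol(data)), names(data))
  }
  if (!all(names(data) %in% names(kinds))) {
    stop("every column needs an entry in `kinds`")
  }
  kinds <- kinds[names(data)]
  ok <- kinds %in% c("continuous", "ordinal", "categorical")
  if (!all(ok)) stop("unknown variable kind: ", paste(unique(kinds[!ok]), collapse = ", "))
  structure(data, var_kinds = kinds, class = c("pheno_table", "data.frame"))
}

#' @export
print.pheno_table <- function(x, ...) {
  k <- table(var_kinds(x))
  cat(sprintf("<pheno_table> %d subjects x %d variables (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%d %s", k, names(k)), collapse = ", ")))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(x)),
              100 * mean(is.na(as.matrix(x)))))
  invisible(x)
}

#' Variable kinds of a phenotype table
#' @param x a `pheno_table`.
#' @return Named character vector of kinds.
#' @export
var_kinds <- function(x) {
  k <- attr(x, "var_kinds")
  if (is.null(k)) stats::setNames(rep("continuous", ncol(x)), names(x)) else k
}

# subset columns, keeping kinds in sync
pt_select <- function(x, cols) {
  pheno_table(as.data.frame(x)[, cols, drop = FALSE], var_kinds(x)[cols])
}

#' Missingness mask
#' @param x a `pheno_table`.
#' @return Logical matrix, `TRUE` where the entry is missing.
#' @export
missing_mask <- function(x) is.na(as.matrix(as.data.frame(x)))

#' Write / read the tab-separated phenotype-table dialect
#'
#' Tables are written as TSV with a header row, one row per subject, first
#' column `subject`, empty field = missing.  A JSON sidecar
#' (`<path>.json`) records the variable kinds and, when present, the true
#' generative parameters attached by the synthetic-cohort generator.
#'
#' @param x a `pheno_table`.
#' @param path output file path.
#' @return `write_pheno_table` returns `path` invisibly; `read_pheno_table`
#'   returns a `pheno_table`.
#' @export
write_pheno_table <- function(x, path) {
  df <- data.frame(subject = rownames(x), as.data.frame(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  side <- list(var_kinds = as.list(var_kinds(x)))
  truth <- attr(x, "truth")
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pheno_table
#' @export
read_pheno_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df$subject
  df$subject <- NULL
  sidecar <- paste0(path, ".json")
  kinds <- "continuous"
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    kinds <- unlist(side$var_kinds)
  }
  pheno_table(df, kinds)
}

#' Strict numeric matrix view of a phenotype table
#'
#' Errors if any column is non-numeric (dummy-code categorical variables
#' first).
#'
#' @param x a `pheno_table`.
#' @return Numeric matrix with subject row names.
#' @export
pt_matrix <- function(x) {
  df <- as.data.frame(x)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric columns present; dummy-code categorical variables first")
  }
  m <- as.matrix(df)
  rownames(m) <- rownames(x)
  m
}
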