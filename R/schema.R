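#' Survey data schema
#'
#' The 17-attribute schema of the obesity survey data: 16 features plus the
#' seven-level obesity label. Encodings follow the survey codebook:
#' binary fields are 0/1, ordinal fields use small integer code sets, and
#' `MTRANS` is categorical. Note the inverted coding of `FAVC`
#' (frequent consumption of high-caloric food): **0 = Yes, 1 = No** --
#' kept exactly as published so files round-trip unchanged.
#'
#' @return A tibble with columns `name`, `kind`
#'   (`numeric`/`binary`/`ordinal`/`categorical`/`label`) and `codes`
#'   (list-column of admissible codes; `NULL` for unrestricted numerics).
#' @examples
#' obesity_schema()
#' @export
obesity_schema <- function() {
  tibble::tibble(
    name = c("Gender", "Age", "Height", "Weight",
             "family_history_with_overweight", "FAVC", "FCVC", "NCP",
             "CAEC", "SMOKE", "CH2O", "SCC", "FAF", "TUE", "CALC",
             "MTRANS", "Obesity_level"),
    kind = c("binary", "numeric", "numeric", "numeric",
             "binary", "binary", "ordinal", "ordinal",
             "ordinal", "binary", "ordinal", "binary", "ordinal",
             "ordinal", "ordinal", "categorical", "label"),
    codes = list(0:1, NULL, NULL, NULL,
                 0:1, 0:1, 1:3, 1:4,
                 1:4, 0:1, 1:3, 0:1, 0:3, 0:2, 1:4,
                 mtrans_levels(), 1:7)
  )
}

#' @rdname obesity_schema
#' @export
mtrans_levels <- function() {
  c("automobile", "motorbike", "public_transportation", "walking")
}

# Column-name aliases accepted on read; canonical name on the left.
label_aliases <- c("Obesity_level", "NObeyesdad", "label", "obesity_level",
                   "Obesity_Level")

normalize_columns <- function(data) {
  nm <- names(data)
  hit <- nm %in% label_aliases
  if (sum(hit) > 1) abort("Multiple label columns found.")
  nm[hit] <- "Obesity_level"
  names(data) <- nm
  data
}

#' Validate records against the survey schema
#'
#' Checks that all schema columns are present, that no unknown columns
#' appear, and that every coded field lies in its code set. Violations
#' raise an error naming the offending rows and fields.
#'
#' @param data A data frame with the columns of [obesity_schema()].
#' @param require_label Is the `Obesity_level` column required? Default TRUE.
#' @return The validated data, invisibly, as a tibble.
#' @export
validate_obesity <- function(data, require_label = TRUE) {
  data <- normalize_columns(tibble::as_tibble(data))
  sch <- obesity_schema()
  if (!require_label) sch <- sch[sch$name != "Obesity_level", ]
  missing_cols <- setdiff(sch$name, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing schema columns: ", paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(names(data), obesity_schema()$name)
  if (length(unknown) > 0) {
    abort(paste0("Unknown columns: ", paste(unknown, collapse = ", ")))
  }
  problems <- character()
  for (i in seq_len(nrow(sch))) {
    codes <- sch$codes[[i]]
    if (is.null(codes)) next
    x <- data[[sch$name[i]]]
    if (is.character(codes)) x <- tolower(as.character(x))
    bad <- which(!is.na(x) & !(x %in% codes))
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        sch$name[i], ": invalid value in row",
        if (length(bad) > 1) "s " else " ",
        paste(head(bad, 5L), collapse = ", "),
        if (length(bad) > 5) paste0(" (and ", length(bad) - 5L, " more)") else ""
      ))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Schema violations:\n", paste("-", problems, collapse = "\n")))
  }
  invisible(data)
}

#' Read and write survey CSV files
#'
#' CSV files use a header row with the published feature names
#' (`Gender`, `Age`, ..., `MTRANS`); the label column may be named
#' `Obesity_level`, `NObeyesdad` or `label`. Files are UTF-8 with "."
#' as decimal separator. Reading validates every coded field against the
#' schema; writing then reading reproduces coded fields exactly.
#'
#' @param path File path.
#' @param require_label Require the label column on read? Default TRUE.
#' @return `read_obesity_csv()` returns a validated tibble;
#'   `write_obesity_csv()` returns `path` invisibly.
#' @export
read_obesity_csv <- function(path, require_label = TRUE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  data <- normalize_columns(data)
  if ("MTRANS" %in% names(data)) data$MTRANS <- tolower(as.character(data$MTRANS))
  validate_obesity(data, require_label = require_label)
  data
}

#' @rdname read_obesity_csv
#' @param data A schema-conformant data frame.
#' @export
write_obesity_csv <- function(data, path) {
  data <- validate_obesity(data, require_label = "Obesity_level" %in% names(data))
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Clean survey records
#'
#' Drops records with any missing field, exact duplicate records, and
#' numeric outliers by the 1.5 x IQR rule on the unbounded numeric fields
#' (age, height, weight by default). The counts removed per reason are
#' attached as the `"removed"` attribute and printed in a message.
#'
#' @param data A schema-conformant data frame.
#' @param iqr_columns Numeric columns screened with the IQR fence;
#'   use `character(0)` (or `iqr_k = Inf`) to disable outlier removal.
#' @param iqr_k Fence multiplier, default 1.5.
#' @param quiet Suppress the summary message? Default FALSE.
#' @return A cleaned tibble with attribute `removed =
#'   c(missing = , duplicate = , outlier = )`.
#' @export
clean_records <- function(data, iqr_columns = c("Age", "Height", "Weight"),
                          iqr_k = 1.5, quiet = FALSE) {
  data <- tibble::as_tibble(normalize_columns(data))
  n0 <- nrow(data)
  complete <- stats::complete.cases(data)
  data <- data[complete, , drop = FALSE]
  n_missing <- n0 - nrow(data)

  dup <- duplicated(data)
  data <- data[!dup, , drop = FALSE]
  n_dup <- sum(dup)

  n_out <- 0L
  iqr_columns <- intersect(iqr_columns, names(data))
  if (length(iqr_columns) > 0 && is.finite(iqr_k) && nrow(data) > 0) {
    keep <- rep(TRUE, nrow(data))
    for (col in iqr_columns) {
      x <- data[[col]]
      q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      fence <- iqr_k * (q[2] - q[1])
      keep <- keep & x >= q[1] - fence & x <= q[2] + fence
    }
    n_out <- sum(!keep)
    data <- data[keep, , drop = FALSE]
  }

  if (nrow(data) == 0) warn("All records were removed during cleaning.")
  removed <- c(missing = n_missing, duplicate = n_dup, outlier = n_out)
  if (!quiet) {
    message(sprintf("clean_records: removed %d missing, %d duplicate, %d outlier record(s); %d remain.",
                    n_missing, n_dup, n_out, nrow(data)))
  }
  attr(data, "removed") <- removed
  data
}
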