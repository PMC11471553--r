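#' Min-max scaler parameters
#'
#' Fit per-feature observed minima and maxima (or mean/sd in z-score
#' mode) on a training split only; apply with [scale_features()]. A
#' degenerate feature (max == min) transforms to 0.
#'
#' @param data Data frame of numeric features (training split).
#' @param columns Columns to fit; defaults to all numeric columns.
#' @param mode `"minmax"` (default) or `"zscore"`.
#' @return An object of class `"feature_scaler"`.
#' @export
fit_scaler <- function(data, columns = NULL, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  data <- tibble::as_tibble(data)
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stats_tbl <- purrr::map(columns, function(col) {
    x <- data[[col]]
    if (mode == "minmax") c(min = min(x), max = max(x))
    else c(mean = mean(x), sd = stats::sd(x))
  })
  structure(list(mode = mode, columns = columns,
                 stats = setNames(stats_tbl, columns)),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `"feature_scaler"`.
#' @export
scale_features <- function(data, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  data <- tibble::as_tibble(data)
  for (col in intersect(scaler$columns, names(data))) {
    s <- scaler$stats[[col]]
    x <- data[[col]]
    data[[col]] <- if (scaler$mode == "minmax") {
      if (s["max"] > s["min"]) (x - s["min"]) / (s["max"] - s["min"]) else rep(0, length(x))
    } else {
      if (s["sd"] > 0) (x - s["mean"]) / s["sd"] else rep(0, length(x))
    }
  }
  data
}

# Min-max rescale of x to [lo, hi] given fitted range (rng = c(min, max));
# degenerate fitted range maps everything to lo.
rescale_range <- function(x, rng, lo, hi) {
  if (rng[2] <= rng[1]) return(rep(lo, length(x)))
  lo + (hi - lo) * (x - rng[1]) / (rng[2] - rng[1])
}

check_codes <- function(x, codes, what) {
  if (any(!x %in% codes)) {
    abort(paste0("`", what, "` contains values outside its code set {",
                 paste(codes, collapse = ","), "}."))
  }
}

#' Meal habits score
#'
#' Joint eating-habit score: the product of vegetable-consumption
#' frequency (`FCVC`, codes 1-3) and number of main meals (`NCP`,
#' codes 1-4). Range 1 to 12.
#'
#' @param fcvc,ncp Ordinal codes (vectorized).
#' @return Numeric score vector.
#' @examples
#' meal_habits(3, 4) # 12
#' @export
meal_habits <- function(fcvc, ncp) {
  check_codes(fcvc, 1:3, "fcvc")
  check_codes(ncp, 1:4, "ncp")
  fcvc * ncp
}

#' Activity balance score
#'
#' Physical activity frequency (`FAF`, codes 0-3) minus technology time
#' (`TUE`) rescaled to FAF's [0, 3] range so that the two terms are
#' commensurable. The TUE range is taken from a scaler fitted on the
#' training split only. Range [-3, 3].
#'
#' @param faf,tue Ordinal codes (vectorized).
#' @param scaler Object from [fit_tue_scaler()].
#' @return Numeric score vector.
#' @export
activity_balance <- function(faf, tue, scaler) {
  check_codes(faf, 0:3, "faf")
  stopifnot(inherits(scaler, "tue_scaler"))
  faf - rescale_range(tue, scaler$range, 0, 3)
}

#' Technology usage score
#'
#' TUE min-max scaled to [0, 1] (range fitted on the training split) and
#' divided by age: the normalized technology time per unit age.
#'
#' @param tue Ordinal codes (vectorized).
#' @param age Age in years, strictly positive.
#' @param scaler Object from [fit_tue_scaler()].
#' @return Non-negative numeric score vector.
#' @export
tech_usage_score <- function(tue, age, scaler) {
  stopifnot(inherits(scaler, "tue_scaler"))
  if (any(!is.finite(age)) || any(age <= 0)) abort("`age` must be positive.")
  rescale_range(tue, scaler$range, 0, 1) / age
}

#' @rdname activity_balance
#' @export
fit_tue_scaler <- function(tue) {
  structure(list(range = c(min(tue), max(tue))), class = "tue_scaler")
}

#' Recode transport mode by physical effort
#'
#' Maps the categorical `MTRANS` feature to an activity ordinal:
#' automobile and motorbike 0 (passive), public transportation 1
#' (incidental walking), walking 2 (active). The survey codebook names
#' the categories but not a mapping; this ordering by physical effort is
#' the package's documented choice.
#'
#' @param mtrans Character vector of transport modes (case-insensitive).
#' @return Integer activity ordinal in 0..2.
#' @examples
#' recode_mtrans(c("walking", "automobile"))
#' @export
recode_mtrans <- function(mtrans) {
  key <- tolower(as.character(mtrans))
  map <- c(automobile = 0L, motorbike = 0L, public_transportation = 1L,
           walking = 2L)
  bad <- setdiff(unique(key), names(map))
  if (length(bad) > 0) {
    abort(paste0("Unknown transport mode(s): ", paste(bad, collapse = ", ")))
  }
  unname(map[key])
}

#' Drop the height column
#'
#' Height (together with weight) determines BMI and hence the label
#' almost trivially; the modeling pipeline removes it so the classifier
#' must rely on dietary and lifestyle features. The label and all other
#' columns are untouched; a missing height column is a warning no-op.
#'
#' @param data A data frame.
#' @return The data without its `Height` column.
#' @export
drop_height <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"Height" %in% names(data)) {
    warn("No `Height` column present; returning data unchanged.")
    return(data)
  }
  data[, setdiff(names(data), "Height"), drop = FALSE]
}

#' Feature-engineering configuration
#'
#' Controls which engineered scores are added, whether the raw
#' `FCVC`/`NCP`/`FAF`/`TUE` columns are kept alongside them, SMOTE
#' balancing, and the scaling mode.
#'
#' @param meal_habits,activity_balance,tech_usage,mtrans_recode Logical
#'   switches for each engineered feature (all on by default).
#' @param keep_original Keep the raw ordinal columns next to the
#'   engineered scores? Default TRUE.
#' @param drop_height Remove height before modeling? Default TRUE.
#' @param smote List `list(enabled = TRUE, k = 5)`.
#' @param scaling `"zscore"` (default; zero-mean inputs condition the
#'   swarm's weight search well) or `"minmax"`.
#' @return A list of class `"feature_config"`.
#' @export
feature_config <- function(meal_habits = TRUE, activity_balance = TRUE,
                           tech_usage = TRUE, mtrans_recode = TRUE,
                           keep_original = TRUE, drop_height = TRUE,
                           smote = list(enabled = TRUE, k = 5),
                           scaling = c("zscore", "minmax")) {
  scaling <- match.arg(scaling)
  stopifnot(is.logical(meal_habits), is.logical(keep_original))
  smote <- utils::modifyList(list(enabled = TRUE, k = 5), as.list(smote))
  structure(list(meal_habits = meal_habits,
                 activity_balance = activity_balance,
                 tech_usage = tech_usage, mtrans_recode = mtrans_recode,
                 keep_original = keep_original, drop_height = drop_height,
                 smote = smote, scaling = scaling),
            class = "feature_config")
}

#' Engineer survey features
#'
#' Adds the engineered scores (`Meal_Habits`, `Activity_Balance`,
#' `Tech_Usage_Score`) and replaces `MTRANS` by its activity ordinal.
#' All scalers involved must be fitted on the training split and passed
#' in for transforming validation/test data (no leakage): call once with
#' `tue_scaler = NULL` on the training split, then reuse the returned
#' `"tue_scaler"` attribute.
#'
#' @param data Schema-conformant data frame.
#' @param config A [feature_config()].
#' @param tue_scaler `NULL` to fit on `data` (training), or a fitted
#'   scaler from a previous call.
#' @return A tibble with engineered columns; the fitted TUE scaler is
#'   attached as attribute `"tue_scaler"`.
#' @export
engineer_features <- function(data, config = feature_config(),
                              tue_scaler = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(tue_scaler)) tue_scaler <- fit_tue_scaler(data$TUE)
  if (isTRUE(config$meal_habits)) {
    data$Meal_Habits <- meal_habits(data$FCVC, data$NCP)
  }
  if (isTRUE(config$activity_balance)) {
    data$Activity_Balance <- activity_balance(data$FAF, data$TUE, tue_scaler)
  }
  if (isTRUE(config$tech_usage)) {
    data$Tech_Usage_Score <- tech_usage_score(data$TUE, data$Age, tue_scaler)
  }
  if (isTRUE(config$mtrans_recode) && "MTRANS" %in% names(data)) {
    data$MTRANS_Activity <- recode_mtrans(data$MTRANS)
    data$MTRANS <- NULL
  }
  if (!isTRUE(config$keep_original)) {
    data <- data[, setdiff(names(data), c("FCVC", "NCP", "FAF", "TUE")),
                 drop = FALSE]
  }
  attr(data, "tue_scaler") <- tue_scaler
  data
}
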