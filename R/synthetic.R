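#' Default class weights for the synthetic cohort
#'
#' Mildly imbalanced seven-class proportions emulating the shape of the
#' survey cohort's label distribution (obesity type I slightly
#' over-represented). Order: insufficient weight ... obesity type III.
#'
#' @return Numeric vector of 7 proportions summing to 1.
#' @export
default_class_weights <- function() {
  c(0.13, 0.14, 0.14, 0.14, 0.17, 0.14, 0.14)
}

# Adiposity-conditional ordered-threshold (cumulative-logit) feature
# model. Each coded feature is generated from the continuous adiposity
# score `s` in [0, 1] (class index plus position inside the class's BMI
# band): the probability of being at or beyond each successive level is
# a logistic step centred at a level-specific adiposity stage `a`,
#   P(X >= level_j | s) = eps/2 + (1 - eps) * plogis(dir * (s - a_j) / tau),
# with dir = +1 for habits that intensify with adiposity (family
# history, high-caloric food, snacking, meals, technology time, alcohol)
# and dir = -1 for habits that decline (vegetables, water, calorie
# monitoring, physical activity, active transport; smoking is a weak
# lean-side marker). The stages are staggered across the whole adiposity
# range -- vegetable intake drops early, family history and calorie
# monitoring flip around overweight, activity collapses around obesity
# I, alcohol and transport mode change last -- so the feature set
# jointly pins down `s` even after height (and hence BMI) is removed.
# `eps` is irreducible response noise; `tau` the transition width.
profile_ends <- function() {
  list(
    family_history_with_overweight =
      list(codes = 0:1, dir = +1, a = 0.26, tau = 0.008, eps = 0.002),
    FAVC  = list(codes = 0:1, dir = +1, a = 0.38, tau = 0.008, eps = 0.002,
                 invert = TRUE),  # published coding: 0 = Yes, 1 = No
    FCVC  = list(codes = 1:3, dir = -1, a = c(0.47, 0.12), tau = 0.008, eps = 0.002),
    NCP   = list(codes = 1:4, dir = +1, a = c(0.10, 0.44, 0.80), tau = 0.008, eps = 0.002),
    CAEC  = list(codes = 1:4, dir = +1, a = c(0.16, 0.53, 0.83), tau = 0.008, eps = 0.002),
    SMOKE = list(codes = 0:1, dir = -1, a = 0.18, tau = 0.12, eps = 0.50),
    CH2O  = list(codes = 1:3, dir = -1, a = c(0.69, 0.28), tau = 0.008, eps = 0.002),
    SCC   = list(codes = 0:1, dir = -1, a = 0.31, tau = 0.008, eps = 0.002),
    FAF   = list(codes = 0:3, dir = -1, a = c(0.76, 0.50, 0.24), tau = 0.008, eps = 0.002),
    TUE   = list(codes = 0:2, dir = +1, a = c(0.33, 0.62), tau = 0.008, eps = 0.002),
    CALC  = list(codes = 1:4, dir = +1, a = c(0.21, 0.58, 0.90), tau = 0.008, eps = 0.002),
    # activity level 0/1/2, mapped to transport modes afterwards
    MTRANS = list(codes = 0:2, dir = -1, a = c(0.72, 0.40), tau = 0.008, eps = 0.002)
  )
}

# P(X >= level j+1 | s) for j = 1..k-1, given the feature spec.
threshold_survival <- function(e, s) {
  vapply(e$a, function(aj) {
    e$eps / 2 + (1 - e$eps) * stats::plogis(e$dir * (s - aj) / e$tau)
  }, numeric(length(s)))
}

# One draw per record: level = 1 + number of survival curves above u.
draw_ordered <- function(e, s, u = runif(length(s))) {
  FF <- threshold_survival(e, s)
  if (is.null(dim(FF))) FF <- matrix(FF, nrow = length(s))
  lvl <- 1L + as.integer(rowSums(u < FF))
  x <- e$codes[lvl]
  if (isTRUE(e$invert)) x <- rev(e$codes)[lvl]
  x
}

#' Class-conditional feature profiles
#'
#' The probability tables implied by the generator's ordered-threshold
#' feature model, evaluated at each class's mid-band adiposity score.
#' Returned in long form for inspection; the generator itself varies
#' these probabilities continuously in the record's BMI.
#'
#' @return A tibble with columns `feature`, `class` (1-7), `code`, `prob`.
#' @export
class_profiles <- function() {
  purrr::imap_dfr(profile_ends(), function(e, feat) {
    purrr::map_dfr(1:7, function(cls) {
      s <- (cls - 0.5) / 7
      FF <- as.numeric(threshold_survival(e, s))
      p <- c(1, FF) - c(FF, 0)   # P(level j), j = 1..k
      codes <- e$codes
      if (isTRUE(e$invert)) p <- rev(p)
      if (feat == "MTRANS") {
        # activity 0 splits into automobile/motorbike
        p <- c(p[1] * 0.88, p[1] * 0.12, p[2], p[3])
        codes <- mtrans_levels()
      }
      tibble::tibble(feature = feat, class = cls, code = as.character(codes),
                     prob = p)
    })
  })
}

#' Synthetic-cohort generator configuration
#'
#' @param n_records Cohort size; 2111 (default, the small survey cohort)
#'   or e.g. 20758 (the large one).
#' @param seed Optional integer seed.
#' @param class_weights Seven class proportions summing to 1.
#' @param label_noise_rate Fraction of labels reassigned uniformly at
#'   random (0 = labels follow BMI exactly).
#' @param bmi_cap Upper BMI bound for the obesity type III class
#'   (default 50 kg/m^2); `bmi_floor` is the lower bound of the
#'   insufficient-weight class (default 14 kg/m^2).
#' @param bmi_floor See `bmi_cap`.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_records = 2111, seed = NULL,
                             class_weights = default_class_weights(),
                             label_noise_rate = 0, bmi_cap = 50,
                             bmi_floor = 14) {
  if (length(n_records) != 1 || n_records < 1) abort("`n_records` must be a positive count.")
  if (length(class_weights) != 7 || any(class_weights <= 0) ||
      abs(sum(class_weights) - 1) > 1e-8) {
    abort("`class_weights` must be 7 positive proportions summing to 1.")
  }
  if (label_noise_rate < 0 || label_noise_rate > 1) {
    abort("`label_noise_rate` must lie in [0, 1].")
  }
  structure(list(n_records = as.integer(n_records), seed = seed,
                 class_weights = class_weights,
                 label_noise_rate = label_noise_rate,
                 bmi_cap = bmi_cap, bmi_floor = bmi_floor),
            class = "generator_config")
}

#' Generate a synthetic obesity survey cohort
#'
#' Draws schema-conformant records with learnable class-conditional
#' structure: the class is sampled from `class_weights`; height is
#' gender-conditional Normal (male 1.75 m, female 1.62 m); BMI is
#' sampled uniformly inside the class's interval of the seven-class
#' table (insufficient weight floored at `bmi_floor`, obesity III capped
#' at `bmi_cap`); weight is set to `BMI * height^2`, so with zero label
#' noise the label is exactly recoverable from weight and height; the
#' ordinal and categorical features follow the [class_profiles()]
#' tables; age increases mildly with obesity level.
#'
#' @param config A [generator_config()]; or pass fields via `...`.
#' @param ... Shorthand: arguments forwarded to [generator_config()]
#'   when `config` is not supplied.
#' @return A validated schema tibble of `n_records` rows.
#' @examples
#' d <- generate_obesity_data(n_records = 200, seed = 1)
#' table(d$Obesity_level)
#' @export
generate_obesity_data <- function(config = NULL, ...) {
  if (is.null(config)) config <- generator_config(...)
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_records
  tbl <- bmi_class_table("seven")
  tbl$lower[1] <- config$bmi_floor
  tbl$upper[7] <- config$bmi_cap
  ends <- profile_ends()

  data <- with_seed_if(config$seed, {
    cls <- sample.int(7, n, replace = TRUE, prob = config$class_weights)
    gender <- stats::rbinom(n, 1, 0.5) # 0 male, 1 female
    height <- ifelse(gender == 0, rnorm(n, 1.75, 0.042), rnorm(n, 1.62, 0.038))
    height <- round(pmin(pmax(height, 1.45), 2.05), 3)
    # 0.05 kg/m^2 interior margin so rounding weight to 0.01 kg can never
    # push a record across a class boundary
    bmi <- runif(n, tbl$lower[cls] + 0.05, tbl$upper[cls] - 0.05)
    weight <- bmi * height^2
    # continuous adiposity score in [0, 1]: class index plus position
    # inside the class's BMI band
    s <- (cls - 1 + (bmi - tbl$lower[cls]) / (tbl$upper[cls] - tbl$lower[cls])) / 7
    age <- round(pmin(pmax(rnorm(n, 18 + 18 * s, 2.5), 14), 61))

    draw_int <- function(feat) as.integer(draw_ordered(ends[[feat]], s))

    # transport: activity level 0/1/2, passive level split into
    # automobile/motorbike
    mt_act <- draw_ordered(ends[["MTRANS"]], s)
    mtrans <- ifelse(mt_act == 2, "walking",
                     ifelse(mt_act == 1, "public_transportation",
                            ifelse(runif(n) < 0.12, "motorbike", "automobile")))

    label <- cls
    if (config$label_noise_rate > 0) {
      flip <- runif(n) < config$label_noise_rate
      label[flip] <- sample.int(7, sum(flip), replace = TRUE)
    }

    tibble::tibble(
      Gender = gender, Age = age, Height = height,
      Weight = round(weight, 2),
      family_history_with_overweight = draw_int("family_history_with_overweight"),
      FAVC = draw_int("FAVC"), FCVC = draw_int("FCVC"), NCP = draw_int("NCP"),
      CAEC = draw_int("CAEC"), SMOKE = draw_int("SMOKE"),
      CH2O = draw_int("CH2O"), SCC = draw_int("SCC"),
      FAF = draw_int("FAF"), TUE = draw_int("TUE"), CALC = draw_int("CALC"),
      MTRANS = mtrans, Obesity_level = label
    )
  })
  validate_obesity(data)
  data
}

#' Merge two cohorts sharing one schema
#'
#' Concatenates two schema-identical datasets and removes exact
#' duplicate records, emulating the integration of two survey waves.
#'
#' @param a,b Schema-conformant data frames with identical column sets.
#' @return A tibble with at most `nrow(a) + nrow(b)` rows.
#' @export
merge_datasets <- function(a, b) {
  a <- tibble::as_tibble(normalize_columns(a))
  b <- tibble::as_tibble(normalize_columns(b))
  if (!identical(sort(names(a)), sort(names(b)))) {
    diff <- union(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    abort(paste0("Schema mismatch; divergent columns: ", paste(diff, collapse = ", ")))
  }
  merged <- dplyr::bind_rows(a, b[names(a)])
  merged[!duplicated(merged), , drop = FALSE]
}
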