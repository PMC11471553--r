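#' Compute body mass index
#'
#' BMI is weight in kilograms divided by the square of height in meters.
#' It is the quantity that defines the obesity-level label used throughout
#' the package.
#'
#' @param weight Body weight in kg (positive numeric, vectorized).
#' @param height Standing height in m (positive numeric, vectorized).
#' @return Numeric vector of BMI values (kg/m^2).
#' @examples
#' compute_bmi(80, 2)    # 20
#' compute_bmi(65, 1.70) # 22.49...
#' @export
compute_bmi <- function(weight, height) {
  if (!is.numeric(weight) || !is.numeric(height)) {
    abort("`weight` and `height` must be numeric.")
  }
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    abort("`weight` and `height` must be finite and strictly positive.")
  }
  weight / height^2
}

#' BMI class tables
#'
#' Ordered, contiguous, half-open BMI intervals `[lower, upper)` covering
#' all positive reals. The default `"seven"` mode matches the seven survey
#' labels (the WHO overweight band 25--29.9 is split into Level I and
#' Level II at 27.5 kg/m^2); `"who"` gives the strict six-row WHO table.
#' Printed WHO ranges look closed ("18.5--24.9"); half-open intervals are
#' used so that every BMI (e.g. 24.95) classifies to exactly one class.
#'
#' @param mode `"seven"` (default) or `"who"`.
#' @return A tibble with columns `class`, `code`, `lower`, `upper`.
#' @examples
#' bmi_class_table()
#' bmi_class_table("who")
#' @export
bmi_class_table <- function(mode = c("seven", "who")) {
  mode <- match.arg(mode)
  if (mode == "seven") {
    tibble::tibble(
      class = c("Insufficient_Weight", "Normal_Weight",
                "Overweight_Level_I", "Overweight_Level_II",
                "Obesity_Type_I", "Obesity_Type_II", "Obesity_Type_III"),
      code  = 1:7,
      lower = c(0, 18.5, 25, 27.5, 30, 35, 40),
      upper = c(18.5, 25, 27.5, 30, 35, 40, Inf)
    )
  } else {
    tibble::tibble(
      class = c("Underweight", "Normal", "Overweight",
                "Obesity_I", "Obesity_II", "Obesity_III"),
      code  = 1:6,
      lower = c(0, 18.5, 25, 30, 35, 40),
      upper = c(18.5, 25, 30, 35, 40, Inf)
    )
  }
}

#' Classify BMI values into obesity classes
#'
#' Total on positive reals: every BMI falls in exactly one half-open
#' interval `[lower, upper)` of the class table.
#'
#' @param bmi Positive numeric vector of BMI values (kg/m^2).
#' @param table A class table from [bmi_class_table()] (or any tibble with
#'   `class`, `code`, `lower`, `upper` forming a contiguous partition).
#' @param as `"class"` (default) returns a factor of class names ordered by
#'   severity; `"code"` returns the integer class code.
#' @return Factor of class names, or integer codes.
#' @examples
#' classify_bmi(c(17, 22, 41))
#' classify_bmi(18.5)  # boundary is inclusive on the left
#' @export
classify_bmi <- function(bmi, table = bmi_class_table(), as = c("class", "code")) {
  as <- match.arg(as)
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be finite and strictly positive.")
  }
  idx <- findInterval(bmi, table$lower)
  if (as == "code") table$code[idx] else factor(table$class[idx], levels = table$class)
}
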