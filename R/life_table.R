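# Background (all-cause) mortality. The model needs an age-indexed annual
# death probability for the Thai general population; when no national life
# table CSV is supplied, a Gompertz stand-in generates one. The stand-in is
# synthetic: a smooth adult-mortality curve of plausible shape, not any
# official Thai table; a real table CSV can be supplied to override it.

#' Generate a synthetic life table from a Gompertz hazard
#'
#' Annual death probability at integer age x is
#' `q(x) = min(cap, 1 - exp(-a * exp(b * x)))`, i.e. a Gompertz annual
#' hazard `a * exp(b * x)` converted to a probability. Defaults give
#' q(60) ~ 0.0050 and q(80) ~ 0.031, keeping background mortality a
#' secondary influence on lifetime outcomes next to the disease pathway.
#'
#' @param a Baseline annual hazard at age 0 (> 0).
#' @param b Log-hazard slope per year of age (> 0).
#' @param cap Maximal annual probability (default 1).
#' @param max_age Last tabulated age (default 110).
#' @return Object of class `life_table`: data frame with columns `age`
#'   (0..max_age) and `qx` (annual death probability).
#' @export
make_life_table <- function(a = 2.0e-5, b = 0.092, cap = 1.0, max_age = 110) {
  if (a <= 0 || b <= 0) stop("make_life_table(): a and b must be > 0")
  if (cap <= 0 || cap > 1) stop("make_life_table(): cap must be in (0, 1]")
  age <- 0:max_age
  qx <- pmin(cap, 1 - exp(-a * exp(b * age)))
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expects columns `age` (integer years) and `qx` (annual death
#' probability); a real national life table supplied this way overrides the
#' synthetic Gompertz stand-in.
#'
#' @param path CSV path.
#' @return A `life_table`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table CSV must have columns 'age' and 'qx': ", path)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]")
  lt <- lt[order(lt$age), c("age", "qx")]
  structure(lt, class = c("life_table", "data.frame"))
}

#' Write a life table as CSV
#'
#' @param life_table A `life_table`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table)[, c("age", "qx")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Monthly background death probability at a given age
#'
#' Converts the annual probability for the completed age to a monthly one
#' under a constant within-year hazard: `1 - (1 - qx)^(1/12)`. Ages beyond
#' the table use the last tabulated value.
#'
#' @param life_table A `life_table`.
#' @param age Age in years (fractional allowed; floored for lookup).
#' @return Monthly death probability (vectorised over `age`).
#' @export
monthly_background_prob <- function(life_table, age) {
  a <- pmin(floor(age), max(life_table$age))
  idx <- match(a, life_table$age)
  if (anyNA(idx)) stop("age(s) not covered by life table: ",
                       paste(unique(a[is.na(idx)]), collapse = ", "))
  1 - (1 - life_table$qx[idx])^(1 / 12)
}
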