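#' Life-stage definitions for the mountain goat demographic model
#'
#' The model tracks two sexes over 20 annual age classes (ages 0--19) and
#' groups ages into the life stages over which annual survival is treated as
#' constant: neonate (age 0), yearling (1), subadult (2), young adult (3--5,
#' pooled across sexes), prime-age adult (6--8, split by sex) and old (9--19,
#' split by sex). The age boundaries follow the sex- and age-structure used in
#' long-term survival analyses for coastal Alaska mountain goats; they are a
#' documented default and can be overridden by supplying a custom table with
#' the same columns.
#'
#' @return A data.frame with columns `stage`, `sex` (`"female"`, `"male"` or
#'   `"both"`), `min_age` and `max_age` (closed integer interval, years).
#' @examples
#' life_stages()
#' @export
life_stages <- function() {
  data.frame(
    stage = c("neonate", "yearling", "subadult", "young_adult",
              "adult_female", "adult_male", "old_female", "old_male"),
    sex = c("both", "both", "both", "both",
            "female", "male", "female", "male"),
    min_age = c(0L, 1L, 2L, 3L, 6L, 6L, 9L, 9L),
    max_age = c(0L, 1L, 2L, 5L, 8L, 8L, 19L, 19L),
    stringsAsFactors = FALSE
  )
}

#' Stage names in the survival model
#'
#' @param monitored If `TRUE` (default) return only the seven stages that
#'   appear in known-fate monitoring data (radio-collared animals are at least
#'   yearlings); if `FALSE` include the neonate stage.
#' @return Character vector of stage names; `"old_male"` last (it is the
#'   reference category of the survival model).
#' @export
stage_names <- function(monitored = TRUE) {
  nm <- c("yearling", "subadult", "young_adult",
          "adult_female", "adult_male", "old_female", "old_male")
  if (monitored) nm else c("neonate", nm)
}

#' Map a sex and age to its life stage
#'
#' @param sex `"female"` or `"male"` (vectorised).
#' @param age Integer age in years, 0--19 (vectorised).
#' @param stages Stage table as returned by [life_stages()].
#' @return Character vector of stage names.
#' @examples
#' stage_of(c("female", "male"), c(7, 12))
#' @export
stage_of <- function(sex, age, stages = life_stages()) {
  stopifnot(all(sex %in% c("female", "male")), all(age >= 0), all(age <= 19))
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  out <- character(n)
  for (i in seq_len(n)) {
    hit <- stages$min_age <= age[i] & stages$max_age >= age[i] &
      (stages$sex == "both" | stages$sex == sex[i])
    if (sum(hit) != 1L) {
      stop("age ", age[i], " (", sex[i], ") does not map to exactly one stage")
    }
    out[i] <- stages$stage[hit]
  }
  out
}
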