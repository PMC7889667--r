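#' Clavien-Dindo grade levels
#'
#' The seven admissible Clavien-Dindo grades in increasing order of
#' severity: I < II < IIIa < IIIb < IVa < IVb < V. Grade V denotes death.
#'
#' @return Character vector of the seven grade labels, from least to most
#'   severe.
#' @export
#' @examples
#' cd_grade_levels()
cd_grade_levels <- function() {
  c("I", "II", "IIIa", "IIIb", "IVa", "IVb", "V")
}

#' Coerce to a Clavien-Dindo grade factor
#'
#' Validates grade labels and returns an ordered factor over the seven
#' Clavien-Dindo grades so that comparisons like `max()` respect the
#' clinical ordering.
#'
#' @param x Character vector (or factor) of grade labels among
#'   `"I", "II", "IIIa", "IIIb", "IVa", "IVb", "V"`.
#' @return An ordered factor with levels `cd_grade_levels()`.
#' @export
#' @examples
#' cd_grade(c("II", "IIIb", "V"))
cd_grade <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% cd_grade_levels())
  if (any(bad)) {
    stop("unknown Clavien-Dindo grade(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; admissible grades are ", paste(cd_grade_levels(), collapse = ", "))
  }
  factor(x, levels = cd_grade_levels(), ordered = TRUE)
}

#' Grade weight table for the comprehensive complication index
#'
#' The CCI sums a weight wC per graded complication and reports
#' sqrt(sum wC)/2. This table carries, per grade, the weight inside the
#' square root and the printed single-event index value it reproduces at
#' one-decimal rounding (8.7, 20.9, 26.2, 33.7, 42.4, 46.2; grade V is
#' reported as 100 exactly by the death override).
#'
#' The default weights are the canonical set {300, 1750, 2750, 4550, 7200,
#' 8550, 39940}. An alternative inversion of the printed values,
#' wC = (2 * printed)^2, can be requested instead; both reproduce the
#' printed per-grade values at one decimal.
#'
#' @param weights Optional named numeric vector of per-grade weights
#'   (names must be exactly the seven grades); overrides `source`.
#' @param source `"canonical"` (default) or `"inverted"` for
#'   wC = (2 * printed single-event value)^2.
#' @return Object of class `"cci_weights"`: a data frame with columns
#'   `grade`, `weight` and `single_event` (the one-decimal single-event
#'   index value).
#' @export
#' @examples
#' cci_weights()
cci_weights <- function(weights = NULL, source = c("canonical", "inverted")) {
  source <- match.arg(source)
  single <- c(I = 8.7, II = 20.9, IIIa = 26.2, IIIb = 33.7,
              IVa = 42.4, IVb = 46.2, V = 100)
  if (is.null(weights)) {
    weights <- switch(source,
      canonical = c(I = 300, II = 1750, IIIa = 2750, IIIb = 4550,
                    IVa = 7200, IVb = 8550, V = 39940),
      inverted = (2 * single)^2
    )
  }
  if (!is.numeric(weights) || is.null(names(weights)) ||
      !identical(sort(names(weights)), sort(cd_grade_levels()))) {
    stop("'weights' must be a numeric vector named by the seven grades")
  }
  weights <- weights[cd_grade_levels()]
  if (any(diff(weights) <= 0)) {
    stop("grade weights must strictly increase with grade")
  }
  out <- data.frame(grade = cd_grade_levels(), weight = unname(weights),
                    single_event = unname(single),
                    stringsAsFactors = FALSE)
  class(out) <- c("cci_weights", "data.frame")
  out
}

#' Translate a clinical event into Clavien-Dindo grades
#'
#' Applies the liver-transplant specific grading conventions: early
#' allograft dysfunction (EAD) counts as grade II; primary non-function
#' (PNF) and renal replacement therapy (RRT) as grade IVa; multiorgan
#' failure (MOF) as grade IVb; retransplantation during the first
#' hospitalization as the composite IVa (liver failure) + IIIb
#' (reoperation); mild renal dysfunction (creatinine above 1.5 mg/dL
#' without RRT) and myelotoxicity as grade I; death as grade V.
#'
#' @param event_kind Character scalar among `"EAD"`, `"PNF"`, `"MOF"`,
#'   `"retransplantation"`, `"mild_renal_dysfunction"`, `"RRT"`,
#'   `"myelotoxicity"`, `"death"`.
#' @return Ordered factor of one or two Clavien-Dindo grades to append to
#'   the patient's course.
#' @export
#' @examples
#' grade_clinical_event("retransplantation")  # IVa + IIIb
#' grade_clinical_event("EAD")                # II
grade_clinical_event <- function(event_kind) {
  map <- list(
    EAD = "II",
    PNF = "IVa",
    MOF = "IVb",
    retransplantation = c("IVa", "IIIb"),
    mild_renal_dysfunction = "I",
    RRT = "IVa",
    myelotoxicity = "I",
    death = "V"
  )
  if (length(event_kind) != 1L || !event_kind %in% names(map)) {
    stop("unknown clinical event kind: ",
         paste(event_kind, collapse = ", "),
         "; known kinds are ", paste(names(map), collapse = ", "))
  }
  cd_grade(map[[event_kind]])
}

#' Highest Clavien-Dindo grade of a course
#'
#' Summarises a patient's course by the most severe grade, the convention
#' used for complication-frequency tables.
#'
#' @param grades Character vector or `cd_grade` factor of the course's
#'   grades; may be empty.
#' @return Ordered-factor scalar with the maximum grade, or `NA` (with
#'   level set) when the course has no complications.
#' @export
#' @examples
#' highest_grade(c("I", "IIIb", "II"))  # IIIb
#' highest_grade(character(0))          # NA: no complication
highest_grade <- function(grades) {
  g <- cd_grade(grades)
  g <- g[!is.na(g)]
  if (length(g) == 0L) {
    return(factor(NA_character_, levels = cd_grade_levels(), ordered = TRUE))
  }
  max(g)
}
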