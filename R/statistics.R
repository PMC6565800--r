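## Cohort statistics: assumption-routed two-group comparisons.  Gender
## contrasts always use the Mann-Whitney test; age contrasts use the pooled
## two-tailed unpaired t-test when both samples pass normality and the
## variance-ratio test, and Mann-Whitney otherwise.  Significance means
## p <= 0.05 (p > 0.05 is read as nonsignificant).

#' Body mass index
#'
#' @param weight body weight, kg, \code{> 0}.
#' @param height body height, m, \code{> 0}.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0))
    stop("weight and height must be finite and positive")
  weight / height^2
}

#' Shapiro-Wilk normality screen
#'
#' Omnibus normality test used to route group comparisons.  A constant
#' sample is not testable and is flagged as such (and treated as non-normal
#' by the routing logic, so such data go to the nonparametric branch).
#'
#' @param x numeric sample, \code{n >= 3}.
#' @param alpha routing level (default 0.05); \code{isNormal} is
#'   \code{p > alpha}.
#' @return list with \code{statistic}, \code{pValue}, \code{isNormal},
#'   \code{testable}.
#' @export
testNormality <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0)
    return(list(statistic = NA_real_, pValue = NA_real_,
                isNormal = FALSE, testable = FALSE))
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), pValue = sw$p.value,
       isNormal = sw$p.value > alpha, testable = TRUE)
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic is reported for the first sample.  The p-value is exact
#' (equal to brute-force enumeration over all rank assignments) for tie-free
#' samples with \code{length(a) + length(b) <= 16}; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param a,b numeric samples, non-empty.
#' @return list with \code{u}, \code{pValue}, \code{method}
#'   (\code{"exact"} or \code{"normal_approximation"}).
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 16L
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(u = unname(wt$statistic), pValue = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Two-tailed unpaired t-test
#'
#' Classical pooled-variance form by default (\code{welch = TRUE} switches
#' to the Welch unequal-variance form).  Degenerate zero-variance input is
#' resolved by limits: equal means give \code{p = 1}, unequal means
#' \code{p = 0}, both flagged.
#'
#' @param a,b numeric samples, \code{n >= 2} each.
#' @param welch use Welch's unequal-variance t-test instead of pooled.
#' @return list with \code{t}, \code{df}, \code{pValue}, \code{degenerate}.
#' @examples
#' tTestUnpaired(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0214
#' @export
tTestUnpaired <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 per group")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L,
                pValue = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value, degenerate = FALSE)
}

#' Assumption-routed two-group comparison
#'
#' Gender context always routes to Mann-Whitney (a few of the underlying
#' reference data sets were non-normal, so the nonparametric test is used
#' throughout for gender).  Age context routes to the pooled t-test when
#' both samples pass the Shapiro-Wilk screen and the variance-ratio F-test
#' at the same level, otherwise to Mann-Whitney.  The percent change is
#' computed on sample means with group a as the baseline (group means are
#' used even when the routed test is nonparametric, matching how the printed
#' percentages relate to the printed means).
#'
#' @param a,b numeric samples; group a is the baseline.
#' @param context \code{"gender"} or \code{"age"}.
#' @param labels length-2 character, names of groups a and b.
#' @param muscle,parameter identifiers carried through to the result row.
#' @param alpha significance level (default 0.05); significant means
#'   \code{p <= alpha}.
#' @param welch use the Welch t-test on the parametric branch.
#' @return one-row data.frame (a ComparisonResult): group labels and sizes,
#'   \code{test_used}, \code{statistic}, \code{p_value},
#'   \code{percent_change} (signed integer), \code{significant}.
#' @export
compareGroups <- function(a, b, context = c("gender", "age"),
                          labels = c("a", "b"), muscle = NA_character_,
                          parameter = NA_character_, alpha = 0.05,
                          welch = FALSE) {
  context <- match.arg(context)
  if (context == "gender") {
    useT <- FALSE
  } else {
    ## samples too small for the normality screen go nonparametric
    screen <- function(x) if (length(x) >= 3L) testNormality(x, alpha)
                          else list(isNormal = FALSE, testable = FALSE)
    na <- screen(a)
    nb <- screen(b)
    equalVar <- if (na$testable && nb$testable) {
      var.test(a, b)$p.value > alpha
    } else FALSE
    useT <- na$isNormal && nb$isNormal && equalVar
  }
  if (useT) {
    res <- tTestUnpaired(a, b, welch = welch)
    testUsed <- "t_test"
    statistic <- res$t
  } else {
    res <- mannWhitney(a, b)
    testUsed <- "mann_whitney"
    statistic <- res$u
  }
  p <- res$pValue
  data.frame(
    parameter = parameter, muscle = muscle, context = context,
    group_a = labels[1], group_b = labels[2],
    n_a = length(a), n_b = length(b),
    test_used = testUsed, statistic = statistic, p_value = p,
    percent_change = percentChange(mean(a), mean(b)),
    significant = p <= alpha, stringsAsFactors = FALSE)
}

#' Age contrast on pooled decades
#'
#' Compares the two youngest decades (20s + 30s, pooled) against the two
#' oldest (50s + 60s, pooled) within one gender for one muscle and
#' parameter; the middle decade (40s) is excluded by design.  Both
#' gastrocnemius sides contribute as recordings (20 per pooled group at the
#' reference design size of 5 subjects per gender and decade); unilateral
#' muscles contribute 10 per group.
#'
#' @param cohort a \code{\linkS4class{BiaCohort}}.
#' @param muscle,parameter,gender canonical identifiers.
#' @param ... passed on to \code{\link{compareGroups}}.
#' @return one-row data.frame, see \code{\link{compareGroups}}; baseline
#'   (group a) is the young pool.
#' @export
ageContrast <- function(cohort, muscle, parameter, gender, ...) {
  muscle <- match.arg(muscle, .BIA_MUSCLES)
  parameter <- match.arg(parameter, .BIA_PARAMETERS)
  gender <- match.arg(gender, .BIA_GENDERS)
  young <- .cohortValues(cohort, muscle, parameter, gender,
                         decades = c("20s", "30s"))
  old <- .cohortValues(cohort, muscle, parameter, gender,
                       decades = c("50s", "60s"))
  for (dec in c("20s", "30s", "50s", "60s")) {
    if (!any(colData(cohort)$age_decade == dec & colData(cohort)$gender == gender))
      stop(sprintf("incomplete design: no %s subjects in decade %s", gender, dec))
  }
  compareGroups(young, old, context = "age",
                labels = c("20s+30s", "50s+60s"),
                muscle = muscle, parameter = parameter, ...)
}

#' Gender contrast across the whole cohort
#'
#' Men (baseline) versus women for one muscle and parameter, always via
#' Mann-Whitney.  Bilateral gastrocnemius recordings are averaged within
#' subject first so that each subject contributes one value per muscle,
#' matching the n = 25 per gender of the normative table.
#'
#' @inheritParams ageContrast
#' @return one-row data.frame, see \code{\link{compareGroups}}.
#' @export
genderContrast <- function(cohort, muscle, parameter, ...) {
  muscle <- match.arg(muscle, .BIA_MUSCLES)
  parameter <- match.arg(parameter, .BIA_PARAMETERS)
  men <- .cohortValues(cohort, muscle, parameter, "men", averageSides = TRUE)
  women <- .cohortValues(cohort, muscle, parameter, "women", averageSides = TRUE)
  compareGroups(men, women, context = "gender", labels = c("men", "women"),
                muscle = muscle, parameter = parameter, ...)
}

## extract a value vector (one element per recording, or per subject when
## averageSides) from the cohort assay
.cohortValues <- function(cohort, muscle, parameter, gender,
                          decades = NULL, averageSides = FALSE) {
  cd <- colData(cohort)
  keep <- cd$muscle == muscle & cd$gender == gender
  if (!is.null(decades)) keep <- keep & cd$age_decade %in% decades
  if (!any(keep)) stop(sprintf("no recordings for (%s, %s)", muscle, gender))
  vals <- assay(cohort)[parameter, keep]
  if (averageSides) {
    vals <- tapply(vals, cd$subject_id[keep], mean)
    vals <- as.numeric(vals)
  }
  unname(vals)
}
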