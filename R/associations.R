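#' Cross-tabulate ICD-10 diagnostic chapters by patient profile
#'
#' Counts patients per diagnosis chapter and profile. A patient carrying
#' several chapters contributes one count to *each* of their chapters
#' (multi-row counting, the convention under which comorbid diagnoses
#' are "examined when present"), so row totals can exceed the number of
#' diagnosed patients; this is flagged in the result. Row percentages
#' give, for each chapter, the share of its patients in each profile,
#' rounded to one decimal.
#'
#' @param cohort a diagnosis-filtered [QuestionnaireCohort] (see
#'   [completenessFilter()]).
#' @param assignment a [ProfileAssignment] aligned with the cohort's
#'   patients (matched by patient id when both are named).
#' @return a list of class `CrosstabResult` with `counts` (chapters x
#'   profiles integer matrix), `rowPercentages` (same shape, one
#'   decimal), `rowTotals` and `multiCounting = TRUE`.
#' @export
crosstabDiagnosisByProfile <- function(cohort, assignment) {
    lab <- alignLabels(cohort, assignment)
    dx <- SummarizedExperiment::colData(cohort)$diagnoses
    if (ncol(cohort) == 0L) stop("empty cohort")
    profiles <- names(assignment@counts)
    chapters <- sort(unique(unlist(dx)))
    if (length(chapters) == 0L) stop("no diagnoses present in cohort")
    counts <- matrix(0L, length(chapters), length(profiles),
                     dimnames = list(chapters, profiles))
    for (i in seq_along(dx)) {
        p <- as.character(lab[i])
        for (ch in dx[[i]])
            counts[ch, p] <- counts[ch, p] + 1L
    }
    rowTot <- rowSums(counts)
    pct <- round(100 * counts / rowTot, 1)
    structure(list(counts = counts, rowPercentages = pct,
                   rowTotals = rowTot, multiCounting = TRUE),
              class = "CrosstabResult")
}

#' Summarize CGI severity scores per profile
#'
#' For each profile with at least one CGI-rated patient: the number of
#' patients, mean and SD of the Clinical Global Impression score
#' (rounded to two decimals), and the score distribution over 0--7 with
#' counts and within-profile percentages (one decimal). Profiles with no
#' patients in the CGI-filtered cohort are omitted with a message.
#'
#' @inheritParams crosstabDiagnosisByProfile
#' @param cohort a CGI-filtered [QuestionnaireCohort].
#' @return a list of class `CgiSummary`: per profile, a list with `n`,
#'   `mean`, `sd`, and `distribution` (data.frame `score`, `n`,
#'   `percent`).
#' @export
cgiByProfile <- function(cohort, assignment) {
    lab <- alignLabels(cohort, assignment)
    cgi <- SummarizedExperiment::colData(cohort)$cgi
    keep <- !is.na(cgi)
    cgi <- cgi[keep]; lab <- lab[keep]
    out <- list()
    for (p in names(assignment@counts)) {
        v <- cgi[as.character(lab) == p]
        if (length(v) == 0L) {
            message("profile ", p,
                    ": no CGI-rated patients; omitted from summary")
            next
        }
        tab <- table(factor(v, levels = 0:7))
        out[[p]] <- list(
            n = length(v),
            mean = round(mean(v), 2),
            sd = if (length(v) > 1L) round(sd(v), 2) else NA_real_,
            distribution = data.frame(
                score = 0:7,
                n = as.integer(tab),
                percent = round(100 * as.integer(tab) / length(v), 1)
            )
        )
    }
    structure(out, class = "CgiSummary")
}

#' Test homogeneity of age or sex across profiles
#'
#' Age is compared across profiles with a one-way ANOVA F test
#' (`k - 1`, `n - k` degrees of freedom); sex with a Pearson chi-square
#' test (no continuity correction) on the sex x profile contingency
#' table. Patients with a missing value of the tested variable are
#' excluded. These are the two checks used to verify that profiles are
#' comparable on basic demographics.
#'
#' @inheritParams crosstabDiagnosisByProfile
#' @param variable `"age"` or `"sex"`.
#' @return a list of class `HomogeneityTest`: `test` (`"one-way-F"` or
#'   `"chi-square"`), `statistic`, `df`, `pValue`.
#' @export
testProfileHomogeneity <- function(cohort, assignment,
                                   variable = c("age", "sex")) {
    variable <- match.arg(variable)
    lab <- alignLabels(cohort, assignment)
    cd <- SummarizedExperiment::colData(cohort)
    grp <- factor(lab)
    if (nlevels(grp) < 2L)
        stop("at least 2 profiles are required")
    if (variable == "age") {
        v <- cd$age
        keep <- !is.na(v)
        v <- v[keep]; g <- droplevels(grp[keep])
        if (any(table(g) < 2L))
            stop("every profile needs >= 2 age observations for ANOVA")
        tab <- anova(aov(v ~ g))
        structure(list(test = "one-way-F",
                       statistic = unname(tab[["F value"]][1]),
                       df = unname(tab[["Df"]]),
                       pValue = unname(tab[["Pr(>F)"]][1])),
                  class = "HomogeneityTest")
    } else {
        v <- cd$sex
        keep <- !is.na(v)
        v <- factor(v[keep], levels = c("female", "male"))
        g <- droplevels(grp[keep])
        ct <- table(v, g)
        ht <- suppressWarnings(chisq.test(ct, correct = FALSE))
        structure(list(test = "chi-square",
                       statistic = unname(ht$statistic),
                       df = unname(ht$parameter),
                       pValue = unname(ht$p.value)),
                  class = "HomogeneityTest")
    }
}

# Align a ProfileAssignment's labels with a (possibly filtered) cohort.
alignLabels <- function(cohort, assignment) {
    stopifnot(methods::is(cohort, "QuestionnaireCohort"),
              methods::is(assignment, "ProfileAssignment"))
    lab <- assignment@labels
    ids <- colnames(cohort)
    if (!is.null(ids) && !is.null(names(lab))) {
        if (!all(ids %in% names(lab)))
            stop("cohort contains patients without a profile assignment")
        return(lab[ids])
    }
    if (length(lab) != ncol(cohort))
        stop("assignment length does not match the cohort; ",
             "use named patient ids or an unfiltered cohort")
    lab
}
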