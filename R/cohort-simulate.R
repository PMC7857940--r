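#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set of [generateCohort()]. The
#' defaults reproduce the structure of the study population the pipeline
#' was designed for: 23 items on a 0--100 scale, two planted latent
#' factor sets (the positive-valence block, items 1--15, and the
#' negative-valence block, items 16--23) with prevalences 0.21 and 0.27,
#' an always-active bias set on aggressiveness, suicidal thoughts and
#' worthlessness (items 16, 17, 23), a 12% cell-level missing rate, and
#' clinical marginals (sex, age, CGI, ICD-10 diagnosis mixture) matching
#' a large psychiatric outpatient sample.
#'
#' @param nPatients number of patients (>= 1; fewer than 100 triggers a
#'   warning because downstream inference is unstable).
#' @param nItems number of questionnaire items (default 23).
#' @param factorPrevalence numeric vector of activation probabilities,
#'   one per planted factor set.
#' @param factorItemSets list of integer vectors: the items each factor
#'   set drives into the high-score regime.
#' @param biasItemSet integer vector of items on which every patient,
#'   active or not, can draw the high-score regime (see `biasRate`).
#' @param biasRate probability that a patient *without* a factor covering
#'   a bias item still draws the high-score regime on it. This is what
#'   makes the bias term identifiable: extreme answers on the bias items
#'   are spread over the whole cohort instead of concentrating in the
#'   factor-active minority.
#' @param missingRate probability that any single score cell is missing
#'   (missing completely at random).
#' @param diagnosisMixture named probability vector over ICD-10 chapters
#'   `F0`..`F9`; must sum to 1.
#' @param comorbidityRate probability that a diagnosed patient carries a
#'   second, distinct chapter.
#' @param diagnosisMissingRate probability that a patient has no recorded
#'   diagnosis at all.
#' @param cgiDistribution named probability vector over CGI scores
#'   `0`..`7`; must sum to 1.
#' @param cgiMissingRate probability that CGI is missing.
#' @param sexProbs named probability vector over
#'   `c(female, male, missing)`.
#' @param ageMean,ageSd mean and SD of the (truncated, 18--95) normal age
#'   distribution.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A validated list of class `CohortConfig`.
#' @examples
#' cfg <- cohortConfig(nPatients = 200, seed = 1)
#' cohort <- generateCohort(cfg)
#' cohort
#' @export
cohortConfig <- function(nPatients,
                         nItems = 23L,
                         factorPrevalence = c(0.21, 0.27),
                         factorItemSets = list(1:15, 16:23),
                         biasItemSet = c(16L, 17L, 23L),
                         biasRate = 0.25,
                         missingRate = 0.12,
                         diagnosisMixture = c(F0 = 14, F1 = 57, F2 = 90,
                                              F3 = 433, F4 = 1199,
                                              F5 = 106, F6 = 222, F7 = 9,
                                              F8 = 5, F9 = 38) / 2173,
                         comorbidityRate = 0.15,
                         diagnosisMissingRate = 467 / 2254,
                         cgiDistribution = c(`0` = 0.100, `1` = 0.060,
                                             `2` = 0.047, `3` = 0.422,
                                             `4` = 0.316, `5` = 0.050,
                                             `6` = 0.0025, `7` = 0.0025),
                         cgiMissingRate = 254 / 2254,
                         sexProbs = c(female = 1184, male = 795,
                                      missing = 275) / 2254,
                         ageMean = 52.0, ageSd = 15.1,
                         seed = 1L) {
    nPatients <- as.integer(nPatients)
    if (is.na(nPatients) || nPatients < 1L)
        stop("nPatients must be at least 1")
    if (nPatients < 100L)
        message("nPatients < 100: latent-factor inference on so small ",
                "a cohort is unstable")
    nItems <- as.integer(nItems)
    if (length(factorPrevalence) != length(factorItemSets))
        stop("one prevalence per factor item set is required")
    probs <- c(factorPrevalence, biasRate, missingRate, comorbidityRate,
               diagnosisMissingRate, cgiMissingRate)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]")
    checkSimplex <- function(p, what, names_) {
        if (!setequal(names(p), names_))
            stop(what, " must be named over ",
                 paste(names_, collapse = ", "))
        if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
            stop(what, " must be a probability vector summing to 1")
        p[names_]
    }
    diagnosisMixture <- checkSimplex(diagnosisMixture, "diagnosisMixture",
                                     ICD10_CHAPTERS)
    cgiDistribution <- checkSimplex(cgiDistribution, "cgiDistribution",
                                    as.character(0:7))
    sexProbs <- checkSimplex(sexProbs, "sexProbs",
                             c("female", "male", "missing"))
    items <- unlist(c(factorItemSets, list(biasItemSet)))
    if (length(items) && (any(items < 1L) || any(items > nItems)))
        stop("factor/bias item sets must index items in 1..", nItems)
    structure(list(
        nPatients = nPatients, nItems = nItems,
        factorPrevalence = factorPrevalence,
        factorItemSets = lapply(factorItemSets, as.integer),
        biasItemSet = as.integer(biasItemSet), biasRate = biasRate,
        missingRate = missingRate, diagnosisMixture = diagnosisMixture,
        comorbidityRate = comorbidityRate,
        diagnosisMissingRate = diagnosisMissingRate,
        cgiDistribution = cgiDistribution,
        cgiMissingRate = cgiMissingRate, sexProbs = sexProbs,
        ageMean = ageMean, ageSd = ageSd, seed = as.integer(seed)
    ), class = "CohortConfig")
}

#' Generate a synthetic cohort with planted latent structure
#'
#' Draws a seeded cohort whose statistical structure matches what the
#' downstream pipeline assumes. Each patient activates each factor set
#' independently with its prevalence. Item scores are expressed on a
#' latent "distress" scale: baseline distress is `Beta(2, 5) * 100`
#' (most answers moderate), while items driven by an active factor draw
#' `Beta(8, 1.2) * 100` (a high-score regime whose draws dominate the
#' upper tail). Bias-set items additionally draw the high regime with
#' probability `biasRate` for every patient, so extreme answers on them
#' appear throughout the cohort. Positive-valence items (1--15) are then
#' stored as `100 - distress`, mirroring how the raw questionnaire asks
#' them; [invertPositiveItems()] undoes this during preprocessing.
#' Score cells are blanked completely at random at `missingRate`.
#' Clinical records (sex, age, CGI, ICD-10 chapters with optional
#' comorbidity) are drawn from the configured marginals, independent of
#' the latent factors.
#'
#' @param config a [cohortConfig()].
#' @return A [QuestionnaireCohort] whose `colData` includes the planted
#'   `trueActivation` matrix (patients x factors).
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    set.seed(config$seed)
    n <- config$nPatients
    d <- config$nItems
    kTrue <- length(config$factorPrevalence)

    zTrue <- matrix(0L, n, kTrue,
                    dimnames = list(NULL, paste0("factor", seq_len(kTrue))))
    for (k in seq_len(kTrue))
        zTrue[, k] <- rbinom(n, 1L, config$factorPrevalence[k])

    # distress scale: high regime on items covered by an active factor
    distress <- matrix(rbeta(n * d, 2, 5) * 100, n, d)
    high <- matrix(FALSE, n, d)
    for (k in seq_len(kTrue))
        high[zTrue[, k] == 1L, config$factorItemSets[[k]]] <- TRUE
    for (j in config$biasItemSet) {
        extra <- runif(n) < config$biasRate
        high[, j] <- high[, j] | extra
    }
    nh <- sum(high)
    if (nh > 0)
        distress[high] <- rbeta(nh, 8, 1.2) * 100

    scores <- distress
    scores[, 1:min(15L, d)] <- 100 - scores[, 1:min(15L, d)]
    if (config$missingRate > 0)
        scores[matrix(runif(n * d) < config$missingRate, n, d)] <- NA_real_

    sexDraw <- sample(names(config$sexProbs), n, replace = TRUE,
                      prob = config$sexProbs)
    sex <- ifelse(sexDraw == "missing", NA_character_, sexDraw)
    age <- round(pmin(pmax(rnorm(n, config$ageMean, config$ageSd), 18), 95))
    cgi <- sample(0:7, n, replace = TRUE, prob = config$cgiDistribution)
    cgi[runif(n) < config$cgiMissingRate] <- NA_integer_

    dx <- vector("list", n)
    hasDx <- runif(n) >= config$diagnosisMissingRate
    primary <- sample(ICD10_CHAPTERS, n, replace = TRUE,
                      prob = config$diagnosisMixture)
    second <- runif(n) < config$comorbidityRate
    for (i in seq_len(n)) {
        if (!hasDx[i]) { dx[[i]] <- character(0); next }
        di <- primary[i]
        if (second[i]) {
            others <- setdiff(ICD10_CHAPTERS, di)
            di <- c(di, sample(others, 1L,
                               prob = config$diagnosisMixture[others]))
        }
        dx[[i]] <- di
    }

    ids <- sprintf("P%05d", seq_len(n))
    catalog <- if (d == 23L) itemCatalog() else
        S4Vectors::DataFrame(item = seq_len(d),
                             label = sprintf("q%02d", seq_len(d)),
                             valence = ifelse(seq_len(d) <= 15L,
                                              "positive", "negative"),
                             instrument = NA_character_)
    rownames(zTrue) <- ids
    cd <- S4Vectors::DataFrame(
        sex = sex, age = as.numeric(age), cgi = as.integer(cgi),
        diagnoses = IRanges::CharacterList(setNames(dx, ids)),
        trueActivation = I(zTrue), row.names = ids
    )
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(scores = t(`dimnames<-`(scores,
                                              list(ids, catalog$label)))),
        rowData = catalog, colData = cd,
        metadata = list(config = config)
    )
    methods::new("QuestionnaireCohort", se)
}

#' @describeIn generateCohort Patients x items score matrix (transposed
#'   assay, the orientation the model works in).
#' @param cohort a [QuestionnaireCohort].
#' @export
scoreMatrix <- function(cohort) {
    stopifnot(methods::is(cohort, "QuestionnaireCohort"))
    t(SummarizedExperiment::assay(cohort, "scores"))
}

#' @describeIn generateCohort Planted factor activation matrix (synthetic
#'   cohorts only; `NULL` for cohorts without ground truth).
#' @export
trueActivation <- function(cohort) {
    stopifnot(methods::is(cohort, "QuestionnaireCohort"))
    cd <- SummarizedExperiment::colData(cohort)
    if (!"trueActivation" %in% colnames(cd)) return(NULL)
    m <- as.matrix(cd$trueActivation)
    attr(m, "class") <- NULL
    storage.mode(m) <- "integer"
    m
}

#' @describeIn generateCohort Clinical record as a `DataFrame` (sex, age,
#'   cgi, diagnoses).
#' @export
clinicalData <- function(cohort) {
    stopifnot(methods::is(cohort, "QuestionnaireCohort"))
    SummarizedExperiment::colData(cohort)[, c("sex", "age", "cgi",
                                              "diagnoses")]
}
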