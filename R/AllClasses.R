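#' @import methods
#' @importFrom stats quantile rbeta rbinom rnorm runif sd aov anova
#'   chisq.test kmeans setNames complete.cases
#' @importFrom utils read.csv write.csv head
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges CharacterList
#' @useDynLib spfmProfiles, .registration = TRUE
NULL

ICD10_CHAPTERS <- paste0("F", 0:9)

#' Cohort of questionnaire responses with clinical records
#'
#' `QuestionnaireCohort` extends
#' [SummarizedExperiment::SummarizedExperiment]: the `"scores"` assay
#' holds the raw item scores (items in rows, patients in columns, values
#' in \[0, 100\] or `NA` for missing), `rowData` carries the item catalog
#' (see [itemCatalog()]), and `colData` carries the per-patient clinical
#' record: `sex` (`"female"`/`"male"`/`NA`), `age` (years), `cgi`
#' (Clinical Global Impression, integer 0--7 or `NA`) and `diagnoses`
#' (an [IRanges::CharacterList] of ICD-10 chapters `F0`--`F9`, possibly
#' empty). Synthetic cohorts additionally carry a `trueActivation`
#' binary matrix column with the planted factor activations.
#'
#' @aliases QuestionnaireCohort
#' @export
setClass("QuestionnaireCohort",
         contains = "SummarizedExperiment")

setValidity("QuestionnaireCohort", function(object) {
    msg <- NULL
    if (!"scores" %in% SummarizedExperiment::assayNames(object))
        return("assay 'scores' is required")
    sc <- SummarizedExperiment::assay(object, "scores")
    ok <- is.na(sc) | (sc >= 0 & sc <= 100)
    if (!all(ok))
        msg <- c(msg, "non-missing scores must lie in [0, 100]")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sex", "age", "cgi", "diagnoses")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks:", paste(miss, collapse = ", ")))
    if (!all(is.na(cd$sex) | cd$sex %in% c("female", "male")))
        msg <- c(msg, "sex must be 'female', 'male' or NA")
    if (!all(is.na(cd$cgi) | (cd$cgi >= 0 & cd$cgi <= 7)))
        msg <- c(msg, "cgi must be in 0..7 or NA")
    dx <- unlist(cd$diagnoses)
    if (length(dx) && !all(dx %in% ICD10_CHAPTERS))
        msg <- c(msg, "diagnoses must be ICD-10 chapters F0..F9")
    if (is.null(msg)) TRUE else msg
})

#' Dichotomized binary response matrix
#'
#' Result of [dichotomizeTopDecile()]: a patients x items binary matrix
#' `X` in which 1 marks a top-decile ("extreme responder") score, `NA`
#' a missing response, together with the per-item score thresholds that
#' produced it.
#'
#' @slot x integer matrix, patients in rows, items in columns; entries
#'   0, 1 or `NA`.
#' @slot thresholds numeric vector, one empirical 90th-percentile cut
#'   value per item.
#' @aliases BinaryResponses
#' @export
setClass("BinaryResponses",
         representation(x = "matrix", thresholds = "numeric"))

setValidity("BinaryResponses", function(object) {
    msg <- NULL
    v <- object@x
    if (!all(is.na(v) | v %in% c(0L, 1L)))
        msg <- c(msg, "entries must be 0, 1 or NA")
    if (length(object@thresholds) != ncol(v))
        msg <- c(msg, "one threshold per item is required")
    if (is.null(msg)) TRUE else msg
})

#' Posterior summary of a sparse Poisson factorization fit
#'
#' Holds the posterior summary returned by [fitSpfm()]: the modal binary
#' activation matrix `Zmap` (patients x factors), posterior-mean factor
#' weights `betaMean` (factors x items), posterior-mean bias weights
#' `biasMean` (one per item), the posterior distribution over the number
#' of retained factor sets, the per-sweep log-joint trace and the
#' inference configuration.
#'
#' @slot Zmap binary matrix, patients x retained factors.
#' @slot betaMean nonnegative matrix, retained factors x items.
#' @slot biasMean nonnegative numeric vector, one entry per item.
#' @slot Kposterior named integer vector: post-burn-in sample counts per
#'   number of factors.
#' @slot trace numeric vector of per-iteration log joint density.
#' @slot alpha concentration of the Indian Buffet Process prior.
#' @slot config list echoing the [fitConfig()] used.
#' @aliases SpfmFit
#' @export
setClass("SpfmFit",
         representation(Zmap = "matrix", betaMean = "matrix",
                        biasMean = "numeric", Kposterior = "integer",
                        trace = "numeric", alpha = "numeric",
                        config = "list"))

setValidity("SpfmFit", function(object) {
    msg <- NULL
    if (!all(object@Zmap %in% c(0L, 1L)))
        msg <- c(msg, "Zmap must be binary")
    if (nrow(object@betaMean) != ncol(object@Zmap))
        msg <- c(msg, "betaMean rows must match Zmap columns")
    if (any(object@betaMean < 0) || any(object@biasMean < 0))
        msg <- c(msg, "weights must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

#' Patient profile assignment
#'
#' Result of [kmeansProfiles()]: each patient is assigned a profile id
#' derived from their latent factor activation pattern. Profile 0 is the
#' bias-only profile (no factor set active); further profiles are ordered
#' by the indices of their active factor sets.
#'
#' @slot labels integer vector of per-patient profile ids.
#' @slot composition named list: profile id (as character) -> integer
#'   vector of active factor-set indices (empty for profile 0).
#' @slot counts named integer vector of patients per profile.
#' @aliases ProfileAssignment
#' @export
setClass("ProfileAssignment",
         representation(labels = "integer", composition = "list",
                        counts = "integer"))

setValidity("ProfileAssignment", function(object) {
    msg <- NULL
    if (sum(object@counts) != length(object@labels))
        msg <- c(msg, "profile counts must sum to the number of patients")
    if (!setequal(names(object@counts), names(object@composition)))
        msg <- c(msg, "counts and composition must name the same profiles")
    if (!all(as.character(object@labels) %in% names(object@counts)))
        msg <- c(msg, "labels must be named in counts")
    if (is.null(msg)) TRUE else msg
})
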