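#' Invert positive-valence item scores
#'
#' Items phrased with positive valence (by the fixed catalog, items
#' 1--15: sleep, appetite, the WHO-5 block, the positive GHQ-12 block)
#' are reflected about the scale endpoints, `s -> 100 - s`, so that a
#' higher score on *any* item indicates poorer mental health.
#' Negative-valence items (16--23) and missing entries are unchanged.
#' The map is an involution: applying it twice restores the input.
#'
#' @param scores patients x items numeric matrix, values in \[0, 100\]
#'   or `NA`.
#' @param catalog item catalog as returned by [itemCatalog()]; its
#'   `valence` column decides which columns are inverted.
#' @return matrix of the same shape.
#' @examples
#' m <- matrix(c(100, 50, 70), 1, 3)
#' cat3 <- S4Vectors::DataFrame(item = 1:3, label = c("a", "b", "c"),
#'     valence = c("positive", "positive", "negative"),
#'     instrument = NA)
#' invertPositiveItems(m, cat3)   # 0, 50, 70
#' @export
invertPositiveItems <- function(scores, catalog = itemCatalog()) {
    scores <- as.matrix(scores)
    if (ncol(scores) != nrow(catalog))
        stop("scores must have one column per catalog item")
    if (any(scores < 0 | scores > 100, na.rm = TRUE))
        stop("scores must lie in [0, 100]")
    pos <- catalog$valence == "positive"
    scores[, pos] <- 100 - scores[, pos]
    scores
}

#' Dichotomize each item at its top decile
#'
#' For every item the empirical 90th percentile of the non-missing
#' scores is taken as that item's threshold (nearest-rank convention,
#' `stats::quantile(type = 1)`); scores strictly above the threshold are
#' coded 1 ("extreme responder"), scores at or below it 0, and missing
#' scores stay missing. Coding strictly above the nearest-rank
#' percentile guarantees at most 10% ones per item, and exactly 10% on
#' tie-free columns whose length is divisible by 10. The coding is
#' invariant under any strictly increasing transform of an item's
#' scores. Scores are assumed already valence-inverted.
#'
#' @param scores patients x items numeric matrix (inverted scale).
#' @return A [BinaryResponses] with the binary matrix and the per-item
#'   thresholds.
#' @examples
#' b <- dichotomizeTopDecile(matrix(1:100, 100, 1))
#' sum(binaryMatrix(b))   # 10
#' thresholds(b)          # 90
#' @export
dichotomizeTopDecile <- function(scores) {
    scores <- as.matrix(scores)
    nOk <- colSums(!is.na(scores))
    if (any(nOk == 0))
        stop("item(s) with all scores missing: ",
             paste(which(nOk == 0), collapse = ", "))
    if (any(nOk < 10))
        warning("item(s) with fewer than 10 non-missing scores: ",
                paste(which(nOk < 10), collapse = ", "))
    thr <- apply(scores, 2, quantile, probs = 0.9, type = 1,
                 na.rm = TRUE, names = FALSE)
    x <- sweep(scores, 2, thr, FUN = ">") * 1L
    storage.mode(x) <- "integer"
    dimnames(x) <- dimnames(scores)
    methods::new("BinaryResponses", x = x,
                 thresholds = setNames(thr, colnames(scores)))
}

#' Apply the per-analysis completeness filter
#'
#' The clinical analyses use different denominators: the latent model
#' keeps every patient (cell-level missing scores are masked inside the
#' likelihood, not imputed), the CGI analysis keeps only patients with a
#' recorded CGI, and the diagnosis analysis keeps only patients with at
#' least one ICD-10 chapter. The number of retained / excluded patients
#' is reported as a message.
#'
#' @param cohort a [QuestionnaireCohort].
#' @param analysis one of `"model"`, `"cgi"`, `"diagnosis"`.
#' @return the filtered [QuestionnaireCohort].
#' @export
completenessFilter <- function(cohort,
                               analysis = c("model", "cgi", "diagnosis")) {
    stopifnot(methods::is(cohort, "QuestionnaireCohort"))
    analysis <- match.arg(analysis)
    cd <- SummarizedExperiment::colData(cohort)
    keep <- switch(analysis,
        model = rep(TRUE, ncol(cohort)),
        cgi = !is.na(cd$cgi),
        diagnosis = lengths(cd$diagnoses) > 0L
    )
    message(sprintf("%s analysis: kept %d of %d patients (%d excluded)",
                    analysis, sum(keep), length(keep), sum(!keep)))
    cohort[, keep]
}
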