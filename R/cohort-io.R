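#' Write / read a cohort as CSV
#'
#' The on-disk format is a plain CSV with header
#' `patient_id,sex,age,cgi,diagnoses,q01..q23`: one row per patient,
#' diagnoses as semicolon-joined ICD-10 chapters (e.g. `F3;F6`), missing
#' values as empty fields. If the cohort carries a planted ground-truth
#' activation matrix it is written to a `*_truth.csv` sidecar next to the
#' main file, so synthetic cohorts round-trip exactly.
#'
#' @param cohort a [QuestionnaireCohort].
#' @param path CSV file path.
#' @return `writeCohort()` returns `path` invisibly; `readCohort()`
#'   returns a [QuestionnaireCohort].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' co <- generateCohort(cohortConfig(nPatients = 120, seed = 3))
#' writeCohort(co, p)
#' co2 <- readCohort(p)
#' stopifnot(all.equal(scoreMatrix(co), scoreMatrix(co2)))
#' @export
writeCohort <- function(cohort, path) {
    stopifnot(methods::is(cohort, "QuestionnaireCohort"))
    sc <- scoreMatrix(cohort)
    cd <- SummarizedExperiment::colData(cohort)
    qn <- sprintf("q%02d", seq_len(ncol(sc)))
    df <- data.frame(
        patient_id = rownames(sc),
        sex = as.character(cd$sex),
        age = cd$age,
        cgi = cd$cgi,
        diagnoses = vapply(cd$diagnoses, paste, character(1),
                           collapse = ";"),
        stringsAsFactors = FALSE
    )
    df[qn] <- as.data.frame(sc)
    write.csv(df, path, row.names = FALSE, na = "")
    zt <- trueActivation(cohort)
    if (!is.null(zt)) {
        tp <- sub("\\.csv$", "_truth.csv", path)
        write.csv(data.frame(patient_id = rownames(sc), zt,
                             check.names = FALSE),
                  tp, row.names = FALSE)
    }
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   na.strings = "", colClasses = "character")
    need <- c("patient_id", "sex", "age", "cgi", "diagnoses")
    qn <- grep("^q[0-9]+$", names(df), value = TRUE)
    if (!all(need %in% names(df)) || length(qn) == 0)
        stop("malformed cohort file: expected columns ",
             paste(c(need, "q01.."), collapse = ", "))
    numify <- function(col, what, lo, hi) {
        x <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(!is.na(df[[col]]) &
                     (is.na(x) | x < lo | x > hi))
        if (length(bad))
            stop(sprintf("parse error at row %d, column '%s': '%s' %s",
                         bad[1], col, df[[col]][bad[1]],
                         sprintf("is not a value in [%g, %g]", lo, hi)))
        x
    }
    scores <- vapply(qn, numify, numeric(nrow(df)),
                     what = "score", lo = 0, hi = 100)
    scores <- matrix(scores, nrow = nrow(df),
                     dimnames = list(df$patient_id, NULL))
    badSex <- which(!is.na(df$sex) & !df$sex %in% c("female", "male"))
    if (length(badSex))
        stop(sprintf("parse error at row %d, column 'sex': '%s'",
                     badSex[1], df$sex[badSex[1]]))
    dxs <- strsplit(ifelse(is.na(df$diagnoses), "", df$diagnoses), ";",
                    fixed = TRUE)
    dxs <- lapply(dxs, function(v) v[nzchar(v)])
    badDx <- which(!vapply(dxs, function(v)
        all(v %in% ICD10_CHAPTERS), logical(1)))
    if (length(badDx))
        stop(sprintf("parse error at row %d, column 'diagnoses': '%s'",
                     badDx[1], df$diagnoses[badDx[1]]))

    d <- length(qn)
    catalog <- if (d == 23L) itemCatalog() else
        S4Vectors::DataFrame(item = seq_len(d), label = qn,
                             valence = ifelse(seq_len(d) <= 15L,
                                              "positive", "negative"),
                             instrument = NA_character_)
    colnames(scores) <- catalog$label
    cd <- S4Vectors::DataFrame(
        sex = df$sex,
        age = numify("age", "age", 0, 150),
        cgi = as.integer(numify("cgi", "cgi", 0, 7)),
        diagnoses = IRanges::CharacterList(setNames(dxs, df$patient_id)),
        row.names = df$patient_id
    )
    tp <- sub("\\.csv$", "_truth.csv", path)
    if (file.exists(tp) && tp != path) {
        tr <- read.csv(tp, stringsAsFactors = FALSE)
        if (!identical(tr$patient_id, df$patient_id))
            stop("truth sidecar does not match cohort patient ids")
        zt <- as.matrix(tr[, -1, drop = FALSE])
        storage.mode(zt) <- "integer"
        rownames(zt) <- df$patient_id
        cd$trueActivation <- I(zt)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(scores = t(scores)),
        rowData = catalog, colData = cd
    )
    methods::new("QuestionnaireCohort", se)
}
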