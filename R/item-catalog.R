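#' Catalog of the 23 questionnaire items
#'
#' The assessment pools 23 items from three short self-report instruments
#' of current mental well-being: a six-item day assessment (sleep,
#' appetite, medication intake, aggressiveness, suicidal thoughts), the
#' five-item WHO-5 Well-Being Index, and the 12-item General Health
#' Questionnaire (GHQ-12). Every item is answered on a 0--100 agreement
#' scale. Items 1--15 are phrased with positive valence (a high score
#' means good health) and are inverted during preprocessing so that high
#' always means poor mental health; items 16--23 are negative-valence and
#' left untouched.
#'
#' @return A [S4Vectors::DataFrame] with one row per item and columns
#'   `item` (1--23), `label` (short snake_case label), `valence`
#'   (`"positive"` or `"negative"`) and `instrument` (`"day-assessment"`,
#'   `"WHO-5"` or `"GHQ-12"`).
#' @examples
#' cat <- itemCatalog()
#' table(cat$valence, cat$instrument)
#' @export
itemCatalog <- function() {
    labels <- c(
        "sleep_hours", "sleep_quality", "appetite", "medication_taken",
        "mood_joyful", "calm_relaxed", "active_energetic", "awake_rested",
        "daily_life_interest", "concentration", "useful_role",
        "decision_making", "enjoy_activities", "coping",
        "reasonably_happy", "aggressiveness", "suicidal_thoughts",
        "worry_sleep_loss", "overwhelmed_tense", "cannot_overcome",
        "unhappy_depressed", "lost_confidence", "worthlessness"
    )
    instrument <- rep("GHQ-12", 23L)
    instrument[c(1:4, 16:17)] <- "day-assessment"
    instrument[5:9] <- "WHO-5"
    S4Vectors::DataFrame(
        item = 1:23,
        label = labels,
        valence = ifelse(1:23 <= 15L, "positive", "negative"),
        instrument = instrument,
        row.names = labels
    )
}

#' Published reference factor-set weights
#'
#' Loads a published reference fit of the sparse Poisson factorization
#' model on a cohort of 2254 psychiatric outpatients: the posterior item
#' weights of the always-active bias term and of the two discovered
#' factor sets, one value per questionnaire item. This table is shipped
#' so that profile weight composition can be exercised against known
#' numbers; it is a reference artifact, not output of this package.
#'
#' @return A data.frame with columns `item`, `label`, `bias`, `factor1`,
#'   `factor2` (23 rows).
#' @examples
#' w <- referenceFactorWeights()
#' w[w$label == "suicidal_thoughts", ]
#' @export
referenceFactorWeights <- function() {
    path <- system.file("extdata", "published_factor_weights.csv",
                        package = "spfmProfiles", mustWork = TRUE)
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(identical(names(out),
                        c("item", "label", "bias", "factor1", "factor2")))
    out
}
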