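#' Cluster patients into profiles by K-means on the activation matrix
#'
#' Applies K-means (the shipped clustering path, with a fixed number of
#' clusters chosen a priori) to the rows of the binary activation
#' matrix, so that patients showing the same pattern of active factor
#' sets fall into the same profile. With two factor sets and the default
#' `k = 4` this reproduces the four canonical profiles: bias only, bias
#' plus factor 1, bias plus factor 2, bias plus both. When the number of
#' distinct activation rows equals `k`, the distinct rows themselves are
#' used as initial centers, so the converged partition is exactly the
#' group-by-pattern partition for every seed; otherwise `kmeans` is run
#' with multiple seeded random starts.
#'
#' Profiles are relabeled canonically from each cluster's (rounded)
#' centroid: profile 0 activates no factor set, and remaining profiles
#' are ordered by the binary code of their active factor indices
#' (factor 1 least significant), so that with two factors profile 1 =
#' factor 1, profile 2 = factor 2, profile 3 = both.
#'
#' @param Z binary patients x factors matrix (e.g.
#'   `activationMatrix(fit)`), or an [SpfmFit].
#' @param k number of clusters; defaults to `2^K` (all activation
#'   combinations).
#' @param seed integer seed for the K-means initialization.
#' @return a [ProfileAssignment].
#' @examples
#' Z <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0, 0))
#' kmeansProfiles(Z, k = 4)
#' @export
kmeansProfiles <- function(Z, k = NULL, seed = 1L) {
    if (methods::is(Z, "SpfmFit")) Z <- activationMatrix(Z)
    Z <- as.matrix(Z)
    if (!all(Z %in% c(0L, 1L))) stop("Z must be binary")
    if (is.null(k)) k <- 2L^ncol(Z)
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    uniq <- unique(Z)
    if (k > nrow(uniq))
        stop(sprintf(paste0("k = %d exceeds the %d distinct activation ",
                            "patterns present; use k <= %d"),
                     k, nrow(uniq), nrow(uniq)))
    set.seed(seed)
    if (ncol(Z) == 0L) {
        cl <- rep(1L, nrow(Z))
        centers <- matrix(0, 1, 0)
    } else if (nrow(uniq) == k) {
        km <- kmeans(Z, centers = uniq)
        cl <- km$cluster
        centers <- km$centers
    } else {
        km <- kmeans(Z, centers = k, nstart = 25L)
        cl <- km$cluster
        centers <- km$centers
    }
    comp <- apply(round(centers) == 1, 1, which, simplify = FALSE)
    if (is.null(dim(centers)) || ncol(centers) == 0L)
        comp <- rep(list(integer(0)), nrow(centers))
    comp <- lapply(comp, as.integer)
    code <- vapply(comp, function(f) sum(2^(f - 1)), numeric(1))
    ord <- order(code)
    relabel <- integer(length(ord))
    relabel[ord] <- seq_along(ord) - 1L
    labels <- relabel[cl]
    names(comp) <- as.character(relabel)
    comp <- comp[as.character(sort(relabel))]
    counts <- vapply(names(comp), function(p)
        sum(labels == as.integer(p)), integer(1))
    methods::new("ProfileAssignment",
                 labels = setNames(labels, rownames(Z)),
                 composition = comp, counts = counts)
}

#' Mean observed item scores per profile
#'
#' The empirical companion to [composeProfileWeights()]: instead of
#' composing model weights, it averages the (valence-inverted) observed
#' scores of each item within each profile, ignoring missing cells.
#' The two tables answer slightly different questions - model weights
#' describe the extreme-response propensity each factor set contributes,
#' while empirical means describe what each profile's patients actually
#' answered - and both are useful when reporting profiles.
#'
#' @param scores patients x items numeric matrix on the inverted scale
#'   (higher = poorer mental health), e.g.
#'   `invertPositiveItems(scoreMatrix(cohort))`.
#' @param assignment a [ProfileAssignment] for the same patients.
#' @return items x profiles matrix of mean scores.
#' @export
profileItemMeans <- function(scores, assignment) {
    scores <- as.matrix(scores)
    lab <- assignment@labels
    if (length(lab) != nrow(scores))
        stop("assignment does not match the score matrix")
    out <- vapply(names(assignment@counts), function(p)
        colMeans(scores[lab == as.integer(p), , drop = FALSE],
                 na.rm = TRUE),
        numeric(ncol(scores)))
    colnames(out) <- paste0("profile", names(assignment@counts))
    out
}

#' @rdname ProfileAssignment-class
#' @details `profileCounts()` returns the per-profile patient counts as
#'   a data.frame with a closing `total` row; the total always equals
#'   the number of patients assigned.
#' @export
setMethod("profileCounts", "ProfileAssignment", function(x) {
    comp <- vapply(x@composition, function(f) {
        if (length(f) == 0) "bias"
        else paste(c("bias", paste0("factor", f)), collapse = "+")
    }, character(1))
    data.frame(
        profile = c(names(x@counts), "total"),
        factorSets = c(comp[names(x@counts)], ""),
        patients = c(as.integer(x@counts), sum(x@counts)),
        row.names = NULL, stringsAsFactors = FALSE
    )
})

#' Compose per-item profile weights from factor weights
#'
#' Builds the profile-by-item weight table: each profile's column is the
#' elementwise sum of the weight rows of its active factor sets, so the
#' column of a profile with both factors equals the sum of the two
#' single-factor columns, item by item (exact additivity). The bias
#' weights are reported as the separate profile-0 column - the bias term
#' is shared by every profile and is not added into the factor columns.
#'
#' @param betaMean factors x items nonnegative weight matrix (or an
#'   [SpfmFit], from which `factorWeights()`/`biasTerm()` are taken).
#' @param biasMean per-item bias weight vector.
#' @param composition named list profile -> integer vector of active
#'   factor indices, as in `profileComposition()`; defaults to all
#'   `2^K` activation combinations in canonical order.
#' @return items x profiles numeric matrix; the bias-only profile column
#'   is named `"profile0_bias"`, other columns
#'   `"profile<p>_factors<...>"`.
#' @examples
#' beta <- rbind(f1 = c(0.0012, 0.0053), f2 = c(0.4573, 0.2362))
#' composeProfileWeights(beta, biasMean = c(0.3177, 0.1745))
#' @export
composeProfileWeights <- function(betaMean, biasMean = NULL,
                                  composition = NULL) {
    if (methods::is(betaMean, "SpfmFit")) {
        if (is.null(biasMean)) biasMean <- biasTerm(betaMean)
        betaMean <- factorWeights(betaMean)
    }
    betaMean <- as.matrix(betaMean)
    kTot <- nrow(betaMean)
    d <- ncol(betaMean)
    if (is.null(biasMean)) stop("biasMean is required")
    if (length(biasMean) != d)
        stop("biasMean must have one entry per item")
    if (any(betaMean < 0) || any(biasMean < 0))
        stop("weights must be nonnegative")
    if (is.null(composition)) {
        composition <- lapply(seq_len(2^kTot) - 1L, function(code)
            which(bitwAnd(code, 2L^(seq_len(kTot) - 1L)) > 0L))
        names(composition) <- as.character(seq_along(composition) - 1L)
    }
    bad <- unlist(composition)
    if (length(bad) && (any(bad < 1L) || any(bad > kTot)))
        stop("composition references unknown factor set(s): ",
             paste(unique(bad[bad < 1L | bad > kTot]), collapse = ", "))
    cols <- lapply(names(composition), function(p) {
        f <- composition[[p]]
        if (length(f) == 0) as.numeric(biasMean)
        else colSums(betaMean[f, , drop = FALSE])
    })
    out <- do.call(cbind, cols)
    colnames(out) <- vapply(names(composition), function(p) {
        f <- composition[[p]]
        if (length(f) == 0) sprintf("profile%s_bias", p)
        else sprintf("profile%s_factors%s", p, paste(f, collapse = "+"))
    }, character(1))
    rownames(out) <- colnames(betaMean)
    out
}
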