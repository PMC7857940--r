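#' Bernoulli-Poisson log likelihood of the sparse Poisson factorization
#'
#' The observation model couples the binary responses to nonnegative
#' rates through the Bernoulli--Poisson link: each cell carries a latent
#' Poisson count with rate `lambda[n, d] = bias[d] + sum_k Z[n, k] *
#' beta[k, d]`, and the observed response is 1 exactly when the count is
#' positive, so `P(x = 1) = 1 - exp(-lambda)`. A larger weight of an
#' active factor set on an item therefore raises the probability of an
#' extreme response on that item. Missing cells (`NA` in `X`) are
#' excluded from the sum, not imputed.
#'
#' @param X patients x items binary matrix (`NA` = missing).
#' @param Z patients x factors binary activation matrix (0 columns
#'   allowed).
#' @param beta factors x items nonnegative weight matrix.
#' @param bias nonnegative weight vector, one entry per item.
#' @return the log likelihood, summed over non-missing cells.
#' @examples
#' X <- matrix(0L, 2, 3)
#' spfmLogLikelihood(X, matrix(0L, 2, 0), matrix(0, 0, 3), rep(0, 3))
#' # 0: with all rates zero, an all-zero matrix has probability 1
#' @export
spfmLogLikelihood <- function(X, Z, beta, bias) {
    X <- as.matrix(X)
    Z <- as.matrix(Z)
    beta <- matrix(as.numeric(beta), nrow = ncol(Z), ncol = ncol(X))
    if (!all(X %in% c(0L, 1L) | is.na(X)))
        stop("X must be binary (0/1/NA)")
    if (!all(Z %in% c(0L, 1L)))
        stop("Z must be binary")
    if (any(beta < 0) || any(bias < 0))
        stop("beta and bias must be nonnegative")
    if (length(bias) != ncol(X) || nrow(Z) != nrow(X))
        stop("dimension mismatch between X, Z, beta, bias")
    lam <- sweep(if (ncol(Z)) Z %*% beta else
                     matrix(0, nrow(X), ncol(X)),
                 2, bias, `+`)
    ll <- ifelse(X == 1L, log(-expm1(-lam)), -lam)
    sum(ll[!is.na(X)])
}

#' Indian Buffet Process log prior of a binary activation matrix
#'
#' Log probability of the left-ordered equivalence class of `Z` under
#' the IBP with concentration `alpha`: the exchangeable prior over
#' binary matrices with unboundedly many columns that makes the number
#' of factor sets itself a random quantity. The value is invariant under
#' row (patient) and column (factor) permutations.
#'
#' @param Z patients x factors binary matrix with no all-zero column
#'   (empty factors are pruned before scoring).
#' @param alpha IBP concentration, > 0.
#' @return log prior probability of the equivalence class of `Z`.
#' @examples
#' ibpLogPrior(matrix(0L, 1, 0), alpha = 1)  # -1: P(no features) = e^-1
#' @export
ibpLogPrior <- function(Z, alpha) {
    Z <- as.matrix(Z)
    if (alpha <= 0) stop("alpha must be positive")
    if (!all(Z %in% c(0L, 1L))) stop("Z must be binary")
    n <- nrow(Z)
    if (n < 1L) stop("Z must have at least one row")
    m <- colSums(Z)
    if (any(m == 0))
        stop("Z has an all-zero column; prune empty factors first")
    kPlus <- ncol(Z)
    hN <- sum(1 / seq_len(n))
    out <- kPlus * log(alpha) - alpha * hN
    if (kPlus > 0) {
        pat <- apply(Z, 2, paste, collapse = "")
        out <- out - sum(lgamma(table(pat) + 1)) +
            sum(lgamma(n - m + 1) + lgamma(m) - lgamma(n + 1))
    }
    out
}

#' Inference settings for [fitSpfm()]
#'
#' @param nIterations total Gibbs sweeps (default 2000).
#' @param burnIn sweeps discarded before summarizing (default 1000; must
#'   be smaller than `nIterations`).
#' @param alpha IBP concentration; the starting value when a hyperprior
#'   is set, otherwise fixed. By default `alpha` is given a Gamma(1, 1)
#'   hyperprior and resampled each sweep, which lets the data determine
#'   the concentration (with ~2 factors in a cohort of 1000 it adapts to
#'   ~0.35, keeping one-patient "idiosyncrasy" factors unprofitable);
#'   set `alphaPrior = NULL` to fix `alpha`.
#' @param betaPrior Gamma (shape, rate) prior shared by all factor and
#'   bias weights. The default `c(1, 5)` (mean 0.2) matches the scale of
#'   rates that top-decile data can support - per-item response
#'   probabilities rarely exceed ~0.5, i.e. rates ~0.7; a mean-1 prior
#'   puts most of its mass on implausibly large weights and makes
#'   single-patient factors likelihood-profitable.
#' @param maxNewFactorsPerStep cap on the number of new factor sets a
#'   single patient may propose in one sweep.
#' @param thin store every `thin`-th post-burn-in sample for posterior
#'   averaging.
#' @param kInit number of factors in the overcomplete random
#'   initialization. Starting from several randomly-membered factors
#'   and letting the surplus decay mixes far better than growing shared
#'   factors out of single-patient birth moves; `kInit = 0` starts from
#'   the empty matrix.
#' @param zInitProb initial activation probability of each
#'   initialization factor.
#' @param seed integer seed; fits are deterministic given the seed.
#' @return a validated list of class `FitConfig`.
#' @export
fitConfig <- function(nIterations = 2000L, burnIn = 1000L,
                      alpha = 1, alphaPrior = c(1, 1),
                      betaPrior = c(1, 5),
                      maxNewFactorsPerStep = 3L,
                      thin = 10L, kInit = 6L, zInitProb = 0.2,
                      seed = 1L) {
    nIterations <- as.integer(nIterations)
    burnIn <- as.integer(burnIn)
    if (nIterations <= 0L || burnIn < 0L || burnIn >= nIterations)
        stop("need 0 <= burnIn < nIterations")
    if (alpha <= 0) stop("alpha must be positive")
    if (!is.null(alphaPrior) &&
        (length(alphaPrior) != 2L || any(alphaPrior <= 0)))
        stop("alphaPrior must be positive c(shape, rate)")
    if (length(betaPrior) != 2L || any(betaPrior <= 0))
        stop("betaPrior must be positive c(shape, rate)")
    if (maxNewFactorsPerStep < 1L)
        stop("maxNewFactorsPerStep must be >= 1")
    if (kInit < 0L || zInitProb < 0 || zInitProb > 1)
        stop("kInit must be >= 0 and zInitProb in [0, 1]")
    structure(list(nIterations = nIterations, burnIn = burnIn,
                   alpha = alpha, alphaPrior = alphaPrior,
                   betaPrior = as.numeric(betaPrior),
                   maxNewFactorsPerStep = as.integer(maxNewFactorsPerStep),
                   thin = as.integer(thin), kInit = as.integer(kInit),
                   zInitProb = zInitProb, seed = as.integer(seed)),
              class = "FitConfig")
}

#' Fit the sparse Poisson factorization model
#'
#' Runs uncollapsed Gibbs sampling for the IBP latent feature model with
#' Bernoulli--Poisson observations and an always-active bias term:
#' per-patient Gibbs updates of existing activations (prior odds
#' `m/(N - m)` from the IBP conditional), a Metropolis--Hastings
#' birth/death move on each patient's singleton factors with prior
#' proposals (`Poisson(alpha / N)` new factors, weights from the Gamma
#' prior), and conjugate Gamma updates of all weights through latent
#' Poisson count augmentation (counts are drawn only on observed
#' `x = 1` cells from a zero-truncated Poisson and thinned
#' multinomially over the active sources). Empty factor columns are
#' pruned every sweep. Missing cells never enter the likelihood.
#'
#' The posterior summary takes the modal number of factors over the
#' post-burn-in sweeps; `Zmap` is the last post-burn-in sample with that
#' modal K, and `betaMean` averages the stored (thinned) samples with
#' the modal K after matching their factor columns to the reference
#' sample by cosine similarity of the weight rows.
#'
#' @param X a [BinaryResponses] or a binary patients x items matrix
#'   (`NA` = missing).
#' @param config a [fitConfig()].
#' @return an [SpfmFit].
#' @export
fitSpfm <- function(X, config = fitConfig()) {
    if (methods::is(X, "BinaryResponses")) X <- binaryMatrix(X)
    X <- as.matrix(X)
    if (!all(X %in% c(0L, 1L) | is.na(X)))
        stop("X must be binary (0/1/NA)")
    if (nrow(X) < 10L)
        stop("at least 10 patients are required")
    stopifnot(inherits(config, "FitConfig"))
    xi <- X
    storage.mode(xi) <- "integer"
    xi[is.na(xi)] <- -1L
    set.seed(config$seed)
    res <- spfm_gibbs(xi, config$nIterations, config$burnIn,
                      config$alpha,
                      if (is.null(config$alphaPrior)) numeric(0)
                      else config$alphaPrior,
                      config$betaPrior[1], config$betaPrior[2],
                      config$maxNewFactorsPerStep, config$thin,
                      config$kInit, config$zInitProb)
    itemNames <- colnames(X)
    if (is.null(itemNames))
        itemNames <- sprintf("q%02d", seq_len(ncol(X)))

    ks <- res$K_samples
    kTab <- table(ks)
    kModal <- as.integer(names(kTab)[which.max(kTab)])
    ref <- res$last_by_K[[as.character(kModal)]]
    zMap <- ref$Z
    storage.mode(zMap) <- "integer"

    # posterior means over thinned samples at the modal K, columns
    # matched to the reference beta by cosine similarity
    thinned <- res$thinned
    sel <- Filter(function(s) nrow(s$beta) == kModal, thinned)
    biasMean <- if (length(thinned))
        Reduce(`+`, lapply(thinned, `[[`, "bias")) / length(thinned)
    else ref$bias
    if (kModal > 0L && length(sel)) {
        acc <- matrix(0, kModal, ncol(X))
        for (s in sel)
            acc <- acc + matchFactorRows(s$beta, ref$beta)
        betaMean <- acc / length(sel)
    } else {
        betaMean <- matrix(ref$beta, nrow = kModal, ncol = ncol(X))
    }
    dimnames(betaMean) <- list(
        if (kModal > 0L) paste0("factor", seq_len(kModal)) else NULL,
        itemNames)
    colnames(zMap) <- rownames(betaMean)
    rownames(zMap) <- rownames(X)
    methods::new("SpfmFit",
                 Zmap = zMap, betaMean = betaMean,
                 biasMean = setNames(as.numeric(biasMean), itemNames),
                 Kposterior = setNames(as.integer(kTab), names(kTab)),
                 trace = as.numeric(res$trace),
                 alpha = res$alpha,
                 config = unclass(config))
}

# Greedy cosine matching of the rows of `beta` onto the rows of `ref`;
# returns `beta` with rows permuted into reference order.
matchFactorRows <- function(beta, ref) {
    k <- nrow(ref)
    if (k <= 1L) return(beta)
    nb <- sqrt(rowSums(beta^2)); nr <- sqrt(rowSums(ref^2))
    sim <- (ref %*% t(beta)) / (outer(nr, nb) + 1e-12)
    perm <- integer(k)
    used <- logical(k)
    for (step in seq_len(k)) {
        ij <- arrayInd(which.max(ifelse(outer(perm == 0L, !used, `&`),
                                        sim, -Inf)), dim(sim))
        perm[ij[1]] <- ij[2]
        used[ij[2]] <- TRUE
    }
    beta[perm, , drop = FALSE]
}
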