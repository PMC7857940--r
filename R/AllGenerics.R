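#' @rdname BinaryResponses-class
#' @param object,x a `BinaryResponses`, `SpfmFit` or `ProfileAssignment`.
#' @export
setGeneric("binaryMatrix", function(x) standardGeneric("binaryMatrix"))

#' @rdname BinaryResponses-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname SpfmFit-class
#' @export
setGeneric("activationMatrix",
           function(x) standardGeneric("activationMatrix"))

#' @rdname SpfmFit-class
#' @export
setGeneric("factorWeights", function(x) standardGeneric("factorWeights"))

#' @rdname SpfmFit-class
#' @export
setGeneric("biasTerm", function(x) standardGeneric("biasTerm"))

#' @rdname SpfmFit-class
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' @rdname ProfileAssignment-class
#' @export
setGeneric("profileLabels", function(x) standardGeneric("profileLabels"))

#' @rdname ProfileAssignment-class
#' @export
setGeneric("profileComposition",
           function(x) standardGeneric("profileComposition"))

#' @rdname ProfileAssignment-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname BinaryResponses-class
#' @export
setMethod("binaryMatrix", "BinaryResponses", function(x) x@x)

#' @rdname BinaryResponses-class
#' @export
setMethod("thresholds", "BinaryResponses", function(x) x@thresholds)

setMethod("show", "BinaryResponses", function(object) {
    v <- object@x
    cat("BinaryResponses:", nrow(v), "patients x", ncol(v), "items\n")
    cat(sprintf("  fraction coded 1: %.3f; missing cells: %d\n",
                mean(v == 1L, na.rm = TRUE), sum(is.na(v))))
})

#' @rdname SpfmFit-class
#' @export
setMethod("activationMatrix", "SpfmFit", function(x) x@Zmap)

#' @rdname SpfmFit-class
#' @export
setMethod("factorWeights", "SpfmFit", function(x) x@betaMean)

#' @rdname SpfmFit-class
#' @details `biasTerm()` returns the posterior-mean weight of the
#'   always-active bias term for each item: the "default" extreme-response
#'   propensity shared by every patient, independent of any factor set.
#' @export
setMethod("biasTerm", "SpfmFit", function(x) x@biasMean)

#' @rdname SpfmFit-class
#' @export
setMethod("nFactors", "SpfmFit", function(x) ncol(x@Zmap))

setMethod("show", "SpfmFit", function(object) {
    cat("SpfmFit:", nrow(object@Zmap), "patients,",
        ncol(object@Zmap), "retained factor sets + bias term\n")
    kp <- object@Kposterior
    cat("  posterior over K:",
        paste(sprintf("K=%s:%d", names(kp), kp), collapse = " "), "\n")
    cat(sprintf("  IBP alpha = %g; %d recorded sweeps\n",
                object@alpha, length(object@trace)))
})

#' @rdname ProfileAssignment-class
#' @export
setMethod("profileLabels", "ProfileAssignment", function(x) x@labels)

#' @rdname ProfileAssignment-class
#' @export
setMethod("profileComposition", "ProfileAssignment",
          function(x) x@composition)

setMethod("show", "ProfileAssignment", function(object) {
    cat("ProfileAssignment:", length(object@labels), "patients in",
        length(object@counts), "profiles\n")
    comp <- vapply(object@composition, function(f) {
        if (length(f) == 0) "bias only"
        else paste0("bias+", paste(f, collapse = "+"))
    }, character(1))
    for (p in names(object@counts))
        cat(sprintf("  profile %s (%s): %d patients\n",
                    p, comp[[p]], object@counts[[p]]))
})
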