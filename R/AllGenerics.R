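#' Accessors for OmicsMatrix, StateMatrix and SLCohort
#'
#' \code{sampleNames}/\code{geneNames} return the sample and gene
#' identifiers; \code{omicsValues} the numeric matrix; \code{omicsRole} the
#' declared role; \code{stateValues}, \code{stateKind} and
#' \code{stateProvenance} the corresponding StateMatrix slots.
#'
#' @param x an [OmicsMatrix-class], [StateMatrix-class] or
#'   [SLCohort-class] object.
#' @return Character vectors of identifiers, a numeric/logical matrix, or a
#'   list, depending on the accessor.
#' @name accessors
#' @aliases sampleNames geneNames omicsValues omicsRole stateValues
#'   stateKind stateProvenance
NULL

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))
#' @rdname accessors
#' @export
setGeneric("omicsRole", function(x) standardGeneric("omicsRole"))
#' @rdname accessors
#' @export
setGeneric("stateValues", function(x) standardGeneric("stateValues"))
#' @rdname accessors
#' @export
setGeneric("stateKind", function(x) standardGeneric("stateKind"))
#' @rdname accessors
#' @export
setGeneric("stateProvenance", function(x) standardGeneric("stateProvenance"))

#' @rdname accessors
setMethod("sampleNames", "OmicsMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneNames", "OmicsMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)
#' @rdname accessors
setMethod("omicsRole", "OmicsMatrix", function(x) x@role)

#' @rdname accessors
setMethod("sampleNames", "StateMatrix", function(x) rownames(x@states))
#' @rdname accessors
setMethod("geneNames", "StateMatrix", function(x) colnames(x@states))
#' @rdname accessors
setMethod("stateValues", "StateMatrix", function(x) x@states)
#' @rdname accessors
setMethod("stateKind", "StateMatrix", function(x) x@stateKind)
#' @rdname accessors
setMethod("stateProvenance", "StateMatrix", function(x) x@provenance)

#' @rdname accessors
setMethod("sampleNames", "SLCohort", function(x) {
    layers <- Filter(Negate(is.null),
        list(x@expression, x@copyNumber, x@geneEffect))
    unique(unlist(lapply(layers, sampleNames)))
})
#' @rdname accessors
setMethod("geneNames", "SLCohort", function(x) {
    layers <- Filter(Negate(is.null),
        list(x@expression, x@copyNumber, x@geneEffect))
    unique(unlist(lapply(layers, geneNames)))
})

#' Cohort layer accessors
#'
#' @param x an [SLCohort-class].
#' @return The requested layer ([OmicsMatrix-class] or NULL), mutation
#'   data.frame, annotation vector, truth table or label.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("exprLayer", function(x) standardGeneric("exprLayer"))
#' @rdname cohort-accessors
#' @export
setGeneric("cnLayer", function(x) standardGeneric("cnLayer"))
#' @rdname cohort-accessors
#' @export
setGeneric("effectLayer", function(x) standardGeneric("effectLayer"))
#' @rdname cohort-accessors
#' @export
setGeneric("mutationTable", function(x) standardGeneric("mutationTable"))
#' @rdname cohort-accessors
#' @export
setGeneric("sampleAnnotation", function(x) standardGeneric("sampleAnnotation"))
#' @rdname cohort-accessors
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortLabel", function(x) standardGeneric("cohortLabel"))

#' @rdname cohort-accessors
setMethod("exprLayer", "SLCohort", function(x) x@expression)
#' @rdname cohort-accessors
setMethod("cnLayer", "SLCohort", function(x) x@copyNumber)
#' @rdname cohort-accessors
setMethod("effectLayer", "SLCohort", function(x) x@geneEffect)
#' @rdname cohort-accessors
setMethod("mutationTable", "SLCohort", function(x) x@mutations)
#' @rdname cohort-accessors
setMethod("sampleAnnotation", "SLCohort", function(x) x@annotation)
#' @rdname cohort-accessors
setMethod("plantedTruth", "SLCohort", function(x) x@truth)
#' @rdname cohort-accessors
setMethod("cohortLabel", "SLCohort", function(x) x@label)

setMethod("show", "OmicsMatrix", function(object) {
    v <- object@values
    cat(sprintf("OmicsMatrix [%s]: %d samples x %d genes (%d missing values)\n",
        object@role, nrow(v), ncol(v), sum(is.na(v))))
    cat("  samples:", paste(head(rownames(v), 4L), collapse = ", "),
        if (nrow(v) > 4L) "..." else "", "\n")
    cat("  genes:  ", paste(head(colnames(v), 4L), collapse = ", "),
        if (ncol(v) > 4L) "..." else "", "\n")
    invisible(NULL)
})

setMethod("show", "StateMatrix", function(object) {
    s <- object@states
    cat(sprintf("StateMatrix [%s]: %d samples x %d genes, %d positive calls\n",
        object@stateKind, nrow(s), ncol(s), sum(s)))
    if (length(object@provenance))
        cat("  provenance:",
            paste(names(object@provenance), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "SLCohort", function(object) {
    cat(sprintf("SLCohort '%s'\n", object@label))
    for (nm in c("expression", "copyNumber", "geneEffect")) {
        layer <- slot(object, nm)
        if (!is.null(layer))
            cat(sprintf("  %-11s %d x %d\n", paste0(nm, ":"),
                nrow(layer@values), ncol(layer@values)))
    }
    cat(sprintf("  mutations:  %d records\n", nrow(object@mutations)))
    if (length(object@annotation))
        cat(sprintf("  annotation: %d samples, %d cancer types\n",
            length(object@annotation), length(unique(object@annotation))))
    if (nrow(object@truth))
        cat(sprintf("  truth:      %d planted pairs\n", nrow(object@truth)))
    invisible(NULL)
})

#' Restrict a cohort to a subset of samples
#'
#' Subsets every omics layer, the mutation table and the annotation to the
#' given samples (intersection with each layer's own samples). Used for
#' tissue-restricted analyses.
#'
#' @param cohort an [SLCohort-class].
#' @param samples character vector of sample identifiers to keep.
#' @return An [SLCohort-class] restricted to \code{samples}.
#' @export
subsetSamples <- function(cohort, samples) {
    stopifnot(is(cohort, "SLCohort"))
    sub <- function(layer) {
        if (is.null(layer)) return(NULL)
        keep <- intersect(rownames(layer@values), samples)
        if (!length(keep))
            stop("no samples left in '", layer@role, "' layer after subsetting")
        OmicsMatrix(layer@values[keep, , drop = FALSE], layer@role)
    }
    mut <- cohort@mutations
    if (nrow(mut)) mut <- mut[mut$sample %in% samples, , drop = FALSE]
    ann <- cohort@annotation[names(cohort@annotation) %in% samples]
    SLCohort(expression = sub(cohort@expression),
             copyNumber = sub(cohort@copyNumber),
             geneEffect = sub(cohort@geneEffect),
             mutations = mut, annotation = ann,
             truth = cohort@truth, params = cohort@params,
             label = cohort@label)
}
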