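#' @import methods
NULL

## Roles an omics layer can play; units differ by role:
##   expression  - log2-scale abundance
##   copy_number - gene-level log2 ratio (0 = diploid)
##   gene_effect - dependency score (negative = more essential)
.OMICS_ROLES <- c("expression", "copy_number", "gene_effect")

.STATE_KINDS <- c("functional_mutation", "inactive", "overactive")

#' OmicsMatrix: a sample-by-gene real-valued matrix with a declared role
#'
#' The central container for one omics layer of a cohort: rows are samples
#' (cell lines or tumors), columns are gene symbols, and the \code{role}
#' declares how the values are to be interpreted (\code{"expression"} on the
#' log2 scale, \code{"copy_number"} as gene-level log2 ratios, or
#' \code{"gene_effect"} as CRISPR/shRNA dependency scores where more negative
#' means more essential). Missing values are allowed and preserved.
#'
#' @slot values numeric matrix, samples in rows, genes in columns, both
#'   dimensions named with unique identifiers.
#' @slot role one of \code{"expression"}, \code{"copy_number"},
#'   \code{"gene_effect"}.
#'
#' @seealso [readOmicsMatrix()], [StateMatrix-class]
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
    representation(values = "matrix", role = "character"))

setValidity("OmicsMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (nrow(v) < 1L || ncol(v) < 1L)
        msg <- c(msg, "matrix must have at least one sample and one gene")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "both sample (row) and gene (column) names are required")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, sprintf("duplicate sample identifiers: %s",
                paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, sprintf("duplicate gene identifiers: %s",
                paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
        if (any(!nzchar(rownames(v))) || any(!nzchar(colnames(v))))
            msg <- c(msg, "empty sample or gene identifiers are not allowed")
    }
    if (length(object@role) != 1L || !object@role %in% .OMICS_ROLES)
        msg <- c(msg, sprintf("'role' must be one of: %s",
            paste(.OMICS_ROLES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix with samples in rows and genes in columns;
#'   both dimensions must carry unique names.
#' @param role character scalar; one of \code{"expression"},
#'   \code{"copy_number"}, \code{"gene_effect"}.
#' @return A validated [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'     dimnames = list(paste0("S", 1:3), c("BRCA2", "PARP1")))
#' OmicsMatrix(m, role = "expression")
#' @export
OmicsMatrix <- function(values, role = c("expression", "copy_number", "gene_effect")) {
    role <- match.arg(role)
    if (is.data.frame(values)) values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("OmicsMatrix", values = values, role = role)
}

#' StateMatrix: binary molecular-state calls per sample and gene
#'
#' Boolean sample-by-gene matrix recording a molecular state call
#' (functional mutation, inactivation, or overactivation) together with the
#' provenance (thresholds and inputs) needed to reconstruct the call.
#'
#' @slot states logical matrix, samples in rows, genes in columns.
#' @slot stateKind one of \code{"functional_mutation"}, \code{"inactive"},
#'   \code{"overactive"}.
#' @slot provenance named list of the parameters that produced the call.
#'
#' @seealso [functionalMutationMask()], [inactivationMask()],
#'   [overactivationMask()]
#' @exportClass StateMatrix
setClass("StateMatrix",
    representation(states = "matrix", stateKind = "character",
                   provenance = "list"))

setValidity("StateMatrix", function(object) {
    msg <- character()
    s <- object@states
    if (!is.logical(s))
        msg <- c(msg, "'states' must be a logical matrix")
    if (anyNA(s))
        msg <- c(msg, "state calls must be TRUE/FALSE, never NA")
    if (is.null(rownames(s)) || is.null(colnames(s)))
        msg <- c(msg, "sample and gene names are required")
    else if (anyDuplicated(rownames(s)) || anyDuplicated(colnames(s)))
        msg <- c(msg, "sample and gene identifiers must be unique")
    if (length(object@stateKind) != 1L || !object@stateKind %in% .STATE_KINDS)
        msg <- c(msg, sprintf("'stateKind' must be one of: %s",
            paste(.STATE_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a StateMatrix
#'
#' @param states logical sample-by-gene matrix with unique dimnames.
#' @param stateKind one of \code{"functional_mutation"}, \code{"inactive"},
#'   \code{"overactive"}.
#' @param provenance named list recording how the calls were made.
#' @return A validated [StateMatrix-class].
#' @export
StateMatrix <- function(states, stateKind, provenance = list()) {
    storage.mode(states) <- "logical"
    new("StateMatrix", states = states, stateKind = stateKind,
        provenance = provenance)
}

setClassUnion("OmicsMatrixOrNULL", c("OmicsMatrix", "NULL"))

#' SLCohort: one cohort's omics layers, mutations and sample annotation
#'
#' Bundles the matrices a synthetic-lethality screen draws on: expression,
#' copy number and gene-effect layers (each optional), a long-form mutation
#' table, and a sample-to-cancer-type annotation. Synthetic cohorts built by
#' [generateCohort()] additionally carry the planted ground truth and the
#' generating parameters.
#'
#' @slot expression,copyNumber,geneEffect [OmicsMatrix-class] or NULL.
#' @slot mutations data.frame with columns \code{sample}, \code{gene},
#'   \code{classification}.
#' @slot annotation named character vector, sample -> cancer type.
#' @slot truth data.frame of planted pairs (empty for real cohorts).
#' @slot params list of generator parameters (empty for real cohorts).
#' @slot label character scalar naming the dataset.
#'
#' @seealso [generateCohort()], [daisyScreen()]
#' @exportClass SLCohort
setClass("SLCohort",
    representation(expression = "OmicsMatrixOrNULL",
                   copyNumber = "OmicsMatrixOrNULL",
                   geneEffect = "OmicsMatrixOrNULL",
                   mutations = "data.frame",
                   annotation = "character",
                   truth = "data.frame",
                   params = "list",
                   label = "character"))

setValidity("SLCohort", function(object) {
    msg <- character()
    layers <- Filter(Negate(is.null),
        list(object@expression, object@copyNumber, object@geneEffect))
    if (!length(layers))
        msg <- c(msg, "at least one omics layer is required")
    if (length(object@label) != 1L || !nzchar(object@label))
        msg <- c(msg, "'label' must be a non-empty string")
    if (length(object@annotation)) {
        if (is.null(names(object@annotation)) ||
            any(!nzchar(names(object@annotation))))
            msg <- c(msg, "'annotation' must be named by sample")
        if (anyDuplicated(names(object@annotation)))
            msg <- c(msg, "each sample maps to exactly one cancer type")
        if (any(is.na(object@annotation)) || any(!nzchar(object@annotation)))
            msg <- c(msg, "cancer-type labels must be non-empty")
    }
    if (nrow(object@mutations) &&
        !all(c("sample", "gene", "classification") %in% colnames(object@mutations)))
        msg <- c(msg, "'mutations' needs columns sample, gene, classification")
    if (length(msg)) msg else TRUE
})

#' Construct an SLCohort
#'
#' @param expression,copyNumber,geneEffect [OmicsMatrix-class] layers
#'   (any may be NULL, at least one required).
#' @param mutations data.frame with columns \code{sample}, \code{gene},
#'   \code{classification} (may be empty).
#' @param annotation named character vector mapping samples to cancer types.
#' @param truth,params ground truth and generator parameters for synthetic
#'   cohorts; leave as defaults for real data.
#' @param label dataset label used in result tables.
#' @return A validated [SLCohort-class].
#' @export
SLCohort <- function(expression = NULL, copyNumber = NULL, geneEffect = NULL,
                     mutations = emptyMutationTable(), annotation = character(),
                     truth = data.frame(), params = list(), label = "cohort") {
    new("SLCohort", expression = expression, copyNumber = copyNumber,
        geneEffect = geneEffect, mutations = mutations,
        annotation = annotation, truth = truth, params = params,
        label = label)
}

#' An empty mutation table with the canonical columns
#' @return zero-row data.frame with columns sample, gene, classification.
#' @export
emptyMutationTable <- function() {
    data.frame(sample = character(), gene = character(),
               classification = character(), stringsAsFactors = FALSE)
}
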