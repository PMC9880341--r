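## Readers and writers for every tabular artifact the workflows consume:
## omics matrices, MAF-like mutation tables, sample annotations, GMT gene
## sets, ortholog maps, yeast interaction tables and prediction tables.
## Delimiter is auto-detected from the extension (.tsv -> tab, .csv ->
## comma) and can be overridden.

.detectSep <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readTable <- function(path, sep = NULL, ...) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = .detectSep(path, sep), header = TRUE,
        quote = "", comment.char = "", check.names = FALSE,
        stringsAsFactors = FALSE, na.strings = c("NA", ""), ...)
}

## Numeric columns are rendered with full precision so that write -> read
## round-trips reproduce the numbers bit-exactly; missing values become "".
.formatForWrite <- function(df) {
    for (j in seq_along(df)) {
        if (is.double(df[[j]])) {
            out <- sprintf("%.17g", df[[j]])
            out[is.na(df[[j]])] <- NA_character_
            df[[j]] <- out
        }
    }
    df
}

.writeTable <- function(df, path, sep = NULL) {
    utils::write.table(.formatForWrite(df), path, sep = .detectSep(path, sep),
        quote = FALSE, row.names = FALSE, col.names = TRUE, na = "")
    invisible(path)
}

#' Read a sample-by-gene omics matrix from delimited text
#'
#' Expects one header row and one leading identifier column. When the file
#' stores genes in rows the parsed matrix is transposed so that samples are
#' always rows. Non-numeric cells become missing values.
#'
#' @param path file path (.tsv tab-delimited, .csv comma-delimited; override
#'   with \code{sep}).
#' @param role matrix role, see [OmicsMatrix()].
#' @param orientation \code{"samples_in_rows"} (default) or
#'   \code{"genes_in_rows"}.
#' @param sep optional field separator overriding extension detection.
#' @return An [OmicsMatrix-class].
#' @export
readOmicsMatrix <- function(path,
        role = c("expression", "copy_number", "gene_effect"),
        orientation = c("samples_in_rows", "genes_in_rows"), sep = NULL) {
    role <- match.arg(role)
    orientation <- match.arg(orientation)
    df <- .readTable(path, sep)
    if (ncol(df) < 2L || nrow(df) < 1L)
        stop("empty matrix in ", path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate identifiers in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")  # non-numeric cells -> NA
    rownames(m) <- ids
    if (anyDuplicated(colnames(m)))
        stop("duplicate identifiers in ", path, ": ",
             paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
    if (orientation == "genes_in_rows") m <- t(m)
    OmicsMatrix(m, role)
}

#' Write an omics matrix to delimited text (samples in rows)
#'
#' @param x an [OmicsMatrix-class].
#' @param path output path; extension selects the delimiter.
#' @param sep optional separator override.
#' @return The path, invisibly.
#' @export
writeOmicsMatrix <- function(x, path, sep = NULL) {
    stopifnot(is(x, "OmicsMatrix"))
    df <- data.frame(sample = rownames(x@values),
        as.data.frame(x@values, check.names = FALSE),
        check.names = FALSE, stringsAsFactors = FALSE)
    .writeTable(df, path, sep)
}

#' Read a MAF-like mutation table
#'
#' One record per row; rows with an empty sample or gene are dropped and the
#' drop count reported via \code{message()}.
#'
#' @param path file path.
#' @param sampleCol,geneCol,classCol column names holding the sample
#'   identifier, gene symbol and variant classification (defaults follow the
#'   CCLE/MAF convention).
#' @param sep optional separator override.
#' @return data.frame with columns \code{sample}, \code{gene},
#'   \code{classification}.
#' @export
readMutationTable <- function(path, sampleCol = "DepMap_ID",
        geneCol = "Hugo_Symbol", classCol = "Variant_Classification",
        sep = NULL) {
    df <- .readTable(path, sep, colClasses = "character")
    for (col in c(sampleCol, geneCol, classCol))
        if (!col %in% colnames(df))
            stop("required column '", col, "' not found in ", path)
    out <- data.frame(sample = df[[sampleCol]], gene = df[[geneCol]],
        classification = df[[classCol]], stringsAsFactors = FALSE)
    bad <- is.na(out$sample) | !nzchar(out$sample) |
           is.na(out$gene) | !nzchar(out$gene) |
           is.na(out$classification) | !nzchar(out$classification)
    if (any(bad))
        message("readMutationTable: dropped ", sum(bad),
                " record(s) with empty fields")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' @rdname readMutationTable
#' @param x mutation data.frame as returned by \code{readMutationTable}.
#' @export
writeMutationTable <- function(x, path, sampleCol = "DepMap_ID",
        geneCol = "Hugo_Symbol", classCol = "Variant_Classification",
        sep = NULL) {
    df <- data.frame(x$sample, x$gene, x$classification,
        stringsAsFactors = FALSE)
    colnames(df) <- c(sampleCol, geneCol, classCol)
    .writeTable(df, path, sep)
}

#' Read / write a sample-to-cancer-type annotation
#'
#' Two-column table (sample, cancer type). Every sample must map to exactly
#' one non-empty label.
#'
#' @param path file path.
#' @param sampleCol,typeCol column names.
#' @param sep optional separator override.
#' @return Named character vector, sample -> cancer type.
#' @export
readSampleAnnotation <- function(path, sampleCol = "DepMap_ID",
        typeCol = "primary_disease", sep = NULL) {
    df <- .readTable(path, sep, colClasses = "character")
    for (col in c(sampleCol, typeCol))
        if (!col %in% colnames(df))
            stop("required column '", col, "' not found in ", path)
    s <- df[[sampleCol]]; lab <- df[[typeCol]]
    if (anyDuplicated(s))
        stop("duplicate samples in annotation: ",
             paste(unique(s[duplicated(s)]), collapse = ", "))
    if (any(is.na(lab) | !nzchar(lab)))
        stop("every sample must carry a non-empty cancer-type label")
    stats::setNames(lab, s)
}

#' @rdname readSampleAnnotation
#' @param x named character vector (sample -> label).
#' @export
writeSampleAnnotation <- function(x, path, sampleCol = "DepMap_ID",
        typeCol = "primary_disease", sep = NULL) {
    df <- data.frame(names(x), unname(x), stringsAsFactors = FALSE)
    colnames(df) <- c(sampleCol, typeCol)
    .writeTable(df, path, sep)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member...}. Duplicate members within a
#' line are removed.
#'
#' @param path GMT file path.
#' @return Named list of sets; each element is a list with \code{description}
#'   and \code{genes}.
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        f <- f[nzchar(f)]
        if (length(f) < 3L)
            stop("GMT parse error at line ", i,
                 ": need name, description and at least one member")
        out[[f[[1L]]]] <- list(description = f[[2L]],
                               genes = unique(f[-c(1L, 2L)]))
    }
    out
}

#' Read a two-column yeast-to-human ortholog map
#'
#' @param path delimited file with a yeast column and a human column; a
#'   yeast gene may appear on several rows (one-to-many orthology).
#' @param sourceCol,targetCol column names (defaults \code{"yeast"} and
#'   \code{"human"}).
#' @param sep optional separator override.
#' @return Named list: yeast symbol -> character vector of human symbols.
#' @export
readOrthologMap <- function(path, sourceCol = "yeast", targetCol = "human",
        sep = NULL) {
    df <- .readTable(path, sep, colClasses = "character")
    for (col in c(sourceCol, targetCol))
        if (!col %in% colnames(df))
            stop("required column '", col, "' not found in ", path)
    src <- df[[sourceCol]]; tgt <- df[[targetCol]]
    ok <- !is.na(src) & nzchar(src) & !is.na(tgt) & nzchar(tgt)
    split(tgt[ok], src[ok]) |> lapply(unique)
}

#' Read / write a pairwise yeast genetic-interaction table
#'
#' TheCellMap pairwise layout: query gene, array gene, interaction score
#' epsilon, and p-value. Validates that p-values lie in [0, 1] and that
#' epsilon is finite.
#'
#' @param path file path.
#' @param queryCol,arrayCol,epsCol,pCol column names.
#' @param sep optional separator override.
#' @return data.frame with columns \code{query_gene}, \code{array_gene},
#'   \code{epsilon}, \code{p_value}.
#' @export
readYeastInteractions <- function(path, queryCol = "query_gene",
        arrayCol = "array_gene", epsCol = "epsilon", pCol = "p_value",
        sep = NULL) {
    df <- .readTable(path, sep)
    for (col in c(queryCol, arrayCol, epsCol, pCol))
        if (!col %in% colnames(df))
            stop("required column '", col, "' not found in ", path)
    out <- data.frame(query_gene = as.character(df[[queryCol]]),
        array_gene = as.character(df[[arrayCol]]),
        epsilon = as.numeric(df[[epsCol]]),
        p_value = as.numeric(df[[pCol]]), stringsAsFactors = FALSE)
    validateYeastInteractions(out)
}

#' @rdname readYeastInteractions
#' @param x yeast-interaction data.frame.
#' @export
writeYeastInteractions <- function(x, path, sep = NULL) {
    .writeTable(x, path, sep)
}

#' Validate a yeast-interaction table against its invariants
#'
#' @param x data.frame with columns \code{query_gene}, \code{array_gene},
#'   \code{epsilon}, \code{p_value}.
#' @return \code{x}, invisibly usable, after checks.
#' @export
validateYeastInteractions <- function(x) {
    need <- c("query_gene", "array_gene", "epsilon", "p_value")
    if (!all(need %in% colnames(x)))
        stop("yeast-interaction table needs columns: ",
             paste(need, collapse = ", "))
    if (any(!is.finite(x$epsilon)))
        stop("epsilon scores must be finite")
    if (any(is.na(x$p_value) | x$p_value < 0 | x$p_value > 1))
        stop("interaction p-values must lie in [0, 1]")
    self <- stripStrainSuffix(x$query_gene) == stripStrainSuffix(x$array_gene)
    if (any(self)) {
        message("validateYeastInteractions: dropped ", sum(self),
                " self-pair record(s)")
        x <- x[!self, , drop = FALSE]
    }
    x
}

#' Write / read a prediction or evidence table
#'
#' Writes any result data.frame that carries \code{p_value} and
#' \code{q_value} columns with a deterministic row order: ascending q, then
#' ascending p, then lexicographic on the remaining identifier columns.
#' Numeric columns are written in full precision so the companion reader
#' reproduces them exactly.
#'
#' @param x result data.frame (e.g. from [mdslpScreen()], [daisyScreen()],
#'   [enrichGeneSets()]).
#' @param path output path.
#' @param sep optional separator override.
#' @return The path, invisibly.
#' @export
writePredictions <- function(x, path, sep = NULL) {
    if (!all(c("p_value", "q_value") %in% colnames(x)))
        stop("prediction tables need 'p_value' and 'q_value' columns")
    if (nrow(x)) {
        idCols <- colnames(x)[vapply(x, is.character, logical(1L))]
        ord <- do.call(order, c(list(x$q_value, x$p_value),
            unname(as.list(x[idCols])), list(method = "radix")))
        x <- x[ord, , drop = FALSE]
    }
    .writeTable(x, path, sep)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path, sep = NULL) {
    df <- .readTable(path, sep)
    for (col in intersect(c("testable", "significant", "combined",
                            "pass_sof", "pass_funex", "pass_coexpression",
                            "degenerate"), colnames(df)))
        df[[col]] <- as.logical(df[[col]])
    df
}

#' Strip the strain/allele suffix from a yeast identifier
#'
#' SGA arrays encode alleles as \code{GENE_suffix}; orthology is gene-level,
#' so everything after the first underscore is removed before lookup.
#'
#' @param x character vector of yeast identifiers.
#' @return Character vector of bare gene identifiers.
#' @export
stripStrainSuffix <- function(x) sub("_.*$", "", x)
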