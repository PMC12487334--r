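#' @include AllClasses.R
NULL

#' Accessors for SVCohort and PopulationPanel
#'
#' \code{svType} returns the per-variant SV type; \code{svID} the variant ids;
#' \code{svLength} breakpoint-interval lengths in bp (\code{NA} for BND);
#' \code{genotypes} the ALT-dosage matrix; \code{dhffcMatrix} the per-call
#' DHFFC matrix (or \code{NULL}); \code{panelGroups} the group labels of a
#' panel; \code{panelSamples} the samples of one group (or all assigned
#' samples when \code{group} is missing).
#'
#' @param x an \code{SVCohort} or \code{PopulationPanel}.
#' @param group optional group label.
#' @return See description.
#' @name svatlas-accessors
NULL

#' @rdname svatlas-accessors
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))
#' @rdname svatlas-accessors
#' @export
setGeneric("svID", function(x) standardGeneric("svID"))
#' @rdname svatlas-accessors
#' @export
setGeneric("svLength", function(x) standardGeneric("svLength"))
#' @rdname svatlas-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname svatlas-accessors
#' @export
setGeneric("dhffcMatrix", function(x) standardGeneric("dhffcMatrix"))
#' @rdname svatlas-accessors
#' @export
setGeneric("panelGroups", function(x) standardGeneric("panelGroups"))
#' @rdname svatlas-accessors
#' @export
setGeneric("panelSamples", function(x, group) standardGeneric("panelSamples"))

#' @rdname svatlas-accessors
setMethod("svType", "SVCohort", function(x) {
    setNames(mcols(rowRanges(x))$svtype, rownames(x))
})

#' @rdname svatlas-accessors
setMethod("svID", "SVCohort", function(x) rownames(x))

#' @rdname svatlas-accessors
setMethod("svLength", "SVCohort", function(x) {
    len <- width(rowRanges(x))
    len[svType(x) == "BND"] <- NA_integer_
    setNames(len, rownames(x))
})

#' @rdname svatlas-accessors
setMethod("genotypes", "SVCohort", function(x) assay(x, "GT"))

#' @rdname svatlas-accessors
setMethod("dhffcMatrix", "SVCohort", function(x) {
    if ("DHFFC" %in% assayNames(x)) assay(x, "DHFFC") else NULL
})

#' @rdname svatlas-accessors
setMethod("panelGroups", "PopulationPanel", function(x) {
    unique(unname(x@assignment))
})

#' @rdname svatlas-accessors
setMethod("panelSamples", "PopulationPanel", function(x, group) {
    if (missing(group)) return(names(x@assignment))
    names(x@assignment)[x@assignment == group]
})

setMethod("show", "SVCohort", function(object) {
    tab <- table(factor(svType(object), levels = .SV_TYPES))
    cat(sprintf("SVCohort: %d SVs x %d samples (%s)\n",
                nrow(object), ncol(object),
                paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
    cat(sprintf("assays: %s\n", paste(assayNames(object), collapse = ", ")))
})

setMethod("show", "PopulationPanel", function(object) {
    tab <- table(object@assignment)
    cat(sprintf("PopulationPanel: %d samples in %d groups (%s); %d excluded\n",
                length(object@assignment), length(tab),
                paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
                length(object@excluded)))
})

setMethod("show", "GeneModelSet", function(object) {
    cat(sprintf("GeneModelSet: %d genes, %d transcripts\n",
                length(object@genes), nrow(object@txGene)))
})
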