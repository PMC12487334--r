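#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits split
#' @importFrom BiocGenerics sort unlist range
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end width
#'   findOverlaps countOverlaps pintersect reduce strand strand<- start<- end<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
#'   assay<- assays assayNames
NULL

.SV_TYPES <- c("DEL", "DUP", "INV", "BND")

#' SVCohort: genotyped structural variants for a sample cohort
#'
#' An \code{SVCohort} extends
#' \linkS4class{RangedSummarizedExperiment}: rows are structural variants
#' (breakpoint intervals carried as a \code{GRanges} with an \code{svtype}
#' metadata column), columns are samples. The \code{"GT"} assay holds diploid
#' genotypes coded as ALT-allele dosage (0 = hom ref, 1 = het, 2 = hom alt,
#' \code{NA} = missing). The optional \code{"DHFFC"} assay holds the per-call
#' depth fold-change of the variant interval relative to its flanks
#' (\code{NA} = no depth evidence).
#'
#' @slot ... inherited from \code{RangedSummarizedExperiment}.
#' @export
setClass("SVCohort", contains = "RangedSummarizedExperiment")

setValidity("SVCohort", function(object) {
    msg <- character()
    if (!"GT" %in% assayNames(object))
        msg <- c(msg, "assay 'GT' is required")
    rr <- rowRanges(object)
    if (is.null(mcols(rr)$svtype))
        msg <- c(msg, "rowRanges must carry an 'svtype' metadata column")
    else if (!all(mcols(rr)$svtype %in% .SV_TYPES))
        msg <- c(msg, sprintf("svtype values must be in {%s}",
                              paste(.SV_TYPES, collapse = ", ")))
    if (length(rr) && (is.null(names(rr)) || anyDuplicated(names(rr))))
        msg <- c(msg, "SV ids (names of rowRanges) must be present and unique")
    if ("GT" %in% assayNames(object)) {
        gt <- assay(object, "GT")
        bad <- gt[!is.na(gt)]
        if (length(bad) && !all(bad %in% 0:2))
            msg <- c(msg, "GT assay values must be 0, 1, 2 or NA")
    }
    if ("DHFFC" %in% assayNames(object)) {
        dh <- assay(object, "DHFFC")
        if (any(dh[!is.na(dh)] < 0))
            msg <- c(msg, "DHFFC values must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an SVCohort
#'
#' @param ranges \code{GRanges} of SV breakpoint intervals; names are SV ids.
#' @param svtype character vector, one of \code{DEL, DUP, INV, BND} per SV.
#' @param gt integer matrix of ALT dosages (SVs x samples); \code{NA} missing.
#' @param dhffc optional numeric matrix of per-call DHFFC values, same shape.
#' @return An \code{SVCohort}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' names(gr) <- "sv1"
#' gt <- matrix(c(0L, 1L, 2L), 1, dimnames = list("sv1", c("s1", "s2", "s3")))
#' SVCohort(gr, svtype = "DEL", gt = gt)
#' @export
SVCohort <- function(ranges, svtype, gt, dhffc = NULL) {
    stopifnot(is(ranges, "GRanges"))
    if (is.null(dim(gt)))
        gt <- matrix(gt, nrow = length(ranges))
    storage.mode(gt) <- "integer"
    mcols(ranges)$svtype <- as.character(svtype)
    assays <- list(GT = gt)
    if (!is.null(dhffc)) {
        storage.mode(dhffc) <- "double"
        assays$DHFFC <- dhffc
    }
    se <- SummarizedExperiment(assays = assays, rowRanges = ranges)
    rownames(se) <- names(ranges)
    new("SVCohort", se)
}

#' PopulationPanel: sample-to-population assignment
#'
#' Maps each sample to one population label and records samples excluded from
#' all statistics (e.g. experimentally produced F1 hybrids).
#'
#' @slot assignment named character vector, sample -> group label.
#' @slot excluded character vector of excluded sample ids.
#' @export
setClass("PopulationPanel",
         representation(assignment = "character", excluded = "character"))

setValidity("PopulationPanel", function(object) {
    msg <- character()
    smp <- names(object@assignment)
    if (length(smp) && (is.null(smp) || anyDuplicated(smp)))
        msg <- c(msg, "each sample may be assigned to at most one group")
    if (any(object@excluded %in% smp))
        msg <- c(msg, "excluded samples must not appear in any group")
    if (length(msg)) msg else TRUE
})

#' @rdname PopulationPanel-class
#' @param assignment named character vector mapping sample id to group label.
#' @param excluded character vector of samples kept out of every statistic.
#' @return A \code{PopulationPanel}.
#' @export
PopulationPanel <- function(assignment = character(), excluded = character()) {
    new("PopulationPanel", assignment = assignment,
        excluded = as.character(excluded))
}

#' GeneModelSet: gene/transcript/exon/CDS geometry
#'
#' A light transcript-model container for consequence classification. Gene
#' bodies are a named \code{GRanges} (strand on the range); per-transcript
#' exon, CDS and UTR intervals are \code{GRangesList}s keyed by transcript id.
#'
#' @slot genes named \code{GRanges} of gene bodies.
#' @slot txGene data.frame with columns \code{tx_id}, \code{gene_id}.
#' @slot exons,cds,utr5,utr3 \code{GRangesList} keyed by transcript id.
#' @export
setClass("GeneModelSet",
         representation(genes = "GRanges", txGene = "data.frame",
                        exons = "GRangesList", cds = "GRangesList",
                        utr5 = "GRangesList", utr3 = "GRangesList"))

## transcripts whose CDS is not fully covered by their exon union
.cdsOutsideExons <- function(cds, exons) {
    cds <- cds[names(cds) %in% names(exons)]
    if (!length(cds)) return(character(0))
    ul_cds <- unlist(cds, use.names = TRUE)
    ul_ex <- unlist(exons, use.names = TRUE)
    hits <- findOverlaps(ul_cds, ul_ex, ignore.strand = TRUE)
    same <- names(ul_cds)[queryHits(hits)] == names(ul_ex)[subjectHits(hits)]
    hits <- hits[same]
    cov <- rep(0L, length(ul_cds))
    ovw <- width(pintersect(ul_cds[queryHits(hits)], ul_ex[subjectHits(hits)],
                            ignore.strand = TRUE))
    agg <- tapply(ovw, queryHits(hits), sum)
    cov[as.integer(names(agg))] <- as.integer(agg)
    unique(names(ul_cds)[cov < width(ul_cds)])
}

setValidity("GeneModelSet", function(object) {
    msg <- character()
    if (length(object@genes) &&
        (is.null(names(object@genes)) || anyDuplicated(names(object@genes))))
        msg <- c(msg, "gene ids must be present and unique")
    if (!all(object@txGene$gene_id %in% names(object@genes)))
        msg <- c(msg, "every transcript must point at a known gene")
    bad <- .cdsOutsideExons(object@cds, object@exons)
    if (length(bad))
        msg <- c(msg, sprintf("CDS extends outside exons for transcript(s): %s",
                              paste(utils::head(bad, 3), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @rdname GeneModelSet-class
#' @param genes named \code{GRanges} of gene bodies (strand set).
#' @param txGene data.frame with columns \code{tx_id} and \code{gene_id}.
#' @param exons,cds,utr5,utr3 \code{GRangesList} keyed by transcript id.
#' @return A \code{GeneModelSet}.
#' @export
GeneModelSet <- function(genes = GRanges(), txGene = data.frame(
                             tx_id = character(), gene_id = character()),
                         exons = GRangesList(), cds = GRangesList(),
                         utr5 = GRangesList(), utr3 = GRangesList()) {
    new("GeneModelSet", genes = genes, txGene = txGene, exons = exons,
        cds = cds, utr5 = utr5, utr3 = utr3)
}

#' FilterConfig: thresholds of the post-calling filter cascade
#'
#' Houses the five filter-step thresholds: chromosome whitelist, high-depth
#' cutoff (depth units), DHFFC masking thresholds per SV type, minimum ALT
#' allele count, minimum genotype call rate, and the flank width used when
#' DHFFC is recomputed from a depth track.
#'
#' @slot chromWhitelist character; empty means "accept all chromosomes".
#' @slot depthThreshold numeric, strict lower bound defining high-depth regions.
#' @slot dhffcDelMax,dhffcDupMin numeric DHFFC masking thresholds (strict).
#' @slot dhffcInvBand numeric length-2 open interval masking inversions.
#' @slot minAlleleCount integer; sites with AC < this are removed (AC <= 2 by default).
#' @slot minCallRate numeric in (0, 1]; sites below are removed (>= survives).
#' @slot flankBp integer flank width in bp for DHFFC computation.
#' @export
setClass("FilterConfig",
         representation(chromWhitelist = "character", depthThreshold = "numeric",
                        dhffcDelMax = "numeric", dhffcDupMin = "numeric",
                        dhffcInvBand = "numeric", minAlleleCount = "integer",
                        minCallRate = "numeric", flankBp = "integer"))

setValidity("FilterConfig", function(object) {
    msg <- character()
    if (!(object@dhffcDelMax > 0 && object@dhffcDelMax < object@dhffcDupMin))
        msg <- c(msg, "need 0 < dhffcDelMax < dhffcDupMin")
    if (!(object@minCallRate > 0 && object@minCallRate <= 1))
        msg <- c(msg, "minCallRate must be in (0, 1]")
    if (length(object@dhffcInvBand) != 2 || diff(object@dhffcInvBand) <= 0)
        msg <- c(msg, "dhffcInvBand must be an increasing length-2 interval")
    if (length(msg)) msg else TRUE
})

#' @rdname FilterConfig-class
#' @param chromWhitelist,depthThreshold,dhffcDelMax,dhffcDupMin,dhffcInvBand
#'   see slots.
#' @param minAlleleCount,minCallRate,flankBp see slots.
#' @return A \code{FilterConfig}.
#' @export
filterConfig <- function(chromWhitelist = character(), depthThreshold = 100,
                         dhffcDelMax = 0.7, dhffcDupMin = 1.3,
                         dhffcInvBand = c(0.7, 1.3), minAlleleCount = 3L,
                         minCallRate = 0.80, flankBp = 1000L) {
    new("FilterConfig", chromWhitelist = as.character(chromWhitelist),
        depthThreshold = depthThreshold, dhffcDelMax = dhffcDelMax,
        dhffcDupMin = dhffcDupMin, dhffcInvBand = dhffcInvBand,
        minAlleleCount = as.integer(minAlleleCount),
        minCallRate = minCallRate, flankBp = as.integer(flankBp))
}
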