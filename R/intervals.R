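#' @include AllClasses.R
NULL

.ids_of <- function(gr) {
    if (is.null(names(gr))) as.character(seq_along(gr)) else names(gr)
}

#' Reciprocal-overlap join of two interval sets
#'
#' Reports every same-chromosome pair with at least \code{minBp} overlapping
#' bases whose reciprocal overlap fraction (the smaller of overlap/query
#' length and overlap/subject length) is at least \code{minRecip}. With
#' \code{minRecip = 0.5} this reproduces the semantics of
#' \code{bedtools intersect -wo -f 0.50 -r} (inclusive thresholds).
#'
#' @param queries,subjects \code{GRanges}; names are used as ids.
#' @param minBp minimum overlap in bp (default 1).
#' @param minRecip minimum reciprocal overlap fraction in [0, 1] (default 0).
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{overlap_bp}, \code{frac_query}, \code{frac_subject}.
#' @export
overlapJoin <- function(queries, subjects, minBp = 1L, minRecip = 0) {
    hits <- suppressWarnings(findOverlaps(queries, subjects,
                                          minoverlap = minBp,
                                          ignore.strand = TRUE))
    q <- queryHits(hits); s <- subjectHits(hits)
    ov <- suppressWarnings(
        width(pintersect(granges(queries)[q], granges(subjects)[s])))
    fq <- ov / width(queries)[q]
    fs <- ov / width(subjects)[s]
    keep <- pmin(fq, fs) >= minRecip
    data.frame(query_id = .ids_of(queries)[q][keep],
               subject_id = .ids_of(subjects)[s][keep],
               overlap_bp = ov[keep], frac_query = fq[keep],
               frac_subject = fs[keep], stringsAsFactors = FALSE)
}

#' Summarise SV overlap with constrained (GERP) elements
#'
#' Joins SVs against constrained elements with a 1-bp minimum overlap and
#' reports per-SV element counts plus global summaries: mean/SD of the length
#' of the distinct overlapped elements and mean/SD of the per-pair overlap
#' lengths. SDs are population SDs by default (\code{popSD = FALSE} gives the
#' sample SD).
#'
#' @param svs \code{GRanges} of SV intervals (named).
#' @param elements \code{GRanges} of constrained elements (named).
#' @param popSD use the population (divide-by-n) standard deviation.
#' @return List with \code{pairs}, \code{perSV} (sv_id, n_elements,
#'   total_overlap_bp), \code{elementLength} and \code{overlapLength}
#'   (each \code{c(mean, sd)}, \code{NULL} when nothing overlaps),
#'   \code{nSVs}, \code{nElements}.
#' @export
summarizeGerpOverlap <- function(svs, elements, popSD = TRUE) {
    if (is.null(names(elements))) names(elements) <- paste0("el", seq_along(elements), recycle0 = TRUE)
    pairs <- overlapJoin(svs, elements, minBp = 1L)
    sdev <- function(v) {
        if (length(v) < 1) return(NA_real_)
        if (popSD) sqrt(mean((v - mean(v))^2)) else stats::sd(v)
    }
    if (!nrow(pairs))
        return(list(pairs = pairs, perSV = data.frame(
            sv_id = character(), n_elements = integer(),
            total_overlap_bp = integer()), elementLength = NULL,
            overlapLength = NULL, nSVs = 0L, nElements = 0L))
    agg <- stats::aggregate(pairs$overlap_bp, by = list(sv_id = pairs$query_id),
                            FUN = function(v) c(n = length(v), tot = sum(v)))
    perSV <- data.frame(sv_id = agg$sv_id, n_elements = agg$x[, "n"],
                        total_overlap_bp = agg$x[, "tot"])
    el <- unique(pairs$subject_id)
    ellen <- width(elements)[match(el, names(elements))]
    list(pairs = pairs, perSV = perSV,
         elementLength = c(mean = mean(ellen), sd = sdev(ellen)),
         overlapLength = c(mean = mean(pairs$overlap_bp),
                           sd = sdev(pairs$overlap_bp)),
         nSVs = length(unique(pairs$query_id)), nElements = length(el))
}

#' Clusters of putatively redundant same-type SVs
#'
#' Single-linkage clusters of records of the same SV type whose pairwise
#' reciprocal overlap strictly exceeds \code{minRecip} (default > 0.95,
#' flagging records likely representing the same variant with slightly
#' different breakpoints).
#'
#' @param ranges named \code{GRanges} of SV intervals.
#' @param svtype character vector of SV types aligned with \code{ranges}.
#' @param minRecip strict reciprocal-overlap threshold (default 0.95).
#' @return List of clusters; each element has \code{ids}, \code{start_spread}
#'   and \code{end_spread} (bp range of member breakpoints). Only clusters of
#'   two or more records are returned.
#' @export
findRedundantSVs <- function(ranges, svtype, minRecip = 0.95) {
    stopifnot(length(ranges) == length(svtype))
    n <- length(ranges)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    hits <- findOverlaps(ranges, drop.self = TRUE, drop.redundant = TRUE,
                         ignore.strand = TRUE)
    q <- queryHits(hits); s <- subjectHits(hits)
    same <- svtype[q] == svtype[s]
    q <- q[same]; s <- s[same]
    if (length(q)) {
        ov <- width(pintersect(granges(ranges)[q], granges(ranges)[s]))
        recip <- pmin(ov / width(ranges)[q], ov / width(ranges)[s])
        link <- recip > minRecip
        for (k in which(link)) {
            a <- find(q[k]); b <- find(s[k])
            if (a != b) parent[b] <- a
        }
    }
    root <- vapply(seq_len(n), find, integer(1))
    ids <- .ids_of(ranges)
    out <- lapply(split(seq_len(n), root), function(members) {
        if (length(members) < 2) return(NULL)
        list(ids = ids[members],
             start_spread = diff(range(start(ranges)[members])),
             end_spread = diff(range(end(ranges)[members])))
    })
    unname(Filter(Negate(is.null), out))
}

.sv_key <- function(ranges, svtype) {
    paste(as.character(seqnames(ranges)), start(ranges), end(ranges), svtype,
          sep = ":")
}

#' Merge two SV call sets through a jointly genotyped combined set
#'
#' A record of the combined (jointly genotyped) set is retained iff it
#' matches a record of either source set at 100% reciprocal overlap with the
#' same SV type — i.e. identical chromosome, start and end. Returns the
#' retained combined records and the fraction of each source set captured.
#'
#' @param setA,setB named \code{GRanges} with an \code{svtype} metadata
#'   column (e.g. \code{rowRanges} of an \code{SVCohort}), the two
#'   independently filtered high-confidence sets.
#' @param combined an \code{SVCohort} genotyped across the union roster.
#' @return List with \code{cohort} (retained combined records),
#'   \code{captureA}, \code{captureB} (fractions in [0, 1]) and
#'   \code{n_multi} (combined records matching more than one source record;
#'   counted once).
#' @export
mergeSVSets <- function(setA, setB, combined) {
    keyA <- .sv_key(setA, mcols(setA)$svtype)
    keyB <- .sv_key(setB, mcols(setB)$svtype)
    rr <- rowRanges(combined)
    keyC <- .sv_key(rr, mcols(rr)$svtype)
    keep <- keyC %in% keyA | keyC %in% keyB
    dupA <- sum(duplicated(keyA[keyA %in% keyC]))
    dupB <- sum(duplicated(keyB[keyB %in% keyC]))
    if (dupA + dupB > 0)
        message(sprintf("%d source record(s) share coordinates with another; counted once",
                        dupA + dupB))
    list(cohort = combined[keep, ],
         captureA = mean(keyA %in% keyC),
         captureB = mean(keyB %in% keyC),
         n_multi = dupA + dupB)
}
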