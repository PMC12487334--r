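#' @include AllClasses.R
NULL

.check_track <- function(track) {
    if (is.null(mcols(track)$depth)) stop("depth track lacks a 'depth' column")
    if (any(countOverlaps(track, track) > 1L))
        stop("depth track segments overlap")
    invisible(track)
}

#' High-depth regions of a depth track
#'
#' Maximal merged intervals where the track's mean depth strictly exceeds
#' \code{threshold}. Regions of this kind (by default > 100x) are dominated
#' by false-positive SV calls and are excluded by the filter cascade.
#'
#' @param track depth track \code{GRanges} (non-overlapping segments with a
#'   \code{depth} metadata column).
#' @param threshold strict depth cutoff (default 100).
#' @return \code{GRanges} of merged high-depth intervals.
#' @export
highDepthRegions <- function(track, threshold = 100) {
    .check_track(track)
    reduce(granges(track[mcols(track)$depth > threshold]))
}

#' Depth fold-change of an SV interval versus its flanks (DHFFC)
#'
#' Length-weighted mean depth inside each interval divided by the
#' length-weighted mean depth over both flanks jointly (each flank
#' \code{flankBp} wide, clipped at the track extent of the chromosome).
#' A zero flank mean yields \code{NA} (no depth evidence).
#'
#' @param track depth track \code{GRanges}.
#' @param sv \code{GRanges} of SV intervals (fully covered by the track).
#' @param flankBp flank width in bp (default 1000).
#' @return Numeric vector of DHFFC values, one per interval.
#' @export
computeDHFFC <- function(track, sv, flankBp = 1000L) {
    .check_track(track)
    meanDepth <- function(region) {
        hits <- findOverlaps(region, track)
        if (!length(hits)) return(NA_real_)
        ov <- width(pintersect(region[queryHits(hits)], track[subjectHits(hits)]))
        sum(ov * mcols(track)$depth[subjectHits(hits)]) / sum(ov)
    }
    covered <- function(region) {
        hits <- findOverlaps(region, track)
        sum(width(pintersect(region[queryHits(hits)], track[subjectHits(hits)])))
    }
    ext <- unlist(range(split(granges(track), seqnames(track))))
    vapply(seq_along(sv), function(i) {
        r <- granges(sv[i])
        chr <- as.character(seqnames(r))
        if (!chr %in% names(ext) || covered(r) < width(r))
            stop(sprintf("SV interval %s:%d-%d extends outside the depth track",
                         chr, start(r), end(r)))
        lo <- start(ext[chr]); hi <- end(ext[chr])
        left <- GRanges(chr, IRanges(max(lo, start(r) - flankBp),
                                     max(lo, start(r) - 1L)))
        right <- GRanges(chr, IRanges(min(hi, end(r) + 1L),
                                      min(hi, end(r) + flankBp)))
        flanks <- c(left, right)
        flanks <- flanks[width(flanks) > 0 & end(flanks) >= start(flanks) &
                         !(start(r) - 1L < lo & end(flanks) < start(r)) &
                         !(end(r) + 1L > hi & start(flanks) > end(r))]
        fl <- meanDepth(flanks)
        if (is.na(fl) || fl == 0) return(NA_real_)
        meanDepth(r) / fl
    }, numeric(1))
}

.report_row <- function(step, input, removed) {
    data.frame(step = step, input = input, removed = removed,
               surviving = input - removed, stringsAsFactors = FALSE)
}

#' Site-level filters: chromosome whitelist, translocations, gaps, high depth
#'
#' Removes records whose chromosome is off the whitelist, all BND
#' (translocation) records, and records overlapping (by >= 1 bp) any assembly
#' gap or high-depth interval.
#'
#' @param x an \code{SVCohort}.
#' @param config a \code{FilterConfig}.
#' @param gaps \code{GRanges} of assembly gaps (may be empty).
#' @param highDepth \code{GRanges} of high-depth intervals (may be empty).
#' @return List with \code{cohort} (survivors), \code{report} (telescoping
#'   per-step counts) and \code{reasons} (named removal reason per dropped id).
#' @export
filterSites <- function(x, config, gaps = GRanges(), highDepth = GRanges()) {
    reasons <- character(0)
    report <- NULL
    drop_step <- function(x, step, bad) {
        reasons <<- c(reasons, setNames(rep(step, sum(bad)), rownames(x)[bad]))
        report <<- rbind(report, .report_row(step, nrow(x), sum(bad)))
        x[!bad, ]
    }
    if (length(config@chromWhitelist)) {
        bad <- !(as.character(seqnames(rowRanges(x))) %in% config@chromWhitelist)
    } else bad <- rep(FALSE, nrow(x))
    x <- drop_step(x, "chromosome", bad)
    x <- drop_step(x, "translocation", unname(svType(x)) == "BND")
    x <- drop_step(x, "gap_overlap",
                   countOverlaps(rowRanges(x), gaps) > 0L)
    x <- drop_step(x, "high_depth",
                   countOverlaps(rowRanges(x), highDepth) > 0L)
    list(cohort = x, report = report, reasons = reasons)
}

#' Mask carrier genotypes with depth-inconsistent DHFFC
#'
#' Carrier genotypes (het or hom-alt) are replaced by missing when the
#' per-call DHFFC contradicts the SV type: deletions with DHFFC > 0.7
#' (no depth drop), duplications with DHFFC < 1.3 (no depth gain), and
#' inversions with DHFFC strictly between 0.7 and 1.3. All inequalities are
#' strict. Hom-ref and already-missing calls are never touched; calls without
#' DHFFC evidence are retained.
#'
#' @param x an \code{SVCohort} carrying a \code{DHFFC} assay.
#' @param config a \code{FilterConfig}.
#' @return List with \code{cohort} (genotypes masked), \code{masked} (logical
#'   matrix of masked cells) and \code{report} (one row; \code{removed} = 0,
#'   masked-call count in \code{n_masked}).
#' @export
maskGenotypesDHFFC <- function(x, config) {
    gt <- genotypes(x)
    dh <- dhffcMatrix(x)
    if (is.null(dh)) stop("cohort has no DHFFC assay; compute or read it first")
    svt <- unname(svType(x))
    carrier <- !is.na(gt) & gt > 0L
    bad <- matrix(FALSE, nrow(gt), ncol(gt))
    del <- svt == "DEL"; dup <- svt == "DUP"; inv <- svt == "INV"
    bad[del, ] <- !is.na(dh[del, , drop = FALSE]) &
        dh[del, , drop = FALSE] > config@dhffcDelMax
    bad[dup, ] <- !is.na(dh[dup, , drop = FALSE]) &
        dh[dup, , drop = FALSE] < config@dhffcDupMin
    bad[inv, ] <- !is.na(dh[inv, , drop = FALSE]) &
        dh[inv, , drop = FALSE] > config@dhffcInvBand[1] &
        dh[inv, , drop = FALSE] < config@dhffcInvBand[2]
    masked <- carrier & bad
    gt[masked] <- NA_integer_
    assay(x, "GT") <- gt
    rep <- .report_row("dhffc_mask", nrow(x), 0L)
    rep$n_masked <- sum(masked)
    list(cohort = x, masked = masked, report = rep)
}

#' Allele-count and call-rate site filter
#'
#' Applied after DHFFC masking. The ALT allele count is recomputed over
#' non-missing genotypes (het = 1, hom-alt = 2); the call rate is the
#' fraction of samples with a non-missing call. Sites with
#' \code{AC < minAlleleCount} (default: AC <= 2 removed) or call rate
#' strictly below \code{minCallRate} are removed; a rate of exactly 0.80
#' survives.
#'
#' @inheritParams filterSites
#' @return List with \code{cohort}, \code{report}, \code{reasons}.
#' @export
filterACCallRate <- function(x, config) {
    gt <- genotypes(x)
    ac <- rowSums(gt, na.rm = TRUE)
    rate <- rowMeans(!is.na(gt))
    bad <- ac < config@minAlleleCount | rate < config@minCallRate
    reasons <- setNames(ifelse(ac[bad] < config@minAlleleCount,
                               "low_allele_count", "low_call_rate"),
                        rownames(x)[bad])
    list(cohort = x[!bad, ], report = .report_row("ac_callrate", nrow(x), sum(bad)),
         reasons = reasons)
}

#' Run the five-step post-calling filter cascade
#'
#' In order: (i) chromosome whitelist, (ii) translocation removal, (iii)
#' assembly-gap and high-depth exclusion, (iv) DHFFC genotype masking, (v)
#' allele-count / call-rate filtering on the masked genotypes. A visual
#' curation stage is recorded as a pass-through step ("curation pending");
#' manual scoring is outside this package. The per-step report telescopes
#' (input - removed = surviving at every step).
#'
#' @param x an \code{SVCohort}.
#' @param config a \code{FilterConfig}.
#' @param gaps \code{GRanges} of assembly gaps.
#' @param highDepth either precomputed high-depth \code{GRanges} or a depth
#'   track (a \code{GRanges} with a \code{depth} column), in which case
#'   \code{\link{highDepthRegions}} is applied first.
#' @return List with \code{cohort} (survivors), \code{report} (data.frame of
#'   step, input, removed, surviving, n_masked), \code{reasons} (named
#'   per-record removal reason), \code{masked} (logical matrix over the
#'   post-site-filter cohort).
#' @export
runFilterCascade <- function(x, config = filterConfig(), gaps = GRanges(),
                             highDepth = GRanges()) {
    if (!is.null(mcols(highDepth)$depth))
        highDepth <- highDepthRegions(highDepth, config@depthThreshold)
    s1 <- filterSites(x, config, gaps = gaps, highDepth = highDepth)
    if ("DHFFC" %in% assayNames(s1$cohort)) {
        s2 <- maskGenotypesDHFFC(s1$cohort, config)
    } else {
        rep2 <- .report_row("dhffc_mask", nrow(s1$cohort), 0L)
        rep2$n_masked <- 0L
        s2 <- list(cohort = s1$cohort, report = rep2,
                   masked = matrix(FALSE, nrow(s1$cohort), ncol(s1$cohort)))
    }
    s3 <- filterACCallRate(s2$cohort, config)
    report <- data.table::rbindlist(list(s1$report, s2$report, s3$report,
                                         .report_row("curation_pending",
                                                     nrow(s3$cohort), 0L)),
                                    fill = TRUE)
    report <- as.data.frame(report)
    report$n_masked[is.na(report$n_masked)] <- 0L
    list(cohort = s3$cohort, report = report,
         reasons = c(s1$reasons, s3$reasons), masked = s2$masked)
}
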