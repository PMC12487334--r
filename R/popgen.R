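#' @include AllClasses.R
NULL

#' Per-SV allele statistics
#'
#' ALT allele frequency, minor allele frequency, allele counts and call rate,
#' computed over non-missing genotypes of the chosen samples. Sites with no
#' called genotype get \code{NA} statistics and \code{defined = FALSE}.
#'
#' @param x an \code{SVCohort}.
#' @param samples optional character vector restricting the computation.
#' @return data.frame with \code{sv_id}, \code{af}, \code{maf}, \code{ac},
#'   \code{an}, \code{call_rate}, \code{defined}.
#' @export
alleleStats <- function(x, samples = NULL) {
    gt <- genotypes(x)
    if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
    called <- rowSums(!is.na(gt))
    ac <- rowSums(gt, na.rm = TRUE)
    an <- 2L * called
    af <- ifelse(an > 0, ac / an, NA_real_)
    data.frame(sv_id = rownames(gt), af = af, maf = pmin(af, 1 - af),
               ac = ac, an = an, call_rate = called / ncol(gt),
               defined = an > 0, stringsAsFactors = FALSE)
}

#' Per-site Weir & Cockerham F_ST for two populations
#'
#' The 1984 variance-component estimator for diploid data: for each SV the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) components are computed from the two groups' sample
#' sizes, ALT allele frequencies and observed heterozygosities;
#' theta = a / (a + b + c). Sites monomorphic across both groups have
#' a + b + c = 0 and an undefined theta (NA, flagged). Negative estimates are
#' retained. \code{delta_af} is the signed frequency difference
#' (group1 - group2). The ratio-of-averages estimate
#' \code{sum(a) / sum(a+b+c)} over defined sites is attached as attribute
#' \code{"ratio_of_averages"}.
#'
#' @param x an \code{SVCohort}.
#' @param panel a \code{PopulationPanel}.
#' @param group1,group2 group labels (group1 first in \code{delta_af}).
#' @return data.frame with \code{sv_id}, \code{comparison}, \code{a},
#'   \code{b}, \code{c}, \code{theta}, \code{delta_af}, \code{defined}.
#' @export
wcFst <- function(x, panel, group1, group2) {
    gt1 <- genotypes(x)[, intersect(colnames(x), panelSamples(panel, group1)),
                        drop = FALSE]
    gt2 <- genotypes(x)[, intersect(colnames(x), panelSamples(panel, group2)),
                        drop = FALSE]
    comp <- sprintf("%s_vs_%s", group1, group2)
    n1 <- rowSums(!is.na(gt1)); n2 <- rowSums(!is.na(gt2))
    p1 <- rowSums(gt1, na.rm = TRUE) / (2 * n1)
    p2 <- rowSums(gt2, na.rm = TRUE) / (2 * n2)
    h1 <- rowSums(gt1 == 1L, na.rm = TRUE) / n1
    h2 <- rowSums(gt2 == 1L, na.rm = TRUE) / n2
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    usable <- n1 >= 2 & n2 >= 2
    a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
    denom <- a + b + cc
    theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
    out <- data.frame(sv_id = rownames(x), comparison = comp, a = a, b = b,
                      c = cc, theta = theta, delta_af = p1 - p2,
                      defined = !is.na(theta), stringsAsFactors = FALSE)
    ok <- out$defined
    attr(out, "ratio_of_averages") <- sum(a[ok]) / sum(denom[ok])
    out
}

#' SV density in fixed windows along the genome
#'
#' Each SV is assigned to the window containing its start coordinate.
#' Windows with counts strictly above \code{high} are HIGH, strictly below
#' \code{low} are LOW, otherwise NORMAL. Trailing partial windows are
#' reported with their raw count and flagged.
#'
#' @param ranges \code{GRanges} of SV intervals.
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param windowBp window size in bp (default 1 Mb).
#' @param high,low strict count thresholds (defaults 80 and 10 per Mb).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{count}, \code{class}, \code{partial}.
#' @export
svDensity <- function(ranges, chromLengths, windowBp = 1e6L, high = 80L,
                      low = 10L) {
    chr <- as.character(seqnames(ranges))
    if (!all(chr %in% names(chromLengths)))
        stop("every SV chromosome must be present in chromLengths")
    out <- lapply(names(chromLengths), function(cn) {
        len <- chromLengths[[cn]]
        nwin <- max(1L, as.integer(ceiling(len / windowBp)))
        ws <- (seq_len(nwin) - 1L) * windowBp + 1L
        we <- pmin(ws + windowBp - 1L, len)
        pos <- start(ranges)[chr == cn]
        idx <- pmin(((pos - 1L) %/% windowBp) + 1L, nwin)
        cnt <- tabulate(idx, nbins = nwin)
        data.frame(chrom = cn, start = ws, end = we, count = cnt,
                   class = ifelse(cnt > high, "HIGH",
                                  ifelse(cnt < low, "LOW", "NORMAL")),
                   partial = we - ws + 1L < windowBp,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Dataset-level size and MAF summaries
#'
#' Per-type counts, cumulative length, mean/median length, counts in the
#' [50, 1000) and [1000, 10000) bp size classes, the overall fraction of SVs
#' shorter than 1.5 kb, a MAF histogram (bins of 0.05) and the count of SVs
#' with MAF < 0.05.
#'
#' @param svtype character vector of SV types.
#' @param lengths integer vector of SV lengths in bp (NA for BND).
#' @param maf numeric vector of minor allele frequencies.
#' @return List with \code{perType} (data.frame) and scalar summaries.
#' @export
sizeMafSummaries <- function(svtype, lengths, maf = NULL) {
    ok <- !is.na(lengths)
    tys <- sort(unique(svtype[ok]))
    perType <- do.call(rbind, lapply(tys, function(t) {
        l <- lengths[ok & svtype == t]
        data.frame(svtype = t, n = length(l), total_bp = sum(l),
                   mean_bp = mean(l), median_bp = stats::median(l),
                   n_50_1000 = sum(l >= 50 & l < 1000),
                   n_1000_10000 = sum(l >= 1000 & l < 10000),
                   stringsAsFactors = FALSE)
    }))
    out <- list(perType = perType,
                n = sum(ok), total_bp = sum(lengths[ok]),
                mean_bp = mean(lengths[ok]),
                median_bp = stats::median(lengths[ok]),
                frac_lt_1500 = mean(lengths[ok] < 1500))
    if (!is.null(maf)) {
        m <- maf[!is.na(maf)]
        out$maf_hist <- stats::setNames(
            as.integer(table(cut(m, breaks = seq(0, 0.5, 0.05),
                                 include.lowest = TRUE, right = FALSE))),
            levels(cut(m, breaks = seq(0, 0.5, 0.05), include.lowest = TRUE,
                       right = FALSE)))
        out$n_maf_lt_0.05 <- sum(m < 0.05)
    }
    out
}

#' PCA of SV genotypes
#'
#' Genotypes are coded 0/1/2, missing calls are imputed with the per-SV mean,
#' each SV is centred (optionally scaled) and the top components are taken
#' from the singular value decomposition of the sample-by-SV matrix.
#' Deterministic up to sign.
#'
#' @param x an \code{SVCohort}.
#' @param nComponents number of components to return.
#' @param scale. scale each SV to unit variance (default \code{FALSE}).
#' @param samples optional character vector of samples to include.
#' @return List with \code{coordinates} (samples x components),
#'   \code{explained} (proportion of variance per component, non-increasing)
#'   and \code{sdev}.
#' @export
genotypePCA <- function(x, nComponents = 2L, scale. = FALSE, samples = NULL) {
    gt <- genotypes(x)
    if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
    if (ncol(gt) < nComponents)
        stop("fewer samples than requested components")
    G <- t(gt)
    mu <- colMeans(G, na.rm = TRUE)
    for (j in seq_len(ncol(G))) {
        miss <- is.na(G[, j])
        if (any(miss)) G[miss, j] <- mu[j]
    }
    G <- sweep(G, 2L, mu)
    if (scale.) {
        sdv <- apply(G, 2L, stats::sd)
        sdv[sdv == 0] <- 1
        G <- sweep(G, 2L, sdv, "/")
    }
    sv <- svd(G, nu = nComponents, nv = 0)
    coords <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
    rownames(coords) <- rownames(G)
    colnames(coords) <- paste0("PC", seq_len(nComponents))
    list(coordinates = coords,
         explained = sv$d[seq_len(nComponents)]^2 / sum(sv$d^2),
         sdev = sv$d / sqrt(max(1, nrow(G) - 1)))
}
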