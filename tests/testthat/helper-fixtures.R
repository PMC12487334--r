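## shared fixture builders; everything is generated in code at test time

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## a small cohort from explicit coordinates/genotypes
make_cohort <- function(chrom, start, end, svtype, gt, dhffc = NULL,
                        ids = NULL) {
    gr <- GRanges(chrom, IRanges(start, end))
    names(gr) <- if (is.null(ids)) paste0("sv", seq_along(gr)) else ids
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(gr), byrow = TRUE)
    if (is.null(colnames(gt))) colnames(gt) <- paste0("s", seq_len(ncol(gt)))
    rownames(gt) <- names(gr)
    if (!is.null(dhffc)) {
        if (is.null(dim(dhffc)))
            dhffc <- matrix(dhffc, nrow = length(gr), byrow = TRUE)
        dimnames(dhffc) <- dimnames(gt)
    }
    SVCohort(gr, svtype = svtype, gt = gt, dhffc = dhffc)
}

## one plus-strand gene: 3 exons at fixed offsets, CDS = exons minus 50-bp
## terminal UTRs; a second minus-strand gene downstream
make_two_gene_models <- function() {
    ex1 <- GRanges("chr1", IRanges(c(1001, 2001, 3001), c(1300, 2300, 3400)),
                   strand = "+")
    cds1 <- ex1
    start(cds1)[1] <- 1051
    end(cds1)[3] <- 3350
    u5 <- GRanges("chr1", IRanges(1001, 1050), strand = "+")
    u3 <- GRanges("chr1", IRanges(3351, 3400), strand = "+")
    ex2 <- GRanges("chr1", IRanges(c(6001, 7001), c(6300, 7400)),
                   strand = "-")
    genes <- GRanges("chr1", IRanges(c(1001, 6001), c(3400, 7400)),
                     strand = c("+", "-"))
    names(genes) <- c("geneA", "geneB")
    GeneModelSet(genes = genes,
                 txGene = data.frame(tx_id = c("txA", "txB"),
                                     gene_id = c("geneA", "geneB")),
                 exons = GRangesList(txA = ex1, txB = ex2),
                 cds = GRangesList(txA = cds1),
                 utr5 = GRangesList(txA = u5),
                 utr3 = GRangesList(txA = u3))
}

## uniform-depth track of 100-bp segments
make_track <- function(depths, chrom = "chr1", bin = 100L) {
    n <- length(depths)
    gr <- GRanges(chrom, IRanges((seq_len(n) - 1L) * bin + 1L,
                                 seq_len(n) * bin))
    mcols(gr)$depth <- depths
    gr
}

## small simulation used by several files
small_sim <- function(seed = 5L, ...) {
    cfg <- simConfig(seed = seed, nGenes = 60L,
                     svCounts = c(DEL = 400L, DUP = 60L, INV = 30L, BND = 10L),
                     nDomestication = 10L,
                     nConsequence = c(intron = 8L, exon_loss = 4L,
                                      fusion = 4L),
                     nRepeats = 60L, nGerp = 80L, nGaps = 8L, nHighDepth = 4L,
                     ...)
    ref <- simulateReference(cfg)
    list(cfg = cfg, ref = ref, sim = simulateCohort(cfg, ref))
}

## brute-force all-pairs reciprocal overlap scan (independent oracle:
## every query x subject pair, plain arithmetic, no interval index)
brute_overlap <- function(q, s, minBp = 1, minRecip = 0) {
    qi <- rep(seq_along(q), each = length(s))
    si <- rep(seq_along(s), times = length(q))
    same <- as.character(seqnames(q))[qi] == as.character(seqnames(s))[si]
    ov <- pmin(end(q)[qi], end(s)[si]) - pmax(start(q)[qi], start(s)[si]) + 1L
    fq <- ov / width(q)[qi]
    fs <- ov / width(s)[si]
    keep <- same & ov >= minBp & pmin(fq, fs) >= minRecip
    if (!any(keep)) return(NULL)
    data.frame(query_id = names(q)[qi][keep],
               subject_id = names(s)[si][keep],
               overlap_bp = ov[keep], frac_query = fq[keep],
               frac_subject = fs[keep])
}

## scalar transcription of the two-population Weir-Cockerham (1984)
## variance components, written independently of the package's matrix code
wc_theta_oracle <- function(g1, g2) {
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    r <- 2
    n_i <- c(length(g1), length(g2))
    p_i <- c(sum(g1) / (2 * n_i[1]), sum(g2) / (2 * n_i[2]))
    h_i <- c(mean(g1 == 1), mean(g2 == 1))
    n_bar <- mean(n_i)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s_sq <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / n_c) * (s_sq - 1 / (n_bar - 1) *
        (p_bar * (1 - p_bar) - (r - 1) / r * s_sq - h_bar / 4))
    b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
        (r - 1) / r * s_sq - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    if (a + b + cc == 0) return(c(a = a, b = b, c = cc, theta = NA_real_))
    c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}
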