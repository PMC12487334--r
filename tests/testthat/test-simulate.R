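test_that("the whole generation path is deterministic under a fixed seed", {
    a <- small_sim(seed = 41)
    b <- small_sim(seed = 41)
    expect_identical(a$sim$truth, b$sim$truth)
    expect_identical(genotypes(a$sim$cohort), genotypes(b$sim$cohort))
    expect_identical(dhffcMatrix(a$sim$cohort), dhffcMatrix(b$sim$cohort))
    f1 <- tempfile(); f2 <- tempfile()
    emitTruthTables(a$sim$truth, f1)
    emitTruthTables(b$sim$truth, f2)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    c1 <- small_sim(seed = 42)
    expect_false(identical(genotypes(a$sim$cohort), genotypes(c1$sim$cohort)))
})

test_that("truth tables align one-to-one with emitted records and counts", {
    s <- small_sim(seed = 43)
    expect_identical(s$sim$truth$sv_id, rownames(s$sim$cohort))
    expect_equal(sum(s$sim$truth$domestication), s$cfg$nDomestication)
    expect_equal(sum(!is.na(s$sim$truth$consequence)),
                 sum(s$cfg$nConsequence))
    expect_equal(sum(s$sim$truth$fail_translocation),
                 unname(s$cfg$svCounts["BND"]))
    ## per-type counts and length medians in the configured ballpark
    tr <- s$sim$truth
    expect_equal(unname(table(tr$svtype)[names(s$cfg$svCounts)]),
                 unname(s$cfg$svCounts), ignore_attr = TRUE)
    ## planted gap records overlap a gap; high-depth records a high-depth region
    rr <- rowRanges(s$sim$cohort)
    expect_true(all(countOverlaps(rr[tr$fail_gap], s$ref$gaps) > 0))
    expect_true(all(countOverlaps(rr[tr$fail_high_depth],
                                  s$ref$highDepth) > 0))
})

test_that("reference geometry is internally consistent", {
    s <- small_sim(seed = 44)
    m <- s$ref$models
    ## CDS inside exon union is enforced by the class validity; spot-check
    expect_true(validObject(m))
    ## exons stay inside their gene body
    for (i in seq_len(min(20, nrow(m@txGene)))) {
        tx <- m@txGene$tx_id[i]
        g <- m@genes[m@txGene$gene_id[i]]
        ex <- m@exons[[tx]]
        expect_true(all(start(ex) >= start(g) & end(ex) <= end(g)))
    }
    ## genes do not overlap
    expect_equal(sum(countOverlaps(m@genes, m@genes) > 1), 0L)
    ## depth track tiles without overlap and realizes high-depth regions
    expect_error(highDepthRegions(c(s$ref$depth, s$ref$depth[1]), 100))
    hd <- highDepthRegions(s$ref$depth, 100)
    expect_true(all(countOverlaps(s$ref$highDepth, hd) > 0))
    ## zero genes still yields a valid, empty model set
    cfg0 <- simConfig(seed = 1, nGenes = 0L, nGerp = 0L,
                      nConsequence = c(intron = 0L, exon_loss = 0L,
                                       fusion = 0L))
    ref0 <- simulateReference(cfg0)
    expect_equal(length(ref0$models@genes), 0L)
    f <- tempfile(fileext = ".gff3")
    writeGeneModels(ref0$models, f)
    expect_equal(readLines(f), "##gff-version 3")
})

test_that("population frequencies and genotypes follow the divergence model", {
    ## near-zero F: per-population AFs hug the ancestral frequency
    cfg <- simConfig(seed = 45, nGenes = 0L,
                     svCounts = c(DEL = 600L, DUP = 0L, INV = 0L, BND = 0L),
                     populations = c(P1 = 50L, P2 = 50L),
                     popF = c(P1 = 0.001, P2 = 0.001),
                     nHybrids = 0L, nDomestication = 0L,
                     failFractions = c(gap = 0, high_depth = 0,
                                       dhffc_artifact = 0, low_ac = 0,
                                       low_call_rate = 0),
                     nConsequence = c(intron = 0L, exon_loss = 0L,
                                      fusion = 0L),
                     nRepeats = 0L, nGerp = 0L, nGaps = 0L, nHighDepth = 0L)
    ref <- simulateReference(cfg)
    sim <- simulateCohort(cfg, ref)
    ## near-zero divergence: population frequencies hug the ancestral value
    expect_gt(mean(abs(sim$truth$af_P1 - sim$truth$ancestral_af) <= 0.05),
              0.95)
    ## reported AF equals the recount from raw genotypes (exact)
    st <- alleleStats(sim$cohort, panelSamples(sim$panel, "P1"))
    gt <- genotypes(sim$cohort)[, panelSamples(sim$panel, "P1")]
    expect_equal(st$af, unname(rowSums(gt, na.rm = TRUE) /
                               (2 * rowSums(!is.na(gt)))))
    ## HWE within a population at alpha = 0.01 for >= 97% of sites
    n <- ncol(gt)
    obs <- cbind(rowSums(gt == 0L), rowSums(gt == 1L), rowSums(gt == 2L))
    p <- (2 * obs[, 3] + obs[, 2]) / (2 * n)
    ex <- cbind(n * (1 - p)^2, 2 * n * p * (1 - p), n * p^2)
    keep <- p > 0 & p < 1
    stat <- rowSums((obs - ex)^2 / pmax(ex, 1e-12))[keep]
    pv <- pchisq(stat, df = 1, lower.tail = FALSE)
    expect_gt(mean(pv >= 0.01), 0.97)
})

test_that("planted DHFFC artifacts are the exactly maskable calls", {
    s <- small_sim(seed = 46)
    dh <- dhffcMatrix(s$sim$cohort)
    gt <- genotypes(s$sim$cohort)
    tr <- s$sim$truth
    svt <- tr$svtype
    carrier <- !is.na(gt) & gt > 0L
    maskable <- matrix(FALSE, nrow(gt), ncol(gt))
    for (t in c("DEL", "DUP", "INV")) {
        i <- svt == t
        maskable[i, ] <- switch(t,
            DEL = dh[i, ] > 0.7,
            DUP = dh[i, ] < 1.3,
            INV = dh[i, ] > 0.7 & dh[i, ] < 1.3)
    }
    maskable <- maskable & carrier & svt != "BND"
    expect_identical(unname(maskable), unname(s$sim$artifactCells))
    ## a planted deletion artifact carrier always exceeds the threshold
    bad_del <- which(tr$dhffc_artifact & svt == "DEL")
    expect_true(all(dh[bad_del, ][carrier[bad_del, ]] > 0.7))
})

test_that("written simulation files parse back through the readers", {
    s <- small_sim(seed = 47)
    d <- tempfile()
    writeSimulation(s$ref, s$sim, d)
    x <- readSVVcf(file.path(d, "cohort.vcf"))
    expect_equal(nrow(x), nrow(s$sim$cohort))
    expect_identical(genotypes(x), genotypes(s$sim$cohort))
    expect_equal(length(readBedIntervals(file.path(d, "repeats.bed"))),
                 length(s$ref$repeats))
    expect_equal(length(readBedIntervals(file.path(d, "gerp.bed"))),
                 length(s$ref$gerp))
    tr <- data.table::fread(file.path(d, "truth_svs.tsv"))
    expect_equal(nrow(tr), nrow(s$sim$cohort))
    dt <- readDepthTrack(file.path(d, "depth.bedgraph"))
    expect_equal(length(dt), length(s$ref$depth))
    unlink(d, recursive = TRUE)
})
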