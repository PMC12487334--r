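test_that("high-depth regions are maximal merged intervals above the cutoff", {
    tr <- make_track(rep(20, 50))
    expect_equal(length(highDepthRegions(tr, 100)), 0L)
    tr2 <- make_track(c(50, 150, 150, 80))
    hd <- highDepthRegions(tr2, 100)
    expect_equal(length(hd), 1L)
    expect_equal(start(hd), 101L)
    expect_equal(end(hd), 300L)
    ## random track equals per-base thresholding + run-length merging
    set.seed(1)
    d <- sample(c(20, 60, 120, 180), 100, replace = TRUE)
    tr3 <- make_track(d)
    hd3 <- highDepthRegions(tr3, 100)
    base <- rep(d, each = 100) > 100
    rl <- rle(base)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    expect_equal(start(hd3), starts[rl$values])
    expect_equal(end(hd3), ends[rl$values])
    ## overlapping segments are rejected
    bad <- c(tr2, GRanges("chr1", IRanges(150, 250)))
    mcols(bad)$depth <- c(mcols(tr2)$depth, 10)
    expect_error(highDepthRegions(bad, 100), "overlap")
})

test_that("DHFFC is the length-weighted inside/flank depth ratio", {
    tr <- make_track(rep(30, 100))
    sv <- GRanges("chr1", IRanges(4001, 4800))
    expect_equal(computeDHFFC(tr, sv, 1000L), 1.0)
    tr2 <- make_track(c(rep(20, 40), rep(10, 10), rep(20, 50)))
    sv2 <- GRanges("chr1", IRanges(4001, 5000))
    expect_equal(computeDHFFC(tr2, sv2, 1000L), 0.5)
    ## flank clipped at the track boundary: length-weighted brute force
    sv3 <- GRanges("chr1", IRanges(501, 1500))
    d <- c(rep(35, 5), rep(15, 10), rep(25, 85))
    tr3 <- make_track(d)
    per_base <- rep(d, each = 100)
    inside <- mean(per_base[501:1500])
    flank <- mean(per_base[c(1:500, 1501:2500)])
    expect_equal(computeDHFFC(tr3, sv3, 1000L), inside / flank)
    expect_error(computeDHFFC(tr, GRanges("chr1", IRanges(9000, 12000))),
                 "outside")
})

test_that("site filters remove translocations and >=1 bp gap/high-depth overlaps", {
    x <- make_cohort("chr1", c(100, 300, 500, 700), c(199, 399, 599, 799),
                     c("DEL", "BND", "DEL", "DEL"),
                     matrix(1L, 4, 3))
    gaps <- GRanges("chr1", IRanges(599, 650))   # 1-bp overlap with sv3
    hd <- GRanges("chr1", IRanges(700, 700))     # 1-bp overlap with sv4
    out <- filterSites(x, filterConfig(), gaps = gaps, highDepth = hd)
    expect_equal(rownames(out$cohort), "sv1")
    expect_equal(unname(out$reasons[c("sv2", "sv3", "sv4")]),
                 c("translocation", "gap_overlap", "high_depth"))
    ## report telescopes
    expect_true(all(out$report$input - out$report$removed ==
                    out$report$surviving))
    ## chromosome whitelist
    x2 <- make_cohort(c("chr1", "chrUn"), c(1, 1), c(100, 100),
                      c("DEL", "DEL"), matrix(1L, 2, 2))
    out2 <- filterSites(x2, filterConfig(chromWhitelist = "chr1"))
    expect_equal(rownames(out2$cohort), "sv1")
})

test_that("DHFFC masking hits carrier genotypes at strict thresholds only", {
    gt <- matrix(c(1L, 1L, 0L,   # DEL: dhffc .5 kept, .71 masked, hom-ref kept
                   2L, 1L, 1L,   # DUP: 1.29 masked, 1.3 kept, 1.5 kept
                   2L, 1L, 1L),  # INV: .7 kept (strict band), 1.0 masked, 1.31 kept
                 3, 3, byrow = TRUE)
    dh <- matrix(c(0.5, 0.71, 1.0,
                   1.29, 1.3, 1.5,
                   0.7, 1.0, 1.31), 3, 3, byrow = TRUE)
    x <- make_cohort("chr1", c(1, 200, 400), c(100, 300, 500),
                     c("DEL", "DUP", "INV"), gt, dh)
    out <- maskGenotypesDHFFC(x, filterConfig())
    m <- genotypes(out$cohort)
    expect_equal(unname(m[1, ]), c(1L, NA, 0L))
    expect_equal(unname(m[2, ]), c(NA, 1L, 1L))
    expect_equal(unname(m[3, ]), c(2L, NA, 1L))
    expect_equal(out$report$n_masked, 3L)
    ## hom-ref and missing calls are never touched; ALT total never grows
    expect_true(sum(m, na.rm = TRUE) <= sum(gt, na.rm = TRUE))
    ## calls without DHFFC evidence are retained
    dh2 <- dh; dh2[1, 2] <- NA
    x2 <- make_cohort("chr1", c(1, 200, 400), c(100, 300, 500),
                      c("DEL", "DUP", "INV"), gt, dh2)
    expect_equal(unname(genotypes(maskGenotypesDHFFC(x2, filterConfig())$cohort)[1, 2]),
                 1L)
})

test_that("allele-count and call-rate filters use the quoted boundaries", {
    ## 10 samples, 1 het -> AC = 1 <= 2 -> removed
    x <- make_cohort("chr1", 1, 100, "DEL",
                     matrix(c(1L, rep(0L, 9)), 1))
    expect_equal(nrow(filterACCallRate(x, filterConfig())$cohort), 0L)
    ## call rate exactly 0.80 survives (with AC above the cutoff)
    gt <- matrix(c(2L, 2L, 1L, 0L, 0L, 0L, 0L, 0L, NA, NA), 1)
    x2 <- make_cohort("chr1", 1, 100, "DEL", gt)
    out <- filterACCallRate(x2, filterConfig())
    expect_equal(nrow(out$cohort), 1L)
    ## 7/10 called -> removed for low call rate
    gt3 <- matrix(c(2L, 2L, 1L, 0L, 0L, 0L, 0L, NA, NA, NA), 1)
    out3 <- filterACCallRate(make_cohort("chr1", 1, 100, "DEL", gt3),
                             filterConfig())
    expect_equal(unname(out3$reasons), "low_call_rate")
    ## random cohorts match a brute-force recount
    set.seed(9)
    gt4 <- matrix(sample(c(0:2, NA), 50 * 20, replace = TRUE,
                         prob = c(.5, .25, .1, .15)), 50, 20)
    x4 <- make_cohort("chr1", seq(1, by = 200, length.out = 50),
                      seq(100, by = 200, length.out = 50),
                      rep("DEL", 50), gt4)
    out4 <- filterACCallRate(x4, filterConfig())
    keep <- vapply(seq_len(50), function(i) {
        g <- gt4[i, ]
        sum(g, na.rm = TRUE) > 2 && mean(!is.na(g)) >= 0.8
    }, logical(1))
    expect_identical(rownames(out4$cohort), rownames(x4)[keep])
})

test_that("cascade is ordered, idempotent, order-independent and telescoping", {
    s <- small_sim(seed = 13)
    cfg <- filterConfig()
    out <- runFilterCascade(s$sim$cohort, cfg, gaps = s$ref$gaps,
                            highDepth = s$ref$highDepth)
    expect_true(all(out$report$input - out$report$removed ==
                    out$report$surviving))
    ## step order: later step inputs equal earlier outputs
    expect_equal(out$report$input[-1], out$report$surviving[-nrow(out$report)])
    ## idempotence
    out2 <- runFilterCascade(out$cohort, cfg, gaps = s$ref$gaps,
                             highDepth = s$ref$highDepth)
    expect_identical(rownames(out2$cohort), rownames(out$cohort))
    expect_identical(genotypes(out2$cohort), genotypes(out$cohort))
    expect_equal(sum(out2$report$removed), 0L)
    ## permuting record order leaves the surviving id-set unchanged
    perm <- sample(nrow(s$sim$cohort))
    out3 <- runFilterCascade(s$sim$cohort[perm, ], cfg, gaps = s$ref$gaps,
                             highDepth = s$ref$highDepth)
    expect_setequal(rownames(out3$cohort), rownames(out$cohort))
    ## clean input passes unchanged
    clean <- out$cohort
    out4 <- runFilterCascade(clean, cfg, gaps = s$ref$gaps,
                             highDepth = s$ref$highDepth)
    expect_equal(sum(out4$report$removed), 0L)
})

test_that("cascade recovers the generator's planted truth exactly", {
    s <- small_sim(seed = 17)
    out <- runFilterCascade(s$sim$cohort, filterConfig(), gaps = s$ref$gaps,
                            highDepth = s$ref$highDepth)
    tr <- s$sim$truth
    expect_setequal(rownames(out$cohort), tr$sv_id[tr$pass])
    ## removal reasons follow the cascade's precedence over the truth flags
    expected <- ifelse(tr$fail_translocation, "translocation",
                ifelse(tr$fail_gap, "gap_overlap",
                ifelse(tr$fail_high_depth, "high_depth",
                ifelse(tr$fail_low_ac, "low_allele_count",
                ifelse(tr$fail_low_call_rate, "low_call_rate", NA)))))
    drop <- !is.na(expected)
    expect_identical(out$reasons[tr$sv_id[drop]],
                     setNames(expected[drop], tr$sv_id[drop]))
    ## masked genotype set equals the planted artifact set
    site_pass <- tr$sv_id[!(tr$fail_translocation | tr$fail_gap |
                            tr$fail_high_depth)]
    expect_identical(unname(out$masked),
                     unname(s$sim$artifactCells[site_pass, ]))
})
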