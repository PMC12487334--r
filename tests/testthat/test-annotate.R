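mods <- make_two_gene_models()

classify1 <- function(start, end, type) {
    gr <- GRanges("chr1", IRanges(start, end)); names(gr) <- "q"
    classifySV(gr, type, mods)
}

test_that("containment rules: intron, exon loss, ablation, duplication, inversion", {
    ## fully inside the first intron of geneA (geneB is near enough for a
    ## proximity term; the geneA annotation must be exactly intron_variant)
    a <- classify1(1500, 1700, "DEL")
    expect_equal(a$consequence[a$gene_id == "geneA"], "intron_variant")
    expect_equal(a$impact[a$gene_id == "geneA"], "MODIFIER")
    ## deletion containing the middle exon but not the whole transcript
    b <- classify1(1900, 2500, "DEL")
    expect_true("exon_loss_variant" %in% b$consequence)
    expect_equal(max(b$impact == "HIGH"), 1)
    ## deletion spanning the whole transcript
    c1 <- classify1(900, 3500, "DEL")
    expect_true("transcript_ablation" %in% c1$consequence)
    expect_false("exon_loss_variant" %in% c1$consequence)
    ## duplication fully containing an exon
    d <- classify1(1900, 2500, "DUP")
    expect_true("duplication" %in% d$consequence)
    expect_false("exon_loss_variant" %in% d$consequence)
    ## inversion spanning the whole gene
    e <- classify1(900, 3500, "INV")
    expect_true("transcript_inversion" %in% e$consequence)
})

test_that("breakpoint rules: frameshift, UTR, fusion with strand awareness", {
    ## DEL breakpoint inside CDS removing a non-multiple-of-3 chunk
    f <- classify1(2100, 2600, "DEL")   # cuts exon2 CDS at 2100..2300 = 201 bp
    aff <- 201
    expect_equal(aff %% 3, 0)           # 201 is divisible -> no frameshift
    expect_false("frameshift_variant" %in% f$consequence)
    f2 <- classify1(2101, 2600, "DEL")  # 200 bp affected -> frameshift
    expect_true("frameshift_variant" %in% f2$consequence)
    ## breakpoint in the 5' UTR
    u <- classify1(1020, 1500, "DEL")
    expect_true("5_prime_UTR_variant" %in% u$consequence)
    ## geneA is + and geneB is -: spanning breakpoints inside both genes
    g <- classify1(2000, 6500, "INV")
    expect_true("bidirectional_gene_fusion" %in% g$consequence)
    expect_setequal(g$gene_id[g$consequence == "bidirectional_gene_fusion"],
                    c("geneA", "geneB"))
    ## same-strand fusion when both genes are +
    mods2 <- mods
    strand(mods2@genes) <- "+"
    gr <- GRanges("chr1", IRanges(2000, 6500)); names(gr) <- "q"
    g2 <- classifySV(gr, "DEL", mods2)
    expect_true("gene_fusion" %in% g2$consequence)
})

test_that("proximity rules: up/downstream by strand, intergenic beyond the window", {
    ## 1000 bp before geneA (+): upstream
    a <- classify1(1, 50, "DEL")
    expect_equal(a$consequence[a$gene_id == "geneA"], "upstream_gene_variant")
    ## 1000 bp after geneB (-): upstream of the minus-strand gene
    b <- classify1(8000, 8100, "DEL")
    expect_equal(b$consequence[b$gene_id == "geneB"], "upstream_gene_variant")
    ## between the genes: downstream of geneA, and near geneB
    m <- classify1(4500, 4600, "DEL")
    expect_equal(m$consequence[m$gene_id == "geneA"],
                 "downstream_gene_variant")
    expect_equal(m$consequence[m$gene_id == "geneB"],
                 "downstream_gene_variant")
    ## farther than updownBp from everything
    i <- classify1(20000, 20100, "DEL")
    expect_equal(i$consequence, "intergenic_region")
    expect_true(is.na(i$gene_id))
    ## chromosome with no genes at all
    gr <- GRanges("chrZ", IRanges(5, 50)); names(gr) <- "z"
    expect_equal(classifySV(gr, "DEL", mods)$consequence, "intergenic_region")
})

test_that("every SV is annotated; enlarging keeps containment-based terms", {
    set.seed(2)
    st <- sample.int(25000, 200, replace = TRUE)
    gr <- GRanges("chr1", IRanges(st, st + sample.int(500, 200, replace = TRUE)))
    names(gr) <- paste0("r", 1:200)
    ann <- classifySV(gr, sample(c("DEL", "DUP", "INV"), 200, replace = TRUE),
                      mods)
    expect_setequal(unique(ann$sv_id), names(gr))
    ## an intronic deletion, enlarged, never loses all annotation
    small <- classify1(1400, 1500, "DEL")
    big <- classify1(1350, 1990, "DEL")
    expect_true(nrow(big) >= 1)
    expect_true("intron_variant" %in% c(small$consequence, big$consequence))
})

test_that("gene sets and category summaries follow set semantics", {
    ann <- data.frame(
        sv_id = c("s1", "s1", "s2", "s3"),
        gene_id = c("gA", "gA", "gB", NA),
        consequence = c("exon_loss_variant", "intron_variant",
                        "upstream_gene_variant", "intergenic_region"),
        impact = c("HIGH", "MODIFIER", "MODIFIER", "MODIFIER"))
    sets <- aggregateGeneSets(ann, c("gA", "gB", "gC"))
    expect_equal(sets$affected, "gA")
    expect_setequal(sets$associated, c("gA", "gB"))
    expect_setequal(sets$background, c("gB", "gC"))
    ## no HIGH annotations anywhere
    sets2 <- aggregateGeneSets(ann[-1, ], c("gA", "gB", "gC"))
    expect_equal(length(sets2$affected), 0L)
    expect_setequal(sets2$background, c("gA", "gB", "gC"))
    cats <- summarizeCategories(ann)
    expect_equal(sum(cats$terms$proportion), 1)
    expect_equal(sum(cats$terms$n), nrow(ann))
    expect_equal(sum(cats$cooccurrence$n), 3L)   # three distinct SVs
    expect_true("exon_loss_variant+intron_variant" %in%
                cats$cooccurrence$term_set)
})

test_that("curation sampling honours the 2+2+3 quota and the seed", {
    gt <- setNames(c(rep(0L, 10), rep(1L, 5), rep(2L, 5)), paste0("s", 1:20))
    sel <- selectCurationSamples(gt, seed = 11)
    expect_equal(length(sel), 7L)
    expect_equal(sum(gt[sel] == 0), 2L)
    expect_equal(sum(gt[sel] == 1), 2L)
    expect_equal(sum(gt[sel] == 2), 3L)
    expect_identical(sel, selectCurationSamples(gt, seed = 11))
    expect_false(identical(sel, selectCurationSamples(gt, seed = 12)))
    ## shortfall in hom-alt is back-filled from remaining called samples
    gt2 <- setNames(c(rep(0L, 10), rep(1L, 8), NA, NA), paste0("s", 1:20))
    sel2 <- selectCurationSamples(gt2, seed = 3)
    expect_equal(length(sel2), 7L)
    expect_true(all(!is.na(gt2[sel2])))
    ## fewer than 7 called samples: all of them
    gt3 <- setNames(c(0L, 1L, 2L, NA, NA), paste0("s", 1:5))
    expect_setequal(selectCurationSamples(gt3, 1), c("s1", "s2", "s3"))
})
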