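test_that("reciprocal-overlap join uses inclusive bedtools -f -r semantics", {
    ## [100,200) x [150,250) in half-open terms: 1-based (101,200) x (151,250)
    q <- GRanges("chr1", IRanges(101, 200)); names(q) <- "A"
    s <- GRanges("chr1", IRanges(151, 250)); names(s) <- "B"
    p <- overlapJoin(q, s, minRecip = 0.5)
    expect_equal(nrow(p), 1L)
    expect_equal(p$overlap_bp, 50L)
    expect_equal(p$frac_query, 0.5)
    expect_equal(p$frac_subject, 0.5)
    ## identical intervals
    p2 <- overlapJoin(q, q)
    expect_equal(c(p2$frac_query, p2$frac_subject), c(1, 1))
    ## nested: inner fraction is 1
    inner <- GRanges("chr1", IRanges(120, 140)); names(inner) <- "I"
    p3 <- overlapJoin(inner, q)
    expect_equal(p3$frac_query, 1)
})

test_that("overlap join equals the brute-force all-pairs scan", {
    set.seed(21)
    n <- 120
    mk <- function(pfx) {
        st <- sample.int(5000, n, replace = TRUE)
        gr <- GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
                      IRanges(st, st + sample.int(300, n, replace = TRUE)))
        names(gr) <- paste0(pfx, seq_len(n))
        gr
    }
    q <- mk("q"); s <- mk("s")
    for (mr in c(0, 0.5, 0.95, 1.0)) {
        got <- overlapJoin(q, s, minRecip = mr)
        want <- brute_overlap(q, s, minRecip = mr)
        key <- function(d) if (is.null(d) || !nrow(d)) character(0) else
            sort(paste(d$query_id, d$subject_id, d$overlap_bp))
        expect_identical(key(got), key(want))
    }
    ## symmetry under swapping query and subject
    a <- overlapJoin(q, s); b <- overlapJoin(s, q)
    expect_setequal(paste(a$query_id, a$subject_id, a$frac_query),
                    paste(b$subject_id, b$query_id, b$frac_subject))
})

test_that("redundancy clustering is single-linkage above a strict threshold", {
    ## three inversions with pairwise reciprocal overlap ~0.96
    gr <- GRanges("chr1", IRanges(c(1000, 1400, 1800), c(100999, 101399,
                                                         101799)))
    names(gr) <- c("i1", "i2", "i3")
    cl <- findRedundantSVs(gr, rep("INV", 3), 0.95)
    expect_equal(length(cl), 1L)
    expect_setequal(cl[[1]]$ids, c("i1", "i2", "i3"))
    expect_equal(cl[[1]]$start_spread, 800L)
    ## reciprocal overlap of exactly 0.95 does not cluster (strict >)
    g2 <- GRanges("chr1", IRanges(c(1, 6), c(100, 105)))
    names(g2) <- c("d1", "d2")   # overlap 95/100 = 0.95 both ways
    expect_equal(length(findRedundantSVs(g2, c("DEL", "DEL"), 0.95)), 0L)
    ## different types never cluster: the DEL drops out of the triple
    mixed <- findRedundantSVs(gr, c("INV", "DEL", "INV"), 0.95)
    expect_equal(length(mixed), 1L)
    expect_setequal(mixed[[1]]$ids, c("i1", "i3"))
    ## random records equal brute-force pairwise graph + components
    set.seed(4)
    n <- 60
    st <- sample.int(2000, n, replace = TRUE)
    rg <- GRanges("chr1", IRanges(st, st + sample(c(100, 101, 102), n,
                                                  replace = TRUE)))
    names(rg) <- paste0("r", seq_len(n))
    ty <- sample(c("DEL", "INV"), n, replace = TRUE)
    got <- findRedundantSVs(rg, ty, 0.9)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (ty[i] != ty[j]) next
        ov <- min(end(rg)[i], end(rg)[j]) - max(start(rg)[i], start(rg)[j]) + 1L
        if (ov < 1) next
        if (min(ov / width(rg)[i], ov / width(rg)[j]) > 0.9)
            adj[i, j] <- adj[j, i] <- TRUE
    }
    comp <- rep(0L, n); cid <- 0L
    for (i in seq_len(n)) {
        if (comp[i] > 0) next
        cid <- cid + 1L
        stack <- i
        while (length(stack)) {
            v <- stack[length(stack)]; stack <- stack[-length(stack)]
            if (comp[v] > 0) next
            comp[v] <- cid
            stack <- c(stack, which(adj[v, ] & comp == 0))
        }
    }
    want <- Filter(function(m) length(m) > 1,
                   split(names(rg), comp))
    got_sets <- lapply(got, function(cl) sort(cl$ids))
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(lapply(want, sort), paste, "", collapse = ","))
})

test_that("100% reciprocal merge keeps exactly coordinate-identical records", {
    setA <- GRanges("chr1", IRanges(c(100, 500), c(199, 799)))
    mcols(setA)$svtype <- c("DEL", "DUP"); names(setA) <- c("a1", "a2")
    setB <- GRanges("chr1", IRanges(900, 999))
    mcols(setB)$svtype <- "DEL"; names(setB) <- "b1"
    comb <- make_cohort("chr1", c(100, 101, 900, 500), c(199, 200, 999, 799),
                        c("DEL", "DEL", "DEL", "DEL"), matrix(1L, 4, 2),
                        ids = paste0("c", 1:4))
    out <- mergeSVSets(setA, setB, comb)
    ## c1 matches a1; c2 is shifted 1 bp; c3 matches b1; c4 has wrong type
    expect_setequal(rownames(out$cohort), c("c1", "c3"))
    expect_equal(out$captureA, 0.5)
    expect_equal(out$captureB, 1.0)
})

test_that("GERP overlap summaries match direct recomputation", {
    svs <- GRanges("chr1", IRanges(c(100, 1000), c(400, 1009)))
    names(svs) <- c("s1", "s2")
    el <- GRanges("chr1", IRanges(c(140, 300, 1000), c(200, 500, 1099)))
    names(el) <- c("e1", "e2", "e3")
    gs <- summarizeGerpOverlap(svs, el)
    ## s1 covers e1 fully (61 bp), hits e2 for 101 bp; s2 ends 10 bp into e3
    expect_equal(sort(gs$pairs$overlap_bp), c(10L, 61L, 101L))
    expect_equal(gs$perSV$n_elements[gs$perSV$sv_id == "s1"], 2L)
    lens <- width(el)
    expect_equal(unname(gs$elementLength["mean"]), mean(lens))
    expect_equal(unname(gs$elementLength["sd"]),
                 sqrt(mean((lens - mean(lens))^2)))
    expect_equal(unname(gs$overlapLength["mean"]), mean(gs$pairs$overlap_bp))
    ## single fully-covered 61-bp element
    gs2 <- summarizeGerpOverlap(svs[1], el[1])
    expect_equal(unname(gs2$overlapLength["mean"]), 61)
    expect_equal(unname(gs2$elementLength["sd"]), 0)
    ## empty overlap -> summaries absent, not zero
    gs3 <- summarizeGerpOverlap(svs, GRanges("chr9", IRanges(1, 10)))
    expect_null(gs3$elementLength)
    expect_null(gs3$overlapLength)
})
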