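#' @include AllClasses.R
NULL

## sample() treats a length-1 numeric first argument as 1:n; avoid that
.resample <- function(x, size = length(x), ...) {
    x[sample.int(length(x), size, ...)]
}

## vectorised truncated-normal draw on [lo, hi] via inverse-CDF
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions the package's analyses assume: a
#' farmed group of 90 samples against three wild groups of 13, 22 and 37
#' samples (plus 8 F1 hybrids that are excluded from every statistic),
#' Balding-Nichols divergence per population, type-specific log-normal SV
#' lengths with medians of about 120 bp (DEL), 619 bp (DUP) and 2,456 bp
#' (INV), planted domestication SVs with a fixed allele-frequency shift, a
#' fraction of planted low-quality records per failure mode, and
#' genotype-conditional DHFFC emission separable by the filter thresholds.
#'
#' @param seed integer seed; the whole generation path is deterministic in it.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param nGenes number of non-overlapping genes to place.
#' @param exonRange integer range of exons per gene.
#' @param svCounts named counts per SV type (DEL, DUP, INV, BND).
#' @param lengthMeanlog,lengthSdlog log-normal length parameters per type.
#' @param maxLength length clip in bp.
#' @param populations named sample sizes per group.
#' @param popF named Balding-Nichols F per group, each in (0, 1).
#' @param nHybrids F1 hybrid samples (excluded from statistics).
#' @param ancestralRange uniform support of the ancestral ALT frequency.
#' @param nDomestication planted domestication SV count.
#' @param deltaAF absolute farmed-vs-ancestral frequency shift at planted SVs.
#' @param failFractions named fractions of records planted to fail each
#'   filter mode (gap, high_depth, dhffc_artifact, low_ac, low_call_rate).
#' @param nConsequence named counts of consequence-planted SVs
#'   (intron, exon_loss, fusion).
#' @param nRepeats,nGerp,gerpExonicFrac,nGaps,nHighDepth reference features.
#' @param depthBin,depthMean,depthSd,highDepthDepth depth-track parameters.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      chromLengths = stats::setNames(rep(5e6L, 4),
                                                     paste0("chr", 1:4)),
                      nGenes = 300L, exonRange = c(2L, 30L),
                      svCounts = c(DEL = 1600L, DUP = 250L, INV = 100L,
                                   BND = 50L),
                      lengthMeanlog = c(DEL = log(120), DUP = log(619),
                                        INV = log(2456)),
                      lengthSdlog = c(DEL = 1.11, DUP = 0.87, INV = 2.47),
                      maxLength = 4e5,
                      populations = c(FARMED = 90L, WILD_A = 13L,
                                      WILD_E = 22L, WILD_W = 37L),
                      popF = c(FARMED = 0.15, WILD_A = 0.10, WILD_E = 0.05,
                               WILD_W = 0.05),
                      nHybrids = 8L, ancestralRange = c(0.05, 0.95),
                      nDomestication = 50L, deltaAF = 0.5,
                      failFractions = c(gap = 0.02, high_depth = 0.02,
                                        dhffc_artifact = 0.05, low_ac = 0.05,
                                        low_call_rate = 0.03),
                      nConsequence = c(intron = 20L, exon_loss = 10L,
                                       fusion = 10L),
                      nRepeats = 300L, nGerp = 400L, gerpExonicFrac = 0.6,
                      nGaps = 20L, nHighDepth = 10L, depthBin = 1000L,
                      depthMean = 20, depthSd = 2, highDepthDepth = 150) {
    stopifnot(all(svCounts >= 0), all(popF > 0 & popF < 1),
              all(names(populations) == names(popF)),
              deltaAF >= 0, deltaAF <= 1,
              all(failFractions >= 0), sum(failFractions) < 1)
    structure(as.list(environment()), class = "SimConfig")
}

#' Simulate a reference: genome layout, gene models, repeats, GERP, gaps, depth
#'
#' Places non-overlapping genes (2-30 exons, one transcript each, CDS inside
#' exons, terminal UTRs), uniform repeats and assembly gaps, GERP constrained
#' elements preferentially inside exons, and a tiled mean-depth track with
#' planted high-depth segments and zero-depth gaps.
#'
#' @param config a \code{\link{simConfig}} list.
#' @return List with \code{chromLengths}, \code{models} (GeneModelSet),
#'   \code{repeats}, \code{gerp}, \code{gaps}, \code{highDepth} (GRanges),
#'   \code{depth} (depth-track GRanges).
#' @export
simulateReference <- function(config) {
    set.seed(config$seed)
    chroms <- config$chromLengths
    exL <- list(); cdsL <- list(); u5L <- list(); u3L <- list()
    g_chr <- character(); g_start <- integer(); g_end <- integer()
    g_strand <- character(); g_id <- character(); tx_of <- character()
    gid <- 0L
    for (cn in names(chroms)) {
        cursor <- 10000L
        while (gid < config$nGenes) {
            k <- sample(seq(config$exonRange[1], config$exonRange[2]), 1)
            exlen <- round(stats::runif(k, 80, 300))
            intlen <- if (k > 1) round(stats::runif(k - 1, 300, 2000)) else integer(0)
            span <- sum(exlen) + sum(intlen)
            gap <- round(stats::runif(1, 2000, 15000))
            if (cursor + gap + span + 10000 > chroms[[cn]]) break
            gid <- gid + 1L
            gstart <- cursor + gap
            starts <- gstart + cumsum(c(0L, head(exlen, -1) + intlen))
            ex <- GRanges(factor(cn, names(chroms)), IRanges(starts, width = exlen))
            strand_g <- sample(c("+", "-"), 1)
            strand(ex) <- strand_g
            gene_id <- sprintf("gene%04d", gid)
            tx_id <- sprintf("tx%04d", gid)
            g_chr <- c(g_chr, cn); g_start <- c(g_start, gstart)
            g_end <- c(g_end, gstart + span - 1L)
            g_strand <- c(g_strand, strand_g); g_id <- c(g_id, gene_id)
            tx_of <- c(tx_of, tx_id)
            ## terminal 50-bp UTRs when the terminal exons allow it
            utr_w <- 50L
            e1 <- ex[1]; eN <- ex[length(ex)]
            cds <- ex
            u5 <- GRanges(); u3 <- GRanges()
            if (width(e1) > utr_w + 10 && width(eN) > utr_w + 10) {
                left <- GRanges(factor(cn, names(chroms)), IRanges(start(e1), start(e1) + utr_w - 1L),
                                strand = strand_g)
                right <- GRanges(factor(cn, names(chroms)), IRanges(end(eN) - utr_w + 1L, end(eN)),
                                 strand = strand_g)
                if (strand_g == "+") { u5 <- left; u3 <- right }
                else { u5 <- right; u3 <- left }
                start(cds)[1] <- start(e1) + utr_w
                end(cds)[length(cds)] <- end(eN) - utr_w
            }
            exL[[tx_id]] <- ex; cdsL[[tx_id]] <- cds
            u5L[[tx_id]] <- u5; u3L[[tx_id]] <- u3
            cursor <- gstart + span
        }
    }
    genes <- GRanges(factor(g_chr, names(chroms)), IRanges(g_start, g_end), strand = g_strand)
    names(genes) <- g_id
    txGene <- data.frame(tx_id = tx_of, gene_id = g_id,
                         stringsAsFactors = FALSE)
    models <- GeneModelSet(genes = genes, txGene = txGene,
                           exons = GRangesList(exL), cds = GRangesList(cdsL),
                           utr5 = GRangesList(u5L[lengths(u5L) > 0]),
                           utr3 = GRangesList(u3L[lengths(u3L) > 0]))

    unif_intervals <- function(n, lens) {
        chr <- sample(names(chroms), n, replace = TRUE,
                      prob = chroms / sum(chroms))
        st <- floor(stats::runif(n, 1, chroms[chr] - lens))
        GRanges(factor(chr, names(chroms)), IRanges(as.integer(st), width = as.integer(lens)))
    }
    repeats <- unif_intervals(config$nRepeats,
                              round(stats::runif(config$nRepeats, 100, 1000)))
    mcols(repeats)$name <- sample(c("Simple_repeat", "LINE", "SINE", "DNA",
                                    "LTR"), config$nRepeats, replace = TRUE)
    names(repeats) <- paste0("rep", seq_along(repeats), recycle0 = TRUE)

    ## GERP elements: a configurable fraction inside exons, the rest uniform
    glen <- pmax(10, round(.rtnorm(config$nGerp, 61, 77, lo = 10)))
    n_ex <- round(config$gerpExonicFrac * config$nGerp)
    all_ex <- unlist(models@exons, use.names = FALSE)
    gerp <- GRanges()
    if (n_ex > 0 && length(all_ex)) {
        host <- all_ex[sample(length(all_ex), n_ex, replace = TRUE)]
        len_e <- pmin(glen[seq_len(n_ex)], width(host))
        off <- floor(stats::runif(n_ex, 0, width(host) - len_e + 1))
        gerp <- GRanges(seqnames(host),
                        IRanges(start(host) + as.integer(off), width = len_e))
    }
    n_un <- config$nGerp - length(gerp)
    if (n_un > 0)
        gerp <- c(gerp, unif_intervals(n_un, glen[(n_ex + 1):config$nGerp]))
    strand(gerp) <- "*"
    names(gerp) <- paste0("gerp", seq_along(gerp), recycle0 = TRUE)

    gaps <- unif_intervals(config$nGaps,
                           round(stats::runif(config$nGaps, 1000, 5000)))
    names(gaps) <- paste0("gap", seq_along(gaps), recycle0 = TRUE)

    ## depth track tiles each chromosome; high-depth segments aligned to bins
    depth <- GRanges()
    for (cn in names(chroms)) {
        nb <- ceiling(chroms[[cn]] / config$depthBin)
        st <- (seq_len(nb) - 1L) * config$depthBin + 1L
        en <- pmin(st + config$depthBin - 1L, chroms[[cn]])
        d <- pmax(0, round(stats::rnorm(nb, config$depthMean,
                                        config$depthSd), 2))
        seg <- GRanges(factor(cn, names(chroms)), IRanges(st, en))
        mcols(seg)$depth <- d
        depth <- c(depth, seg)
    }
    hd_bins <- sample(length(depth), config$nHighDepth)
    highDepth <- GRanges()
    for (b in hd_bins) {
        run <- sample(3:8, 1)
        idx <- b:min(b + run - 1L, length(depth))
        idx <- idx[as.character(seqnames(depth))[idx] ==
                   as.character(seqnames(depth))[b]]
        mcols(depth)$depth[idx] <- round(config$highDepthDepth +
                                         stats::rnorm(length(idx), 0, 5), 2)
        highDepth <- c(highDepth, reduce(granges(depth[idx])))
    }
    ov <- findOverlaps(depth, gaps)
    mcols(depth)$depth[unique(queryHits(ov))] <- 0
    highDepth <- reduce(highDepth)
    list(chromLengths = chroms, models = models, repeats = repeats,
         gerp = gerp, gaps = gaps, highDepth = highDepth, depth = depth)
}

.place_uniform <- function(n, lens, chroms, avoid = GRanges()) {
    lens <- as.integer(pmin(lens, min(chroms) - 2L))
    chrom <- character(n); st <- integer(n)
    todo <- seq_len(n)
    while (length(todo)) {
        chr <- sample(names(chroms), length(todo), replace = TRUE,
                      prob = chroms / sum(chroms))
        l <- pmin(lens[todo], chroms[chr] - 2L)
        s <- as.integer(floor(stats::runif(length(todo), 1, chroms[chr] - l)))
        cand <- GRanges(factor(chr, names(chroms)), IRanges(s, width = l))
        good <- countOverlaps(cand, avoid) == 0L
        chrom[todo[good]] <- chr[good]
        st[todo[good]] <- s[good]
        lens[todo[good]] <- l[good]
        todo <- todo[!good]
    }
    GRanges(chrom, IRanges(st, width = lens))
}

#' Simulate a genotyped multi-population SV cohort with truth labels
#'
#' Draws SV intervals on the reference (uniform outside gaps and high-depth
#' regions, with planted exceptions), an ancestral ALT frequency per SV,
#' per-population frequencies under the Balding-Nichols model, genotypes
#' under Hardy-Weinberg equilibrium within populations, and per-call DHFFC
#' from truncated normals conditional on SV type and genotype. Planted:
#' domestication SVs (farmed frequency shifted by \code{deltaAF} with a
#' recorded direction), consequence-class SVs (fully intronic, exon-deleting,
#' two-gene-spanning), and per-mode filter failures. The truth table records,
#' per SV, everything the filter cascade and downstream scans should find,
#' with the allele-count/call-rate labels computed on the post-masking
#' genotypes the generator itself emitted.
#'
#' @param config a \code{\link{simConfig}} list.
#' @param reference output of \code{\link{simulateReference}}.
#' @return List with \code{cohort} (an \code{SVCohort} with GT and DHFFC
#'   assays), \code{panel} (a \code{PopulationPanel}), \code{truth}
#'   (data.frame, one row per VCF record), \code{artifactCells} (logical
#'   matrix of planted bad-DHFFC carrier calls), \code{depth} (the reference
#'   depth track).
#' @export
simulateCohort <- function(config, reference) {
    set.seed(config$seed + 1L)
    chroms <- reference$chromLengths
    avoid <- reduce(c(granges(reference$gaps), reference$highDepth))
    models <- reference$models

    types <- rep(names(config$svCounts), config$svCounts)
    nSV <- length(types)
    lens <- integer(nSV)
    for (t in c("DEL", "DUP", "INV")) {
        idx <- types == t
        lens[idx] <- pmax(50L, pmin(as.integer(round(stats::rlnorm(
            sum(idx), config$lengthMeanlog[[t]], config$lengthSdlog[[t]]))),
            as.integer(config$maxLength)))
    }
    lens[types == "BND"] <- 1L

    ## consequence planting claims the first DELs / INVs
    cons <- rep(NA_character_, nSV)
    chrom_v <- rep(names(chroms)[1], nSV)
    start_v <- rep(1L, nSV)
    end_v <- rep(1L, nSV)
    placed <- rep(FALSE, nSV)
    del_pool <- which(types == "DEL")
    inv_pool <- which(types == "INV")

    exon_list <- models@exons
    tx_ids <- names(exon_list)
    ## introns wide enough to hold a small DEL strictly inside
    plant_intron <- function(k) {
        picks <- integer(0)
        for (txi in sample(tx_ids)) {
            ex <- exon_list[[txi]]
            if (length(ex) < 2) next
            gaps_tx <- IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1] - 1L)
            wide <- which(width(gaps_tx) >= 400)
            if (!length(wide)) next
            gi <- wide[1]
            st <- start(gaps_tx)[gi] + 50L
            en <- st + min(200L, width(gaps_tx)[gi] - 150L)
            picks <- c(picks, gi)
            i <- del_pool[1]; del_pool <<- del_pool[-1]
            chrom_v[i] <<- as.character(seqnames(ex))[1]
            start_v[i] <<- st; end_v[i] <<- en
            lens[i] <<- en - st + 1L
            cons[i] <<- "intron"; placed[i] <<- TRUE
            if (length(picks) >= k) break
        }
    }
    plant_exon_loss <- function(k) {
        done <- 0L
        for (txi in sample(tx_ids)) {
            ex <- exon_list[[txi]]
            if (length(ex) < 3) next
            j <- .resample(2:(length(ex) - 1L), 1)
            st <- end(ex)[j - 1] + max(2L, (start(ex)[j] - end(ex)[j - 1]) %/% 2L)
            en <- start(ex)[j + 1] - max(2L, (start(ex)[j + 1] - end(ex)[j]) %/% 2L)
            if (en <= st || st <= end(ex)[j - 1] || en >= start(ex)[j + 1]) next
            i <- del_pool[1]; del_pool <<- del_pool[-1]
            chrom_v[i] <<- as.character(seqnames(ex))[1]
            start_v[i] <<- st; end_v[i] <<- en
            lens[i] <<- en - st + 1L
            cons[i] <<- "exon_loss"; placed[i] <<- TRUE
            done <- done + 1L
            if (done >= k) break
        }
    }
    plant_fusion <- function(k) {
        genes <- sort(models@genes)
        done <- 0L
        ord <- sample(seq_len(max(0, length(genes) - 1L)))
        for (gi in ord) {
            g1 <- genes[gi]; g2 <- genes[gi + 1L]
            if (as.character(seqnames(g1)) != as.character(seqnames(g2))) next
            if (width(g1) < 10 || width(g2) < 10) next
            st <- start(g1) + floor(width(g1) / 2)
            en <- start(g2) + floor(width(g2) / 2)
            if (en <= st) next
            pool <- if (done %% 2 == 0 && length(inv_pool)) "INV" else "DEL"
            if (pool == "INV") { i <- inv_pool[1]; inv_pool <<- inv_pool[-1] }
            else { i <- del_pool[1]; del_pool <<- del_pool[-1] }
            chrom_v[i] <<- as.character(seqnames(g1))
            start_v[i] <<- st; end_v[i] <<- en
            lens[i] <<- en - st + 1L
            cons[i] <<- "fusion"; placed[i] <<- TRUE
            done <- done + 1L
            if (done >= k) break
        }
    }
    if (length(tx_ids)) {
        plant_intron(config$nConsequence[["intron"]])
        plant_exon_loss(config$nConsequence[["exon_loss"]])
        plant_fusion(config$nConsequence[["fusion"]])
    }

    ## fail-mode assignment over unplaced records
    free <- which(!placed)
    modes <- c("gap", "high_depth", "dhffc_artifact", "low_ac",
               "low_call_rate")
    fail <- matrix(FALSE, nSV, length(modes),
                   dimnames = list(NULL, modes))
    pool <- .resample(free)
    for (m in modes) {
        nm <- round(config$failFractions[[m]] * nSV)
        nm <- min(nm, length(pool))
        if (m %in% c("dhffc_artifact")) {
            ## needs carriers with maskable DHFFC: restrict to DEL/DUP/INV
            sel <- pool[types[pool] != "BND"][seq_len(min(nm, sum(types[pool] != "BND")))]
        } else sel <- pool[seq_len(nm)]
        fail[sel, m] <- TRUE
        pool <- setdiff(pool, sel)
    }

    ## placement: planted gap / high-depth overlaps, everything else clean
    for (i in which(fail[, "gap"])) {
        g <- reference$gaps[sample(length(reference$gaps), 1)]
        st <- max(1L, start(g) - as.integer(lens[i] %/% 2L))
        chrom_v[i] <- as.character(seqnames(g))
        start_v[i] <- st; end_v[i] <- st + lens[i] - 1L
        placed[i] <- TRUE
    }
    hd <- reference$highDepth
    for (i in which(fail[, "high_depth"])) {
        g <- hd[sample(length(hd), 1)]
        st <- max(1L, start(g) - as.integer(lens[i] %/% 2L))
        chrom_v[i] <- as.character(seqnames(g))
        start_v[i] <- st; end_v[i] <- st + lens[i] - 1L
        placed[i] <- TRUE
    }
    rest <- which(!placed)
    if (length(rest)) {
        got <- .place_uniform(length(rest), lens[rest], chroms, avoid = avoid)
        chrom_v[rest] <- as.character(seqnames(got))
        start_v[rest] <- start(got); end_v[rest] <- end(got)
        lens[rest] <- width(got)
        lens[types == "BND"] <- 1L
    }
    ids <- sprintf("sv%05d", seq_len(nSV))
    ranges <- GRanges(factor(chrom_v, names(chroms)), IRanges(start_v, end_v))
    names(ranges) <- ids

    ## population frequencies: Balding-Nichols around a shared ancestral p
    pops <- names(config$populations)
    p0 <- stats::runif(nSV, config$ancestralRange[1], config$ancestralRange[2])
    af <- matrix(NA_real_, nSV, length(pops), dimnames = list(ids, pops))
    for (pp in pops) {
        F <- config$popF[[pp]]
        af[, pp] <- stats::rbeta(nSV, p0 * (1 - F) / F,
                                 (1 - p0) * (1 - F) / F)
    }
    dom_pool <- setdiff(which(types != "BND" & !fail[, "low_ac"] &
                              !fail[, "low_call_rate"] &
                              !fail[, "gap"] & !fail[, "high_depth"] &
                              !fail[, "dhffc_artifact"] & is.na(cons)),
                        integer(0))
    dom <- sort(.resample(dom_pool, min(config$nDomestication,
                                     length(dom_pool))))
    ## planted SVs bypass the Balding-Nichols draw: every wild group sits at
    ## the shared wild (ancestral) frequency and only the farmed group is
    ## shifted by deltaAF, so the farmed-vs-wild contrast is the planted shift
    wild_pops <- setdiff(pops, "FARMED")
    dom_dir <- ifelse(p0[dom] <= 0.5, 1, -1)
    if (length(dom)) {
        for (pp in wild_pops) af[dom, pp] <- p0[dom]
        if ("FARMED" %in% pops)
            af[dom, "FARMED"] <- pmin(1, pmax(0, p0[dom] +
                                              dom_dir * config$deltaAF))
    }

    ## samples and genotypes (HWE within populations)
    prefix <- c(FARMED = "F", WILD_A = "A", WILD_E = "E", WILD_W = "W")
    smp <- unlist(lapply(pops, function(pp) {
        pre <- if (pp %in% names(prefix)) prefix[[pp]] else paste0(pp, "_")
        sprintf("%s%03d", pre, seq_len(config$populations[[pp]]))
    }))
    assignment <- stats::setNames(rep(pops, config$populations), smp)
    hyb <- if (config$nHybrids > 0) sprintf("H%03d", seq_len(config$nHybrids))
        else character(0)
    panel <- PopulationPanel(assignment = assignment, excluded = hyb)
    all_smp <- c(smp, hyb)
    gt <- matrix(NA_integer_, nSV, length(all_smp),
                 dimnames = list(ids, all_smp))
    for (pp in pops) {
        cols <- smp[assignment == pp]
        gt[, cols] <- matrix(stats::rbinom(nSV * length(cols), 2L,
                                           rep(af[, pp], length(cols))),
                             nSV, length(cols))
    }
    if (length(hyb)) {
        wilds <- setdiff(pops, "FARMED")
        haf <- if (length(wilds) >= 2)
            (af[, wilds[1]] + af[, wilds[2]]) / 2 else af[, pops[1]]
        gt[, hyb] <- matrix(stats::rbinom(nSV * length(hyb), 2L,
                                          rep(haf, length(hyb))),
                            nSV, length(hyb))
    }
    ## planted low-AC records: exactly 1 or 2 ALT alleles in total
    for (i in which(fail[, "low_ac"])) {
        gt[i, ] <- 0L
        nalt <- sample(1:2, 1)
        gt[i, sample(length(all_smp), nalt)] <- 1L
    }
    ## planted low call rate: 25-40% missing
    for (i in which(fail[, "low_call_rate"])) {
        nmiss <- ceiling(stats::runif(1, 0.25, 0.40) * length(all_smp))
        gt[i, sample(length(all_smp), nmiss)] <- NA_integer_
    }

    ## DHFFC conditional on (type, genotype); artifacts inside the mask band
    dh <- matrix(.rtnorm(nSV * length(all_smp), 1, 0.05, lo = 0),
                 nSV, length(all_smp), dimnames = list(ids, all_smp))
    carrier <- !is.na(gt) & gt > 0L
    draw_cells <- function(cells, mean, sd, lo, hi) {
        n <- sum(cells)
        if (n) dh[cells] <<- .rtnorm(n, mean, sd, lo, hi)
    }
    art <- fail[, "dhffc_artifact"]
    is_t <- function(t) types == t
    draw_cells(carrier & is_t("DEL") & !art & gt == 1L, 0.5, 0.1, 0, 0.7)
    draw_cells(carrier & is_t("DEL") & !art & gt == 2L, 0.05, 0.05, 0, 0.7)
    draw_cells(carrier & is_t("DUP") & !art, 1.6, 0.15, 1.3, Inf)
    inv_clean <- which(carrier & is_t("INV") & !art)
    if (length(inv_clean)) {
        lowside <- stats::runif(length(inv_clean)) < 0.5
        dh[inv_clean[lowside]] <- .rtnorm(sum(lowside), 0.5, 0.08, 0, 0.7)
        dh[inv_clean[!lowside]] <- .rtnorm(sum(!lowside), 1.5, 0.08, 1.3, Inf)
    }
    eps <- 1e-6
    draw_cells(carrier & is_t("DEL") & art, 1.0, 0.1, 0.7 + eps, Inf)
    draw_cells(carrier & is_t("DUP") & art, 1.0, 0.1, 0, 1.3 - eps)
    draw_cells(carrier & is_t("INV") & art, 1.0, 0.1, 0.7 + eps, 1.3 - eps)
    artifactCells <- carrier & art

    ## truth labels; AC / call rate on the post-masking genotypes
    gt_masked <- gt
    gt_masked[artifactCells] <- NA_integer_
    ac_post <- rowSums(gt_masked, na.rm = TRUE)
    rate_post <- rowMeans(!is.na(gt_masked))
    gap_ov <- countOverlaps(ranges, reference$gaps) > 0L
    hd_ov <- countOverlaps(ranges, reference$highDepth) > 0L
    truth <- data.frame(
        sv_id = ids, chrom = as.character(seqnames(ranges)),
        start = start(ranges), end = end(ranges), svtype = types,
        length = ifelse(types == "BND", NA_integer_, lens),
        ancestral_af = p0, stringsAsFactors = FALSE)
    for (pp in pops) truth[[paste0("af_", pp)]] <- af[, pp]
    truth$domestication <- seq_len(nSV) %in% dom
    truth$dom_direction <- NA_integer_
    truth$dom_direction[dom] <- as.integer(dom_dir)
    truth$consequence <- cons
    truth$fail_translocation <- types == "BND"
    truth$fail_gap <- gap_ov
    truth$fail_high_depth <- hd_ov
    truth$dhffc_artifact <- fail[, "dhffc_artifact"]
    truth$n_masked <- rowSums(artifactCells)
    truth$fail_low_ac <- ac_post < 3L
    truth$fail_low_call_rate <- rate_post < 0.80
    truth$pass <- !(truth$fail_translocation | truth$fail_gap |
                    truth$fail_high_depth | truth$fail_low_ac |
                    truth$fail_low_call_rate)

    cohort <- SVCohort(ranges, svtype = types, gt = gt, dhffc = dh)
    list(cohort = cohort, panel = panel, truth = truth,
         artifactCells = artifactCells, depth = reference$depth)
}

#' Write simulation truth tables as TSV
#' @param truth truth data.frame from \code{\link{simulateCohort}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
emitTruthTables <- function(truth, path) {
    data.table::fwrite(truth, path, sep = "\t")
    invisible(path)
}

#' Write all simulation artifacts to a directory
#'
#' Emits genome.tsv, genes.gff3, repeats.bed, gerp.bed, gaps.bed,
#' depth.bedgraph, cohort.vcf, pops.tsv and truth_svs.tsv.
#'
#' @param reference output of \code{\link{simulateReference}}.
#' @param sim output of \code{\link{simulateCohort}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(reference, sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    data.table::fwrite(data.frame(chrom = names(reference$chromLengths),
                                  length = unname(reference$chromLengths)),
                       p("genome.tsv"), sep = "\t")
    writeGeneModels(reference$models, p("genes.gff3"))
    writeBedIntervals(reference$repeats, p("repeats.bed"))
    writeBedIntervals(reference$gerp, p("gerp.bed"))
    writeBedIntervals(reference$gaps, p("gaps.bed"))
    writeDepthTrack(reference$depth, p("depth.bedgraph"))
    writeSVVcf(sim$cohort, p("cohort.vcf"))
    writePopulationMap(sim$panel, p("pops.tsv"))
    emitTruthTables(sim$truth, p("truth_svs.tsv"))
    invisible(dir)
}
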