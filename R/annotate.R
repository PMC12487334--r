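#' @include AllClasses.R
NULL

.IMPACT_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

.TERM_IMPACT <- c(
    transcript_ablation = "HIGH", exon_loss_variant = "HIGH",
    frameshift_variant = "HIGH", gene_fusion = "HIGH",
    bidirectional_gene_fusion = "HIGH",
    duplication = "MODERATE", transcript_inversion = "MODERATE",
    "5_prime_UTR_variant" = "LOW", "3_prime_UTR_variant" = "LOW",
    intron_variant = "MODIFIER", upstream_gene_variant = "MODIFIER",
    downstream_gene_variant = "MODIFIER", intergenic_region = "MODIFIER",
    gene_variant = "MODIFIER")

#' The HIGH-impact consequence terms
#' @return Character vector of terms in the HIGH tier.
#' @export
highImpactTerms <- function() {
    names(.TERM_IMPACT)[.TERM_IMPACT == "HIGH"]
}

.pos_in <- function(pos, gr) {
    any(pos >= start(gr) & pos <= end(gr))
}

#' Classify the gene-level consequences of structural variants
#'
#' A deliberately compact SnpEff-style vocabulary at SV granularity. Per
#' overlapping or nearby gene it emits: \code{transcript_ablation} (DEL
#' spanning a whole transcript), \code{exon_loss_variant} (DEL fully
#' containing at least one exon but not a whole transcript),
#' \code{frameshift_variant} (DEL/DUP breakpoint strictly inside CDS with the
#' affected CDS length not a multiple of 3), \code{gene_fusion} /
#' \code{bidirectional_gene_fusion} (one breakpoint inside each of two genes,
#' same / opposite strand), \code{duplication} (DUP fully containing exons),
#' \code{transcript_inversion} (INV spanning whole genes), UTR variants
#' (breakpoint in a UTR), \code{intron_variant} (SV fully inside one intron),
#' \code{upstream_gene_variant}/\code{downstream_gene_variant} (within
#' \code{updownBp} of a gene without overlapping it) and
#' \code{intergenic_region} (no gene within \code{updownBp}). All applicable
#' terms are emitted per gene; every SV yields at least one annotation.
#'
#' @param ranges named \code{GRanges} of SV intervals.
#' @param svtype character vector of SV types aligned with \code{ranges}.
#' @param models a \code{GeneModelSet}.
#' @param updownBp up/downstream window in bp (default 5000).
#' @return data.frame with columns \code{sv_id}, \code{gene_id} (\code{NA}
#'   for intergenic), \code{consequence}, \code{impact}.
#' @export
classifySV <- function(ranges, svtype, models, updownBp = 5000L) {
    stopifnot(length(ranges) == length(svtype))
    genes <- models@genes
    ids <- .ids_of(ranges)
    tx_by_gene <- split(models@txGene$tx_id, models@txGene$gene_id)
    ## plain-vector views of the gene models (the per-SV loop is base arithmetic)
    gS <- start(genes); gE <- end(genes)
    gStr <- as.character(strand(genes)); gId <- names(genes)
    exS <- as.list(start(models@exons)); exE <- as.list(end(models@exons))
    cdS <- as.list(start(models@cds)); cdE <- as.list(end(models@cds))
    u5S <- as.list(start(models@utr5)); u5E <- as.list(end(models@utr5))
    u3S <- as.list(start(models@utr3)); u3E <- as.list(end(models@utr3))
    svS <- start(ranges); svE <- end(ranges)
    out_sv <- character(); out_gene <- character(); out_term <- character()
    emit <- function(sv_id, gene_id, term) {
        out_sv[length(out_sv) + 1L] <<- sv_id
        out_gene[length(out_gene) + 1L] <<- gene_id
        out_term[length(out_term) + 1L] <<- term
    }
    ovAll <- suppressWarnings(findOverlaps(ranges, genes,
                                           ignore.strand = TRUE))
    nearAll <- suppressWarnings(findOverlaps(ranges, genes, maxgap = updownBp,
                                             ignore.strand = TRUE))
    ov_by_sv <- split(subjectHits(ovAll), factor(queryHits(ovAll),
                                                 seq_along(ranges)))
    near_by_sv <- split(subjectHits(nearAll), factor(queryHits(nearAll),
                                                     seq_along(ranges)))
    for (i in seq_along(ranges)) {
        n_before <- length(out_sv)
        t <- svtype[i]
        s1 <- svS[i]; s2 <- svE[i]
        gidx <- ov_by_sv[[i]]
        nidx <- setdiff(near_by_sv[[i]], gidx)
        if (!length(gidx) && !length(nidx)) {
            emit(ids[i], NA_character_, "intergenic_region")
            next
        }
        ## fusion: one breakpoint strictly inside each of two distinct genes
        if (length(gidx) >= 2) {
            in1 <- gidx[s1 > gS[gidx] & s1 < gE[gidx]]
            in2 <- gidx[s2 > gS[gidx] & s2 < gE[gidx]]
            for (ga in in1) for (gb in in2) {
                if (ga == gb) next
                term <- if (gStr[ga] == gStr[gb]) "gene_fusion" else
                    "bidirectional_gene_fusion"
                emit(ids[i], gId[ga], term)
                emit(ids[i], gId[gb], term)
            }
        }
        for (gi in gidx) {
            gid <- gId[gi]
            for (txi in tx_by_gene[[gid]]) {
                es <- exS[[txi]]
                if (is.null(es)) next
                ee <- exE[[txi]]
                txS <- min(es); txE <- max(ee)
                whole_tx <- s1 <= txS && s2 >= txE
                exon_contained <- any(s1 <= es & s2 >= ee)
                if (t == "DEL" && whole_tx)
                    emit(ids[i], gid, "transcript_ablation")
                if (t == "DEL" && !whole_tx && exon_contained)
                    emit(ids[i], gid, "exon_loss_variant")
                if (t == "DUP" && exon_contained)
                    emit(ids[i], gid, "duplication")
                cs <- cdS[[txi]]
                if (t %in% c("DEL", "DUP") && !is.null(cs)) {
                    ce <- cdE[[txi]]
                    bp_in_cds <- any(s1 > cs & s1 < ce) ||
                        any(s2 > cs & s2 < ce)
                    if (bp_in_cds) {
                        aff <- sum(pmax(0L, pmin(s2, ce) - pmax(s1, cs) + 1L))
                        if (aff %% 3L != 0L)
                            emit(ids[i], gid, "frameshift_variant")
                    }
                }
                ## fully inside one intron: within transcript, no exon touched
                if (s1 >= txS && s2 <= txE && !any(s1 <= ee & s2 >= es))
                    emit(ids[i], gid, "intron_variant")
                us <- u5S[[txi]]
                if (!is.null(us) && length(us)) {
                    ue <- u5E[[txi]]
                    if (any(s1 >= us & s1 <= ue) || any(s2 >= us & s2 <= ue))
                        emit(ids[i], gid, "5_prime_UTR_variant")
                }
                us <- u3S[[txi]]
                if (!is.null(us) && length(us)) {
                    ue <- u3E[[txi]]
                    if (any(s1 >= us & s1 <= ue) || any(s2 >= us & s2 <= ue))
                        emit(ids[i], gid, "3_prime_UTR_variant")
                }
            }
            if (t == "INV" && s1 <= gS[gi] && s2 >= gE[gi])
                emit(ids[i], gid, "transcript_inversion")
        }
        for (gi in nidx) {
            before <- s2 < gS[gi]
            term <- if ((before && gStr[gi] != "-") ||
                        (!before && gStr[gi] == "-"))
                "upstream_gene_variant" else "downstream_gene_variant"
            emit(ids[i], gId[gi], term)
        }
        ## catch-all: a gene is overlapped/nearby but no rule above fired
        if (length(out_sv) == n_before) {
            if (length(gidx))
                for (gi in gidx) emit(ids[i], gId[gi], "gene_variant")
            else emit(ids[i], NA_character_, "intergenic_region")
        }
    }
    ann <- data.frame(sv_id = out_sv, gene_id = out_gene,
                      consequence = out_term,
                      impact = unname(.TERM_IMPACT[out_term]),
                      stringsAsFactors = FALSE)
    ann <- unique(ann[order(match(ann$sv_id, ids)), , drop = FALSE])
    rownames(ann) <- NULL
    ann
}

#' Gene sets for enrichment from an annotation table
#'
#' @param annotations data.frame from \code{\link{classifySV}}.
#' @param allGeneIds character vector of every gene id in the annotation.
#' @return List with \code{affected} (genes with at least one HIGH-impact
#'   annotation), \code{associated} (genes with any annotation, including
#'   up/downstream) and \code{background} (\code{allGeneIds} minus
#'   \code{affected}).
#' @export
aggregateGeneSets <- function(annotations, allGeneIds) {
    with_gene <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
    affected <- unique(with_gene$gene_id[with_gene$impact == "HIGH"])
    list(affected = affected,
         associated = unique(with_gene$gene_id),
         background = setdiff(allGeneIds, affected))
}

#' Summarise annotation categories
#'
#' Per-term counts and proportions (over all emitted annotations; one SV may
#' contribute several), per-impact proportions, and per-SV term-set
#' co-occurrence counts (UpSet-style).
#'
#' @param annotations data.frame from \code{\link{classifySV}}.
#' @return List with \code{terms} (term, n, proportion), \code{impacts},
#'   \code{cooccurrence} (term_set, n over SVs).
#' @export
summarizeCategories <- function(annotations) {
    tt <- table(annotations$consequence)
    it <- table(annotations$impact)
    sets <- vapply(split(annotations$consequence, annotations$sv_id),
                   function(v) paste(sort(unique(v)), collapse = "+"),
                   character(1))
    st <- table(sets)
    list(terms = data.frame(term = names(tt), n = as.integer(tt),
                            proportion = as.numeric(tt) / sum(tt)),
         impacts = data.frame(impact = names(it), n = as.integer(it),
                              proportion = as.numeric(it) / sum(it)),
         cooccurrence = data.frame(term_set = names(st), n = as.integer(st)))
}

#' Select samples for visual curation of one SV
#'
#' Draws, without replacement and seeded, up to seven samples: two hom-ref,
#' two het and three hom-alt when available; shortfalls in a class are
#' back-filled at random from the remaining called samples. With fewer than
#' seven called samples, all of them are returned.
#'
#' @param gt named integer vector of ALT dosages for one SV.
#' @param seed integer seed making the draw reproducible.
#' @return Character vector of at most seven sample ids.
#' @export
selectCurationSamples <- function(gt, seed = 1L) {
    stopifnot(!is.null(names(gt)))
    called <- names(gt)[!is.na(gt)]
    if (length(called) <= 7L) return(called)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    pick <- function(pool, k) {
        if (length(pool) <= k) pool else sample(pool, k)
    }
    sel <- c(pick(names(gt)[!is.na(gt) & gt == 0L], 2L),
             pick(names(gt)[!is.na(gt) & gt == 1L], 2L),
             pick(names(gt)[!is.na(gt) & gt == 2L], 3L))
    short <- 7L - length(sel)
    if (short > 0)
        sel <- c(sel, pick(setdiff(called, sel), short))
    sel
}
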