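#' @include AllClasses.R
NULL

.gt_to_dosage <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
}

.dosage_to_gt <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0L] <- "0/0"
    out[!is.na(d) & d == 1L] <- "0/1"
    out[!is.na(d) & d == 2L] <- "1/1"
    out
}

#' Read a multi-sample SV VCF into an SVCohort
#'
#' Parses a VCF 4.x of symbolic structural variants. \code{POS}/\code{END}
#' (1-based inclusive) become the breakpoint interval; \code{SVTYPE} is taken
#' from INFO; per-sample \code{GT} is mapped to ALT dosage and an optional
#' per-sample \code{DHFFC} FORMAT field is kept as a matrix. Records lacking
#' \code{SVTYPE} are rejected with a warning; \code{END < POS} is an error.
#' Record and sample order are preserved. BND records keep a 1-bp interval at
#' \code{POS} (their length is undefined; they exist only to be filtered).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return An \code{SVCohort}. The number of rejected records is available as
#'   \code{metadata(x)$n_rejected}.
#' @export
readSVVcf <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    info <- vcf@fix[, "INFO"]
    grab <- function(key) {
        m <- regmatches(info, regexpr(sprintf("(?:^|;)%s=([^;]+)", key), info,
                                      perl = TRUE))
        out <- rep(NA_character_, length(info))
        hit <- grepl(sprintf("(?:^|;)%s=", key), info, perl = TRUE)
        out[hit] <- sub(sprintf("^;?%s=", key), "", m)
        out
    }
    svtype <- grab("SVTYPE")
    endv <- suppressWarnings(as.numeric(grab("END")))
    pos <- as.numeric(fix[, "POS"])
    id <- fix[, "ID"]
    no_id <- is.na(id) | id == "."
    id[no_id] <- paste0("sv", seq_along(id)[no_id])

    keep <- !is.na(svtype)
    if (any(!keep))
        warning(sprintf("rejected %d record(s) lacking SVTYPE", sum(!keep)))
    endv[is.na(endv) | svtype == "BND"] <- pos[is.na(endv) | svtype == "BND"]
    bad_end <- keep & endv < pos
    if (any(bad_end))
        stop(sprintf("END < POS for record(s): %s",
                     paste(id[bad_end], collapse = ", ")))

    samples <- setdiff(colnames(vcf@gt), "FORMAT")
    if (nrow(vcf@fix) == 0L) {
        gr0 <- GRanges()
        x <- SVCohort(gr0, character(0),
                      matrix(integer(0), 0, length(samples),
                             dimnames = list(NULL, samples)))
        metadata(x)$n_rejected <- 0L
        return(x)
    }
    gt_chr <- vcfR::extract.gt(vcf, element = "GT")
    gt <- matrix(.gt_to_dosage(gt_chr), nrow = nrow(gt_chr),
                 ncol = ncol(gt_chr))
    colnames(gt) <- colnames(gt_chr)
    dh <- NULL
    fmt <- vcf@gt[, "FORMAT"]
    if (any(grepl("(^|:)DHFFC(:|$)", fmt))) {
        dh <- suppressWarnings(
            vcfR::extract.gt(vcf, element = "DHFFC", as.numeric = TRUE))
        rownames(dh) <- NULL
    }
    gr <- GRanges(fix[keep, "CHROM"], IRanges(pos[keep], endv[keep]))
    names(gr) <- id[keep]
    x <- SVCohort(gr, svtype = svtype[keep],
                  gt = gt[keep, , drop = FALSE],
                  dhffc = if (is.null(dh)) NULL else dh[keep, , drop = FALSE])
    metadata(x)$n_rejected <- sum(!keep)
    x
}

#' Write an SVCohort as a VCF 4.2 file
#'
#' Emits symbolic ALT records with \code{SVTYPE}/\code{END}/\code{SVLEN} INFO
#' and \code{GT} (plus \code{DHFFC} when present) FORMAT fields. Masked
#' genotypes are written as \code{./.}. Output is deterministic: identical
#' cohorts produce byte-identical files.
#'
#' @param x an \code{SVCohort}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSVVcf <- function(x, path) {
    stopifnot(is(x, "SVCohort"))
    rr <- rowRanges(x)
    has_dh <- "DHFFC" %in% assayNames(x)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=svatlas",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    if (has_dh)
        hdr <- c(hdr, "##FORMAT=<ID=DHFFC,Number=1,Type=Float,Description=\"Duphold depth fold-change: variant versus flanking regions\">")
    for (chr in unique(as.character(seqnames(rr))))
        hdr <- c(hdr, sprintf("##contig=<ID=%s>", chr))
    hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT", colnames(x)),
                        collapse = "\t"))
    gt <- genotypes(x)
    svt <- unname(svType(x))
    n <- nrow(x)
    body <- character(n)
    dh <- if (has_dh) dhffcMatrix(x) else NULL
    for (i in seq_len(n)) {
        info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", svt[i], end(rr)[i],
                        width(rr)[i])
        cells <- .dosage_to_gt(gt[i, ])
        if (has_dh) {
            dhv <- ifelse(is.na(dh[i, ]), ".", sprintf("%.6g", dh[i, ]))
            cells <- paste(cells, dhv, sep = ":")
        }
        body[i] <- paste(c(as.character(seqnames(rr))[i], start(rr)[i],
                           rownames(x)[i], "N", sprintf("<%s>", svt[i]), ".",
                           "PASS", info, if (has_dh) "GT:DHFFC" else "GT",
                           cells), collapse = "\t")
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a BED3/BED4 file as a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the internal 1-based
#' closed convention. Lines with \code{start >= end} are rejected with a
#' warning; duplicates and order are preserved verbatim, no merging. A fourth
#' column, when present, is kept as the \code{name} metadata column.
#'
#' @param path path to a BED file.
#' @return \code{GRanges}; rejected-line count in \code{metadata(x)$n_rejected}
#'   is attached as attribute \code{"n_rejected"}.
#' @export
readBedIntervals <- function(path) {
    bed <- data.table::fread(path, header = FALSE, sep = "\t",
                             data.table = FALSE)
    if (!ncol(bed) >= 3) stop("BED file needs at least 3 columns")
    bad <- bed[[2]] >= bed[[3]]
    if (any(bad))
        warning(sprintf("rejected %d BED line(s) with start >= end", sum(bad)))
    bed <- bed[!bad, , drop = FALSE]
    gr <- GRanges(as.character(bed[[1]]), IRanges(bed[[2]] + 1L, bed[[3]]))
    if (ncol(bed) >= 4) mcols(gr)$name <- as.character(bed[[4]])
    attr(gr, "n_rejected") <- sum(bad)
    gr
}

#' Write a GRanges as BED (0-based half-open)
#' @param gr a \code{GRanges}; a \code{name} metadata column becomes column 4.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedIntervals <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                     end = end(gr))
    if (!is.null(mcols(gr)$name)) df$name <- mcols(gr)$name
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read a bedGraph-like mean-depth track
#'
#' Four columns: chrom, start (0-based), end, mean depth over the segment.
#'
#' @param path path to the track.
#' @return \code{GRanges} with a numeric \code{depth} metadata column.
#' @export
readDepthTrack <- function(path) {
    d <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE)
    if (ncol(d) < 4) stop("depth track needs 4 columns (chrom,start,end,depth)")
    gr <- GRanges(as.character(d[[1]]), IRanges(d[[2]] + 1L, d[[3]]))
    mcols(gr)$depth <- as.numeric(d[[4]])
    gr
}

#' @rdname readDepthTrack
#' @param gr depth track \code{GRanges} (with \code{depth} column).
#' @export
writeDepthTrack <- function(gr, path) {
    data.table::fwrite(data.frame(as.character(seqnames(gr)), start(gr) - 1L,
                                  end(gr), mcols(gr)$depth),
                       path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read GFF3 gene models
#'
#' Builds a \code{GeneModelSet} from \code{gene}, \code{mRNA}/\code{transcript},
#' \code{exon}, \code{CDS} and UTR features linked by \code{ID}/\code{Parent}.
#' Exons whose parent transcript cannot be resolved are skipped with a
#' warning; a CDS extending outside its transcript's exon union is an error.
#'
#' @param path path to a GFF3 file.
#' @return A \code{GeneModelSet}.
#' @export
readGeneModels <- function(path) {
    g <- rtracklayer::import(path, format = "gff3")
    type <- as.character(g$type)
    first_parent <- function(p) vapply(p, function(v)
        if (length(v)) v[[1]] else NA_character_, character(1))
    genes <- g[type == "gene"]
    names(genes) <- genes$ID
    mcols(genes) <- NULL
    tx <- g[type %in% c("mRNA", "transcript")]
    txGene <- data.frame(tx_id = tx$ID, gene_id = first_parent(tx$Parent),
                         stringsAsFactors = FALSE)
    known_tx <- txGene$tx_id

    collect <- function(what) {
        feat <- g[type %in% what]
        par <- first_parent(feat$Parent)
        orphan <- !(par %in% known_tx)
        if (any(orphan) && what[1] == "exon")
            warning(sprintf("skipped %d exon(s) with unresolvable Parent",
                            sum(orphan)))
        feat <- feat[!orphan]
        par <- par[!orphan]
        mcols(feat) <- NULL
        out <- split(feat, factor(par, levels = known_tx))
        out[lengths(out) > 0]
    }
    exons <- collect("exon")
    cds <- collect("CDS")
    bad <- .cdsOutsideExons(cds, exons)
    if (length(bad))
        stop(sprintf("CDS outside exon union for transcript(s): %s",
                     paste(bad, collapse = ", ")))
    GeneModelSet(genes = genes, txGene = txGene, exons = exons, cds = cds,
                 utr5 = collect(c("five_prime_UTR", "5UTR")),
                 utr3 = collect(c("three_prime_UTR", "3UTR")))
}

#' Write a GeneModelSet as GFF3
#' @param models a \code{GeneModelSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    ln <- "##gff-version 3"
    fmt <- function(gr, type, attrs) {
        sprintf("%s\tsvatlas\t%s\t%d\t%d\t.\t%s\t.\t%s",
                as.character(seqnames(gr)), type, start(gr), end(gr),
                as.character(strand(gr)), attrs)
    }
    genes <- models@genes
    for (gid in names(genes)) {
        ln <- c(ln, fmt(genes[gid], "gene", sprintf("ID=%s", gid)))
        txs <- models@txGene$tx_id[models@txGene$gene_id == gid]
        for (txi in txs) {
            ex <- models@exons[[txi]]
            tx_range <- range(ex)
            ln <- c(ln, fmt(tx_range, "mRNA",
                            sprintf("ID=%s;Parent=%s", txi, gid)))
            ln <- c(ln, fmt(ex, "exon", sprintf("Parent=%s", txi)))
            if (txi %in% names(models@cds))
                ln <- c(ln, fmt(models@cds[[txi]], "CDS",
                                sprintf("Parent=%s", txi)))
            if (txi %in% names(models@utr5))
                ln <- c(ln, fmt(models@utr5[[txi]], "five_prime_UTR",
                                sprintf("Parent=%s", txi)))
            if (txi %in% names(models@utr3))
                ln <- c(ln, fmt(models@utr3[[txi]], "three_prime_UTR",
                                sprintf("Parent=%s", txi)))
        }
    }
    writeLines(ln, path)
    invisible(path)
}

#' Read a sample-to-population map
#'
#' Two tab-separated columns (sample, group) with an optional third column
#' whose non-empty/non-zero values flag the sample as excluded from all
#' statistics (e.g. F1 hybrids). A sample assigned to two groups is an error.
#'
#' @param path path to the TSV (no header).
#' @return A \code{PopulationPanel}.
#' @export
readPopulationMap <- function(path) {
    m <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                           data.table = FALSE, colClasses = "character")
    if (ncol(m) < 2) stop("population map needs 2 columns (sample, group)")
    excl <- if (ncol(m) >= 3)
        m[[3]] %in% c("1", "TRUE", "exclude", "excluded", "hybrid") else
        rep(FALSE, nrow(m))
    smp <- m[[1]][!excl]
    if (anyDuplicated(smp))
        stop(sprintf("sample(s) assigned to two groups: %s",
                     paste(unique(smp[duplicated(smp)]), collapse = ", ")))
    PopulationPanel(assignment = setNames(m[[2]][!excl], smp),
                    excluded = m[[1]][excl])
}

#' @rdname readPopulationMap
#' @param panel a \code{PopulationPanel}.
#' @export
writePopulationMap <- function(panel, path) {
    df <- data.frame(sample = c(names(panel@assignment), panel@excluded),
                     group = c(unname(panel@assignment),
                               rep("HYBRID", length(panel@excluded))),
                     exclude = c(rep(0L, length(panel@assignment)),
                                 rep(1L, length(panel@excluded))))
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
    invisible(path)
}
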