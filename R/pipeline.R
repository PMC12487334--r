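#' @include AllClasses.R
NULL

.write_tsv <- function(x, path) {
    data.table::fwrite(as.data.frame(x), path, sep = "\t")
    path
}

#' Run the full SV post-calling analysis pipeline
#'
#' Orchestrates filter cascade, consequence annotation, repeat and
#' constrained-element overlap, allele statistics, density, F_ST, the
#' domestication candidate scan and (when term maps are supplied) enrichment,
#' writing every table as TSV plus a machine-readable run manifest. GERP and
#' repeat stages are skipped, and recorded as skipped, when their inputs are
#' absent.
#'
#' @param paths named list of input paths: \code{vcf}, \code{pops},
#'   \code{genome} (TSV chrom/length), and optionally \code{gff3},
#'   \code{gaps}, \code{depth}, \code{repeats}, \code{gerp}, \code{terms}
#'   (TSV term, gene).
#' @param outDir output directory (created).
#' @param config a \code{FilterConfig}.
#' @param quantile top-tail quantile of the candidate scan.
#' @param updownBp annotation up/downstream window (bp).
#' @param farmedGroup label of the group shared by all scan comparisons.
#' @param seed integer seed for the curation-sample stage.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
runPipeline <- function(paths, outDir, config = filterConfig(),
                        quantile = 0.95, updownBp = 5000L,
                        farmedGroup = "FARMED", seed = 1L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(outDir, f)
    manifest <- list(seed = seed, stages = list(), skipped = character())
    has <- function(k) !is.null(paths[[k]]) && file.exists(paths[[k]])

    cohort <- readSVVcf(paths$vcf)
    panel <- readPopulationMap(paths$pops)
    genome <- data.table::fread(paths$genome, data.table = FALSE)
    chromLengths <- stats::setNames(as.integer(genome[[2]]),
                                    as.character(genome[[1]]))
    manifest$stages$input <- list(n_sv = nrow(cohort), n_samples = ncol(cohort))

    gaps <- if (has("gaps")) readBedIntervals(paths$gaps) else GRanges()
    hd <- if (has("depth"))
        highDepthRegions(readDepthTrack(paths$depth), config@depthThreshold)
        else GRanges()
    casc <- runFilterCascade(cohort, config, gaps = gaps, highDepth = hd)
    filtered <- casc$cohort
    .write_tsv(casc$report, o("filter_funnel.tsv"))
    writeSVVcf(filtered, o("filtered.vcf"))
    manifest$stages$filter <- list(n_in = nrow(cohort),
                                   n_out = nrow(filtered),
                                   n_masked = sum(casc$report$n_masked))

    keep <- intersect(colnames(filtered), panelSamples(panel))
    stats <- alleleStats(filtered, keep)
    summ <- sizeMafSummaries(unname(svType(filtered)),
                             unname(svLength(filtered)), stats$maf)
    .write_tsv(summ$perType, o("size_maf.tsv"))
    dens <- svDensity(rowRanges(filtered), chromLengths)
    .write_tsv(dens, o("density.tsv"))
    manifest$stages$summaries <- list(
        n_maf_lt_0.05 = summ$n_maf_lt_0.05,
        n_high_windows = sum(dens$class == "HIGH"),
        n_low_windows = sum(dens$class == "LOW"))

    ann <- NULL
    if (has("gff3")) {
        models <- readGeneModels(paths$gff3)
        ann <- classifySV(rowRanges(filtered), unname(svType(filtered)),
                          models, updownBp = updownBp)
        .write_tsv(ann, o("annotations.tsv"))
        cats <- summarizeCategories(ann)
        .write_tsv(cats$terms, o("categories.tsv"))
        .write_tsv(cats$cooccurrence, o("category_cooccurrence.tsv"))
        manifest$stages$annotate <- list(
            n_annotations = nrow(ann),
            n_high = sum(ann$impact == "HIGH"))
    } else manifest$skipped <- c(manifest$skipped, "annotate")

    if (has("repeats")) {
        reps <- readBedIntervals(paths$repeats)
        names(reps) <- paste0("rep", seq_along(reps), recycle0 = TRUE)
        rp <- overlapJoin(rowRanges(filtered), reps, minRecip = 0.5)
        .write_tsv(rp, o("repeat_overlap.tsv"))
        manifest$stages$repeats <- list(n_pairs = nrow(rp),
                                        n_sv = length(unique(rp$query_id)))
    } else manifest$skipped <- c(manifest$skipped, "repeats")

    if (has("gerp")) {
        gerp <- readBedIntervals(paths$gerp)
        gs <- summarizeGerpOverlap(rowRanges(filtered), gerp)
        .write_tsv(gs$perSV, o("gerp_per_sv.tsv"))
        manifest$stages$gerp <- list(n_sv = gs$nSVs, n_elements = gs$nElements)
        if (!is.null(ann) && gs$nSVs > 0) {
            hi <- unique(ann$sv_id[ann$impact == "HIGH"])
            sub_ids <- unique(gs$perSV$sv_id)
            tst <- subsetProportionTest(sum(sub_ids %in% hi),
                                        length(sub_ids), length(hi),
                                        nrow(filtered))
            .write_tsv(data.frame(k_sub = sum(sub_ids %in% hi),
                                  n_sub = length(sub_ids),
                                  k_all = length(hi), n_all = nrow(filtered),
                                  statistic = tst$statistic, p = tst$p),
                       o("gerp_high_impact_test.tsv"))
        }
    } else manifest$skipped <- c(manifest$skipped, "gerp")

    wild <- setdiff(panelGroups(panel), farmedGroup)
    fstTables <- lapply(wild, function(g) wcFst(filtered, panel,
                                                farmedGroup, g))
    .write_tsv(do.call(rbind, fstTables), o("fst.tsv"))
    pca <- genotypePCA(filtered, nComponents = 2L, samples = keep)
    .write_tsv(data.frame(sample = rownames(pca$coordinates),
                          pca$coordinates,
                          group = panel@assignment[rownames(pca$coordinates)]),
               o("pca.tsv"))
    cand <- candidateScan(fstTables, quantile = quantile)
    .write_tsv(cand, o("candidates.tsv"))
    manifest$stages$scan <- list(n_candidates = nrow(cand),
                                 thresholds = as.list(attr(cand, "thresholds")))
    if (!is.null(ann)) {
        cg <- candidateGeneTable(cand, ann, ranges = rowRanges(filtered))
        .write_tsv(cg$table, o("candidate_genes.tsv"))
        manifest$stages$scan$n_genes <- length(cg$genes)
    }

    if (has("terms") && !is.null(ann)) {
        tm <- data.table::fread(paths$terms, data.table = FALSE,
                                header = FALSE)
        termMap <- split(as.character(tm[[2]]), as.character(tm[[1]]))
        sets <- aggregateGeneSets(ann, unique(ann$gene_id[!is.na(ann$gene_id)]))
        enr <- genesetEnrichment(intersect(sets$affected, sets$associated),
                                 sets$associated, termMap)
        if (!is.null(enr)) .write_tsv(enr, o("enrichment.tsv"))
        manifest$stages$enrichment <- list(
            n_terms = if (is.null(enr)) 0L else nrow(enr))
    } else manifest$skipped <- c(manifest$skipped, "enrichment")

    cfg_txt <- paste(deparse(list(quantile = quantile, updownBp = updownBp,
                                  farmed = farmedGroup,
                                  thresholds = c(config@dhffcDelMax,
                                                 config@dhffcDupMin,
                                                 config@dhffcInvBand),
                                  minAC = config@minAlleleCount,
                                  minCallRate = config@minCallRate)),
                     collapse = "")
    tmp <- tempfile(); writeLines(cfg_txt, tmp)
    manifest$config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(list(cohort = filtered, report = casc$report,
                   annotations = ann, fst = fstTables, candidates = cand,
                   manifest = manifest))
}
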