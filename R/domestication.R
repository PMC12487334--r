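#' @include AllClasses.R
NULL

#' Top-quantile F_ST set for one comparison
#'
#' The threshold is the empirical quantile (linear interpolation, type 7) of
#' the defined theta values; membership is theta >= threshold, so ties at the
#' threshold are all included. Undefined thetas are excluded.
#'
#' @param fst data.frame from \code{\link{wcFst}}.
#' @param quantile quantile in (0, 1) (default 0.95, i.e. top 5%).
#' @param minDefined minimum number of defined theta values (default 20).
#' @return List with \code{ids} (sv ids at or above the threshold) and
#'   \code{threshold}.
#' @export
topQuantileSet <- function(fst, quantile = 0.95, minDefined = 20L) {
    th <- fst$theta[fst$defined]
    if (length(th) < minDefined)
        stop(sprintf("only %d defined theta values (need >= %d)",
                     length(th), minDefined))
    thr <- unname(stats::quantile(th, quantile, type = 7))
    list(ids = fst$sv_id[fst$defined & fst$theta >= thr], threshold = thr)
}

#' Farmed-versus-wild domestication candidate scan
#'
#' Keeps SVs that (i) fall in the top \code{1 - quantile} tail of per-site
#' F_ST in every comparison and (ii) show the same non-zero sign of allele
#' frequency change (group1 - group2) in every comparison. Output is sorted
#' by mean theta, descending.
#'
#' @param fstTables list of \code{\link{wcFst}} data.frames, one per
#'   comparison, all sharing the same first (e.g. farmed) group.
#' @param quantile top-tail quantile (default 0.95).
#' @return data.frame with one row per candidate: \code{sv_id}, per-comparison
#'   \code{theta_*} and \code{delta_af_*} columns, \code{mean_theta},
#'   \code{direction} (+1/-1). Attribute \code{"thresholds"} holds the
#'   per-comparison quantile thresholds.
#' @export
candidateScan <- function(fstTables, quantile = 0.95) {
    stopifnot(length(fstTables) >= 1)
    tops <- lapply(fstTables, topQuantileSet, quantile = quantile)
    ids <- Reduce(intersect, lapply(tops, `[[`, "ids"))
    comp <- vapply(fstTables, function(f) f$comparison[1], character(1))
    rows <- lapply(fstTables, function(f) f[match(ids, f$sv_id), ])
    signs <- vapply(rows, function(f) sign(f$delta_af), numeric(length(ids)))
    if (length(ids) == 1L) signs <- matrix(signs, nrow = 1)
    if (length(ids) == 0L) signs <- matrix(numeric(0), nrow = 0,
                                           ncol = length(fstTables))
    consistent <- apply(signs, 1L, function(s) all(s != 0) &&
                            length(unique(s)) == 1L)
    ids <- ids[consistent]
    out <- data.frame(sv_id = ids, stringsAsFactors = FALSE)
    for (k in seq_along(fstTables)) {
        f <- fstTables[[k]][match(ids, fstTables[[k]]$sv_id), ]
        out[[paste0("theta_", comp[k])]] <- f$theta
        out[[paste0("delta_af_", comp[k])]] <- f$delta_af
    }
    th <- as.matrix(out[, grep("^theta_", names(out)), drop = FALSE])
    out$mean_theta <- if (nrow(out)) rowMeans(th) else numeric(0)
    out$direction <- if (nrow(out))
        sign(out[[paste0("delta_af_", comp[1])]]) else numeric(0)
    out <- out[order(-out$mean_theta), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "thresholds") <- stats::setNames(
        vapply(tops, `[[`, numeric(1), "threshold"), comp)
    out
}

#' Gene and regulatory-element association of candidate SVs
#'
#' Joins scan candidates with their consequence annotations (unique genes
#' counted once), optional z-scaled tissue expression for associated genes,
#' and optional regulatory-element overlaps (>= 1 bp).
#'
#' @param candidates data.frame from \code{\link{candidateScan}}.
#' @param annotations data.frame from \code{\link{classifySV}}.
#' @param ranges optional named \code{GRanges} of the candidate SV intervals
#'   (needed for regulatory overlap).
#' @param expression optional numeric matrix (genes x tissues) of TPM values;
#'   rows are z-scaled across tissues.
#' @param regulatory optional \code{GRanges} of regulatory elements (named).
#' @return List with \code{table} (per-candidate gene list and optional
#'   regulatory ids), \code{genes} (unique associated genes) and optionally
#'   \code{expression} (z-scaled rows for associated genes).
#' @export
candidateGeneTable <- function(candidates, annotations, ranges = NULL,
                               expression = NULL, regulatory = NULL) {
    gene_of <- function(id) {
        g <- annotations$gene_id[annotations$sv_id == id]
        unique(g[!is.na(g)])
    }
    glists <- lapply(candidates$sv_id, gene_of)
    tab <- data.frame(sv_id = candidates$sv_id,
                      genes = vapply(glists, paste, character(1),
                                     collapse = ","),
                      n_genes = lengths(glists), stringsAsFactors = FALSE)
    if (!is.null(regulatory) && !is.null(ranges)) {
        if (is.null(names(regulatory)))
            names(regulatory) <- paste0("re", seq_along(regulatory), recycle0 = TRUE)
        pr <- overlapJoin(ranges[tab$sv_id], regulatory, minBp = 1L)
        tab$regulatory <- vapply(tab$sv_id, function(id)
            paste(unique(pr$subject_id[pr$query_id == id]), collapse = ","),
            character(1))
    }
    genes <- unique(unlist(glists))
    out <- list(table = tab, genes = genes)
    if (!is.null(expression)) {
        keep <- intersect(genes, rownames(expression))
        z <- t(scale(t(expression[keep, , drop = FALSE])))
        out$expression <- z
    }
    out
}
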