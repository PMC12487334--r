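#' @include AllClasses.R
NULL

.hyper_tail <- function(k, K, n_query, N) {
    ## one-sided over-representation p: P(X >= k), X ~ Hypergeom(N, K, n_query)
    stats::phyper(k - 1, K, N - K, n_query, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement; order-preserving. Rejecting at
#' level alpha on the adjusted values reproduces the classical step-up
#' rejection set.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
    stats::p.adjust(p, method = "BH")
}

#' Per-domain Fisher exact enrichment of an affected gene set
#'
#' For every term (protein domain), the 2x2 table
#' \code{[[k, n_affected - k], [K - k, n_background - (K - k)]]} compares the
#' proportion of term-carrying genes inside the affected set against the
#' background (non-affected) set. The p-value is the one-sided (enrichment)
#' Fisher exact tail, computed as the hypergeometric upper tail. Fold
#' enrichment is \code{(k / n_affected) / ((K - k) / n_background)} and
#' \code{+Inf} when all term genes are affected (K = k > 0). BH adjustment is
#' applied across all tested terms; terms with no genes in either set are
#' skipped with a warning.
#'
#' @param affected character vector of affected gene ids.
#' @param background character vector of non-affected gene ids (disjoint).
#' @param domainMap named list: term -> character vector of gene ids.
#' @return data.frame with \code{term}, \code{k}, \code{K},
#'   \code{n_affected}, \code{n_background}, \code{fold}, \code{p},
#'   \code{p_adj}.
#' @export
fisherDomainEnrichment <- function(affected, background, domainMap) {
    stopifnot(!any(affected %in% background))
    nA <- length(affected); nB <- length(background)
    N <- nA + nB
    rows <- lapply(names(domainMap), function(term) {
        genes <- intersect(domainMap[[term]], c(affected, background))
        K <- length(genes)
        if (K == 0L) return(NULL)
        k <- sum(genes %in% affected)
        fold <- if (k > 0 && K == k) Inf else
            (k / nA) / ((K - k) / nB)
        data.frame(term = term, k = k, K = K, n_affected = nA,
                   n_background = nB, fold = fold,
                   p = .hyper_tail(k, K, nA, N), stringsAsFactors = FALSE)
    })
    skipped <- sum(vapply(rows, is.null, logical(1)))
    if (skipped > 0)
        warning(sprintf("skipped %d term(s) with no genes in the universe",
                        skipped))
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) return(out)
    out$p_adj <- bhAdjust(out$p)
    out
}

#' Hypergeometric gene-set over-representation test
#'
#' Generic over-representation of a query gene set against a universe, for
#' user-supplied term-to-gene maps (e.g. flat GO or KEGG annotations; no
#' ontology propagation). One-sided hypergeometric p per term, BH adjustment,
#' and significance flags at the configured thresholds.
#'
#' @param genes character vector of query gene ids (subset of universe).
#' @param universe character vector of background gene ids.
#' @param termMap named list: term -> character vector of gene ids.
#' @param pThreshold,qThreshold significance thresholds on adjusted p
#'   (default 0.05 each).
#' @return data.frame as \code{\link{fisherDomainEnrichment}} plus
#'   \code{significant}.
#' @export
genesetEnrichment <- function(genes, universe, termMap, pThreshold = 0.05,
                              qThreshold = 0.05) {
    if (!length(universe)) stop("empty universe")
    stopifnot(all(genes %in% universe))
    n <- length(genes); N <- length(universe)
    rows <- lapply(names(termMap), function(term) {
        tg <- intersect(termMap[[term]], universe)
        K <- length(tg)
        if (K == 0L) return(NULL)
        k <- sum(tg %in% genes)
        data.frame(term = term, k = k, K = K, n_query = n, n_universe = N,
                   fold = (k / n) / (K / N),
                   p = .hyper_tail(k, K, n, N), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) return(out)
    out$p_adj <- bhAdjust(out$p)
    out$significant <- out$p_adj < pThreshold & out$p_adj < qThreshold
    out
}

#' Chi-square test comparing a subset proportion with its complement
#'
#' Builds the 2x2 table
#' \code{[[k_sub, n_sub - k_sub], [k_all - k_sub, (n_all - n_sub) - (k_all - k_sub)]]}
#' (subset versus complement) and applies the Pearson chi-square test without
#' continuity correction (df = 1, two-sided). A warning is attached when any
#' expected cell is below 1.
#'
#' @param kSub,nSub successes and size of the subset.
#' @param kAll,nAll successes and size of the full set (subset included).
#' @return List with \code{statistic}, \code{p}, \code{prop_subset},
#'   \code{prop_all}, \code{prop_complement}, \code{table},
#'   \code{expected_ok}.
#' @export
subsetProportionTest <- function(kSub, nSub, kAll, nAll) {
    stopifnot(kSub <= nSub, kAll <= nAll, nSub <= nAll, kSub <= kAll)
    tab <- matrix(c(kSub, nSub - kSub,
                    kAll - kSub, (nAll - nSub) - (kAll - kSub)),
                  nrow = 2, byrow = TRUE)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expected_ok <- all(ht$expected >= 1)
    if (!expected_ok)
        warning("expected cell count < 1; chi-square approximation unreliable")
    list(statistic = unname(ht$statistic), p = unname(ht$p.value),
         prop_subset = kSub / nSub, prop_all = kAll / nAll,
         prop_complement = (kAll - kSub) / (nAll - nSub),
         table = tab, expected_ok = expected_ok)
}
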