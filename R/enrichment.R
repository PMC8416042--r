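## Term enrichment (chi-squared on 2x2 tables) and the auxiliary tests
## used alongside the scans (Mann-Whitney U, Pearson correlation).

#' Chi-squared term enrichment of a candidate gene set
#'
#' For every annotation term carried by at least one selected gene,
#' builds the 2x2 table (selected vs non-selected) x (with-term vs
#' without-term) over the background set and evaluates the Pearson
#' chi-squared statistic (1 df, no continuity correction), with the
#' upper-tail p-value. A term is marked significant when `p < alpha`
#' with no multiple-testing correction; a Benjamini-Hochberg adjusted
#' column (`pBH`) is reported for reference but never drives the
#' `significant` flag.
#'
#' @param selected character vector of selected gene ids; must be a
#'   subset of `background`.
#' @param background character vector of background gene ids; defaults
#'   to all genes present in the annotation.
#' @param annotation list from [readAnnotation()] (`gene2terms`,
#'   `termDesc`).
#' @param alpha significance cutoff on the raw p-value (default 0.05).
#' @return a data.frame sorted by ascending p with columns `term`,
#'   `description`, `selWith`, `selWithout`, `bgWith`, `bgWithout`,
#'   `chi2`, `p`, `pBH`, `significant`. Count columns partition the
#'   selected and the non-selected background genes, so the four sum to
#'   the background total.
#' @export
chi2Enrichment <- function(selected, annotation,
                           background = names(annotation$gene2terms),
                           alpha = 0.05) {
    selected <- unique(selected)
    background <- unique(background)
    if (!length(selected) || !length(background))
        stop("selected and background gene sets must be non-empty")
    if (!all(selected %in% background))
        stop("selected genes absent from background: ",
             paste(utils::head(setdiff(selected, background), 3L),
                   collapse = ", "))
    g2t <- annotation$gene2terms
    terms <- unique(unlist(g2t[intersect(selected, names(g2t))]))
    terms <- terms[!is.na(terms) & terms != ""]
    if (!length(terms))
        return(data.frame(term = character(), description = character(),
                          selWith = integer(), selWithout = integer(),
                          bgWith = integer(), bgWithout = integer(),
                          chi2 = numeric(), p = numeric(),
                          pBH = numeric(), significant = logical()))
    nonsel <- setdiff(background, selected)
    termsOf <- g2t[names(g2t) %in% background]
    withTerm <- function(term, genes)
        sum(vapply(genes, function(g) {
            t <- termsOf[[g]]
            !is.null(t) && term %in% t
        }, logical(1)))
    rows <- lapply(terms, function(tm) {
        a <- withTerm(tm, selected)
        b <- length(selected) - a
        c <- withTerm(tm, nonsel)
        d <- length(nonsel) - c
        ct <- .chi2x2(a, b, c, d)
        data.frame(term = tm,
                   description = unname(
                       annotation$termDesc[tm] %||% ""),
                   selWith = a, selWithout = b, bgWith = c,
                   bgWithout = d, chi2 = ct$chi2, p = ct$p)
    })
    out <- do.call(rbind, rows)
    out$description[is.na(out$description)] <- ""
    out$pBH <- p.adjust(out$p, method = "BH")
    out$significant <- out$p < alpha
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

## Pearson chi-squared on one 2x2 table; degenerate margins -> no
## association (chi2 = 0, p = 1)
.chi2x2 <- function(a, b, c, d) {
    m <- matrix(c(a, b, c, d), 2L)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
        return(list(chi2 = 0, p = 1))
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Mann-Whitney U test (two-sided)
#'
#' Reports `U = min(U_a, U_b)` with a two-sided p-value: exact
#' enumeration when both samples have at most 20 observations and no
#' ties, otherwise the normal approximation with tie correction (no
#' continuity correction).
#'
#' @param a,b numeric samples, each non-empty.
#' @return a list with elements `U` and `p`.
#' @export
mannWhitneyU <- function(a, b) {
    if (!length(a) || !length(b))
        stop("both samples must be non-empty")
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (!length(a) || !length(b))
        stop("both samples must contain finite values")
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- length(a) <= 20L && length(b) <= 20L && !ties
    wt <- suppressWarnings(
        wilcox.test(a, b, exact = exact, correct = FALSE))
    Ua <- unname(wt$statistic)
    U <- min(Ua, length(a) * length(b) - Ua)
    list(U = U, p = unname(wt$p.value))
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation and the two-sided p-value from the
#' t-transform with `length(x) - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero
#'   variance.
#' @return a list with elements `r` and `p`.
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) stop("need at least 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in x or y")
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = unname(ct$p.value))
}
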