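# Gene-set over-representation analysis: 2x2 contingency construction,
# one-sided Fisher's exact (hypergeometric tail) test, Pearson
# chi-squared test (optionally Yates-corrected), Benjamini-Hochberg FDR,
# the dual significance rule (P < 0.05 and FDR < 0.05), and binary
# term x gene membership matrices for 2-D views.

#' Build the 2x2 over-representation contingency table
#'
#' Counts `a` = selected genes in the set, `b` = selected genes not in
#' the set, `c` = background genes in the set but not selected, `d` =
#' the rest.  Term members are intersected with the background before
#' counting; the selected list must be a subset of the background.
#'
#' @param selected character vector of selected gene symbols.
#' @param term_set character vector of term member symbols.
#' @param background character vector: the gene universe.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(selected, term_set, background) {
  background <- unique(normalize_symbols(background))
  if (!length(background)) contract_error("empty background universe")
  selected <- unique(normalize_symbols(selected))
  term_set <- unique(normalize_symbols(term_set))
  stray <- setdiff(selected, background)
  if (length(stray))
    contract_error(paste("selected genes outside background:",
                         paste(stray, collapse = ", ")))
  term_set <- intersect(term_set, background)
  a <- length(intersect(selected, term_set))
  b <- length(selected) - a
  cc <- length(term_set) - a
  d <- length(background) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided Fisher's exact test for over-representation
#'
#' Hypergeometric upper tail `P(X >= a)` with
#' `X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b)`: the probability of
#' drawing at least `a` set members when sampling the selected list from
#' the background without replacement.
#'
#' @param table a `c(a, b, c, d)` vector from [build_contingency()], or
#'   a matrix whose rows are such tables.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_exact_enrichment <- function(table) {
  tb <- if (is.matrix(table)) table else matrix(table, nrow = 1)
  a <- tb[, 1]; b <- tb[, 2]; cc <- tb[, 3]; d <- tb[, 4]
  N <- a + b + cc + d
  K <- a + cc
  n <- a + b
  # P(X >= a) = 1 - P(X <= a - 1)
  p <- phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Two-sided chi-squared with 1 degree of freedom; Yates continuity
#' correction applied iff `yates`.  Tables with a zero marginal are
#' degenerate: the statistic is undefined and `p = 1` is returned with a
#' `degenerate` attribute.
#'
#' @param table `c(a, b, c, d)` counts.
#' @param yates logical; apply the continuity correction.
#' @return p-value with attributes `statistic` and `degenerate`.
#' @export
chi_square_enrichment <- function(table, yates = FALSE) {
  a <- table[1]; b <- table[2]; cc <- table[3]; d <- table[4]
  N <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    p <- 1
    attr(p, "statistic") <- NA_real_
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  num <- abs(a * d - b * cc)
  if (yates) num <- max(num - N / 2, 0)
  stat <- N * num^2 / (r1 * r2 * c1 * c2)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  attr(p, "statistic") <- unname(stat)
  attr(p, "degenerate") <- FALSE
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q(i) = min over j >= i of p(j) * m / j`, clipped to `[0, 1]`, with
#' ties handled stably and the output aligned to the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values aligned to `pvalues`.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)                     # stable in R
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))          # running min from the tail upward
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Over-representation analysis of a gene list against a collection
#'
#' For every term in `collection`, builds the 2x2 table of `selected`
#' against the background, computes the one-sided Fisher p, the
#' chi-squared p, and BH q-values over the whole tested family, and
#' applies the dual significance rule `p_fisher < alpha` and
#' `q_bh < fdr` (strict).  Fisher's test governs significance; the
#' chi-squared p is reported alongside.
#'
#' @param selected character vector of selected gene symbols.
#' @param collection a `GeneSetCollection`.
#' @param background gene universe; defaults to the union of all term
#'   members (the annotated universe) if `NULL`.
#' @param alpha,fdr strict significance cutoffs (default 0.05 both).
#' @param yates logical for [chi_square_enrichment()].
#' @return an `EnrichmentResult` data.frame: `term_id`, `term_name`,
#'   `a`, `b`, `c`, `d`, `p_fisher`, `p_chi2`, `q_bh`, `significant`.
#' @export
enrich_terms <- function(selected, collection, background = NULL,
                         alpha = 0.05, fdr = 0.05, yates = FALSE) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(background))
    background <- unique(unlist(collection$sets, use.names = FALSE))
  background <- unique(normalize_symbols(background))
  selected <- intersect(unique(normalize_symbols(selected)), background)
  ids <- names(collection$sets)
  tabs <- t(vapply(ids, function(id)
    build_contingency(selected, collection$sets[[id]], background),
    numeric(4)))
  p_fisher <- fisher_exact_enrichment(tabs)
  p_chi2 <- vapply(seq_along(ids), function(i)
    as.numeric(chi_square_enrichment(tabs[i, ], yates = yates)), numeric(1))
  q <- bh_fdr(p_fisher)
  res <- data.frame(term_id = ids,
                    term_name = unname(collection$descriptions[ids]),
                    a = tabs[, 1], b = tabs[, 2], c = tabs[, 3], d = tabs[, 4],
                    p_fisher = p_fisher, p_chi2 = p_chi2, q_bh = q,
                    significant = p_fisher < alpha & q < fdr,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  attr(res, "background_size") <- length(background)
  attr(res, "selected") <- selected
  res
}

#' Filter enrichment results by the dual significance rule
#'
#' Keeps terms with `p_fisher < alpha` and `q_bh < fdr`, both strict.
#' The q-values must already have been computed over the full tested
#' family (as [enrich_terms()] does).
#'
#' @param results an `EnrichmentResult`.
#' @param alpha,fdr strict cutoffs.
#' @return the significant subset, ordered by `p_fisher`.
#' @export
significant_terms <- function(results, alpha = 0.05, fdr = 0.05) {
  keep <- results$p_fisher < alpha & results$q_bh < fdr
  out <- results[keep, , drop = FALSE]
  out[order(out$p_fisher, out$term_id), , drop = FALSE]
}

#' Binary term x gene membership matrix (2-D view)
#'
#' Entry (t, g) is 1 iff gene g belongs to term t and to the selected
#' gene list.  Rows and columns are ordered by descending marginal sums,
#' ties broken lexicographically.
#'
#' @param collection a `GeneSetCollection` (or named list of member
#'   vectors).
#' @param term_ids terms to include (rows).
#' @param genes selected genes (columns restricted to these).
#' @return binary integer matrix, terms x genes.
#' @export
membership_matrix <- function(collection, term_ids, genes) {
  sets <- if (inherits(collection, "GeneSetCollection")) collection$sets
          else collection
  genes <- unique(normalize_symbols(genes))
  term_ids <- as.character(term_ids)
  m <- matrix(0L, length(term_ids), length(genes),
              dimnames = list(term_ids, genes))
  for (t in term_ids)
    m[t, intersect(normalize_symbols(sets[[t]]), genes)] <- 1L
  ro <- order(-rowSums(m), rownames(m))
  co <- order(-colSums(m), colnames(m))
  m[ro, co, drop = FALSE]
}
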