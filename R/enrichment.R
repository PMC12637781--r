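#' Expected de novo count from a mutability table
#'
#' Expected DNVs in `n_probands` probands for a variant class (and
#' optionally a gene set): `2 * n_probands * sum(p)`, the factor two
#' accounting for diploidy since the table gives per-chromosome-copy
#' probabilities. Gene-set expectations are the sum over member genes, so
#' the expectation is additive over disjoint sets.
#'
#' @param table mutability data frame `gene`, `class`, `prob`.
#' @param n_probands proband count.
#' @param classes variant classes to sum (default: all in the table).
#' @param genes optional gene subset; unknown genes raise an error.
#' @return expected count (numeric scalar).
#' @export
#' @examples
#' tab <- data.frame(gene = "G1", class = "LoF", prob = 0.001)
#' expected_dnv_count(tab, 100)  # 0.2
expected_dnv_count <- function(table, n_probands, classes = NULL,
                               genes = NULL) {
  stopifnot(n_probands >= 0)
  if (!is.null(genes)) {
    unknown <- setdiff(genes, table$gene)
    if (length(unknown))
      stop("genes absent from mutability table: ",
           paste(unknown, collapse = ", "))
    table <- table[table$gene %in% genes, ]
  }
  if (!is.null(classes)) table <- table[table$class %in% classes, ]
  2 * n_probands * sum(table$prob)
}

#' One-tailed Poisson observed/expected test
#'
#' Upper-tail probability `P(X >= observed)` for `X ~ Poisson(expected)`,
#' with the O/E ratio.
#'
#' @param observed observed count.
#' @param expected expected count; must be positive.
#' @return list with `observed`, `expected`, `oe_ratio`, `p`.
#' @export
#' @examples
#' poisson_oe_test(3, 0.2)$p  # ~1.148e-3
poisson_oe_test <- function(observed, expected) {
  if (!is.finite(expected) || expected <= 0)
    stop("expected must be positive")
  stopifnot(observed >= 0, observed == round(observed))
  p <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  list(observed = observed, expected = expected,
       oe_ratio = observed / expected, p = p)
}

#' Permutation null for recurrently mutated genes
#'
#' Redistributes the observed number of DNVs across genes `B` times,
#' multinomially with probabilities proportional to per-gene mutability,
#' and estimates for each observed recurrence level k the probability that
#' at least one gene is hit k or more times. The empirical estimator is
#' `(r + 1) / (B + 1)` with `r` the number of iterations achieving the
#' event, which avoids zero p-values.
#'
#' @param observed_genes character vector: the gene of each observed DNV
#'   (length N fixes the redistributed total).
#' @param table mutability data frame `gene`, `class`, `prob` (classes are
#'   summed per gene); all-zero mutability is an error.
#' @param B iterations (>= 1).
#' @param max_level highest recurrence level to tabulate (default: the
#'   maximum observed recurrence, at least 2).
#' @return list with `B`, `levels` (data frame `k`, `r`, `p`), `per_gene`
#'   (data frame `gene`, `count`, `p` for genes hit >= 2 times) and
#'   `max_count` (per-iteration maxima, for diagnostics).
#' @export
permutation_recurrence <- function(observed_genes, table, B = 1e5,
                                   max_level = NULL) {
  stopifnot(B >= 1)
  pg <- tapply(table$prob, table$gene, sum)
  if (all(pg == 0)) stop("all-zero mutability")
  genes <- names(pg)
  N <- length(observed_genes)
  obs_counts <- table(factor(observed_genes, levels = genes))
  if (is.null(max_level)) max_level <- max(2L, max(obs_counts))
  prob <- as.numeric(pg) / sum(pg)
  max_count <- integer(B)
  # chunked multinomial draws keep memory bounded for large B
  chunk <- max(1L, min(B, floor(5e6 / length(genes))))
  done <- 0L
  while (done < B) {
    m <- min(chunk, B - done)
    draws <- stats::rmultinom(m, N, prob)
    max_count[done + seq_len(m)] <- apply(draws, 2, max)
    done <- done + m
  }
  ks <- 2:max_level
  r <- vapply(ks, function(k) sum(max_count >= k), 0L)
  levels <- data.frame(k = ks, r = r, p = (r + 1) / (B + 1))
  rec <- obs_counts[obs_counts >= 2]
  per_gene <- data.frame(
    gene = names(rec), count = as.integer(rec),
    p = (vapply(as.integer(rec), function(k) sum(max_count >= k), 0L) + 1) /
      (B + 1),
    stringsAsFactors = FALSE)
  list(B = B, levels = levels, per_gene = per_gene, max_count = max_count)
}

#' Bonferroni significance threshold
#'
#' `alpha / (n_units * n_classes)`. With 19,365 genes tested in two variant
#' classes (LoF and D-Mis, the lower of the two p-values retained per gene)
#' this gives the genome-wide threshold ~1.29e-6; with 17 modules and one
#' class, 2.94e-3.
#'
#' @param n_units number of tested units (genes, modules, cell types).
#' @param n_classes number of variant classes tested per unit.
#' @param alpha family-wise error target.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(n_units, n_classes = 1, alpha = 0.05) {
  stopifnot(n_units >= 1, n_classes >= 1, alpha > 0)
  alpha / (n_units * n_classes)
}
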