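#' Rank-sum comparison of ROH burden between groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: exact null distribution
#' for small untied samples, normal approximation with tie correction
#' otherwise (the default behavior of [stats::wilcox.test()]).
#'
#' @param burden_a,burden_b per-sample observed burdens (Mb), one group
#'   each; both must be non-empty.
#' @return list with `u` (Mann-Whitney U for the first group), `p`,
#'   `n_a`, `n_b`.
#' @export
#' @examples
#' compare_burden_groups(c(1, 2, 3), c(4, 5, 6))$p  # exact 0.1
compare_burden_groups <- function(burden_a, burden_b) {
  if (!length(burden_a) || !length(burden_b)) stop("empty group")
  wt <- suppressWarnings(stats::wilcox.test(burden_a, burden_b,
                                            alternative = "two.sided"))
  list(u = unname(wt$statistic), p = wt$p.value,
       n_a = length(burden_a), n_b = length(burden_b))
}

#' Observed vs pedigree-expected ROH burden
#'
#' Paired t-test on (observed - expected) burdens across families, plus the
#' fraction of families whose observed burden exceeds expectation by at
#' least two standard deviations. The per-family SD is not a fixed
#' convention, so it is a required input — typically the gene-drop
#' Monte-Carlo SD from [expected_roh_sd()], or one global value recycled
#' across families.
#'
#' @param observed_mb,expected_mb per-family burdens (Mb), same length >= 2.
#' @param sd_mb per-family SD of the expected burden (Mb); length 1 or
#'   `length(observed_mb)`.
#' @return list with `t`, `df`, `p`, `flagged` (logical per family),
#'   `frac_flagged`.
#' @export
observed_vs_expected <- function(observed_mb, expected_mb, sd_mb) {
  stopifnot(length(observed_mb) == length(expected_mb),
            length(observed_mb) >= 2)
  d <- observed_mb - expected_mb
  if (stats::sd(d) == 0)
    stop("degenerate input: observed - expected has zero variance")
  tt <- stats::t.test(observed_mb, expected_mb, paired = TRUE)
  sd_mb <- rep_len(sd_mb, length(observed_mb))
  flagged <- observed_mb >= expected_mb + 2 * sd_mb
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       flagged = flagged, frac_flagged = mean(flagged))
}

#' Monte-Carlo SD of pedigree autozygous burden
#'
#' Standard deviation of the autozygous burden (Mb) of one individual over
#' gene-drop replicates of their pedigree — the per-family SD used for the
#' two-standard-deviation flag in [observed_vs_expected()].
#'
#' @param ped a [pedigree()].
#' @param id individual id.
#' @param genome a [genome_config()].
#' @param n_rep replicates (default 200).
#' @return list with `mean_mb`, `sd_mb`.
#' @export
expected_roh_sd <- function(ped, id, genome, n_rep = 200) {
  fr <- vapply(seq_len(n_rep), function(i)
    autozygous_fraction(gene_drop(ped, genome), id, genome), 0)
  list(mean_mb = mean(fr) * genome$genome_mb,
       sd_mb = stats::sd(fr) * genome$genome_mb)
}

#' Method-of-moments inbreeding estimate from genotypes
#'
#' `F-hat = 1 - (observed het count) / sum(2 q (1 - q))` over informative
#' markers with panel allele frequency q — the single-sample moment
#' estimator, cross-checkable against the pedigree F.
#'
#' @param geno genotype codes (0/1/2, `NA` missing) for one sample.
#' @param af panel allele frequencies aligned with `geno`.
#' @param min_markers minimum informative markers required.
#' @return F-hat (can be slightly negative by sampling noise).
#' @export
estimate_inbreeding_from_genotypes <- function(geno, af,
                                               min_markers = 100) {
  stopifnot(length(geno) == length(af))
  ok <- !is.na(geno) & !is.na(af) & af > 0 & af < 1
  if (sum(ok) < min_markers)
    stop("need >= ", min_markers, " informative markers, have ", sum(ok))
  exp_het <- sum(2 * af[ok] * (1 - af[ok]))
  if (exp_het == 0) stop("expected heterozygosity is zero")
  1 - sum(geno[ok] == 1L) / exp_het
}

#' Multilocus pathogenic variant (MPV) status of one family
#'
#' A family is an MPV carrier when candidates span two or more distinct
#' causative genes. Each gene pair is additionally flagged co-localized
#' when both supporting variants fall inside one segregated ROH segment.
#'
#' @param candidates data frame with `gene`, `chrom`, `pos` (putative
#'   causative tier for one family).
#' @param segments segregated ROH segments for the family (may be empty).
#' @return list with `mpv` (logical), `n_genes`, `pairs` (data frame
#'   `gene1`, `gene2`, `same_roh`).
#' @export
detect_mpv <- function(candidates, segments = NULL) {
  genes <- unique(candidates$gene)
  mpv <- length(genes) >= 2
  pairs <- NULL
  if (mpv) {
    in_seg <- function(chrom, pos) {
      if (is.null(segments) || !nrow(segments)) return(NA_integer_)
      hit <- which(segments$chrom == chrom & segments$start <= pos &
                     segments$end >= pos)
      if (length(hit)) hit[1] else NA_integer_
    }
    seg_of <- vapply(seq_len(nrow(candidates)), function(i)
      in_seg(candidates$chrom[i], candidates$pos[i]), 0L)
    cmb <- utils::combn(genes, 2)
    pairs <- data.frame(gene1 = cmb[1, ], gene2 = cmb[2, ],
                        same_roh = vapply(seq_len(ncol(cmb)), function(k) {
                          s1 <- seg_of[candidates$gene == cmb[1, k]]
                          s2 <- seg_of[candidates$gene == cmb[2, k]]
                          any(!is.na(s1) & !is.na(s2) &
                                outer(s1, s2, "==")) &&
                            candidates$chrom[candidates$gene == cmb[1, k]][1] ==
                            candidates$chrom[candidates$gene == cmb[2, k]][1]
                        }, TRUE),
                        stringsAsFactors = FALSE)
  }
  list(mpv = mpv, n_genes = length(genes), pairs = pairs)
}

# round half-up / truncate to `digits` decimals
.round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits
.trunc_digits <- function(x, digits = 2) floor(x * 10^digits) / 10^digits

#' Cohort summary from per-family results
#'
#' Tallies the cohort: etiologic yield (solved / enrolled), inheritance
#' breakdown among solved families, MPV and actionable shares (denominator:
#' solved families), consanguinity and multiplex shares (denominator: all
#' families). Percentages are recomputed from integer counts and rendered
#' two ways — `pct` (half-up rounding to 2 decimals) and `pct_trunc`
#' (truncation to 2 decimals) — because published tables mix both
#' conventions.
#'
#' @param families data frame with one row per family: logical `solved`,
#'   `mpv`, `actionable`, `consanguineous`, `multiplex`, and `model` (one
#'   of `"hom_recessive"`, `"comp_het"`, `"x_linked"`, `"de_novo"`, `NA`
#'   for unsolved).
#' @return data frame with one row per summary quantity: `measure`,
#'   `count`, `denominator`, `pct`, `pct_trunc`.
#' @export
summarize_cohort <- function(families) {
  n <- nrow(families)
  solved <- sum(families$solved, na.rm = TRUE)
  row <- function(measure, count, denom) {
    pct <- if (denom > 0) 100 * count / denom else 0
    data.frame(measure = measure, count = count, denominator = denom,
               pct = .round_half_up(pct), pct_trunc = .trunc_digits(pct),
               stringsAsFactors = FALSE)
  }
  mod <- function(m) sum(families$solved & !is.na(families$model) &
                           families$model == m, na.rm = TRUE)
  out <- rbind(
    row("yield", solved, n),
    row("hom_recessive", mod("hom_recessive"), solved),
    row("comp_het", mod("comp_het"), solved),
    row("x_linked", mod("x_linked"), solved),
    row("de_novo", mod("de_novo"), solved),
    row("mpv", sum(families$solved & families$mpv, na.rm = TRUE), solved),
    row("actionable", sum(families$solved & families$actionable,
                          na.rm = TRUE), solved),
    row("consanguineous", sum(families$consanguineous, na.rm = TRUE), n),
    row("multiplex", sum(families$multiplex, na.rm = TRUE), n))
  out
}

#' Logistic gene-set enrichment with covariates
#'
#' Fits `outcome ~ membership + covariates` with a binomial GLM (logit
#' link, iteratively reweighted least squares as in [stats::glm()]) and
#' reports the Wald test on the membership coefficient. Complete
#' separation is reported as a flagged status rather than a numeric
#' p-value.
#'
#' @param outcome logical/0-1 vector per gene (e.g. is-disease-gene).
#' @param membership logical/0-1 vector per gene (e.g. is-module-member).
#' @param covariates data frame of numeric covariates (GC content, gene
#'   length, mean expression, ...), or `NULL`.
#' @return list with `coef`, `se`, `p`, `status` (`"ok"` or
#'   `"separation"`).
#' @export
enrichment_regression <- function(outcome, membership, covariates = NULL) {
  outcome <- as.integer(outcome)
  membership <- as.integer(membership)
  if (length(unique(membership)) < 2 || length(unique(outcome)) < 2)
    stop("need genes inside and outside the unit, and both outcomes")
  dat <- data.frame(y = outcome, member = membership)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  co <- sm["member", ]
  if (sep || abs(co["Estimate"]) > 15 || co["Std. Error"] > 100)
    return(list(coef = unname(co["Estimate"]), se = unname(co["Std. Error"]),
                p = NA_real_, status = "separation"))
  list(coef = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       p = unname(co["Pr(>|z|)"]), status = "ok")
}
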