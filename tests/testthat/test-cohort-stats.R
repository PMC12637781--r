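test_that("rank-sum burden comparison uses the exact small-sample null", {
  r <- compare_burden_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)  # 2/20 rank arrangements as extreme
  expect_equal(compare_burden_groups(c(5, 6), c(5, 6))$p, 1)
  swap <- compare_burden_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$p, r$p)
  expect_error(compare_burden_groups(numeric(0), 1), "empty")
})

test_that("observed vs expected burden: paired t and the 2-SD flag", {
  obs <- c(101, 202, 303)
  exp_ <- c(100, 200, 300)
  r <- observed_vs_expected(obs, exp_, sd_mb = 0.1)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)  # diffs 1,2,3
  expect_equal(r$df, 2)
  expect_true(all(r$flagged))
  # z = (300 - 200) / 40 = 2.5 flags; z below 2 does not
  r2 <- observed_vs_expected(c(300, 210), c(200, 200), sd_mb = 40)
  expect_equal(r2$flagged, c(TRUE, FALSE))
  expect_equal(r2$frac_flagged, 0.5)
  expect_error(observed_vs_expected(c(1, 2), c(1, 2), 1), "degenerate")
})

test_that("2-SD flagging is invariant to a consistent unit change", {
  obs <- c(310, 205, 150); exp_ <- c(200, 180, 140); sdv <- c(40, 10, 3)
  a <- observed_vs_expected(obs, exp_, sdv)$flagged
  b <- observed_vs_expected(obs * 1e6, exp_ * 1e6, sdv * 1e6)$flagged
  expect_identical(a, b)
})

test_that("moment estimator recovers inbreeding from genotypes", {
  set.seed(61)
  q <- stats::rbeta(5000, 1.2, 3)
  # founder drawn at HWE: F-hat near 0
  g_founder <- stats::rbinom(5000, 2, q)
  f0 <- estimate_inbreeding_from_genotypes(g_founder, q)
  expect_lt(abs(f0), 0.03)
  # fully homozygous sample: F-hat exactly 1
  g_hom <- 2L * stats::rbinom(5000, 1, q)
  expect_equal(estimate_inbreeding_from_genotypes(g_hom, q), 1)
  expect_error(estimate_inbreeding_from_genotypes(g_hom[1:50], q[1:50]),
               "informative markers")
})

test_that("genotype-based F matches simulated autozygous fraction", {
  sc <- simulation_scenario(n_families = 4, seed = 47)
  sim <- simulate_cohort(sc)
  mrows <- match(paste(sim$markers$chrom, sim$markers$pos),
                 paste(sim$cohort$variants$chrom, sim$cohort$variants$pos))
  for (ped in sim$peds[1:2]) {
    for (id in affected_ids(ped)) {
      fhat <- estimate_inbreeding_from_genotypes(
        sim$true_geno[mrows, id], sim$markers$af)
      tr <- sim$truth_segments[sim$truth_segments$sample == id, ]
      frac <- sum(tr$end - tr$start + 1) / (sc$genome$genome_mb * 1e6)
      expect_lt(abs(fhat - frac), 0.05)
    }
  }
})

test_that("MPV detection needs two causative genes; co-localization per ROH", {
  seg <- data.frame(chrom = "chr1", start = 1e6, end = 9e6)
  two <- data.frame(gene = c("GA", "GB"), chrom = "chr1", pos = c(2e6, 8e6))
  r <- detect_mpv(two, seg)
  expect_true(r$mpv)
  expect_true(r$pairs$same_roh)
  one <- detect_mpv(two[1, ], seg)
  expect_false(one$mpv)
  apart <- data.frame(gene = c("GA", "GB"), chrom = c("chr1", "chr2"),
                      pos = c(2e6, 2e6))
  r2 <- detect_mpv(apart, seg)
  expect_true(r2$mpv)
  expect_false(r2$pairs$same_roh)
})

test_that("cohort summary recomputes percentages from counts", {
  fam <- data.frame(solved = c(TRUE, TRUE, FALSE),
                    model = c("hom_recessive", "de_novo", NA),
                    mpv = c(TRUE, FALSE, FALSE),
                    actionable = c(FALSE, TRUE, FALSE),
                    consanguineous = c(TRUE, TRUE, FALSE),
                    multiplex = c(TRUE, FALSE, FALSE))
  s <- summarize_cohort(fam)
  expect_equal(s$pct[s$measure == "yield"], 66.67)
  expect_equal(s$pct_trunc[s$measure == "yield"], 66.66)
  expect_equal(s$count[s$measure == "hom_recessive"], 1)
  expect_equal(s$denominator[s$measure == "hom_recessive"], 2)
  # yield times n rounds back to the solved count
  expect_equal(round(s$pct[s$measure == "yield"] / 100 * 3), 2)
  empty <- summarize_cohort(fam[0, ])
  expect_true(all(empty$pct == 0))
})

test_that("logistic enrichment regression detects planted enrichment", {
  simulate_once <- function(seed) {
    set.seed(seed)
    n <- 2000
    member <- seq_len(n) <= 200
    gc <- stats::runif(n, 0.3, 0.6)
    len <- stats::rlnorm(n, 10, 1)
    expr <- stats::rnorm(n)
    # 5x odds enrichment of disease genes in the module
    p <- plogis(qlogis(0.05) + log(5) * member)
    disease <- stats::rbinom(n, 1, p)
    enrichment_regression(disease, member,
                          data.frame(gc = gc, len = len, expr = expr))
  }
  fits <- lapply(1:10, simulate_once)
  expect_true(all(vapply(fits, function(f) f$status, "") == "ok"))
  expect_true(all(vapply(fits, function(f) f$coef, 0) > 0))
  sig <- vapply(fits, function(f) f$p, 0) < bonferroni_threshold(17)
  expect_gte(mean(sig), 0.9)
})

test_that("null regression p-values are roughly uniform", {
  set.seed(83)
  rejections <- replicate(200, {
    n <- 400
    member <- seq_len(n) <= 60
    disease <- stats::rbinom(n, 1, 0.1)
    r <- enrichment_regression(disease, member,
                               data.frame(gc = stats::runif(n)))
    !is.na(r$p) && r$p < 0.05
  })
  # binomial 99% envelope around 0.05 with 200 draws
  expect_lt(mean(rejections), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("complete separation is flagged, not reported as a p-value", {
  disease <- c(rep(1, 30), rep(0, 170))
  member <- disease == 1
  r <- enrichment_regression(disease, member)
  expect_equal(r$status, "separation")
  expect_true(is.na(r$p))
})

test_that("Monte-Carlo pedigree SD tracks the analytic mean", {
  set.seed(19)
  r <- expected_roh_sd(ped_first_cousin(), "c1", toy_genome(), n_rep = 150)
  expect_lt(abs(r$mean_mb - 0.0625 * 250), 3 * r$sd_mb / sqrt(150))
  expect_gt(r$sd_mb, 0)
})
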