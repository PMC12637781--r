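# independent upper-tail oracle by direct series summation
poisson_upper_oracle <- function(k, lambda) {
  if (k == 0) return(1)
  terms <- exp(-lambda) * lambda^(0:(k - 1)) / factorial(0:(k - 1))
  1 - sum(terms)
}

test_that("expected DNV counts apply the 2N-diploidy factor and add up", {
  tab <- data.frame(gene = c("G1", "G2", "G3"),
                    class = "LoF", prob = c(4e-4, 4e-4, 2e-4))
  expect_equal(expected_dnv_count(tab, 100), 0.2)
  expect_equal(expected_dnv_count(tab, 0), 0)
  # additivity over disjoint gene sets
  e12 <- expected_dnv_count(tab, 50, genes = c("G1", "G2"))
  e3 <- expected_dnv_count(tab, 50, genes = "G3")
  expect_equal(e12 + e3, expected_dnv_count(tab, 50))
  expect_error(expected_dnv_count(tab, 10, genes = "G9"), "absent")
})

test_that("Poisson O/E test matches series summation to 1e-12", {
  r <- poisson_oe_test(3, 0.2)
  expect_equal(r$p, poisson_upper_oracle(3, 0.2), tolerance = 1e-12)
  expect_equal(r$p, 1 - exp(-0.2) * (1 + 0.2 + 0.02), tolerance = 1e-12)
  expect_equal(r$oe_ratio, 15)
  expect_equal(poisson_oe_test(0, 5)$p, 1)
  for (case in list(c(2, 0.7), c(10, 3.3), c(1, 1e-4))) {
    expect_equal(poisson_oe_test(case[1], case[2])$p,
                 poisson_upper_oracle(case[1], case[2]), tolerance = 1e-12)
  }
  # observed == expected at large lambda sits near 0.5
  expect_equal(poisson_oe_test(400, 400)$p, 0.5, tolerance = 0.02)
  expect_error(poisson_oe_test(3, 0), "positive")
})

test_that("permutation recurrence converges to exact enumeration", {
  tab <- data.frame(gene = c("A", "B", "C"), class = "LoF",
                    prob = c(0.5, 0.3, 0.2))
  # N = 2 DNVs; P(some gene hit twice) = .25 + .09 + .04 = 0.38 exactly
  set.seed(1)
  B <- 2e4
  r <- permutation_recurrence(c("A", "B"), tab, B = B)
  p_hat <- r$levels$p[r$levels$k == 2]
  se <- sqrt(0.38 * 0.62 / B)
  expect_lt(abs(p_hat - 0.38), 3 * se)
  # estimator never returns zero
  expect_true(all(r$levels$p > 0))
  b1 <- permutation_recurrence(c("A", "A"), tab, B = 1)
  expect_equal(b1$per_gene$p[b1$per_gene$gene == "A"], 1, tolerance = 0.5)
  expect_error(permutation_recurrence("A",
                                      data.frame(gene = "A", class = "LoF",
                                                 prob = 0), 10),
               "all-zero")
})

test_that("permutation null is reproducible under a fixed seed", {
  tab <- data.frame(gene = c("A", "B"), class = "LoF", prob = c(0.6, 0.4))
  set.seed(7); a <- permutation_recurrence(c("A", "B", "B"), tab, B = 500)
  set.seed(7); b <- permutation_recurrence(c("A", "B", "B"), tab, B = 500)
  expect_identical(a$max_count, b$max_count)
  expect_identical(a$levels, b$levels)
})

test_that("Bonferroni thresholds reproduce the published corrections", {
  expect_equal(bonferroni_threshold(19365, 2), 0.05 / (19365 * 2))
  expect_equal(signif(bonferroni_threshold(19365, 2), 3), 1.29e-6)
  expect_equal(signif(bonferroni_threshold(17), 3), 2.94e-3)
  expect_equal(bonferroni_threshold(16), 0.003125)
  # 0.003125 renders as 3.13e-3 under half-up rounding at 3 significant digits
  expect_equal(floor(bonferroni_threshold(16) * 1e5 + 0.5) / 1e5, 3.13e-3)
  expect_equal(bonferroni_threshold(1, 1), 0.05)
})

test_that("per-class Poisson p-values are calibrated under the null", {
  # DNVs simulated from the mutability model itself: rejection at 0.05
  # stays at or below nominal (super-uniform, mildly conservative)
  set.seed(23)
  genes <- data.frame(gene = sprintf("g%02d", 1:40),
                      length_bp = rep(5e4, 40))
  tab <- build_mutability_table(genes, total_rate = 0.5)
  n_probands <- 188
  classes <- unique(tab$class)
  lam <- vapply(classes, function(cl)
    expected_dnv_count(tab, n_probands, classes = cl), 0)
  reject <- replicate(300, {
    obs <- stats::rpois(length(lam), lam)
    p <- vapply(seq_along(lam), function(i)
      poisson_oe_test(obs[i], lam[i])$p, 0)
    p <= 0.05
  })
  rate <- mean(reject)
  expect_lte(rate, 0.065)
  expect_gte(rate, 0.03)
})
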