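test_that("damaging classification follows the consequence and score rules", {
  expect_equal(classify_damaging("stop_gain"), "LoF")
  expect_equal(classify_damaging("canonical_splice"), "LoF")
  expect_equal(classify_damaging("missense", "T", 25), "D-Mis")
  expect_equal(classify_damaging("missense", "D", 5), "D-Mis")
  expect_equal(classify_damaging("missense", "T", 15), "not_damaging")
  expect_equal(classify_damaging("missense", NA, NA), "not_damaging")
  expect_equal(classify_damaging("nonframeshift_indel"), "nonframeshift_indel")
  expect_equal(classify_damaging("synonymous", "D", 30), "not_damaging")
  # CADD boundary: 20 passes, just below fails
  expect_equal(classify_damaging("missense", "T", 20), "D-Mis")
  expect_equal(classify_damaging("missense", "T", 19.99), "not_damaging")
})

test_that("de novo filter passes clean trios and reports first failed rule", {
  v <- make_variant()
  pro <- make_call(1L, ref = 6L, alt = 6L)
  par <- make_call(0L, ref = 15L, alt = 0L)
  expect_equal(filter_denovo(v, pro, par, par)$status, "pass")
  # each printed threshold: pass at the boundary, fail one unit beyond
  expect_equal(filter_denovo(make_variant(af_bravo = 5e-4), pro, par, par)$status,
               "pass")
  r <- filter_denovo(make_variant(af_bravo = 5.1e-4), pro, par, par)
  expect_equal(r[c("status", "reason")],
               list(status = "fail", reason = "population_af"))
  expect_equal(filter_denovo(v, make_call(1L, 5L, 5L), par, par)$status,
               "pass")   # depth exactly 10
  expect_equal(filter_denovo(v, make_call(1L, 4L, 5L), par, par)$reason,
               "proband_depth")
  expect_equal(filter_denovo(v, make_call(1L, 10L, 4L), par, par)$reason,
               "proband_alt_reads")
  # alt >= 10: ratio boundary 20%
  expect_equal(filter_denovo(v, make_call(1L, 40L, 10L), par, par)$status,
               "pass")
  expect_equal(filter_denovo(v, make_call(1L, 41L, 10L), par, par)$reason,
               "allele_ratio")
  # alt < 10: boundary 28%
  expect_equal(filter_denovo(v, make_call(1L, 18L, 7L), par, par)$status,
               "pass")
  expect_equal(filter_denovo(v, make_call(1L, 19L, 7L), par, par)$reason,
               "allele_ratio")
  # parents: >= 10 ref reads, alt ratio < 3.5%
  expect_equal(filter_denovo(v, pro, make_call(0L, 10L, 0L), par)$status,
               "pass")
  expect_equal(filter_denovo(v, pro, make_call(0L, 9L, 0L), par)$reason,
               "parent_ref_reads")
  expect_equal(filter_denovo(v, pro, make_call(0L, 27L, 1L), par)$reason,
               "parent_alt_ratio")  # 1/28 = 3.57% fails; 1/29 = 3.45% passes
  expect_equal(filter_denovo(v, pro, make_call(0L, 28L, 1L), par)$status,
               "pass")
  expect_equal(filter_denovo(make_variant(csq = "other"), pro, par, par)$reason,
               "consequence")
  expect_equal(filter_denovo(make_variant(segdup = TRUE), pro, par, par)$reason,
               "segdup")
  # missing parent: not evaluable, distinct from fail
  expect_equal(filter_denovo(v, pro, NULL, par)$status, "not_evaluable")
})

test_that("X-linked filter enforces its printed thresholds", {
  v <- make_variant(chrom = "chrX")
  pro <- make_call(2L, ref = 0L, alt = 20L, gq = 30L, hemi = TRUE)
  mo <- make_call(1L)
  expect_equal(filter_xlinked(v, pro, mo)$status, "pass")
  expect_equal(filter_xlinked(make_variant(chrom = "chrX", af_bravo = 5e-5),
                              pro, mo)$status, "pass")
  expect_equal(filter_xlinked(make_variant(chrom = "chrX", af_bravo = 1e-4),
                              pro, mo)$reason, "population_af")
  expect_equal(filter_xlinked(make_variant(chrom = "chrX",
                                           filter_pass = FALSE),
                              pro, mo)$reason, "vqsr")
  expect_equal(filter_xlinked(v, make_call(2L, 0L, 8L, gq = 30L,
                                           hemi = TRUE), mo)$status, "pass")
  expect_equal(filter_xlinked(v, make_call(2L, 0L, 7L, gq = 30L,
                                           hemi = TRUE), mo)$reason, "depth")
  expect_equal(filter_xlinked(v, make_call(2L, 0L, 20L, gq = 20L,
                                           hemi = TRUE), mo)$status, "pass")
  expect_equal(filter_xlinked(v, make_call(2L, 0L, 20L, gq = 19L,
                                           hemi = TRUE), mo)$reason,
               "genotype_quality")
  expect_equal(filter_xlinked(make_variant(chrom = "chrX", mq = 40), pro,
                              mo)$status, "pass")
  expect_equal(filter_xlinked(make_variant(chrom = "chrX", mq = 39), pro,
                              mo)$reason, "mapping_quality")
  expect_equal(filter_xlinked(v, pro, make_call(0L))$reason,
               "mother_not_carrier")
  expect_equal(filter_xlinked(v, pro, mo,
                              unaffected_male_genos = 2L)$reason,
               "unaffected_male_hemizygous")
  expect_equal(filter_xlinked(v, make_call(1L, sex = "female"), mo)$status,
               "not_evaluable")
})

.rec_family <- function() ped_trio(n_affected = 2, n_unaffected = 1)

.rec_calls <- function(geno_rows, ids = c("p1", "p2", "c1", "c2", "c3"),
                       depth = 30L) {
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- ids
  alt <- matrix(as.integer(depth / 2 * geno), nrow(geno), length(ids))
  list(geno = geno, ref = matrix(depth, nrow(geno), length(ids),
                                 dimnames = list(NULL, ids)) - alt,
       alt = `colnames<-`(alt, ids))
}

test_that("recessive filter keeps the segregating homozygote and bounds AF", {
  ped <- .rec_family()
  v <- make_variant()
  # father het, mother het, both affected hom, unaffected het
  calls <- .rec_calls(list(c(1L, 1L, 2L, 2L, 1L)))
  out <- filter_recessive(v, calls, ped)
  expect_equal(nrow(out), 1)
  expect_equal(out$model, "hom_recessive")
  # AF boundaries: 1e-3 passes, above fails; GME 0.01 passes, above fails
  expect_equal(nrow(filter_recessive(make_variant(af_gnomad = 1e-3), calls,
                                     ped)), 1)
  expect_equal(nrow(filter_recessive(make_variant(af_gnomad = 2e-3), calls,
                                     ped)), 0)
  expect_equal(nrow(filter_recessive(make_variant(af_gme = 0.01), calls,
                                     ped)), 1)
  expect_equal(nrow(filter_recessive(make_variant(af_gme = 0.02), calls,
                                     ped)), 0)
  expect_equal(nrow(filter_recessive(make_variant(filter_pass = FALSE),
                                     calls, ped)), 0)
  expect_equal(nrow(filter_recessive(make_variant(csq = "synonymous"),
                                     calls, ped)), 0)
  # proband depth boundary: 8 passes, 7 fails
  c8 <- .rec_calls(list(c(1L, 1L, 2L, 2L, 1L)), depth = 8L)
  expect_equal(nrow(filter_recessive(v, c8, ped)), 1)
  c7 <- .rec_calls(list(c(1L, 1L, 2L, 2L, 1L)), depth = 7L)
  expect_equal(nrow(filter_recessive(v, c7, ped)), 0)
  # an affected sib not homozygous, or a hom unaffected sib, kills it
  expect_equal(nrow(filter_recessive(
    v, .rec_calls(list(c(1L, 1L, 2L, 1L, 1L))), ped)), 0)
  expect_equal(nrow(filter_recessive(
    v, .rec_calls(list(c(1L, 1L, 2L, 2L, 2L))), ped)), 0)
})

test_that("compound hets require trans configuration and flag the rest", {
  ped <- .rec_family()
  v2 <- rbind(make_variant(pos = 1000001),
              make_variant(pos = 1000101))
  # site 1 paternal (father het, mother ref), site 2 maternal
  trans <- .rec_calls(list(c(1L, 0L, 1L, 1L, 0L),
                           c(0L, 1L, 1L, 1L, 0L)))
  out <- filter_recessive(v2, trans, ped)
  expect_equal(out$model, "comp_het")
  expect_equal(out$flags, "")
  # both from the father: cis, not emitted
  cis <- .rec_calls(list(c(1L, 0L, 1L, 1L, 0L),
                         c(1L, 0L, 1L, 1L, 0L)))
  expect_equal(nrow(filter_recessive(v2, cis, ped)), 0)
  # unaffected sib carrying both alleles kills the pair
  both <- .rec_calls(list(c(1L, 0L, 1L, 1L, 1L),
                          c(0L, 1L, 1L, 1L, 1L)))
  expect_equal(nrow(filter_recessive(v2, both, ped)), 0)
  # ungenotyped parent: emitted but flagged phase_unknown
  ids4 <- c("p2", "c1", "c2", "c3")
  g <- do.call(rbind, list(c(0L, 1L, 1L, 0L), c(1L, 1L, 1L, 0L)))
  colnames(g) <- ids4
  alt <- matrix(15L * g, 2, 4, dimnames = list(NULL, ids4))
  calls4 <- list(geno = g, ref = matrix(30L, 2, 4,
                                        dimnames = list(NULL, ids4)) - alt,
                 alt = alt)
  out4 <- filter_recessive(v2, calls4, ped)
  expect_true(all(grepl("phase_unknown", out4$flags)))
  # three qualifying hets: pairs flagged multi_pair
  v3 <- rbind(v2, make_variant(pos = 1000201))
  multi <- .rec_calls(list(c(1L, 0L, 1L, 1L, 0L),
                           c(0L, 1L, 1L, 1L, 0L),
                           c(0L, 1L, 1L, 1L, 0L)))
  out3 <- filter_recessive(v3, multi, ped)
  expect_true(all(grepl("multi_pair", out3$flags)))
  expect_gt(nrow(out3), 1)
})

test_that("relaxing any single numeric threshold never shrinks the pass set", {
  set.seed(55)
  n <- 300
  vs <- lapply(seq_len(n), function(i)
    make_variant(af_bravo = stats::rbeta(1, 0.3, 50),
                 af_gnomad = stats::rbeta(1, 0.3, 50)))
  pros <- lapply(seq_len(n), function(i)
    make_call(1L, ref = sample(0:20, 1), alt = sample(0:20, 1)))
  pars <- lapply(seq_len(n), function(i)
    make_call(0L, ref = sample(5:20, 1), alt = sample(0:2, 1)))
  passes <- function(th) vapply(seq_len(n), function(i)
    filter_denovo(vs[[i]], pros[[i]], pars[[i]], pars[[i]], th)$status ==
      "pass", TRUE)
  base <- passes(default_thresholds())
  relaxed <- list(
    default_thresholds(dnv_max_af = 1e-3),
    default_thresholds(dnv_min_depth = 8),
    default_thresholds(dnv_min_alt = 3),
    default_thresholds(dnv_min_ratio = 0.1, dnv_min_ratio_lowalt = 0.15),
    default_thresholds(dnv_parent_min_ref = 5),
    default_thresholds(dnv_parent_max_ratio = 0.1))
  for (th in relaxed) expect_true(all(passes(th) >= base))
})

test_that("constraint gene set applies missense and LoF rules per allele", {
  cst <- data.frame(gene = c("G1", "G2", "G3"),
                    pli = c(0.95, 0.5, NA), mis_z = c(2.5, 3, 1))
  solo <- function(gene, csq, metasvm = "D", cadd = 25)
    data.frame(gene = gene, csq = csq, metasvm = metasvm, cadd = cadd,
               pair_id = NA_character_, stringsAsFactors = FALSE)
  # missense rule: MetaSVM D + CADD >= 24 + mis-Z >= 2
  expect_equal(constraint_gene_set(solo("G1", "missense", "D", 25), cst)$genes,
               "G1")
  expect_equal(length(constraint_gene_set(solo("G1", "missense", "D", 23.9),
                                          cst)$genes), 0)
  expect_equal(length(constraint_gene_set(solo("G3", "missense", "D", 30),
                                          cst)$genes), 0)  # mis_z < 2
  # LoF rule: pLI >= 0.9
  expect_equal(constraint_gene_set(solo("G1", "stop_gain"), cst)$genes, "G1")
  out <- constraint_gene_set(solo("G2", "stop_gain"), cst)
  expect_equal(length(out$genes), 0)
  expect_equal(out$excluded$reason, "pli")
  # missing constraint entry
  miss <- constraint_gene_set(solo("G9", "missense"), cst)
  expect_equal(miss$excluded$reason, "missing_constraint")
  # compound het: both alleles must pass independently
  pair_ok <- rbind(solo("G1", "missense", "D", 25),
                   solo("G1", "missense", "D", 24))
  pair_ok$pair_id <- "p1"
  expect_equal(constraint_gene_set(pair_ok, cst)$genes, "G1")
  pair_bad <- pair_ok
  pair_bad$cadd[2] <- 20
  expect_equal(length(constraint_gene_set(pair_bad, cst)$genes), 0)
})
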