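test_that("gene drop recovers pedigree F and respects partition bounds", {
  set.seed(101)
  g <- toy_genome()
  # outbred trio: founder haplotypes unique, so autozygosity is exactly 0
  for (i in 1:5) {
    gd <- gene_drop(ped_trio(), g)
    expect_equal(autozygous_fraction(gd, "c1", g), 0)
  }
  # first-cousin offspring: mean fraction matches F within 3 MC SEs
  ped <- ped_first_cousin()
  fr <- replicate(400, autozygous_fraction(gene_drop(ped, g), "c1", g))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 1 / 16), 3 * se)
  # truth segments never exceed the genome and never overlap per sample
  gd <- gene_drop(ped, g)
  tr <- gd$truth_segments
  expect_lte(sum(tr$end[tr$sample == "c1"] - tr$start[tr$sample == "c1"] + 1),
             g$genome_mb * 1e6)
  for (ch in unique(tr$chrom)) {
    s <- tr[tr$sample == "c1" & tr$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
})

test_that("marker panel has the configured spacing and MAF distribution", {
  sc <- simulation_scenario(marker_spacing_kb = 20,
                            genome = genome_config(c(chr1 = 10)),
                            maf_alpha = 0.2, maf_beta = 2, seed = 1)
  set.seed(1)
  mk <- simulate_founder_haplotypes(sc)
  expect_equal(nrow(mk), 500)  # 10 Mb / 20 kb
  expect_equal(mk$pos[1:3], c(20000, 40000, 60000))
  sc2 <- simulation_scenario(maf_alpha = 0.2, maf_beta = 2,
                             marker_spacing_kb = 2, seed = 1)
  set.seed(2)
  mk2 <- simulate_founder_haplotypes(sc2)
  expect_lt(abs(mean(mk2$af) - 0.2 / 2.2),
            3 * sd(mk2$af) / sqrt(nrow(mk2)))
})

test_that("recorded AF is the generating parameter, not a sample frequency", {
  sc <- simulation_scenario(n_families = 2, n_genes = 30, seed = 4)
  sim <- simulate_cohort(sc)
  marker_rows <- match(paste(sim$markers$chrom, sim$markers$pos),
                       paste(sim$cohort$variants$chrom,
                             sim$cohort$variants$pos))
  expect_equal(sim$cohort$variants$af_gnomad[marker_rows], sim$markers$af)
})

test_that("simulated genotypes are Mendelian-consistent with parents", {
  sc <- simulation_scenario(n_families = 3, n_genes = 40, seed = 13)
  sim <- simulate_cohort(sc)
  dnv_keys <- paste(sim$planted$chrom, sim$planted$pos)[
    sim$planted$model %in% c("de_novo", "benign_dnv")]
  site_key <- paste(sim$cohort$variants$chrom, sim$cohort$variants$pos)
  rows <- !(site_key %in% dnv_keys) & sim$cohort$variants$chrom != "chrX"
  for (ped in sim$peds) {
    kids <- ped$id[!is.na(ped$father_id) & !is.na(ped$mother_id) &
                     ped$father_id %in% ped$id & ped$mother_id %in% ped$id]
    for (k in kids) {
      gk <- sim$true_geno[rows, k]
      gf <- sim$true_geno[rows, ped$father_id[ped$id == k]]
      gm <- sim$true_geno[rows, ped$mother_id[ped$id == k]]
      # child allele count bounded by transmissible parental alleles
      expect_true(all(gk >= (gf == 2) + (gm == 2)))
      expect_true(all(gk <= (gf >= 1) + (gm >= 1)))
    }
  }
})

test_that("planted truth and emitted genotypes agree when reads are clean", {
  sc <- simulation_scenario(n_families = 3, depth_mean = 80, error_rate = 0,
                            n_genes = 40, seed = 17)
  sim <- simulate_cohort(sc)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim$cohort, f)
  back <- parse_cohort_vcf(f)
  key <- paste(back$variants$chrom, back$variants$pos)
  pl <- sim$planted[sim$planted$class == "causal", ]
  for (i in seq_len(nrow(pl))) {
    r <- match(paste(pl$chrom[i], pl$pos[i]), key)
    ped <- sim$peds[[match(pl$family_id[i],
                           vapply(sim$peds, function(p) p$family_id[1], ""))]]
    aff <- affected_ids(ped)
    expect_true(all(back$geno[r, match(aff, back$samples)] == 2L))
    par <- c(ped$father_id[ped$id == aff[1]], ped$mother_id[ped$id == aff[1]])
    expect_true(all(back$geno[r, match(par, back$samples)] == 1L))
  }
})

test_that("read simulation matches its sampling model", {
  set.seed(5)
  n <- 12000
  geno <- matrix(rep(c(0L, 1L, 2L), each = n / 3), ncol = 3)
  rd <- simulate_reads(geno, depth_mean = 30, error_rate = 0.01)
  depth <- rd$ad_ref + rd$ad_alt
  expect_lt(abs(mean(depth) - 30), 3 * sd(depth) / sqrt(n))
  ratio <- rd$ad_alt / pmax(depth, 1)
  expect_lt(abs(mean(ratio[geno == 0L]) - 0.01), 0.002)
  expect_lt(abs(mean(ratio[geno == 1L]) - 0.5), 0.005)
  expect_gt(mean(ratio[geno == 2L]), 0.98)
  # GQ is monotone in depth among concordant hom-ref calls
  hr <- geno == 0L & rd$called == 0L & rd$ad_alt == 0L
  expect_gt(cor(depth[hr], rd$gq[hr]), 0.9)
})

test_that("mutability table normalizes to the total rate", {
  set.seed(3)
  genes <- tile_genes(toy_genome(), 50)
  tab <- build_mutability_table(genes, total_rate = 0.4)
  expect_equal(sum(tab$prob), 0.4)
  # probabilities proportional to gene length within each class
  lof <- tab[tab$class == "LoF", ]
  expect_equal(lof$prob / genes$length_bp[match(lof$gene, genes$gene)],
               rep(lof$prob[1] / genes$length_bp[match(lof$gene[1],
                                                       genes$gene)],
                   nrow(lof)))
  expect_error(build_mutability_table(genes[0, ], 0.4), "empty gene list")
})

test_that("seeded simulation is reproducible bit-for-bit", {
  sc <- simulation_scenario(n_families = 2, n_genes = 30, seed = 99)
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(a$cohort$geno, b$cohort$geno)
  expect_identical(a$planted, b$planted)
  expect_identical(a$truth_segments, b$truth_segments)
})

test_that("hom-recessive planting demands autozygosity in every affected", {
  # an outbred trio can never satisfy the autozygous-segment precondition
  sc <- simulation_scenario(template = "unrelated_trio", n_families = 1,
                            n_affected = 1, n_unaffected = 0,
                            causal_model = "hom_recessive_in_roh",
                            seed = 8)
  expect_error(simulate_cohort(sc, max_tries = 3), "autozygous segment|placement")
})
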