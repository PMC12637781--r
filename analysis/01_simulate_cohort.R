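#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study cohort.
#
# Gene-drops 20 multiplex first-cousin families (2 affected + 1 unaffected
# children) on the 250 Mb toy genome, plants one homozygous-recessive causal
# variant inside a shared autozygous segment per family, scatters ~1 benign
# coding de novo variant per proband from the synthetic mutability table,
# and simulates 30x read evidence. Everything downstream works from the
# files written here.

library(autozygr)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scenario <- simulation_scenario(template = "first_cousin", n_families = 20,
                                n_affected = 2, n_unaffected = 1,
                                genome = toy_genome(), depth_mean = 30,
                                causal_model = "hom_recessive_in_roh",
                                dnv_rate = 1, seed = 20240901)
sim <- simulate_cohort(scenario)

write_cohort_vcf(sim$cohort, file.path(out_dir, "cohort.vcf"))
write_pedigree(sim$peds, file.path(out_dir, "families.ped"))
write_bed(sim$truth_segments, file.path(out_dir, "truth_segments.bed"))
write.table(sim$planted, file.path(out_dir, "planted_variants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$mutability, file.path(out_dir, "mutability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$genes, file.path(out_dir, "genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_causal <- sum(sim$planted$class == "causal")
n_dnv <- sum(sim$planted$model == "benign_dnv")
cat(sprintf(
  "Simulated %d families (%d samples, %d sites): %d planted causal variants, %d benign DNVs.\n",
  length(sim$peds), length(sim$cohort$samples), nrow(sim$cohort$variants),
  n_causal, n_dnv))
cat(sprintf(paste0(
  "Mean true autozygous fraction in probands: %.4f (unconditional pedigree",
  " F = %.4f;\n  planting conditions each drop on a shared affected",
  " autozygous segment, which selects\n  for higher-than-expected",
  " autozygosity - visible again in step 2's burden comparison).\n"),
  mean(vapply(sim$peds, function(p) {
    id <- affected_ids(p)[1]
    tr <- sim$truth_segments[sim$truth_segments$sample == id, ]
    sum(tr$end - tr$start + 1) / (scenario$genome$genome_mb * 1e6)
  }, 0)), 1 / 16))
cat("Outputs in", out_dir, "\n")
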