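#!/usr/bin/env Rscript
# Step 5 — MPV detection, cohort summary, and gene-set enrichment.
#
# Assembles per-family results from the prioritization step (plus an MPV
# scenario run in-process), produces the cohort summary table with its
# documented denominators, re-tallies the published-scale per-family
# fixture, and demonstrates the covariate-adjusted logistic gene-set
# enrichment on simulated module memberships.

library(autozygr)

out_dir <- "results/summary"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

candidates <- read.delim("results/prioritization/candidates.tsv")
peds <- read_pedigree("results/sim/families.ped")
seg <- read_bed("results/roh/segregated_roh.bed")

fam_rows <- lapply(peds, function(ped) {
  fam <- ped$family_id[1]
  # causative tier: damaging candidates only (benign de novo scatter from
  # the mutability model stays out of the solved/MPV accounting)
  cd <- candidates[candidates$family_id == fam &
                     !grepl("not_damaging", candidates$damaging), ]
  solved <- nrow(cd) > 0
  tier_order <- c("hom_recessive", "comp_het", "x_linked", "de_novo")
  model <- if (solved) tier_order[min(match(cd$model, tier_order))] else
    NA_character_
  mp <- detect_mpv(cd, seg[seg$sample == fam, ])
  data.frame(family_id = fam, solved = solved, model = model,
             mpv = mp$mpv, actionable = FALSE,
             consanguineous = TRUE, multiplex = TRUE)
})
fam <- do.call(rbind, fam_rows)
write.table(fam, file.path(out_dir, "family_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
s <- summarize_cohort(fam)
write.table(s, file.path(out_dir, "cohort_summary_simulated.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Simulated-cohort summary:\n"); print(s)

# published-scale fixture: 188 families with the study's marginal counts
fx <- system.file("extdata", "cohort_family_results_synthetic.tsv",
                  package = "autozygr")
s2 <- summarize_cohort(read.delim(fx))
write.table(s2, file.path(out_dir, "cohort_summary_published_scale.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPublished-scale summary (synthetic per-family reconstruction):\n")
print(s2)

# covariate-adjusted logistic enrichment on a simulated module structure
set.seed(20240905)
n <- 2000
member <- seq_len(n) <= 200
p <- plogis(qlogis(0.05) + log(5) * member)
disease <- rbinom(n, 1, p)
covs <- data.frame(gc = runif(n, 0.3, 0.6), len = rlnorm(n, 10, 1),
                   expr = rnorm(n))
er <- enrichment_regression(disease, member, covs)
cat(sprintf("\nModule enrichment (5x planted odds): beta = %.2f (SE %.2f), p = %.3g; module threshold = %.3g.\n",
            er$coef, er$se, er$p, bonferroni_threshold(17)))
cat("Outputs in", out_dir, "\n")
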