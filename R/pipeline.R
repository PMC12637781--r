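#' Prioritize candidate variants in one family
#'
#' The per-family pipeline: detect ROH in the family's children, segregate
#' them across affected/unaffected siblings, apply the de novo, recessive
#' and X-linked filters to every rare coding variant carried by the
#' affected children, and annotate each candidate with its ROH context
#' (top-3 largest ROH of the proband, smaller ROH, or outside).
#'
#' @param cohort a [cohort_data()] containing the family's samples.
#' @param ped the family [pedigree()].
#' @param roh precomputed [detect_roh_cohort()] output (optional; computed
#'   for the family's members when `NULL`).
#' @param params a [roh_params()].
#' @param thresholds a [default_thresholds()].
#' @return list with `candidates` (data frame: `family_id`, `gene`,
#'   `model`, `chrom`, `pos`, `chrom2`, `pos2`, `damaging`, `flags`,
#'   `roh_category`, `in_segregated_roh`), `segregated` (segregated ROH
#'   segments) and `roh` (per-sample segments used).
#' @export
prioritize_family <- function(cohort, ped, roh = NULL,
                              params = roh_params(),
                              thresholds = default_thresholds()) {
  ids <- intersect(ped$id, cohort$samples)
  aff <- intersect(affected_ids(ped), ids)
  if (!length(aff)) stop("no genotyped affected individual in family")
  proband <- aff[1]
  if (is.null(roh)) {
    sub <- cohort
    keep <- match(ids, cohort$samples)
    sub$samples <- ids
    sub$geno <- cohort$geno[, keep, drop = FALSE]
    roh <- detect_roh_cohort(sub, params)
  }
  kids <- c(aff, intersect(unaffected_sib_ids(ped), ids))
  seg <- segregate_roh(roh[roh$sample %in% kids, , drop = FALSE], ped)

  v <- cohort$variants
  col <- match(ids, cohort$samples)
  geno <- cohort$geno[, col, drop = FALSE]
  colnames(geno) <- ids
  adr <- cohort$ad_ref[, col, drop = FALSE]
  ada <- cohort$ad_alt[, col, drop = FALSE]
  gq <- cohort$gq[, col, drop = FALSE]
  colnames(adr) <- colnames(ada) <- colnames(gq) <- ids
  hemi <- cohort$hemi[, col, drop = FALSE]
  colnames(hemi) <- ids

  fa <- ped$father_id[ped$id == proband]
  mo <- ped$mother_id[ped$id == proband]
  fa <- if (!is.na(fa) && fa %in% ids) fa else NA_character_
  mo <- if (!is.na(mo) && mo %in% ids) mo else NA_character_
  th <- thresholds

  # restrict to rare sites carried by an affected child
  af_b <- ifelse(is.na(v$af_bravo), 0, v$af_bravo)
  af_g <- ifelse(is.na(v$af_gnomad), 0, v$af_gnomad)
  carried <- rowSums(geno[, aff, drop = FALSE] >= 1L, na.rm = TRUE) > 0
  rare <- af_b <= th$rec_max_af & af_g <= th$rec_max_af & carried
  cands <- list()

  # recessive per gene
  rec_rows <- which(rare & !is.na(v$gene) & v$chrom != "chrX")
  for (g in unique(v$gene[rec_rows])) {
    rows <- rec_rows[v$gene[rec_rows] == g]
    res <- filter_recessive(
      v[rows, , drop = FALSE],
      list(geno = geno[rows, , drop = FALSE],
           ref = adr[rows, , drop = FALSE],
           alt = ada[rows, , drop = FALSE]),
      ped, th)
    if (nrow(res)) cands[[length(cands) + 1]] <- res
  }

  # de novo per rare het site in the proband (complete trio only)
  if (!is.na(fa) && !is.na(mo)) {
    dnv_rows <- which(af_b <= th$dnv_max_af & af_g <= th$dnv_max_af &
                        !is.na(geno[, proband]) & geno[, proband] == 1L &
                        !is.na(geno[, fa]) & geno[, fa] == 0L &
                        !is.na(geno[, mo]) & geno[, mo] == 0L &
                        v$chrom != "chrX")
    for (i in dnv_rows) {
      res <- filter_denovo(
        v[i, ],
        proband = list(geno = geno[i, proband], ref = adr[i, proband],
                       alt = ada[i, proband]),
        father = list(geno = geno[i, fa], ref = adr[i, fa],
                      alt = ada[i, fa]),
        mother = list(geno = geno[i, mo], ref = adr[i, mo],
                      alt = ada[i, mo]),
        thresholds = th)
      if (res$status == "pass")
        cands[[length(cands) + 1]] <- data.frame(
          family_id = ped$family_id[1], gene = v$gene[i], model = "de_novo",
          chrom = v$chrom[i], pos = v$pos[i], chrom2 = NA_character_,
          pos2 = NA_real_,
          damaging = classify_damaging(v$csq[i], v$metasvm[i], v$cadd[i],
                                       th),
          flags = "", stringsAsFactors = FALSE)
    }
  }

  # X-linked per rare hemizygous site in a male proband
  sexes <- stats::setNames(ped$sex, ped$id)
  if (sexes[[proband]] == "male") {
    unaff_m <- intersect(unaffected_sib_ids(ped), ids)
    unaff_m <- unaff_m[sexes[unaff_m] == "male"]
    xl_rows <- which(v$chrom == "chrX" &
                       af_b <= th$xl_max_af & af_g <= th$xl_max_af &
                       !is.na(geno[, proband]) & geno[, proband] == 2L &
                       hemi[, proband])
    for (i in xl_rows) {
      res <- filter_xlinked(
        v[i, ],
        proband = list(geno = geno[i, proband], ref = adr[i, proband],
                       alt = ada[i, proband], gq = gq[i, proband],
                       hemi = hemi[i, proband], sex = "male"),
        mother = if (!is.na(mo)) list(geno = geno[i, mo]),
        unaffected_male_genos = if (length(unaff_m)) geno[i, unaff_m]
                                else integer(0),
        thresholds = th)
      if (res$status == "pass")
        cands[[length(cands) + 1]] <- data.frame(
          family_id = ped$family_id[1], gene = v$gene[i], model = "x_linked",
          chrom = "chrX", pos = v$pos[i], chrom2 = NA_character_,
          pos2 = NA_real_,
          damaging = classify_damaging(v$csq[i], v$metasvm[i], v$cadd[i],
                                       th),
          flags = "", stringsAsFactors = FALSE)
    }
  }

  candidates <- if (length(cands)) do.call(rbind, cands) else
    data.frame(family_id = character(0), gene = character(0),
               model = character(0), chrom = character(0), pos = numeric(0),
               chrom2 = character(0), pos2 = numeric(0),
               damaging = character(0), flags = character(0),
               stringsAsFactors = FALSE)
  if (nrow(candidates)) {
    prob_seg <- roh[roh$sample == proband, , drop = FALSE]
    candidates$roh_category <- vapply(seq_len(nrow(candidates)), function(i)
      rank_variant_roh(candidates$chrom[i], candidates$pos[i], prob_seg), "")
    candidates$in_segregated_roh <- vapply(seq_len(nrow(candidates)),
                                           function(i)
      any(seg$chrom == candidates$chrom[i] &
            seg$start <= candidates$pos[i] &
            seg$end >= candidates$pos[i]), TRUE)
  } else {
    candidates$roh_category <- character(0)
    candidates$in_segregated_roh <- logical(0)
  }
  list(candidates = candidates, segregated = seg, roh = roh)
}
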