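#' Variant filter thresholds
#'
#' All numeric thresholds of the inheritance-model filters, exposed as one
#' object. The defaults are the study thresholds: de novo variants need
#' Bravo and gnomAD-genome MAF <= 5e-4, >= 10 total and >= 5 alternate reads
#' in the proband with alternate allele ratio >= 20% (>= 28% when alternate
#' reads < 10), and parents with >= 10 reference reads and alternate ratio
#' < 3.5%; recessive genotypes need MAF <= 1e-3, VQSR pass and >= 8 proband
#' reads; X-linked hemizygous variants need MAF <= 5e-5, VQSR pass, >= 8
#' reads, GQ >= 20 and MQ >= 40; GME Variome MAF must be <= 0.01 for
#' recessive candidates; segmental-duplication variants are excluded
#' everywhere. A missing population frequency is treated as 0 (novel
#' allele).
#'
#' @param ... name-value overrides of the defaults listed above.
#' @return a `filter_thresholds` list.
#' @export
default_thresholds <- function(...) {
  th <- list(
    dnv_max_af = 5e-4,
    dnv_min_depth = 10, dnv_min_alt = 5,
    dnv_min_ratio = 0.20, dnv_min_ratio_lowalt = 0.28, dnv_lowalt_below = 10,
    dnv_parent_min_ref = 10, dnv_parent_max_ratio = 0.035,
    rec_max_af = 1e-3, rec_max_af_gme = 0.01, rec_min_depth = 8,
    xl_max_af = 5e-5, xl_min_depth = 8, xl_min_gq = 20, xl_min_mq = 40,
    xl_min_ratio = 0.20, xl_min_ratio_lowalt = 0.28, xl_lowalt_below = 10,
    dmis_min_cadd = 20,
    constraint_min_cadd = 24, constraint_min_misz = 2,
    constraint_min_pli = 0.9)
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad)) stop("unknown threshold: ", paste(bad, collapse = ", "))
  th[names(dots)] <- dots
  structure(th, class = "filter_thresholds")
}

.LOF_CSQ <- c("stop_gain", "stop_loss", "frameshift_indel",
              "canonical_splice", "start_loss")

#' Damaging-class of a variant annotation
#'
#' LoF for stop-gain/stop-loss/frameshift/canonical-splice/start-loss;
#' missense is D-Mis when MetaSVM calls it deleterious or CADD >= 20
#' (missing scores fail that criterion, never pass it); non-frameshift
#' indels are their own class; everything else is not damaging.
#'
#' @param csq consequence string (see [cohort_data()] vocabulary).
#' @param metasvm `"D"`, `"T"` or `NA`.
#' @param cadd CADD phred score or `NA`.
#' @param thresholds a [default_thresholds()].
#' @return `"LoF"`, `"D-Mis"`, `"nonframeshift_indel"` or `"not_damaging"`
#'   (vectorized).
#' @export
#' @examples
#' classify_damaging("missense", "T", 25)  # D-Mis via CADD
classify_damaging <- function(csq, metasvm = NA, cadd = NA,
                              thresholds = default_thresholds()) {
  n <- max(length(csq), length(metasvm), length(cadd))
  csq <- rep_len(csq, n); metasvm <- rep_len(metasvm, n)
  cadd <- rep_len(cadd, n)
  out <- rep("not_damaging", n)
  out[csq %in% .LOF_CSQ] <- "LoF"
  dmis <- csq == "missense" &
    ((!is.na(metasvm) & metasvm == "D") |
       (!is.na(cadd) & cadd >= thresholds$dmis_min_cadd))
  out[dmis] <- "D-Mis"
  out[csq == "nonframeshift_indel"] <- "nonframeshift_indel"
  out
}

.ratio <- function(alt, ref) ifelse(alt + ref == 0, 0, alt / (alt + ref))

.fail <- function(reason) list(status = "fail", reason = reason)
.pass <- list(status = "pass", reason = NA_character_)
.not_evaluable <- function(reason)
  list(status = "not_evaluable", reason = reason)

#' De novo variant filter for one trio call
#'
#' Applies the de novo thresholds (see [default_thresholds()]) in a fixed
#' documented order — population frequency, segmental duplication,
#' consequence (exonic or canonical splice), proband depth, proband
#' alternate reads, proband allele ratio, parental reference depth,
#' parental alternate ratio — and reports the first violated rule.
#'
#' @param variant one-row annotation (as in [cohort_data()]`$variants`).
#' @param proband,father,mother lists with `geno`, `ref`, `alt` (read
#'   counts); a `NULL` or genotype-missing parent makes the trio
#'   not-evaluable rather than failing.
#' @param thresholds a [default_thresholds()].
#' @return list with `status` (`"pass"`, `"fail"`, `"not_evaluable"`) and
#'   `reason`.
#' @export
filter_denovo <- function(variant, proband, father, mother,
                          thresholds = default_thresholds()) {
  th <- thresholds
  if (is.null(father) || is.null(mother) ||
      is.na(father$geno) || is.na(mother$geno))
    return(.not_evaluable("missing_parental_call"))
  if (is.na(proband$geno) || proband$geno != 1L)
    return(.not_evaluable("proband_not_het"))
  af_b <- ifelse(is.na(variant$af_bravo), 0, variant$af_bravo)
  af_g <- ifelse(is.na(variant$af_gnomad), 0, variant$af_gnomad)
  if (af_b > th$dnv_max_af || af_g > th$dnv_max_af)
    return(.fail("population_af"))
  if (isTRUE(variant$segdup)) return(.fail("segdup"))
  if (variant$csq == "other") return(.fail("consequence"))
  dp <- proband$ref + proband$alt
  if (dp < th$dnv_min_depth) return(.fail("proband_depth"))
  if (proband$alt < th$dnv_min_alt) return(.fail("proband_alt_reads"))
  min_ratio <- if (proband$alt < th$dnv_lowalt_below)
    th$dnv_min_ratio_lowalt else th$dnv_min_ratio
  if (.ratio(proband$alt, proband$ref) < min_ratio)
    return(.fail("allele_ratio"))
  for (par in list(father, mother)) {
    if (par$ref < th$dnv_parent_min_ref) return(.fail("parent_ref_reads"))
    if (.ratio(par$alt, par$ref) >= th$dnv_parent_max_ratio)
      return(.fail("parent_alt_ratio"))
  }
  .pass
}

#' X-linked hemizygous filter for one family call
#'
#' Rules in order: proband hemizygous-alt male (else not evaluable),
#' population frequency, VQSR pass, segmental duplication, depth, genotype
#' quality, mapping quality, allele ratio, carrier mother heterozygous when
#' genotyped, no unaffected male hemizygous-alt.
#'
#' @param variant one-row annotation; must lie on `chrX`.
#' @param proband list with `geno`, `ref`, `alt`, `gq`, `hemi`, `sex`.
#' @param mother optional list with `geno` (`NA`-genotype skips the check).
#' @param unaffected_male_genos integer vector of unaffected male genotype
#'   codes at this site (hemizygous coding, `2` = alt).
#' @param thresholds a [default_thresholds()].
#' @return list with `status` and `reason` as in [filter_denovo()].
#' @export
filter_xlinked <- function(variant, proband, mother = NULL,
                           unaffected_male_genos = integer(0),
                           thresholds = default_thresholds()) {
  th <- thresholds
  if (variant$chrom != "chrX") stop("filter_xlinked needs an X variant")
  if (!identical(proband$sex, "male"))
    return(.not_evaluable("female_proband"))
  if (is.na(proband$geno) || proband$geno != 2L || !isTRUE(proband$hemi))
    return(.not_evaluable("proband_not_hemizygous_alt"))
  af_b <- ifelse(is.na(variant$af_bravo), 0, variant$af_bravo)
  af_g <- ifelse(is.na(variant$af_gnomad), 0, variant$af_gnomad)
  if (af_b > th$xl_max_af || af_g > th$xl_max_af)
    return(.fail("population_af"))
  if (!isTRUE(variant$filter_pass)) return(.fail("vqsr"))
  if (isTRUE(variant$segdup)) return(.fail("segdup"))
  dp <- proband$ref + proband$alt
  if (dp < th$xl_min_depth) return(.fail("depth"))
  if (is.na(proband$gq) || proband$gq < th$xl_min_gq)
    return(.fail("genotype_quality"))
  if (is.na(variant$mq) || variant$mq < th$xl_min_mq)
    return(.fail("mapping_quality"))
  min_ratio <- if (proband$alt < th$xl_lowalt_below)
    th$xl_min_ratio_lowalt else th$xl_min_ratio
  if (.ratio(proband$alt, proband$ref) < min_ratio)
    return(.fail("allele_ratio"))
  if (!is.null(mother) && !is.na(mother$geno) && mother$geno != 1L)
    return(.fail("mother_not_carrier"))
  if (length(unaffected_male_genos) &&
      any(unaffected_male_genos == 2L, na.rm = TRUE))
    return(.fail("unaffected_male_hemizygous"))
  .pass
}

# shared site-level checks for recessive candidates; returns NA_character_
# when clean, else the first violated rule
.recessive_site_fail <- function(variant, proband_dp, damaging, th) {
  af_b <- ifelse(is.na(variant$af_bravo), 0, variant$af_bravo)
  af_g <- ifelse(is.na(variant$af_gnomad), 0, variant$af_gnomad)
  af_m <- ifelse(is.na(variant$af_gme), 0, variant$af_gme)
  if (af_b > th$rec_max_af || af_g > th$rec_max_af) return("population_af")
  if (af_m > th$rec_max_af_gme) return("population_af_gme")
  if (!isTRUE(variant$filter_pass)) return("vqsr")
  if (isTRUE(variant$segdup)) return("segdup")
  if (any(proband_dp < th$rec_min_depth)) return("depth")
  if (damaging == "not_damaging") return("not_damaging")
  NA_character_
}

#' Recessive candidates (homozygous and compound het) in one gene
#'
#' Homozygous candidates: proband homozygous-alt, every genotyped parent
#' heterozygous, all affected siblings homozygous-alt and no unaffected
#' sibling homozygous-alt; the site must be rare (Bravo/gnomAD <= 1e-3, GME
#' <= 0.01), VQSR-pass, outside segmental duplications, covered by >= 8
#' reads in each proband, and damaging per [classify_damaging()].
#'
#' Compound heterozygotes: two distinct heterozygous variants in the gene,
#' each independently passing the site rules, in trans (one inherited from
#' each parent, as witnessed by parental genotypes), with the same carrier
#' pattern in affected siblings and not jointly carried by an unaffected
#' sibling. When a parent is ungenotyped the pair cannot be phased and is
#' emitted flagged `phase_unknown` instead of dropped. Genes with more than
#' two qualifying heterozygous variants emit every trans-consistent pair,
#' flagged `multi_pair`.
#'
#' @param gene_variants annotation rows of one gene's variants.
#' @param calls list of per-variant call matrices: for variant `i`,
#'   `calls$geno[i, ]`, `calls$ref[i, ]`, `calls$alt[i, ]` indexed by sample
#'   id.
#' @param ped the family [pedigree()].
#' @param thresholds a [default_thresholds()].
#' @return data frame of candidates: `family_id`, `gene`, `model`,
#'   `chrom`, `pos` (and `chrom2`/`pos2` for pairs), `damaging`, `flags`.
#' @export
filter_recessive <- function(gene_variants, calls, ped,
                             thresholds = default_thresholds()) {
  th <- thresholds
  aff <- affected_ids(ped)
  if (!length(aff)) stop("no affected proband in pedigree")
  unaff <- unaffected_sib_ids(ped)
  fam <- ped$family_id[1]
  fa <- ped$father_id[ped$id == aff[1]]
  mo <- ped$mother_id[ped$id == aff[1]]
  fa_typed <- !is.na(fa) && fa %in% colnames(calls$geno)
  mo_typed <- !is.na(mo) && mo %in% colnames(calls$geno)
  gene <- gene_variants$gene[1]
  n <- nrow(gene_variants)
  damaging <- classify_damaging(gene_variants$csq, gene_variants$metasvm,
                                gene_variants$cadd, th)
  out <- list()
  add <- function(row) out[[length(out) + 1]] <<- row

  site_ok <- vapply(seq_len(n), function(i) {
    dp <- calls$ref[i, aff] + calls$alt[i, aff]
    is.na(.recessive_site_fail(gene_variants[i, ], dp, damaging[i], th))
  }, TRUE)

  # --- homozygous candidates
  for (i in which(site_ok)) {
    g <- calls$geno[i, ]
    if (any(is.na(g[aff])) || !all(g[aff] == 2L)) next
    if (fa_typed && (is.na(g[fa]) || g[fa] != 1L)) next
    if (mo_typed && (is.na(g[mo]) || g[mo] != 1L)) next
    if (length(unaff) && any(!is.na(g[unaff]) & g[unaff] == 2L)) next
    add(data.frame(family_id = fam, gene = gene, model = "hom_recessive",
                   chrom = gene_variants$chrom[i], pos = gene_variants$pos[i],
                   chrom2 = NA_character_, pos2 = NA_real_,
                   damaging = damaging[i], flags = "",
                   stringsAsFactors = FALSE))
  }

  # --- compound heterozygous candidates
  het_idx <- which(site_ok & vapply(seq_len(n), function(i) {
    g <- calls$geno[i, ]
    all(!is.na(g[aff]) & g[aff] == 1L)
  }, TRUE))
  if (length(het_idx) >= 2) {
    multi <- length(het_idx) > 2
    origin <- function(i) {
      # "paternal": father carries the allele and mother does not
      if (!fa_typed || !mo_typed) return("unknown")
      gf <- calls$geno[i, fa]; gm <- calls$geno[i, mo]
      if (is.na(gf) || is.na(gm)) return("unknown")
      if (gf >= 1L && gm == 0L) return("paternal")
      if (gm >= 1L && gf == 0L) return("maternal")
      "ambiguous"
    }
    org <- vapply(het_idx, origin, "")
    for (a in seq_along(het_idx)) for (b in seq_along(het_idx)) {
      if (a >= b) next
      i <- het_idx[a]; j <- het_idx[b]
      flags <- character(0)
      if (org[a] == "unknown" || org[b] == "unknown") {
        flags <- c(flags, "phase_unknown")
      } else {
        trans <- (org[a] == "paternal" && org[b] == "maternal") ||
          (org[a] == "maternal" && org[b] == "paternal")
        if (!trans) next
      }
      if (length(unaff)) {
        gi <- calls$geno[i, unaff]; gj <- calls$geno[j, unaff]
        if (any(!is.na(gi) & !is.na(gj) & gi >= 1L & gj >= 1L)) next
      }
      if (multi) flags <- c(flags, "multi_pair")
      add(data.frame(family_id = fam, gene = gene, model = "comp_het",
                     chrom = gene_variants$chrom[i],
                     pos = gene_variants$pos[i],
                     chrom2 = gene_variants$chrom[j],
                     pos2 = gene_variants$pos[j],
                     damaging = paste(damaging[i], damaging[j], sep = "+"),
                     flags = paste(flags, collapse = ","),
                     stringsAsFactors = FALSE))
    }
  }
  if (!length(out))
    return(data.frame(family_id = character(0), gene = character(0),
                      model = character(0), chrom = character(0),
                      pos = numeric(0), chrom2 = character(0),
                      pos2 = numeric(0), damaging = character(0),
                      flags = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Constraint-filtered gene set from candidate variants
#'
#' Retains genes whose supporting variant(s) pass the constraint rules:
#' missense variants need MetaSVM deleterious, CADD >= 24 and gene
#' mis-Z >= 2; LoF variants need gene pLI >= 0.9. Compound-het pairs
#' require both alleles to pass independently. Genes without a constraint
#' entry are excluded with reason `missing_constraint`.
#'
#' @param candidates data frame with `gene`, `csq` (or `csq1`/`csq2` via
#'   two rows sharing `pair_id`), `metasvm`, `cadd`; one row per supporting
#'   allele, `pair_id` non-`NA` linking compound-het alleles.
#' @param constraints data frame `gene`, `pli`, `mis_z`.
#' @param thresholds a [default_thresholds()].
#' @return list with `genes` (retained character vector) and `excluded`
#'   (data frame `gene`, `reason`).
#' @export
constraint_gene_set <- function(candidates, constraints,
                                thresholds = default_thresholds()) {
  th <- thresholds
  cst <- constraints[!duplicated(constraints$gene), ]
  rownames(cst) <- cst$gene
  allele_ok <- function(row) {
    if (!row$gene %in% rownames(cst)) return("missing_constraint")
    pli <- cst[row$gene, "pli"]; misz <- cst[row$gene, "mis_z"]
    dmg <- classify_damaging(row$csq, row$metasvm, row$cadd, th)
    if (dmg == "LoF") {
      if (!is.na(pli) && pli >= th$constraint_min_pli) return(NA_character_)
      return("pli")
    }
    if (row$csq == "missense") {
      if (!is.na(row$metasvm) && row$metasvm == "D" &&
          !is.na(row$cadd) && row$cadd >= th$constraint_min_cadd &&
          !is.na(misz) && misz >= th$constraint_min_misz)
        return(NA_character_)
      return("missense_constraint")
    }
    "class_not_covered"
  }
  reasons <- vapply(seq_len(nrow(candidates)), function(i)
    allele_ok(candidates[i, ]), "")
  # a gene is retained when every allele of at least one supporting
  # candidate (pair alleles grouped) passes
  key <- ifelse(is.na(candidates$pair_id),
                paste0("solo", seq_len(nrow(candidates))),
                candidates$pair_id)
  unit_ok <- tapply(is.na(reasons), paste(candidates$gene, key), all)
  gene_of_unit <- tapply(candidates$gene, paste(candidates$gene, key),
                         function(x) x[1])
  retained <- unique(unlist(gene_of_unit[unit_ok]))
  excl <- candidates$gene[!candidates$gene %in% retained]
  excl_reason <- reasons[!candidates$gene %in% retained]
  list(genes = retained,
       excluded = unique(data.frame(gene = excl, reason = excl_reason,
                                    stringsAsFactors = FALSE)))
}
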