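#' Simulation scenario for synthetic consanguineous cohorts
#'
#' Bundles every knob of the gene-drop cohort simulator. Defaults describe
#' the study conditions the package is validated under: multiplex
#' first-cousin families with two affected and one unaffected child, a
#' polymorphic marker panel every 20 kb with allele frequencies drawn from
#' Beta(1.2, 3) (mean MAF ~0.29, emulating the common, ascertained
#' polymorphisms that drive ROH detection rather than a rare-variant site
#' frequency spectrum), 30x mean read depth with a 0.2% per-read error rate,
#' and one planted causal configuration per family.
#'
#' @param template pedigree template: `"first_cousin"`,
#'   `"double_first_cousin"`, `"avuncular"`, `"unrelated_trio"`, or a list of
#'   custom [pedigree()] objects (one per family).
#' @param n_families number of families.
#' @param n_affected,n_unaffected children per family.
#' @param genome a [genome_config()].
#' @param marker_spacing_kb marker spacing in kb.
#' @param maf_alpha,maf_beta Beta parameters of the marker MAF distribution.
#' @param depth_mean mean sequencing depth (Poisson).
#' @param error_rate per-read miscall probability, in \[0, 0.05\].
#' @param causal_model `"hom_recessive_in_roh"`, `"comp_het"`, `"de_novo"`,
#'   `"x_linked"`, `"mpv_pair"` or `"none"`.
#' @param causal_maf population frequency of planted causal alleles; `NULL`
#'   picks a model-specific default below that model's filter threshold
#'   (5e-4 recessive/compound het/MPV, 1e-5 X-linked, absent for de novo).
#' @param dnv_rate expected benign coding de novo variants per proband
#'   (drawn from the synthetic mutability table).
#' @param same_segment for `"mpv_pair"`: plant both genes inside one shared
#'   autozygous segment.
#' @param n_genes number of synthetic genes tiled on the genome.
#' @param seed integer seed; every random draw descends from it.
#' @return a `simulation_scenario` list.
#' @export
simulation_scenario <- function(template = "first_cousin", n_families = 10,
                                n_affected = 2, n_unaffected = 1,
                                genome = toy_genome(),
                                marker_spacing_kb = 20,
                                maf_alpha = 1.2, maf_beta = 3,
                                depth_mean = 30, error_rate = 0.002,
                                causal_model = "hom_recessive_in_roh",
                                causal_maf = NULL, dnv_rate = 1,
                                same_segment = TRUE,
                                n_genes = 120, seed = 1) {
  stopifnot(n_families >= 1, n_affected >= 0, n_unaffected >= 0,
            marker_spacing_kb > 0, depth_mean > 0,
            error_rate >= 0, error_rate <= 0.05,
            maf_alpha > 0, maf_beta > 0, n_genes >= 1)
  causal_model <- match.arg(causal_model,
                            c("hom_recessive_in_roh", "comp_het", "de_novo",
                              "x_linked", "mpv_pair", "none"))
  if (is.null(causal_maf))
    causal_maf <- switch(causal_model,
                         x_linked = 1e-5, de_novo = NA_real_, none = NA_real_,
                         5e-4)
  structure(list(template = template, n_families = n_families,
                 n_affected = n_affected, n_unaffected = n_unaffected,
                 genome = genome, marker_spacing_kb = marker_spacing_kb,
                 maf_alpha = maf_alpha, maf_beta = maf_beta,
                 depth_mean = depth_mean, error_rate = error_rate,
                 causal_model = causal_model, causal_maf = causal_maf,
                 dnv_rate = dnv_rate, same_segment = same_segment,
                 n_genes = n_genes, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Marker panel: positions and population allele frequencies
#'
#' Places markers every `marker_spacing_kb` kb along each chromosome and
#' draws each marker's population alternate-allele frequency from
#' Beta(alpha, beta). The drawn frequency is the truth recorded in the
#' `af_*` annotation fields — the generating parameter, not the realized
#' sample frequency.
#'
#' @param scenario a [simulation_scenario()] (uses the current RNG state).
#' @param include_x also place markers on the X.
#' @return data frame `chrom`, `pos`, `af`.
#' @export
simulate_founder_haplotypes <- function(scenario, include_x = FALSE) {
  lens <- .chrom_lengths_bp(scenario$genome, include_x = include_x)
  sp <- round(scenario$marker_spacing_kb * 1000)
  out <- lapply(names(lens), function(ch) {
    n <- floor(lens[[ch]] / sp)
    if (n == 0) return(NULL)
    data.frame(chrom = ch, pos = sp * seq_len(n), stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, out)
  mk$af <- stats::rbeta(nrow(mk), scenario$maf_alpha, scenario$maf_beta)
  mk
}

#' Tile synthetic genes along the genome
#'
#' Genes are placed in equal slots per chromosome (count proportional to
#' chromosome length) with log-normal lengths, plus GC content and a mean
#' expression covariate for enrichment regressions.
#'
#' @param genome a [genome_config()].
#' @param n_genes total gene count.
#' @param include_x tile genes on the X too (an extra ~5% of `n_genes`).
#' @return data frame `gene`, `chrom`, `start`, `end`, `length_bp`, `gc`,
#'   `expr`.
#' @export
tile_genes <- function(genome, n_genes = 120, include_x = FALSE) {
  lens <- .chrom_lengths_bp(genome, include_x = include_x)
  weights <- lens / sum(lens)
  counts <- pmax(1L, round(n_genes * weights))
  rows <- lapply(seq_along(lens), function(k) {
    n <- counts[k]
    slot <- lens[k] / n
    len <- pmin(round(stats::rlnorm(n, log(4e4), 0.6)), round(slot * 0.6))
    start <- round(slot * (seq_len(n) - 1) + slot * 0.2) + 1
    data.frame(chrom = names(lens)[k], start = start,
               end = start + len - 1, length_bp = len,
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  g$gene <- sprintf("G%04d", seq_len(nrow(g)))
  g$gc <- stats::runif(nrow(g), 0.35, 0.6)
  g$expr <- stats::rnorm(nrow(g), 5, 2)
  g[, c("gene", "chrom", "start", "end", "length_bp", "gc", "expr")]
}

#' Per-gene de novo mutability table
#'
#' Synthetic counterpart of trinucleotide-context mutability tables:
#' per-gene probabilities proportional to gene length, split across variant
#' classes by fixed fractions (LoF 0.10, D-Mis 0.20, missense 0.35,
#' synonymous 0.35), normalized so the genome-wide per-chromosome-copy sum
#' equals `total_rate`.
#'
#' @param genes data frame with `gene` and `length_bp` (see [tile_genes()]).
#' @param total_rate genome-wide de novo probability per chromosome copy.
#' @return data frame `gene`, `class`, `prob`.
#' @export
build_mutability_table <- function(genes, total_rate = 0.5) {
  if (!nrow(genes)) stop("empty gene list")
  stopifnot(total_rate > 0, all(genes$length_bp > 0))
  frac <- c(LoF = 0.10, `D-Mis` = 0.20, missense = 0.35, synonymous = 0.35)
  per_gene <- genes$length_bp / sum(genes$length_bp) * total_rate
  out <- do.call(rbind, lapply(names(frac), function(cl) {
    data.frame(gene = genes$gene, class = cl, prob = per_gene * frac[[cl]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- read-level evidence ----------------------------------------------------

#' Simulate read evidence and call genotypes
#'
#' Per site and sample, total depth is Poisson(`depth_mean`) and alternate
#' reads are Binomial(depth, p) with p = `error_rate`, 0.5, or
#' 1 - `error_rate` for hom-ref / het / hom-alt (hemizygous sites use the two
#' homozygous states). Genotypes are then re-called by maximum likelihood
#' under the same error model (error floored at 1e-3 so every genotype keeps
#' positive likelihood), and GQ is the phred-scaled likelihood gap between
#' the best and second-best genotype, capped at 99 — deterministic given the
#' reads, monotone in depth and allele-balance consistency. Zero-depth calls
#' are missing.
#'
#' @param geno integer matrix of true genotypes (0/1/2, `NA` missing).
#' @param depth_mean mean depth.
#' @param error_rate per-read miscall probability.
#' @param hemi logical matrix marking hemizygous entries (no het state).
#' @return list of matrices `ad_ref`, `ad_alt`, `gq`, `called` (ML genotype
#'   codes; `NA` where depth is 0 or the true genotype was missing).
#' @export
simulate_reads <- function(geno, depth_mean, error_rate, hemi = NULL) {
  stopifnot(depth_mean > 0, error_rate >= 0)
  n <- length(geno)
  if (is.null(hemi)) hemi <- matrix(FALSE, nrow(geno), ncol(geno))
  depth <- stats::rpois(n, depth_mean)
  p_alt <- ifelse(is.na(geno), 0,
                  ifelse(geno == 0L, error_rate,
                         ifelse(geno == 1L, 0.5, 1 - error_rate)))
  alt <- stats::rbinom(n, depth, p_alt)
  alt[is.na(geno)] <- NA_integer_
  depth[is.na(geno)] <- NA_integer_
  ref <- depth - alt
  e <- max(error_rate, 1e-3)
  ll0 <- alt * log(e) + ref * log(1 - e)
  ll1 <- depth * log(0.5)
  ll2 <- alt * log(1 - e) + ref * log(e)
  ll1[hemi] <- -Inf
  ll <- cbind(ll0, ll1, ll2)
  best <- max.col(ll, ties.method = "first")
  second <- vapply(seq_len(n), function(i) {
    v <- ll[i, ]
    v[best[i]] <- -Inf
    max(v)
  }, 0)
  called <- best - 1L
  gq <- pmin(99L, as.integer(round(10 * (ll[cbind(seq_len(n), best)] - second) /
                                     log(10))))
  zero <- !is.na(depth) & depth == 0L
  called[zero] <- NA_integer_
  gq[zero] <- 0L
  called[is.na(geno)] <- NA_integer_
  gq[is.na(geno)] <- NA_integer_
  dims <- dim(geno)
  list(ad_ref = matrix(as.integer(ref), dims[1], dims[2]),
       ad_alt = matrix(as.integer(alt), dims[1], dims[2]),
       gq = matrix(gq, dims[1], dims[2]),
       called = matrix(called, dims[1], dims[2]))
}

# ---- planting ---------------------------------------------------------------

# Labels of a sample's two haplotypes at (chrom, pos); male X gives one label.
.labels_at <- function(gd, id, chrom, pos) {
  h <- gd$haplotypes[[id]]
  pat <- h$pat[[chrom]]
  mat <- h$mat[[chrom]]
  c(if (!is.null(pat)) .hap_at(pat, pos) else NA_integer_,
    if (!is.null(mat)) .hap_at(mat, pos) else NA_integer_)
}

# Intervals on chrom where every id in `ids` is autozygous for one common
# label; returns data.frame(start, end, lab).
.shared_autozygous_intervals <- function(gd, ids, chrom, len_bp) {
  tracks <- lapply(ids, function(id) gd$haplotypes[[id]])
  bp <- sort(unique(unlist(lapply(tracks, function(h)
    c(h$pat[[chrom]]$bp, h$mat[[chrom]]$bp)))))
  labs <- vapply(tracks, function(h) {
    p <- .hap_at(h$pat[[chrom]], bp)
    m <- .hap_at(h$mat[[chrom]], bp)
    ifelse(p == m, p, NA_integer_)
  }, integer(length(bp)))
  labs <- matrix(labs, nrow = length(bp))
  ok <- !apply(labs, 1, anyNA) &
    apply(labs, 1, function(x) length(unique(x)) == 1L)
  if (!any(ok)) return(NULL)
  lab <- labs[, 1]
  ends <- c(bp[-1] - 1, len_bp)
  grp <- rle(paste(ok, ifelse(ok, lab, 0)))
  iend <- cumsum(grp$lengths)
  istart <- iend - grp$lengths + 1
  keep <- which(startsWith(grp$values, "TRUE"))
  if (!length(keep)) return(NULL)
  data.frame(start = bp[istart[keep]], end = ends[iend[keep]],
             lab = lab[istart[keep]])
}

# choose a position inside gene & interval avoiding marker positions
.pick_pos <- function(start, end, spacing_bp) {
  pos <- round((start + end) / 2)
  if (pos %% spacing_bp == 0) pos <- pos + 1
  min(max(pos, start), end)
}

#' Plant causal variants into a simulated family
#'
#' Inserts alleles onto founder haplotypes (or as de novo events) so the
#' requested inheritance configuration holds exactly: homozygous in affected
#' children, heterozygous in the transmitting parents, absent or
#' heterozygous in unaffected siblings; de novo variants appear in the
#' proband only; `mpv_pair` plants two genes, optionally inside one shared
#' autozygous segment. Because planted alleles ride real founder haplotypes,
#' Mendelian consistency is automatic.
#'
#' @param gd a [gene_drop()] result for one family.
#' @param ped the family [pedigree()].
#' @param genes gene map from [tile_genes()].
#' @param scenario the [simulation_scenario()].
#' @return `NULL` when no eligible placement exists (caller may redraw the
#'   gene drop), otherwise a list with `sites` (annotation rows), `carrier`
#'   (list of founder-label sets per site; `NULL` for de novo),
#'   `dnv_child` (proband id for de novo sites) and `truth` rows.
#' @export
plant_variants <- function(gd, ped, genes, scenario) {
  model <- scenario$causal_model
  if (model == "none") return(.empty_plant())
  aff <- affected_ids(ped)
  unaff <- unaffected_sib_ids(ped)
  fam <- ped$family_id[1]
  spacing <- round(scenario$marker_spacing_kb * 1000)
  lens <- .chrom_lengths_bp(scenario$genome,
                            include_x = model == "x_linked")

  if (model %in% c("hom_recessive_in_roh", "mpv_pair")) {
    if (!length(aff)) stop("no affected children in family ", fam)
    # precondition: every affected child carries >=1 autozygous segment >=1 Mb
    tr <- gd$truth_segments
    for (a in aff) {
      sa <- tr[tr$sample == a & tr$chrom != "chrX", , drop = FALSE]
      if (!nrow(sa) || max(sa$end - sa$start + 1) < 1e6)
        stop("family ", fam, ": affected child ", a,
             " has no autozygous segment >= 1 Mb")
    }
    hits <- .recessive_placements(gd, ped, genes, lens, spacing)
    need <- if (model == "mpv_pair") 2L else 1L
    if (is.null(hits) || nrow(hits) < need) return(NULL)
    if (model == "mpv_pair") {
      if (scenario$same_segment) {
        key <- paste(hits$chrom, hits$seg_start, hits$lab)
        tab <- table(key)
        ok <- names(tab)[tab >= 2]
        if (!length(ok)) return(NULL)
        hits <- hits[key == ok[1], ][1:2, ]
      } else {
        if (length(unique(hits$chrom)) < 2) return(NULL)
        hits <- hits[!duplicated(hits$chrom), ][1:2, ]
      }
    } else {
      hits <- hits[which.max(hits$seg_end - hits$seg_start), , drop = FALSE]
    }
    sites <- do.call(rbind, lapply(seq_len(nrow(hits)), function(k)
      .causal_site_row(hits$chrom[k], hits$pos[k], hits$gene[k], scenario)))
    return(list(
      sites = sites,
      carrier = lapply(hits$lab, identity),
      dnv_child = rep(NA_character_, nrow(hits)),
      truth = data.frame(family_id = fam, model = model, gene = hits$gene,
                         chrom = hits$chrom, pos = hits$pos,
                         pair_id = if (model == "mpv_pair") "pair1" else NA_character_,
                         stringsAsFactors = FALSE)))
  }

  if (model == "comp_het") {
    pl <- .comp_het_placement(gd, ped, genes, spacing)
    if (is.null(pl)) return(NULL)
    sites <- rbind(
      .causal_site_row(pl$chrom, pl$pos1, pl$gene, scenario),
      .causal_site_row(pl$chrom, pl$pos2, pl$gene, scenario))
    return(list(
      sites = sites,
      carrier = list(pl$lab1, pl$lab2),
      dnv_child = c(NA_character_, NA_character_),
      truth = data.frame(family_id = fam, model = model, gene = pl$gene,
                         chrom = pl$chrom, pos = c(pl$pos1, pl$pos2),
                         pair_id = "cis_trans_pair",
                         stringsAsFactors = FALSE)))
  }

  if (model == "de_novo") {
    proband <- aff[1]
    g <- genes[genes$chrom != "chrX", ]
    gi <- g[sample.int(nrow(g), 1), ]
    pos <- .pick_pos(gi$start, gi$end, spacing)
    return(list(
      sites = .causal_site_row(gi$chrom, pos, gi$gene, scenario),
      carrier = list(NULL),
      dnv_child = proband,
      truth = data.frame(family_id = fam, model = model, gene = gi$gene,
                         chrom = gi$chrom, pos = pos,
                         pair_id = NA_character_,
                         stringsAsFactors = FALSE)))
  }

  if (model == "x_linked") {
    pl <- .xlinked_placement(gd, ped, genes, spacing)
    if (is.null(pl)) return(NULL)
    return(list(
      sites = .causal_site_row("chrX", pl$pos, pl$gene, scenario),
      carrier = list(pl$lab),
      dnv_child = NA_character_,
      truth = data.frame(family_id = fam, model = model, gene = pl$gene,
                         chrom = "chrX", pos = pl$pos,
                         pair_id = NA_character_,
                         stringsAsFactors = FALSE)))
  }
  stop("unknown causal model: ", model)
}

.empty_plant <- function() {
  list(sites = NULL, carrier = list(), dnv_child = character(0),
       truth = data.frame(family_id = character(0), model = character(0),
                          gene = character(0), chrom = character(0),
                          pos = numeric(0), pair_id = character(0),
                          stringsAsFactors = FALSE))
}

.causal_site_row <- function(chrom, pos, gene, scenario, class = "D-Mis") {
  af <- scenario$causal_maf
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
             filter_pass = TRUE, mq = 60,
             gene = gene,
             csq = if (class == "LoF") "stop_gain" else "missense",
             metasvm = if (class == "D-Mis") "D" else "T",
             cadd = 28, af_bravo = af, af_gnomad = af, af_gme = af,
             segdup = FALSE, stringsAsFactors = FALSE)
}

# All (gene, position, label) placements where every affected child is
# autozygous for one shared label, no unaffected sib is homozygous for it,
# and each transmitting parent carries exactly one copy.
.recessive_placements <- function(gd, ped, genes, lens, spacing) {
  aff <- affected_ids(ped)
  unaff <- unaffected_sib_ids(ped)
  fa <- ped$father_id[ped$id == aff[1]]
  mo <- ped$mother_id[ped$id == aff[1]]
  out <- list()
  for (ch in setdiff(names(lens), "chrX")) {
    iv <- .shared_autozygous_intervals(gd, aff, ch, lens[[ch]])
    if (is.null(iv)) next
    iv <- iv[iv$end - iv$start + 1 >= 1e6, , drop = FALSE]
    if (!nrow(iv)) next
    gch <- genes[genes$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(iv))) {
      hit_g <- gch[gch$start <= iv$end[k] & gch$end >= iv$start[k], ,
                   drop = FALSE]
      if (!nrow(hit_g)) next
      for (j in seq_len(nrow(hit_g))) {
        lo <- max(iv$start[k], hit_g$start[j])
        hi <- min(iv$end[k], hit_g$end[j])
        pos <- .pick_pos(lo, hi, spacing)
        lab <- iv$lab[k]
        # parents het (exactly one copy of the carrier label)
        ok_par <- all(vapply(c(fa, mo), function(p)
          sum(.labels_at(gd, p, ch, pos) == lab, na.rm = TRUE) == 1L, TRUE))
        if (!ok_par) next
        # unaffected sibs must not be homozygous for the label
        ok_unaff <- !length(unaff) || all(vapply(unaff, function(u)
          sum(.labels_at(gd, u, ch, pos) == lab, na.rm = TRUE) < 2L, TRUE))
        if (!ok_unaff) next
        out[[length(out) + 1]] <- data.frame(
          gene = hit_g$gene[j], chrom = ch, pos = pos, lab = lab,
          seg_start = iv$start[k], seg_end = iv$end[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

.comp_het_placement <- function(gd, ped, genes, spacing) {
  aff <- affected_ids(ped)
  unaff <- unaffected_sib_ids(ped)
  fa <- ped$father_id[ped$id == aff[1]]
  mo <- ped$mother_id[ped$id == aff[1]]
  g <- genes[genes$chrom != "chrX", ]
  for (j in sample.int(nrow(g))) {
    ch <- g$chrom[j]
    pos1 <- .pick_pos(g$start[j], g$end[j], spacing)
    pos2 <- min(pos1 + 101, g$end[j])
    if (pos2 <= pos1) next
    # paternal-origin label shared by all affecteds at pos1
    pat_labs <- vapply(aff, function(a)
      .hap_at(gd$haplotypes[[a]]$pat[[ch]], pos1), 0L)
    mat_labs <- vapply(aff, function(a)
      .hap_at(gd$haplotypes[[a]]$mat[[ch]], pos2), 0L)
    if (length(unique(pat_labs)) != 1L || length(unique(mat_labs)) != 1L)
      next
    lab1 <- pat_labs[1]; lab2 <- mat_labs[1]
    if (lab1 == lab2) next
    # each affected child must be het at both sites (other copy lacks label)
    het_ok <- all(vapply(aff, function(a)
      sum(.labels_at(gd, a, ch, pos1) == lab1) == 1L &&
        sum(.labels_at(gd, a, ch, pos2) == lab2) == 1L, TRUE))
    if (!het_ok) next
    # parents het for their own allele, non-carriers of the other
    par_ok <-
      sum(.labels_at(gd, fa, ch, pos1) == lab1) == 1L &&
      sum(.labels_at(gd, fa, ch, pos2) == lab2) == 0L &&
      sum(.labels_at(gd, mo, ch, pos2) == lab2) == 1L &&
      sum(.labels_at(gd, mo, ch, pos1) == lab1) == 0L
    if (!par_ok) next
    # unaffected sibs must not carry both alleles
    unaff_ok <- !length(unaff) || all(vapply(unaff, function(u)
      !(sum(.labels_at(gd, u, ch, pos1) == lab1) >= 1L &&
          sum(.labels_at(gd, u, ch, pos2) == lab2) >= 1L), TRUE))
    if (!unaff_ok) next
    return(list(gene = g$gene[j], chrom = ch, pos1 = pos1, pos2 = pos2,
                lab1 = lab1, lab2 = lab2))
  }
  NULL
}

.xlinked_placement <- function(gd, ped, genes, spacing) {
  sex <- stats::setNames(ped$sex, ped$id)
  aff <- affected_ids(ped)
  aff_m <- aff[sex[aff] == "male"]
  if (!length(aff_m)) stop("x_linked model needs >=1 affected male child")
  unaff <- unaffected_sib_ids(ped)
  mo <- ped$mother_id[ped$id == aff_m[1]]
  gx <- genes[genes$chrom == "chrX", , drop = FALSE]
  if (!nrow(gx)) stop("x_linked model needs genes on chrX (include_x)")
  for (j in sample.int(nrow(gx))) {
    pos <- .pick_pos(gx$start[j], gx$end[j], spacing)
    labs <- vapply(aff_m, function(a)
      .hap_at(gd$haplotypes[[a]]$mat[["chrX"]], pos), 0L)
    if (length(unique(labs)) != 1L) next
    lab <- labs[1]
    if (sum(.labels_at(gd, mo, "chrX", pos) == lab, na.rm = TRUE) != 1L) next
    unaff_m <- unaff[sex[unaff] == "male"]
    if (length(unaff_m) && any(vapply(unaff_m, function(u)
      .hap_at(gd$haplotypes[[u]]$mat[["chrX"]], pos) == lab, TRUE))) next
    return(list(gene = gx$gene[j], pos = pos, lab = lab))
  }
  NULL
}

# ---- cohort assembly --------------------------------------------------------

# Genotype matrix (markers x samples) from haplotype label tracks and a
# founder allele matrix (marker x label). Male X entries are hemizygous.
.marker_genotypes <- function(gd, ped, markers, founder_alleles) {
  ids <- ped$id
  sex <- stats::setNames(ped$sex, ped$id)
  geno <- matrix(NA_integer_, nrow(markers), length(ids))
  hemi <- matrix(FALSE, nrow(markers), length(ids))
  for (s in seq_along(ids)) {
    h <- gd$haplotypes[[ids[s]]]
    for (ch in unique(markers$chrom)) {
      rows <- which(markers$chrom == ch)
      pos <- markers$pos[rows]
      if (ch == "chrX" && sex[[ids[s]]] == "male") {
        lab <- .hap_at(h$mat[[ch]], pos)
        a <- founder_alleles[cbind(rows, lab)]
        geno[rows, s] <- 2L * a
        hemi[rows, s] <- TRUE
      } else {
        lp <- .hap_at(h$pat[[ch]], pos)
        lm <- .hap_at(h$mat[[ch]], pos)
        geno[rows, s] <- founder_alleles[cbind(rows, lp)] +
          founder_alleles[cbind(rows, lm)]
      }
    }
  }
  list(geno = geno, hemi = hemi)
}

#' Simulate a full synthetic cohort
#'
#' End-to-end generator: per family, drops founder haplotypes through the
#' pedigree template, genotypes a shared marker panel, plants the scenario's
#' causal configuration (redrawing the gene drop, up to `max_tries`, for
#' families where no eligible placement exists), scatters benign de novo
#' variants from the synthetic mutability table, simulates read evidence and
#' emits maximum-likelihood genotype calls.
#'
#' @param scenario a [simulation_scenario()].
#' @param max_tries gene-drop redraws allowed per family before failing.
#' @return list with `cohort` (a [cohort_data()] of called genotypes and
#'   reads), `true_geno` (matrix of generating genotypes), `peds` (list of
#'   pedigrees), `truth_segments`, `planted` (truth table of planted
#'   variants, causal and benign de novo), `markers`, `genes`, `mutability`
#'   and the `scenario`.
#' @export
simulate_cohort <- function(scenario, max_tries = 40) {
  set.seed(scenario$seed)
  with_x <- scenario$causal_model == "x_linked"
  if (with_x && is.na(scenario$genome$x_mb))
    stop("x_linked scenario requires a genome with an X chromosome")
  markers <- simulate_founder_haplotypes(scenario, include_x = with_x)
  genes <- tile_genes(scenario$genome, scenario$n_genes, include_x = with_x)
  mut <- if (scenario$dnv_rate > 0)
    build_mutability_table(genes[genes$chrom != "chrX", ],
                           total_rate = scenario$dnv_rate / 2)

  fam_ids <- sprintf("fam%03d", seq_len(scenario$n_families))
  custom <- is.list(scenario$template)
  per_fam <- vector("list", scenario$n_families)
  for (f in seq_along(fam_ids)) {
    ped <- if (custom) scenario$template[[f]]
           else .ped_template(scenario$template, scenario$n_affected,
                              scenario$n_unaffected, fam_ids[f])
    ped$id <- paste0(fam_ids[f], "_", ped$id)
    ped$father_id <- ifelse(is.na(ped$father_id), NA,
                            paste0(fam_ids[f], "_", ped$father_id))
    ped$mother_id <- ifelse(is.na(ped$mother_id), NA,
                            paste0(fam_ids[f], "_", ped$mother_id))
    ped$family_id <- fam_ids[f]
    ped <- pedigree(as.data.frame(ped))
    plant <- NULL
    for (try in seq_len(max_tries)) {
      gd <- gene_drop(ped, scenario$genome, include_x = with_x)
      plant <- tryCatch(plant_variants(gd, ped, genes, scenario),
                        error = function(e) {
                          if (grepl("no autozygous segment", conditionMessage(e)))
                            NULL else stop(e)
                        })
      if (!is.null(plant)) break
    }
    if (is.null(plant))
      stop("family ", fam_ids[f], ": no eligible causal placement after ",
           max_tries, " gene-drop redraws")
    per_fam[[f]] <- list(ped = ped, gd = gd, plant = plant)
  }

  # background benign DNVs per proband from the mutability table
  dnv_sites <- list(); dnv_owner <- character(0); dnv_class <- character(0)
  gene_row <- stats::setNames(seq_len(nrow(genes)), genes$gene)
  mut_p <- if (!is.null(mut)) mut$prob / sum(mut$prob)
  spacing <- round(scenario$marker_spacing_kb * 1000)
  for (f in if (is.null(mut)) integer(0) else seq_along(per_fam)) {
    for (a in affected_ids(per_fam[[f]]$ped)) {
      k <- stats::rpois(1, scenario$dnv_rate)
      if (k == 0) next
      pick <- sample.int(nrow(mut), k, replace = TRUE, prob = mut_p)
      for (i in pick) {
        gi <- genes[gene_row[[mut$gene[i]]], ]
        pos <- .pick_pos(round(stats::runif(1, gi$start, gi$end)),
                         gi$end, spacing)
        cls <- mut$class[i]
        row <- data.frame(chrom = gi$chrom, pos = pos, ref = "A", alt = "T",
                          filter_pass = TRUE, mq = 60, gene = gi$gene,
                          csq = switch(cls, LoF = "stop_gain",
                                       `D-Mis` = "missense",
                                       missense = "missense", "synonymous"),
                          metasvm = switch(cls, `D-Mis` = "D", missense = "T",
                                           NA_character_),
                          cadd = switch(cls, LoF = 35, `D-Mis` = 25,
                                        missense = 8, 2),
                          af_bravo = NA_real_, af_gnomad = NA_real_,
                          af_gme = NA_real_, segdup = FALSE,
                          stringsAsFactors = FALSE)
        dnv_sites[[length(dnv_sites) + 1]] <- row
        dnv_owner <- c(dnv_owner, a)
        dnv_class <- c(dnv_class, cls)
      }
    }
  }

  # assemble the site table: markers + causal sites + benign DNVs
  marker_ann <- .marker_annotation(markers, genes)
  causal_sites <- do.call(rbind, lapply(per_fam, function(x) x$plant$sites))
  site_tab <- rbind(marker_ann, causal_sites,
                    if (length(dnv_sites)) do.call(rbind, dnv_sites))
  ord <- order(match(site_tab$chrom, names(.chrom_lengths_bp(scenario$genome,
                                                             include_x = TRUE))),
               site_tab$pos)
  site_tab <- site_tab[ord, ]
  # different families may plant the same gene midpoint: one row per site
  site_tab <- site_tab[!duplicated(paste(site_tab$chrom, site_tab$pos)), ]
  rownames(site_tab) <- NULL
  n_marker <- nrow(marker_ann)
  site_key <- paste(site_tab$chrom, site_tab$pos)
  is_marker <- seq_len(nrow(site_tab)) %in%
    match(paste(marker_ann$chrom, marker_ann$pos), site_key)

  # per-family genotypes at every site
  all_samples <- unlist(lapply(per_fam, function(x) x$ped$id))
  sex_all <- unlist(lapply(per_fam, function(x)
    stats::setNames(x$ped$sex, x$ped$id)))
  geno <- matrix(NA_integer_, nrow(site_tab), length(all_samples))
  hemi <- matrix(FALSE, nrow(site_tab), length(all_samples))
  colnames(geno) <- all_samples
  col0 <- 0L
  marker_rows <- match(paste(markers$chrom, markers$pos), site_key)
  for (f in seq_along(per_fam)) {
    ped <- per_fam[[f]]$ped
    gd <- per_fam[[f]]$gd
    n_lab <- gd$founder_labels
    founder_alleles <- matrix(
      stats::rbinom(nrow(markers) * n_lab, 1, rep(markers$af, n_lab)),
      nrow(markers), n_lab)
    mg <- .marker_genotypes(gd, ped, markers, founder_alleles)
    cols <- col0 + seq_along(ped$id)
    geno[marker_rows, cols] <- mg$geno
    hemi[marker_rows, cols] <- mg$hemi
    # other sites default hom-ref (alt alleles are family-private and rare)
    sub <- geno[!is_marker, cols, drop = FALSE]
    sub[is.na(sub)] <- 0L
    geno[!is_marker, cols] <- sub
    # causal sites of this family: genotype from carrier label membership
    plant <- per_fam[[f]]$plant
    if (!is.null(plant$sites)) for (k in seq_len(nrow(plant$sites))) {
      r <- match(paste(plant$sites$chrom[k], plant$sites$pos[k]), site_key)
      if (!is.na(plant$dnv_child[k])) {
        geno[r, cols] <- 0L
        geno[r, match(plant$dnv_child[k], all_samples)] <- 1L
      } else {
        lab <- plant$carrier[[k]]
        ch <- plant$sites$chrom[k]
        for (s in seq_along(ped$id)) {
          ls <- .labels_at(gd, ped$id[s], ch, plant$sites$pos[k])
          cnt <- sum(ls == lab, na.rm = TRUE)
          if (ch == "chrX" && sex_all[[ped$id[s]]] == "male") {
            geno[r, cols[s]] <- 2L * as.integer(cnt >= 1L)
            hemi[r, cols[s]] <- TRUE
          } else geno[r, cols[s]] <- cnt
        }
      }
    }
    # X sites in non-X-carrying rows already handled via markers
    col0 <- col0 + length(ped$id)
  }
  # benign DNV genotypes
  if (length(dnv_sites)) {
    for (i in seq_along(dnv_sites)) {
      r <- match(paste(dnv_sites[[i]]$chrom, dnv_sites[[i]]$pos), site_key)
      geno[r, match(dnv_owner[i], all_samples)] <- 1L
    }
  }
  # X hemizygosity for males at all X sites
  if (with_x) {
    xrows <- site_tab$chrom == "chrX"
    males <- all_samples[sex_all[all_samples] == "male"]
    hemi[xrows, match(males, all_samples)] <- TRUE
  }

  reads <- simulate_reads(geno, scenario$depth_mean, scenario$error_rate,
                          hemi = hemi)
  cohort <- cohort_data(all_samples, site_tab, reads$called,
                        ad_ref = reads$ad_ref, ad_alt = reads$ad_alt,
                        gq = reads$gq, hemi = hemi, sex = sex_all)

  planted <- do.call(rbind, lapply(per_fam, function(x) x$plant$truth))
  if (length(dnv_sites)) {
    benign <- data.frame(
      family_id = sub("_.*", "", dnv_owner),
      model = "benign_dnv",
      gene = vapply(dnv_sites, function(x) x$gene, ""),
      chrom = vapply(dnv_sites, function(x) x$chrom, ""),
      pos = vapply(dnv_sites, function(x) x$pos, 0),
      pair_id = NA_character_, stringsAsFactors = FALSE)
    benign$sample <- dnv_owner
    benign$class <- dnv_class
    planted$sample <- NA_character_
    planted$class <- "causal"
    planted <- rbind(planted, benign)
  } else if (nrow(planted)) {
    planted$sample <- NA_character_
    planted$class <- "causal"
  }
  truth_segments <- do.call(rbind, lapply(per_fam, function(x)
    x$gd$truth_segments))

  list(cohort = cohort, true_geno = geno, peds = lapply(per_fam, `[[`, "ped"),
       truth_segments = truth_segments, planted = planted,
       markers = markers, genes = genes, mutability = mut,
       scenario = scenario)
}

.marker_annotation <- function(markers, genes) {
  n <- nrow(markers)
  gene <- rep(NA_character_, n)
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    rows <- which(markers$chrom == ch)
    gi <- findInterval(markers$pos[rows], g$start)
    inside <- gi >= 1 & markers$pos[rows] <= g$end[pmax(gi, 1)]
    gene[rows[inside]] <- g$gene[gi[inside]]
  }
  csq <- ifelse(is.na(gene), "other",
                sample(c("synonymous", "other", "missense"), n, replace = TRUE,
                       prob = c(0.3, 0.55, 0.15)))
  data.frame(chrom = markers$chrom, pos = markers$pos, ref = "A", alt = "G",
             filter_pass = TRUE, mq = 60, gene = gene, csq = csq,
             metasvm = ifelse(csq == "missense", "T", NA_character_),
             cadd = ifelse(csq == "missense",
                           round(stats::runif(n, 0, 18), 2), NA_real_),
             af_bravo = markers$af, af_gnomad = markers$af,
             af_gme = markers$af, segdup = FALSE, stringsAsFactors = FALSE)
}
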