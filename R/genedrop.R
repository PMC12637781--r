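#' Gene-drop simulation through a pedigree
#'
#' Drops uniquely labeled founder haplotypes through a pedigree. Each
#' founder receives two labeled haplotypes per chromosome; each meiosis
#' draws a crossover count from Poisson(length_cM / 100) (no interference)
#' with breakpoints uniform along the chromosome, and transmits the
#' recombinant. A child's autozygous segments are the maximal intervals
#' where its two inherited haplotype labels coincide — the ground truth that
#' ROH detection is later scored against.
#'
#' Haplotypes are represented as piecewise-constant label tracks
#' (`list(bp = segment start positions, lab = founder haplotype labels)`),
#' so runtime scales with crossovers, not genome size.
#'
#' When the genome carries an X and `include_x = TRUE`, males receive a
#' single X (the maternal recombinant) and transmit it intact to daughters;
#' X truth segments are only defined for females.
#'
#' @param ped a [pedigree()].
#' @param genome a [genome_config()].
#' @param include_x simulate the X chromosome (requires `genome$x_mb`).
#' @return list with `haplotypes` (per individual: `pat`/`mat`, each a list
#'   of label tracks per chromosome; male X under `mat` only),
#'   `truth_segments` (data frame `sample`, `chrom`, `start`, `end`,
#'   `autozygous`), and `founder_labels`.
#' @export
#' @examples
#' set.seed(1)
#' gd <- gene_drop(ped_first_cousin(), toy_genome())
#' autozygous_fraction(gd, "c1", toy_genome())
gene_drop <- function(ped, genome, include_x = FALSE) {
  stopifnot(inherits(ped, "pedigree"), inherits(genome, "genome_config"))
  if (include_x && is.na(genome$x_mb))
    stop("genome has no X chromosome; use genome_config(..., x_mb = )")
  lens_bp <- .chrom_lengths_bp(genome, include_x = FALSE)
  chroms <- names(lens_bp)
  x_len <- if (include_x) round(genome$x_mb * 1e6) else NA_real_
  cmmb <- genome$cM_per_Mb

  sex <- stats::setNames(ped$sex, ped$id)
  father <- stats::setNames(ped$father_id, ped$id)
  mother <- stats::setNames(ped$mother_id, ped$id)
  haps <- new.env(parent = emptyenv())
  next_lab <- 0L
  new_founder_hap <- function(lab, lens) {
    lapply(lens, function(L) list(bp = 1, lab = lab))
  }
  fresh_label <- function() {
    next_lab <<- next_lab + 1L
    next_lab
  }
  # anonymous founders for single-known-parent individuals get fresh labels
  get_parent_gamete <- function(pid, child_sex, chrom_set, lens) {
    if (is.na(pid)) {
      lab <- fresh_label()
      return(new_founder_hap(lab, lens))
    }
    h <- haps[[pid]]
    lapply(seq_along(lens), function(k) {
      .meiosis_chrom(h$pat[[chrom_set[k]]], h$mat[[chrom_set[k]]],
                     lens[k], cmmb)
    })
  }

  for (id in attr(ped, "topo_order")) {
    fa <- father[[id]]; mo <- mother[[id]]
    is_founder <- is.na(fa) && is.na(mo)
    if (is_founder) {
      pat <- new_founder_hap(fresh_label(), lens_bp)
      mat <- new_founder_hap(fresh_label(), lens_bp)
      names(pat) <- names(mat) <- chroms
      if (include_x) {
        if (sex[[id]] == "male") {
          matx <- new_founder_hap(fresh_label(), c(chrX = x_len))
          mat <- c(mat, matx)
        } else {
          pat <- c(pat, new_founder_hap(fresh_label(), c(chrX = x_len)))
          mat <- c(mat, new_founder_hap(fresh_label(), c(chrX = x_len)))
        }
      }
      haps[[id]] <- list(pat = pat, mat = mat)
      next
    }
    pat <- get_parent_gamete(fa, sex[[id]], chroms, lens_bp)
    mat <- get_parent_gamete(mo, sex[[id]], chroms, lens_bp)
    names(pat) <- names(mat) <- chroms
    if (include_x) {
      # mother's X gamete: recombinant of her two Xs (or fresh if anonymous)
      mx <- if (is.na(mo)) {
        list(bp = 1, lab = fresh_label())
      } else {
        hm <- haps[[mo]]
        .meiosis_chrom(hm$pat[["chrX"]], hm$mat[["chrX"]], x_len, cmmb)
      }
      if (sex[[id]] == "male") {
        mat <- c(mat, list(chrX = mx))
      } else {
        # father passes his single X unrecombined to daughters
        fx <- if (is.na(fa)) list(bp = 1, lab = fresh_label())
              else haps[[fa]]$mat[["chrX"]]
        pat <- c(pat, list(chrX = fx))
        mat <- c(mat, list(chrX = mx))
      }
    }
    haps[[id]] <- list(pat = pat, mat = mat)
  }

  truth <- .autozygous_truth(haps, ped$id, sex, chroms, lens_bp)
  list(haplotypes = mget(ped$id, envir = haps),
       truth_segments = truth,
       founder_labels = next_lab)
}

# One meiosis on one chromosome: Poisson crossovers, uniform positions,
# random starting phase; returns the recombinant label track.
.meiosis_chrom <- function(hapA, hapB, len_bp, cM_per_Mb) {
  n_cross <- stats::rpois(1, (len_bp / 1e6) * cM_per_Mb / 100)
  phase <- sample.int(2L, 1L)
  if (n_cross == 0) return(if (phase == 1L) hapA else hapB)
  cuts <- sort(stats::runif(n_cross, min = 1, max = len_bp))
  bounds <- c(1, floor(cuts) + 1, len_bp + 1)  # interval k: [bounds k, k+1)
  src <- rep(c(phase, 3L - phase), length.out = length(bounds) - 1)
  bp <- numeric(0); lab <- integer(0)
  for (k in seq_len(length(bounds) - 1)) {
    h <- if (src[k] == 1L) hapA else hapB
    a <- bounds[k]; b <- bounds[k + 1] - 1
    if (b < a) next
    i0 <- findInterval(a, h$bp)
    i1 <- findInterval(b, h$bp)
    seg_bp <- pmax(h$bp[i0:i1], a)
    bp <- c(bp, seg_bp)
    lab <- c(lab, h$lab[i0:i1])
  }
  keep <- c(TRUE, lab[-1] != lab[-length(lab)])
  list(bp = bp[keep], lab = lab[keep])
}

# Label of a haplotype track at position(s) pos
.hap_at <- function(hap, pos) hap$lab[findInterval(pos, hap$bp)]

# Maximal intervals where the two label tracks agree
.autozygous_intervals <- function(hp, hm, len_bp) {
  bp <- sort(unique(c(hp$bp, hm$bp)))
  same <- .hap_at(hp, bp) == .hap_at(hm, bp)
  ends <- c(bp[-1] - 1, len_bp)
  if (!any(same)) return(NULL)
  # merge adjacent agreeing intervals
  runs <- rle(same)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  keep <- runs$values
  data.frame(start = bp[idx_start[keep]], end = ends[idx_end[keep]])
}

.autozygous_truth <- function(haps, ids, sex, chroms, lens_bp) {
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    h <- haps[[id]]
    per_chrom <- lapply(seq_along(chroms), function(k) {
      iv <- .autozygous_intervals(h$pat[[chroms[k]]], h$mat[[chroms[k]]],
                                  lens_bp[k])
      if (is.null(iv)) return(NULL)
      cbind(chrom = chroms[k], iv)
    })
    per_chrom <- do.call(rbind, per_chrom)
    if (!is.null(per_chrom) && nrow(per_chrom))
      out[[i]] <- cbind(sample = id, per_chrom)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
  res$autozygous <- rep(TRUE, nrow(res))
  rownames(res) <- NULL
  res
}

#' Autozygous genome fraction of one simulated individual
#'
#' Total autosomal length identical by descent divided by the autosomal
#' genome size; its long-run mean over gene-drop replicates equals the
#' pedigree inbreeding coefficient F.
#'
#' @param gd result of [gene_drop()].
#' @param id individual id.
#' @param genome the [genome_config()] used for the drop.
#' @return fraction in \[0, 1\].
#' @export
autozygous_fraction <- function(gd, id, genome) {
  tr <- gd$truth_segments
  tr <- tr[tr$sample == id & tr$chrom != "chrX", , drop = FALSE]
  if (!nrow(tr)) return(0)
  sum(tr$end - tr$start + 1) / sum(.chrom_lengths_bp(genome))
}
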