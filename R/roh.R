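#' ROH caller parameters
#'
#' Controls the sliding-window run-of-homozygosity caller. Only the 1 Mb
#' emission floor is a fixed analysis convention; the window geometry
#' defaults are chosen to tolerate sporadic genotyping error at ~30x depth
#' and are fully exposed.
#'
#' @param window_markers genotyped markers per sliding window.
#' @param max_het_per_window heterozygous calls tolerated per window.
#' @param min_length_mb minimum emitted segment length (Mb); at least 0.1.
#' @param min_markers minimum genotyped markers per emitted segment.
#' @param merge_gap_kb adjacent homozygous stretches closer than this are
#'   merged before emission.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_markers = 20, max_het_per_window = 1,
                       min_length_mb = 1.0, min_markers = 25,
                       merge_gap_kb = 100) {
  stopifnot(window_markers >= 1, max_het_per_window >= 0,
            min_length_mb >= 0.1, min_markers >= 0, merge_gap_kb >= 0)
  structure(list(window_markers = window_markers,
                 max_het_per_window = max_het_per_window,
                 min_length_mb = min_length_mb, min_markers = min_markers,
                 merge_gap_kb = merge_gap_kb),
            class = "roh_params")
}

#' Detect runs of homozygosity in one sample
#'
#' Slides a window of `window_markers` consecutive genotyped markers along
#' each chromosome; windows containing at most `max_het_per_window`
#' heterozygous calls are flagged homozygous. Maximal unions of overlapping
#' flagged windows are merged across gaps up to `merge_gap_kb`, trimmed to
#' the outermost homozygous marker, and emitted when they span at least
#' `min_length_mb` and contain at least `min_markers` genotyped markers.
#' Missing genotypes are ignored (they neither break nor extend runs).
#'
#' @param calls data frame with `chrom`, `pos` and `geno` (0/1/2 codes,
#'   `NA` missing) for one sample, sorted by (chrom, pos).
#' @param params a [roh_params()].
#' @param sample sample id stamped on the output.
#' @return data frame `sample`, `chrom`, `start`, `end`, `n_markers`,
#'   `length_mb` (1-based inclusive coordinates).
#' @export
detect_roh <- function(calls, params = roh_params(), sample = "sample") {
  stopifnot(all(c("chrom", "pos", "geno") %in% names(calls)))
  out <- lapply(unique(calls$chrom), function(ch) {
    cc <- calls[calls$chrom == ch, ]
    if (is.unsorted(cc$pos, strictly = FALSE))
      stop("calls must be sorted by (chrom, pos)")
    cc <- cc[!is.na(cc$geno), ]
    .detect_roh_chrom(cc$pos, cc$geno == 1L, params, ch)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_markers = integer(0))
  res <- cbind(sample = rep(sample, nrow(res)), res)
  res$length_mb <- (res$end - res$start + 1) / 1e6
  rownames(res) <- NULL
  res
}

.detect_roh_chrom <- function(pos, het, params, chrom) {
  n <- length(pos)
  w <- params$window_markers
  if (n < w) return(NULL)
  hs <- cumsum(c(0, het))
  n_win <- n - w + 1
  flagged <- (hs[w + seq_len(n_win)] - hs[seq_len(n_win)]) <=
    params$max_het_per_window
  if (!any(flagged)) return(NULL)
  # marker j covered by >=1 flagged window starting in [j - w + 1, j]
  delta <- integer(n + 1)
  st <- which(flagged)
  for (i in st) {
    delta[i] <- delta[i] + 1L
    delta[min(i + w, n + 1)] <- delta[min(i + w, n + 1)] - 1L
  }
  covered <- cumsum(delta[seq_len(n)]) > 0
  runs <- rle(covered)
  iend <- cumsum(runs$lengths)
  istart <- iend - runs$lengths + 1
  keep <- which(runs$values)
  if (!length(keep)) return(NULL)
  seg <- data.frame(i0 = istart[keep], i1 = iend[keep])
  # merge across short gaps
  if (nrow(seg) > 1) {
    gap_bp <- pos[seg$i0[-1]] - pos[seg$i1[-nrow(seg)]] - 1
    new_grp <- cumsum(c(TRUE, gap_bp > params$merge_gap_kb * 1000))
    seg <- do.call(rbind, lapply(split(seg, new_grp), function(s)
      data.frame(i0 = s$i0[1], i1 = s$i1[nrow(s)])))
  }
  # trim to outermost homozygous marker; count markers; apply floors
  res <- lapply(seq_len(nrow(seg)), function(k) {
    idx <- seg$i0[k]:seg$i1[k]
    hom <- idx[!het[idx]]
    if (!length(hom)) return(NULL)
    i0 <- min(hom); i1 <- max(hom)
    data.frame(chrom = chrom, start = pos[i0], end = pos[i1],
               n_markers = i1 - i0 + 1L)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(NULL)
  res <- res[(res$end - res$start + 1) / 1e6 >= params$min_length_mb &
               res$n_markers >= params$min_markers, , drop = FALSE]
  if (!nrow(res)) return(NULL)
  res
}

#' Detect ROH for every sample of a cohort
#'
#' @param cohort a [cohort_data()].
#' @param params a [roh_params()].
#' @param autosomes_only drop X-chromosome calls first (default; hemizygous
#'   males confound homozygosity runs).
#' @return combined data frame of [detect_roh()] results.
#' @export
detect_roh_cohort <- function(cohort, params = roh_params(),
                              autosomes_only = TRUE) {
  v <- cohort$variants
  keep <- if (autosomes_only) v$chrom != "chrX" else rep(TRUE, nrow(v))
  out <- lapply(seq_along(cohort$samples), function(s) {
    detect_roh(data.frame(chrom = v$chrom[keep], pos = v$pos[keep],
                          geno = cohort$geno[keep, s]),
               params, sample = cohort$samples[s])
  })
  do.call(rbind, out)
}

#' Total autosomal ROH burden of one sample
#'
#' @param segments [detect_roh()] output for a single sample.
#' @return summed segment length in Mb (X excluded).
#' @export
roh_burden <- function(segments) {
  if (!nrow(segments)) return(0)
  if (length(unique(segments$sample)) > 1)
    stop("segments from more than one sample; split first")
  segments <- segments[segments$chrom != "chrX", , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments within one sample on ", ch)
  }
  sum(segments$end - segments$start + 1) / 1e6
}

.seg_to_iranges <- function(seg) {
  IRanges::IRanges(start = seg$start, end = seg$end)
}

#' ROH segments segregating with affected status
#'
#' Per chromosome, intersects the ROH of all affected children and subtracts
#' every basepair covered by an unaffected sibling's ROH (so no retained
#' interval shares any basepair with an unaffected ROH). Families with a
#' single affected child return that child's ROH minus unaffected-covered
#' basepairs.
#'
#' @param segments [detect_roh_cohort()]-style data frame covering the
#'   family's children.
#' @param ped the family [pedigree()].
#' @return data frame `sample` (the family id), `chrom`, `start`, `end`,
#'   `length_mb`.
#' @export
segregate_roh <- function(segments, ped) {
  aff <- affected_ids(ped)
  if (!length(aff)) stop("no affected individuals in pedigree")
  unaff <- unaffected_sib_ids(ped)
  fam <- ped$family_id[1]
  chroms <- unique(segments$chrom[segments$sample %in% aff])
  out <- lapply(chroms, function(ch) {
    per_aff <- lapply(aff, function(a)
      .seg_to_iranges(segments[segments$sample == a & segments$chrom == ch, ]))
    shared <- Reduce(IRanges::intersect, per_aff)
    if (!length(shared)) return(NULL)
    if (length(unaff)) {
      ua <- .seg_to_iranges(
        segments[segments$sample %in% unaff & segments$chrom == ch, ])
      if (length(ua)) shared <- IRanges::setdiff(shared, IRanges::reduce(ua))
    }
    if (!length(shared)) return(NULL)
    data.frame(sample = fam, chrom = ch, start = IRanges::start(shared),
               end = IRanges::end(shared))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
  res$length_mb <- (res$end - res$start + 1) / 1e6
  res[order(res$chrom, res$start), ]
}

#' Classify a variant position by ROH context
#'
#' `"top3"` when the position falls inside one of the proband's three
#' longest ROH segments genome-wide (ties broken by length descending, then
#' chromosome, then start), `"smaller_roh"` inside any other segment,
#' `"outside_roh"` otherwise.
#'
#' @param chrom,pos variant position (1-based).
#' @param segments one proband's ROH segments.
#' @return one of `"top3"`, `"smaller_roh"`, `"outside_roh"`.
#' @export
rank_variant_roh <- function(chrom, pos, segments) {
  if (!nrow(segments)) return("outside_roh")
  if (length(unique(segments$sample)) > 1)
    stop("segments must belong to one proband")
  o <- order(-(segments$end - segments$start + 1), segments$chrom,
             segments$start)
  segments <- segments[o, ]
  hit <- which(segments$chrom == chrom & segments$start <= pos &
                 segments$end >= pos)
  if (!length(hit)) return("outside_roh")
  if (min(hit) <= 3) "top3" else "smaller_roh"
}

#' Score detected ROH against simulated truth
#'
#' Recall: fraction of truth segments of at least `min_truth_mb` matched by
#' a detected segment of the same sample with at least `min_overlap`
#' reciprocal overlap. Precision: fraction of detected segments (of at
#' least `min_truth_mb`) matched by a truth segment under the same rule.
#'
#' @param detected,truth segment data frames (`sample`, `chrom`, `start`,
#'   `end`).
#' @param min_truth_mb smallest truth segment scored, in Mb.
#' @param min_overlap reciprocal overlap fraction required for a match.
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
roh_accuracy <- function(detected, truth, min_truth_mb = 1.5,
                         min_overlap = 0.5) {
  truth_all <- truth[truth$chrom != "chrX", , drop = FALSE]
  truth <- truth_all[(truth_all$end - truth_all$start + 1) / 1e6 >=
                       min_truth_mb, , drop = FALSE]
  big_det <- detected[(detected$end - detected$start + 1) / 1e6 >=
                        min_truth_mb, , drop = FALSE]
  match_frac <- function(a, b) {
    # for each row of a: does any row of b (same sample, chrom) reciprocally
    # overlap >= min_overlap?
    if (!nrow(a)) return(numeric(0))
    vapply(seq_len(nrow(a)), function(i) {
      bb <- b[b$sample == a$sample[i] & b$chrom == a$chrom[i], , drop = FALSE]
      if (!nrow(bb)) return(0)
      ov <- pmin(bb$end, a$end[i]) - pmax(bb$start, a$start[i]) + 1
      la <- a$end[i] - a$start[i] + 1
      lb <- bb$end - bb$start + 1
      as.numeric(any(ov >= min_overlap * la & ov >= min_overlap * lb))
    }, 0)
  }
  rec <- match_frac(truth, detected)
  prec <- match_frac(big_det, truth_all)
  list(recall = if (length(rec)) mean(rec) else NA_real_,
       precision = if (length(prec)) mean(prec) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(big_det))
}
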