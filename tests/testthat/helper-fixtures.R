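# Shared builders for small in-code fixtures.

# one-row variant annotation with overridable fields
make_variant <- function(...) {
  v <- data.frame(chrom = "chr1", pos = 1000001, ref = "A", alt = "C",
                  filter_pass = TRUE, mq = 60, gene = "G0001",
                  csq = "missense", metasvm = "D", cadd = 28,
                  af_bravo = 0, af_gnomad = 0, af_gme = 0, segdup = FALSE,
                  stringsAsFactors = FALSE)
  dots <- list(...)
  v[names(dots)] <- dots
  v
}

make_call <- function(geno, ref = 15L, alt = 15L, gq = 99L, hemi = FALSE,
                      sex = "male") {
  list(geno = geno, ref = ref, alt = alt, gq = gq, hemi = hemi, sex = sex)
}

# random pedigree: founders plus layered children with random parents
random_pedigree <- function(n_founders = 4, n_children = 6) {
  ids <- paste0("f", seq_len(n_founders))
  sexes <- rep(c("male", "female"), length.out = n_founders)
  df <- data.frame(id = ids, family_id = "fam", father_id = NA,
                   mother_id = NA, sex = sexes, affected = "unknown",
                   stringsAsFactors = FALSE)
  for (k in seq_len(n_children)) {
    males <- df$id[df$sex == "male"]
    females <- df$id[df$sex == "female"]
    df <- rbind(df, data.frame(
      id = paste0("c", k), family_id = "fam",
      father_id = sample(males, 1), mother_id = sample(females, 1),
      sex = sample(c("male", "female"), 1), affected = "unknown",
      stringsAsFactors = FALSE))
  }
  pedigree(df)
}

# genotype track for detect_roh tests: hom run with optional het positions
hom_track <- function(n, start = 1e6, spacing = 2e4, het_at = integer(0),
                      chrom = "chr1") {
  geno <- rep(0L, n)
  geno[het_at] <- 1L
  data.frame(chrom = chrom, pos = start + (seq_len(n) - 1) * spacing,
             geno = geno)
}

# Independent re-statement of the sliding-window ROH rules, written as
# direct enumeration (used as oracle against the vectorized caller).
roh_oracle <- function(calls, params) {
  out <- NULL
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch & !is.na(calls$geno), ]
    pos <- cc$pos; het <- cc$geno == 1L
    n <- length(pos); w <- params$window_markers
    if (n < w) next
    covered <- rep(FALSE, n)
    for (i in seq_len(n - w + 1)) {
      if (sum(het[i:(i + w - 1)]) <= params$max_het_per_window)
        covered[i:(i + w - 1)] <- TRUE
    }
    # runs of covered markers
    segs <- list()
    i <- 1
    while (i <= n) {
      if (!covered[i]) { i <- i + 1; next }
      j <- i
      while (j < n && covered[j + 1]) j <- j + 1
      segs[[length(segs) + 1]] <- c(i, j)
      i <- j + 1
    }
    if (!length(segs)) next
    # merge across gaps
    merged <- list(segs[[1]])
    for (s in segs[-1]) {
      last <- merged[[length(merged)]]
      if (pos[s[1]] - pos[last[2]] - 1 <= params$merge_gap_kb * 1000)
        merged[[length(merged)]] <- c(last[1], s[2])
      else merged[[length(merged) + 1]] <- s
    }
    for (s in merged) {
      idx <- s[1]:s[2]
      hom <- idx[!het[idx]]
      if (!length(hom)) next
      i0 <- min(hom); i1 <- max(hom)
      len <- pos[i1] - pos[i0] + 1
      if (len / 1e6 >= params$min_length_mb &&
          (i1 - i0 + 1) >= params$min_markers)
        out <- rbind(out, data.frame(chrom = ch, start = pos[i0],
                                     end = pos[i1]))
    }
  }
  out
}

# per-basepair oracle for affected/unaffected ROH segregation on a toy
# chromosome of length len
segregation_oracle_bp <- function(segments, aff, unaff, len) {
  cover <- function(ids, combine) {
    m <- matrix(FALSE, length(ids), len)
    for (k in seq_along(ids)) {
      s <- segments[segments$sample == ids[k], ]
      for (i in seq_len(nrow(s))) m[k, s$start[i]:s$end[i]] <- TRUE
    }
    if (!nrow(m)) return(rep(FALSE, len))
    apply(m, 2, combine)
  }
  shared <- cover(aff, all)
  if (length(unaff)) shared <- shared & !cover(unaff, any)
  shared
}

bp_cover <- function(segments, len) {
  v <- rep(FALSE, len)
  for (i in seq_len(nrow(segments))) v[segments$start[i]:segments$end[i]] <- TRUE
  v
}
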