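test_that("an unbroken homozygous run is called as one segment", {
  # 81 markers every 20 kb spanning chr1:1,000,000-2,600,000
  calls <- hom_track(81, start = 1e6)
  seg <- detect_roh(calls, roh_params(), sample = "s1")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 1e6)
  expect_equal(seg$end, 2.6e6)
  expect_equal(seg$length_mb, (2.6e6 - 1e6 + 1) / 1e6)
  expect_equal(seg$n_markers, 81L)
})

test_that("runs below the 1 Mb floor are not emitted", {
  calls <- hom_track(41, start = 1e6)  # spans 0.8 Mb
  expect_equal(nrow(detect_roh(calls)), 0)
})

test_that("a single isolated het does not break a run (window tolerance)", {
  calls <- hom_track(60, het_at = 30)
  seg <- detect_roh(calls)
  oracle <- roh_oracle(calls, roh_params())
  expect_equal(nrow(seg), 1)
  expect_equal(seg[, c("chrom", "start", "end")], oracle,
               ignore_attr = TRUE)
})

test_that("caller agrees with direct window enumeration on noisy tracks", {
  set.seed(77)
  params <- roh_params(min_length_mb = 0.5, min_markers = 10)
  for (rep in 1:10) {
    n <- 150
    geno <- rbinom(n, 1L, 0.25)
    run <- sample(20:60, 1)
    at <- sample(seq_len(n - run), 1)
    geno[at:(at + run)] <- 0L
    calls <- data.frame(chrom = "chr1", pos = 2e4 * seq_len(n), geno = geno)
    got <- detect_roh(calls, params)
    want <- roh_oracle(calls, params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("chrom", "start", "end")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("flanking heterozygous markers do not change emitted segments", {
  calls <- hom_track(81)
  base <- detect_roh(calls)
  pre <- data.frame(chrom = "chr1", pos = c(1e5, 2e5), geno = 1L)
  post <- data.frame(chrom = "chr1",
                     pos = max(calls$pos) + c(5e6, 5.02e6), geno = 1L)
  padded <- rbind(pre, calls, post)
  expect_equal(detect_roh(padded)[, c("start", "end")],
               base[, c("start", "end")])
})

test_that("missing genotypes are ignored, not run-breaking", {
  calls <- hom_track(60)
  calls$geno[c(20, 40)] <- NA_integer_
  seg <- detect_roh(calls)
  expect_equal(nrow(seg), 1)
})

test_that("unsorted input errors", {
  calls <- hom_track(30)[c(2, 1, 3:30), ]
  expect_error(detect_roh(calls), "sorted")
})

test_that("burden sums autosomal segment lengths", {
  seg <- data.frame(sample = "s", chrom = c("chr1", "chr2"),
                    start = c(1, 1), end = c(1.5e6, 2.5e6))
  expect_equal(roh_burden(seg), 4.0, tolerance = 1e-5)
  expect_equal(roh_burden(seg[0, ]), 0)
  bad <- data.frame(sample = "s", chrom = "chr1",
                    start = c(1, 1e6), end = c(2e6, 3e6))
  expect_error(roh_burden(bad), "overlapping")
  expect_error(roh_burden(data.frame(sample = c("a", "b"), chrom = "chr1",
                                     start = 1, end = 2)), "one sample")
})

test_that("segregation intersects affected ROH and excludes unaffected", {
  ped <- ped_first_cousin(n_affected = 2, n_unaffected = 1)
  seg <- rbind(
    data.frame(sample = "c1", chrom = "chr1", start = 10e6, end = 20e6),
    data.frame(sample = "c2", chrom = "chr1", start = 12e6, end = 22e6),
    data.frame(sample = "c1", chrom = "chr2", start = 5e6, end = 9e6),
    data.frame(sample = "c2", chrom = "chr2", start = 5e6, end = 9e6),
    data.frame(sample = "c3", chrom = "chr2", start = 5e6, end = 9e6))
  out <- segregate_roh(seg, ped)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 12e6)
  expect_equal(out$end, 20e6)
  # affected-only segment untouched
  solo <- segregate_roh(seg[seg$sample != "c3", ], ped)
  expect_true(any(solo$chrom == "chr2" & solo$start == 5e6 &
                    solo$end == 9e6))
  expect_error(segregate_roh(seg, ped_trio(n_affected = 0, n_unaffected = 1)),
               "no affected")
})

test_that("segregation matches a per-basepair oracle on random families", {
  set.seed(31)
  ped <- ped_first_cousin(n_affected = 2, n_unaffected = 2)
  len <- 1000
  rand_segs <- function(id, k) {
    start <- sort(sample.int(len - 50, k))
    data.frame(sample = id, chrom = "chrT", start = start,
               end = pmin(start + sample.int(80, k), len))
  }
  for (rep in 1:20) {
    seg <- do.call(rbind, lapply(c("c1", "c2", "c3", "c4"), function(id)
      rand_segs(id, sample.int(4, 1))))
    out <- segregate_roh(seg, ped)
    want <- segregation_oracle_bp(seg, c("c1", "c2"), c("c3", "c4"), len)
    got <- if (nrow(out)) bp_cover(out, len) else rep(FALSE, len)
    expect_identical(got, want)
    # invariants: subset of every affected; disjoint from unaffected cover
    expect_true(all(!got | bp_cover(seg[seg$sample == "c1", ], len)))
    expect_true(all(!got | bp_cover(seg[seg$sample == "c2", ], len)))
    un <- bp_cover(seg[seg$sample %in% c("c3", "c4"), ], len)
    expect_false(any(got & un))
  }
})

test_that("variants rank against the three largest ROH deterministically", {
  seg <- data.frame(sample = "s", chrom = paste0("chr", 1:4),
                    start = 1e6, end = 1e6 + c(12, 9, 5, 3) * 1e6)
  expect_equal(rank_variant_roh("chr3", 2e6, seg), "top3")
  expect_equal(rank_variant_roh("chr4", 2e6, seg), "smaller_roh")
  expect_equal(rank_variant_roh("chr1", 900000, seg), "outside_roh")
  expect_equal(rank_variant_roh("chr1", 1, seg[0, ]), "outside_roh")
  # tie on length: earlier (chrom, start) wins the top-3 slot
  tie <- data.frame(sample = "s", chrom = c("chr1", "chr2", "chr3", "chr4"),
                    start = 1e6, end = 5e6)
  expect_equal(rank_variant_roh("chr4", 2e6, tie), "smaller_roh")
})
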