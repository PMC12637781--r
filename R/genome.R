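#' Genome configuration
#'
#' Chromosome lengths (in Mb) plus the recombination map density used by the
#' gene-drop simulator and by pedigree-expected autozygosity. The expected
#' autozygous burden of an individual with inbreeding coefficient F is
#' `F * genome_mb`, where `genome_mb` is the total autosomal size (default
#' 3,200 Mb, the conventional human figure).
#'
#' @param autosome_mb named numeric vector of autosomal lengths in Mb
#'   (names are chromosome labels, e.g. `"chr1"`).
#' @param x_mb length of the X chromosome in Mb, or `NA` to omit the X.
#' @param cM_per_Mb recombination map density; the default uniform
#'   1 cM/Mb gives a ~35-Morgan female+male-averaged autosomal map when the
#'   autosomes sum to 3,200 Mb.
#' @return an object of class `genome_config` with elements `autosome_mb`,
#'   `x_mb`, `genome_mb` (sum of autosomes) and `cM_per_Mb`.
#' @export
#' @examples
#' g <- toy_genome()
#' g$genome_mb
genome_config <- function(autosome_mb, x_mb = NA_real_, cM_per_Mb = 1) {
  stopifnot(is.numeric(autosome_mb), length(autosome_mb) >= 1,
            all(autosome_mb > 0), cM_per_Mb > 0)
  if (is.null(names(autosome_mb)) || anyDuplicated(names(autosome_mb)))
    stop("autosome_mb must have unique chromosome names")
  if (!is.na(x_mb) && x_mb <= 0) stop("x_mb must be positive")
  structure(
    list(autosome_mb = autosome_mb,
         x_mb = x_mb,
         genome_mb = sum(autosome_mb),
         cM_per_Mb = cM_per_Mb),
    class = "genome_config"
  )
}

#' Toy genome preset: 5 autosomes of 50 Mb
#'
#' Small genome for fast simulation and exhaustive checking. Autosomal total
#' 250 Mb. Optionally carries a 50 Mb X.
#'
#' @param with_x include an X chromosome.
#' @return a [genome_config()].
#' @export
toy_genome <- function(with_x = FALSE) {
  lens <- rep(50, 5)
  names(lens) <- paste0("chr", 1:5)
  genome_config(lens, x_mb = if (with_x) 50 else NA_real_)
}

#' Human-scale genome preset
#'
#' 22 autosomes with lengths proportional to GRCh38 assembly sizes, rescaled
#' so that the autosomal total equals `genome_mb` (default 3,200 Mb, the
#' conventional size used for pedigree-expected ROH burden). The X is scaled
#' by the same factor.
#'
#' @param genome_mb target total autosomal size in Mb.
#' @param with_x include an X chromosome.
#' @return a [genome_config()].
#' @export
human_genome <- function(genome_mb = 3200, with_x = FALSE) {
  # GRCh38 chromosome lengths, Mb (rounded)
  raw <- c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
           114, 107, 102, 90, 83, 80, 59, 64, 47, 51)
  names(raw) <- paste0("chr", 1:22)
  scl <- genome_mb / sum(raw)
  genome_config(raw * scl, x_mb = if (with_x) 156 * scl else NA_real_)
}

#' Expected autozygous genome per inbreeding coefficient
#'
#' The expected autosomal length that is autozygous (identical by descent
#' from a common ancestor) in an individual with inbreeding coefficient F is
#' F times the autosomal genome size.
#'
#' @param F inbreeding coefficient, in \[0, 1\].
#' @param genome a [genome_config()].
#' @return expected autozygous burden in Mb.
#' @export
#' @examples
#' expected_autozygous_mb(1 / 16, human_genome())  # 200 Mb
expected_autozygous_mb <- function(F, genome) {
  stopifnot(inherits(genome, "genome_config"))
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1))
    stop("F must lie in [0, 1]")
  F * genome$genome_mb
}

# Internal: chromosome lengths in bp (autosomes, plus X when present)
.chrom_lengths_bp <- function(genome, include_x = FALSE) {
  lens <- round(genome$autosome_mb * 1e6)
  if (include_x && !is.na(genome$x_mb)) {
    lens <- c(lens, chrX = round(genome$x_mb * 1e6))
  }
  lens
}
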