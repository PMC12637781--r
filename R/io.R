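#' Cohort genotype container
#'
#' The in-memory representation of a multi-sample cohort used throughout the
#' package: a site-by-sample genotype matrix plus per-site annotations and
#' per-call read evidence. Genotypes are coded `0` (hom ref), `1` (het),
#' `2` (hom alt) and `NA` (missing); hemizygous calls (male X) use codes
#' `0`/`2` with the corresponding entry of `hemi` set to `TRUE`.
#'
#' @param samples character vector of sample ids (column order of matrices).
#' @param variants data frame with one row per site: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `filter_pass` (logical), `mq` (mapping quality), `gene`,
#'   `csq` (consequence), `metasvm` (`"D"`, `"T"` or `NA`), `cadd`,
#'   `af_bravo`, `af_gnomad`, `af_gme` (all `NA` when missing), `segdup`
#'   (logical).
#' @param geno integer matrix sites x samples.
#' @param ad_ref,ad_alt,gq integer matrices of the same shape (read counts
#'   and genotype quality); may be `NULL` when no read evidence exists.
#' @param hemi logical matrix marking hemizygous calls; defaults to all
#'   `FALSE`.
#' @param sex optional named character vector (`"male"`/`"female"`) per
#'   sample, used when writing X genotypes.
#' @return a `cohort_data` list object.
#' @export
cohort_data <- function(samples, variants, geno, ad_ref = NULL,
                        ad_alt = NULL, gq = NULL, hemi = NULL, sex = NULL) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(variants), nrow(variants) == nrow(geno),
            ncol(geno) == length(samples))
  need <- c("chrom", "pos", "ref", "alt", "filter_pass", "mq", "gene", "csq",
            "metasvm", "cadd", "af_bravo", "af_gnomad", "af_gme", "segdup")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(variants$pos < 1)) stop("positions must be 1-based (pos >= 1)")
  for (af in c("af_bravo", "af_gnomad", "af_gme")) {
    v <- variants[[af]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(af, " outside [0, 1]")
  }
  if (is.null(hemi)) hemi <- matrix(FALSE, nrow(geno), ncol(geno))
  colnames(geno) <- samples
  structure(list(samples = samples, variants = variants, geno = geno,
                 ad_ref = ad_ref, ad_alt = ad_alt, gq = gq, hemi = hemi,
                 sex = sex),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", length(x$samples), "samples,",
      nrow(x$variants), "sites on",
      length(unique(x$variants$chrom)), "chromosomes\n")
  invisible(x)
}

.CSQ_LEVELS <- c("stop_gain", "stop_loss", "frameshift_indel",
                 "canonical_splice", "start_loss", "missense",
                 "nonframeshift_indel", "synonymous", "other")

# ---- VCF dialect ------------------------------------------------------------

.fmt_info <- function(v) {
  parts <- character(0)
  add <- function(key, val) {
    if (length(val) == 1 && !is.na(val)) c(parts, paste0(key, "=", val))
    else parts
  }
  parts <- add("GENE", v$gene)
  parts <- add("CSQ", v$csq)
  parts <- add("METASVM", v$metasvm)
  if (!is.na(v$cadd)) parts <- c(parts, paste0("CADD=", format(v$cadd, digits = 10)))
  for (k in c("af_bravo", "af_gnomad", "af_gme")) {
    val <- v[[k]]
    if (!is.na(val))
      parts <- c(parts, paste0(toupper(k), "=", format(val, digits = 10)))
  }
  if (!is.na(v$mq)) parts <- c(parts, paste0("MQ=", format(v$mq, digits = 10)))
  if (isTRUE(v$segdup)) parts <- c(parts, "SEGDUP")
  if (!length(parts)) "." else paste(parts, collapse = ";")
}

#' Write a cohort to the package's VCF dialect
#'
#' VCF 4.2 subset: columns CHROM POS ID REF ALT QUAL FILTER INFO FORMAT plus
#' one column per sample, FORMAT fixed to `GT:AD:GQ`. Annotations are INFO
#' keys `GENE`, `CSQ`, `METASVM`, `CADD`, `AF_BRAVO`, `AF_GNOMAD`, `AF_GME`,
#' `MQ` and the flag `SEGDUP`; a missing annotation omits its key. Hemizygous
#' genotypes are written with single-allele GT (`0` / `1`).
#'
#' @param cohort a [cohort_data()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_data"))
  v <- cohort$variants
  n <- nrow(v)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=autozygr"),
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=METASVM,Number=1,Type=String,Description="MetaSVM verdict D/T">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">',
    '##INFO=<ID=AF_BRAVO,Number=1,Type=Float,Description="Bravo allele frequency">',
    '##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description="gnomAD-genome allele frequency">',
    '##INFO=<ID=AF_GME,Number=1,Type=Float,Description="GME Variome allele frequency">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=SEGDUP,Number=0,Type=Flag,Description="In segmental duplication">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref,alt read depths">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  gt_chr <- matrix("./.", n, length(cohort$samples))
  codes <- cohort$geno
  hemi <- cohort$hemi
  gt_chr[!is.na(codes) & codes == 0 & !hemi] <- "0/0"
  gt_chr[!is.na(codes) & codes == 1 & !hemi] <- "0/1"
  gt_chr[!is.na(codes) & codes == 2 & !hemi] <- "1/1"
  gt_chr[!is.na(codes) & codes == 0 & hemi] <- "0"
  gt_chr[!is.na(codes) & codes == 2 & hemi] <- "1"
  gt_chr[is.na(codes) & hemi] <- "."
  has_reads <- !is.null(cohort$ad_ref)
  if (has_reads) {
    ad <- matrix(paste0(cohort$ad_ref, ",", cohort$ad_alt),
                 n, length(cohort$samples))
    gqm <- cohort$gq
    gqm[is.na(gqm)] <- 0L
    cell <- matrix(paste0(gt_chr, ":", ad, ":", gqm), n,
                   length(cohort$samples))
  } else {
    cell <- matrix(paste0(gt_chr, ":.,.:."), n, length(cohort$samples))
  }
  info <- vapply(seq_len(n), function(i) .fmt_info(v[i, ]), "")
  body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                ".", v$ref, v$alt, ".",
                ifelse(v$filter_pass, "PASS", "lowqual"), info, "GT:AD:GQ",
                sep = "\t")
  body <- paste(body, apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

.parse_info_field <- function(s) {
  out <- list(gene = NA_character_, csq = NA_character_,
              metasvm = NA_character_, cadd = NA_real_,
              af_bravo = NA_real_, af_gnomad = NA_real_, af_gme = NA_real_,
              mq = NA_real_, segdup = FALSE)
  if (s == ".") return(out)
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq == -1L) {
      if (kv == "SEGDUP") out$segdup <- TRUE
      next
    }
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    switch(key,
           GENE = out$gene <- val,
           CSQ = out$csq <- val,
           METASVM = out$metasvm <- val,
           CADD = out$cadd <- as.numeric(val),
           AF_BRAVO = out$af_bravo <- as.numeric(val),
           AF_GNOMAD = out$af_gnomad <- as.numeric(val),
           AF_GME = out$af_gme <- as.numeric(val),
           MQ = out$mq <- as.numeric(val))
  }
  out
}

#' Read a cohort VCF written in the package dialect
#'
#' Inverse of [write_cohort_vcf()]: `GT:AD:GQ` calls and the documented INFO
#' keys are mapped losslessly into a [cohort_data()]; keys absent from INFO
#' become `NA`, never defaults.
#'
#' @param path VCF file in the dialect documented at [write_cohort_vcf()].
#' @return a [cohort_data()].
#' @export
parse_cohort_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (length(hdr_i) != 1)
    stop("malformed VCF: expected exactly one #CHROM header line")
  cols <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) stop("malformed VCF header: no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  n <- length(body)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 9 + length(samples))
  if (length(bad))
    stop("malformed VCF record at line ", hdr_i + bad[1], ": expected ",
         9 + length(samples), " fields, got ", nf[bad[1]])
  m <- matrix(unlist(fields), ncol = 9 + length(samples), byrow = TRUE)
  info <- lapply(m[, 8], .parse_info_field)
  pull_c <- function(k) vapply(info, function(x) x[[k]], "")
  pull_n <- function(k) vapply(info, function(x) x[[k]], 0)
  variants <- data.frame(
    chrom = m[, 1], pos = as.integer(m[, 2]), ref = m[, 4], alt = m[, 5],
    filter_pass = m[, 7] == "PASS", mq = pull_n("mq"),
    gene = pull_c("gene"), csq = pull_c("csq"), metasvm = pull_c("metasvm"),
    cadd = pull_n("cadd"), af_bravo = pull_n("af_bravo"),
    af_gnomad = pull_n("af_gnomad"), af_gme = pull_n("af_gme"),
    segdup = vapply(info, function(x) x$segdup, TRUE),
    stringsAsFactors = FALSE)
  if (any(variants$alt == variants$ref))
    stop("malformed record: ALT equals REF at line ",
         hdr_i + which(variants$alt == variants$ref)[1])
  calls <- m[, -(1:9), drop = FALSE]
  parts <- strsplit(calls, ":", fixed = TRUE)
  np <- lengths(parts)
  if (any(np != 3))
    stop("malformed call: FORMAT must be GT:AD:GQ")
  gt <- vapply(parts, `[[`, "", 1)
  adf <- vapply(parts, `[[`, "", 2)
  gqf <- vapply(parts, `[[`, "", 3)
  code <- rep(NA_integer_, length(gt))
  hemi <- gt %in% c("0", "1", ".")
  code[gt %in% c("0/0", "0|0", "0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1", "1")] <- 2L
  known_gt <- c("0/0", "0|0", "0", "0/1", "1/0", "0|1", "1|0",
                "1/1", "1|1", "1", "./.", ".")
  if (any(!gt %in% known_gt)) stop("unsupported GT value: ",
                                   gt[!gt %in% known_gt][1])
  ad2 <- strsplit(adf, ",", fixed = TRUE)
  if (any(lengths(ad2) != 2)) stop("AD must carry ref,alt for one ALT allele")
  ref_r <- suppressWarnings(as.integer(vapply(ad2, `[[`, "", 1)))
  alt_r <- suppressWarnings(as.integer(vapply(ad2, `[[`, "", 2)))
  gq <- suppressWarnings(as.integer(gqf))
  dims <- c(n, length(samples))
  has_reads <- !all(is.na(ref_r))
  cohort_data(
    samples = samples, variants = variants,
    geno = matrix(code, dims[1], dims[2]),
    ad_ref = if (has_reads) matrix(ref_r, dims[1], dims[2]),
    ad_alt = if (has_reads) matrix(alt_r, dims[1], dims[2]),
    gq = if (has_reads) matrix(gq, dims[1], dims[2]),
    hemi = matrix(hemi, dims[1], dims[2]))
}

# ---- PED --------------------------------------------------------------------

#' Read pedigrees from a 6-column PED file
#'
#' Whitespace-delimited columns: family, individual, father, mother, sex
#' (1 = male, 2 = female, 0 = unknown), phenotype (2 = affected,
#' 1 = unaffected, 0 = unknown). `"0"` parents mark founders.
#'
#' @param path PED file.
#' @return named list of [pedigree()] objects, one per family.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 6) stop("PED file must have exactly 6 columns")
  names(tab) <- c("family_id", "id", "father_id", "mother_id", "sexcode",
                  "phenocode")
  df <- data.frame(
    id = tab$id, family_id = tab$family_id,
    father_id = tab$father_id, mother_id = tab$mother_id,
    sex = c(`1` = "male", `2` = "female", `0` = "unknown")[tab$sexcode],
    affected = c(`2` = "affected", `1` = "unaffected",
                 `0` = "unknown")[tab$phenocode],
    stringsAsFactors = FALSE)
  if (anyNA(df$sex)) stop("PED sex code must be 0/1/2")
  if (anyNA(df$affected)) stop("PED phenotype code must be 0/1/2")
  out <- lapply(split(df, df$family_id), pedigree)
  out[unique(df$family_id)]
}

#' Write pedigrees to a 6-column PED file
#'
#' @param peds a [pedigree()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- do.call(rbind, lapply(peds, function(p) {
    data.frame(
      fam = p$family_id, id = p$id,
      fa = ifelse(is.na(p$father_id), "0", p$father_id),
      mo = ifelse(is.na(p$mother_id), "0", p$mother_id),
      sex = c(male = "1", female = "2", unknown = "0")[p$sex],
      pheno = c(affected = "2", unaffected = "1", unknown = "0")[p$affected],
      stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

# ---- BED --------------------------------------------------------------------

#' Write ROH / IBD segments as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so a
#' segment `chr1:1,000,001-2,600,000` becomes the line
#' `chr1 1000000 2600000`. Output is sorted by (chrom, start); the name
#' column carries the sample id.
#'
#' @param segments data frame with `sample`, `chrom`, `start`, `end`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  header <- "#chrom\tstart\tend\tname"
  if (!nrow(segments)) {
    writeLines(header, path)
    return(invisible(path))
  }
  stopifnot(all(segments$end >= segments$start), all(segments$start >= 1))
  o <- order(segments$chrom, segments$start)
  s <- segments[o, ]
  writeLines(c(header,
               paste(s$chrom, format(s$start - 1, scientific = FALSE, trim = TRUE),
                     format(s$end, scientific = FALSE, trim = TRUE),
                     s$sample, sep = "\t")),
             path)
  invisible(path)
}

#' Read a BED3+ file into 1-based inclusive segments
#'
#' @param path BED file (0-based half-open; `#` comment lines ignored).
#' @return data frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `sample` when a name column is present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sample = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[[`, "", 1),
    start = as.integer(vapply(f, `[[`, "", 2)) + 1L,
    end = as.integer(vapply(f, `[[`, "", 3)),
    sample = vapply(f, function(x) if (length(x) >= 4) x[[4]] else NA_character_, ""),
    stringsAsFactors = FALSE)
}
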