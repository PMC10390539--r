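# VCF 4.2 reading/writing. Writers emit plain text; readers go through vcfR.
# Orientation convention throughout the package: samples (or haplotypes) in
# rows, variants in columns.

vcf_header <- function(samples, format_lines, info_lines = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=panelbench",
    info_lines,
    format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_fixed_cols <- function(variants, info = ".") {
  id <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  cbind(variants$chrom, variants$pos, id, variants$ref, variants$alt,
        ".", "PASS", info)
}

#' Write a phased haplotype VCF
#'
#' Adjacent haplotype rows `2i - 1, 2i` form diploid individual `i`; GT is
#' written phased (`a|b`).
#'
#' @param path Output file.
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`).
#' @param haps Haplotype matrix (2N x M, values 0/1).
#' @param samples N sample names.
#' @return `path`, invisibly.
#' @export
write_vcf_haps <- function(path, variants, haps, samples) {
  n <- length(samples)
  stopifnot(nrow(haps) == 2 * n, ncol(haps) == nrow(variants))
  a1 <- haps[seq(1, 2 * n, by = 2), , drop = FALSE]
  a2 <- haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow = n)  # samples x variants
  body <- cbind(vcf_fixed_cols(variants), "GT", t(gt))
  writeLines(c(vcf_header(samples,
                          '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Write an unphased genotype VCF
#'
#' @param path Output file.
#' @param variants Variant table.
#' @param G Genotype matrix (N x M, values 0/1/2, `NA` for missing).
#' @param samples Sample names.
#' @param filter Optional per-variant FILTER strings (default `PASS`).
#' @return `path`, invisibly.
#' @export
write_vcf_geno <- function(path, variants, G, samples, filter = NULL) {
  stopifnot(nrow(G) == length(samples), ncol(G) == nrow(variants))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(G), ncol = ncol(G))
  ok <- !is.na(G)
  gt[ok] <- code[as.character(G[ok])]
  fx <- vcf_fixed_cols(variants)
  if (!is.null(filter)) fx[, 7] <- filter
  body <- cbind(fx, "GT", t(gt))
  writeLines(c(vcf_header(samples,
                          '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Write an imputed-dataset VCF
#'
#' Mirrors common imputation-server output: FORMAT `GT:DS:GP`, per-variant
#' INFO `R2=` (estimated imputation confidence) and a `TYPED` flag on array
#' sites.
#'
#' @param path Output file.
#' @param imp An `imputed_dataset` (see [impute_cohort()]).
#' @return `path`, invisibly.
#' @export
write_imputed_vcf <- function(path, imp) {
  stopifnot(inherits(imp, "imputed_dataset"))
  n <- nrow(imp$dosages); m <- ncol(imp$dosages)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(code[as.character(imp$hard_calls)], nrow = n)
  ds <- matrix(sprintf("%.4f", imp$dosages), nrow = n)
  gp <- matrix(sprintf("%.4f,%.4f,%.4f",
                       imp$genotype_probs[, , 1],
                       imp$genotype_probs[, , 2],
                       imp$genotype_probs[, , 3]), nrow = n)
  cell <- matrix(paste(gt, ds, gp, sep = ":"), nrow = n)
  info <- sprintf("R2=%.6f%s", imp$est_r2, ifelse(imp$typed_flag, ";TYPED", ""))
  body <- cbind(vcf_fixed_cols(imp$variants, info), "GT:DS:GP", t(cell))
  hdr <- vcf_header(
    rownames(imp$dosages),
    c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">',
      '##FORMAT=<ID=GP,Number=3,Type=Float,Description="Genotype posterior probabilities">'),
    c('##INFO=<ID=R2,Number=1,Type=Float,Description="Estimated imputation accuracy">',
      '##INFO=<ID=TYPED,Number=0,Type=Flag,Description="Genotyped on the array">'))
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

vcf_variant_table <- function(vcf) {
  fx <- vcf@fix  # CHROM POS ID REF ALT QUAL FILTER INFO
  data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
             ref = fx[, "REF"], alt = fx[, "ALT"],
             vclass = ifelse(nchar(fx[, "REF"]) == 1 & nchar(fx[, "ALT"]) == 1,
                             "SNP", "INDEL"),
             filter = fx[, "FILTER"], stringsAsFactors = FALSE)
}

gt_to_dosage <- function(gt) {
  # "0|1", "0/1", "./." -> 0/1/2/NA; counts "1" alleles
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  d[ok] <- (substr(gt[ok], 1, 1) == "1") + (substr(gt[ok], 3, 3) == "1")
  d
}

#' Read a genotype VCF
#'
#' @param path VCF file with a GT FORMAT field.
#' @return List: `variants` (with a `filter` column), `G` (samples x
#'   variants genotype matrix, 0/1/2/NA), `phased` (logical, TRUE if all
#'   non-missing calls are phased), `samples`.
#' @export
read_vcf_geno <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")  # variants x samples
  variants <- vcf_variant_table(vcf)
  G <- t(gt_to_dosage(gt))
  storage.mode(G) <- "integer"
  rownames(G) <- colnames(gt)
  phased <- all(grepl("\\|", gt[!is.na(gt) & !grepl("\\.", gt)]))
  list(variants = variants, G = G, phased = phased, samples = colnames(gt))
}

#' Read a phased VCF as a haplotype matrix
#'
#' @param path VCF with phased GT.
#' @return List: `variants`, `haps` (2N x M, rows `2i-1, 2i` are the two
#'   haplotypes of sample `i`), `samples`.
#' @export
read_vcf_haps <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(!grepl("\\|", gt)))
    stop("read_vcf_haps: unphased genotypes in ", path, call. = FALSE)
  n <- ncol(gt); m <- nrow(gt)
  haps <- matrix(0L, nrow = 2 * n, ncol = m)
  haps[seq(1, 2 * n, by = 2), ] <- t(substr(gt, 1, 1) == "1")
  haps[seq(2, 2 * n, by = 2), ] <- t(substr(gt, 3, 3) == "1")
  storage.mode(haps) <- "integer"
  list(variants = vcf_variant_table(vcf), haps = haps, samples = colnames(gt))
}

#' Read an imputed VCF (GT/DS/GP + R2/TYPED INFO)
#'
#' @param path VCF written by [write_imputed_vcf()] or with compatible
#'   fields.
#' @return An `imputed_dataset` list: `variants`, `dosages`, `genotype_probs`
#'   (N x M x 3), `hard_calls`, `est_r2`, `typed_flag`, `samples`.
#' @export
read_imputed_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  variants <- vcf_variant_table(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ds <- t(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
  gp <- vcfR::extract.gt(vcf, element = "GP")
  n <- ncol(gt); m <- nrow(gt)
  probs <- array(NA_real_, c(n, m, 3))
  sp <- strsplit(as.vector(gp), ",", fixed = TRUE)
  pm <- matrix(as.numeric(unlist(sp)), nrow = 3)  # over variants-major vector
  for (k in 1:3) probs[, , k] <- t(matrix(pm[k, ], nrow = m))
  r2 <- as.numeric(vcfR::extract.info(vcf, element = "R2"))
  typed <- grepl("(^|;)TYPED(;|$)", vcfR::getINFO(vcf))
  hc <- t(gt_to_dosage(gt))
  rownames(ds) <- rownames(hc) <- colnames(gt)
  new_imputed_dataset(variants, ds, probs, hc, r2, typed, colnames(gt))
}

#' Read/write the allele-frequency table and phenotype table
#'
#' The AF table has columns `CHROM POS REF ALT AF` (the gnomAD role in the
#' pipeline); the phenotype table has `SAMPLE STATUS` with 0 = control,
#' 1 = case.
#'
#' @param path TSV file path.
#' @return A data.frame.
#' @export
read_af_table <- function(path) {
  af <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(CHROM = "character"))
  stopifnot(all(c("CHROM", "POS", "REF", "ALT", "AF") %in% names(af)))
  af
}

#' @rdname read_af_table
#' @export
read_phenotypes <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("SAMPLE", "STATUS") %in% names(ph)))
  ph
}
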