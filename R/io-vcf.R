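#' Read a VCF file into a genotype dataset
#'
#' Uses vcfR to parse VCF 4.x; dosage is the count of the ALT allele in
#' the GT field, with "./." (or any missing GT) mapped to `NA`.  Only
#' diploid biallelic records are accepted.  Population labels are taken
#' from the optional `populations` argument (named by sample id) and
#' default to "pop1".
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param populations Optional named character vector of population labels.
#' @return A [geno_dataset()].
#' @export
read_vcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multi-allelic VCF records are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  uniq <- unique(as.vector(gt_clean))
  uniq <- uniq[!is.na(uniq)]
  known <- c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (length(setdiff(uniq, known))) {
    stop("non-diploid or unsupported GT field: ",
         paste(setdiff(uniq, known), collapse = ", "))
  }
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dosage[gt_clean == "0/0"] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean == "1/1"] <- 2L
  map <- data.frame(chrom = fix[, "CHROM"],
                    id = fix[, "ID"],
                    bp = as.numeric(fix[, "POS"]),
                    allele_a = fix[, "REF"],
                    allele_b = alt,
                    stringsAsFactors = FALSE)
  no_id <- is.na(map$id) | map$id == "."
  map$id[no_id] <- paste0(map$chrom[no_id], "_", as.integer(map$bp[no_id]))
  pops <- rep("pop1", length(ids))
  if (!is.null(populations)) {
    idx <- match(ids, names(populations))
    if (anyNA(idx)) stop("populations lacks labels for: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    pops <- unname(populations[idx])
  }
  ord <- order(map$chrom, map$bp)
  geno_dataset(ids, pops, map[ord, ], t(dosage[ord, , drop = FALSE]))
}

#' Write a genotype dataset as VCF 4.2
#'
#' REF is the A allele, ALT the B allele; genotypes are emitted as
#' unphased GT calls ("0/0", "0/1", "1/1", "./.").
#'
#' @param dataset A [geno_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "geno_dataset"))
  map <- dataset$map
  g <- dataset$genotypes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=herdstruct",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", dataset$ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(map))) {
    gj <- g[, j]
    gt <- ifelse(is.na(gj), "./.", gt_code[gj + 1L])
    writeLines(paste(c(map$chrom[j], as.integer(map$bp[j]), map$id[j],
                       map$allele_a[j], map$allele_b[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
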