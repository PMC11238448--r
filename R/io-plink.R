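#' Read PLINK text .ped/.map files
#'
#' Parses whitespace-delimited PLINK text pedigree/map files into a
#' [geno_dataset()].  The family id column is used as the population
#' label.  For each marker the two observed alleles are ordered
#' lexicographically; the B allele (dosage-counted) is the
#' lexicographically larger one, so that write/read round-trips preserve
#' the dosage matrix.  Markers with position 0 or chromosome "0"
#' (unknown placement) are excluded with a message.
#'
#' @param ped_path Path to the .ped file.
#' @param map_path Path to the .map file (chrom, id, cM, bp).
#' @return A `geno_dataset`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf != 4L)) {
    stop(sprintf("map format error: line %d has %d fields (expected 4)",
                 which(nf != 4L)[1], nf[which(nf != 4L)[1]]))
  }
  map <- data.frame(chrom = vapply(map_tok, `[`, "", 1L),
                    id = vapply(map_tok, `[`, "", 2L),
                    bp = as.numeric(vapply(map_tok, `[`, "", 4L)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$id)) {
    stop("map format error: duplicate marker id ",
         map$id[duplicated(map$id)][1])
  }
  m_all <- nrow(map)
  keep <- !(map$bp <= 0 | map$chrom == "0")
  if (any(!keep)) {
    message(sprintf("excluding %d marker(s) with unknown chromosomal position", sum(!keep)))
  }

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  expect <- 6L + 2L * m_all
  nf <- lengths(ped_tok)
  if (any(nf != expect)) {
    i <- which(nf != expect)[1]
    stop(sprintf("ped format error: line %d has %d fields (expected %d)", i, nf[i], expect))
  }
  n <- length(ped_tok)
  fam <- vapply(ped_tok, `[`, "", 1L)
  iid <- vapply(ped_tok, `[`, "", 2L)
  a1 <- matrix("", n, m_all); a2 <- matrix("", n, m_all)
  for (i in seq_len(n)) {
    al <- ped_tok[[i]][-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m_all, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m_all, by = 2L)]
  }

  map <- map[keep, , drop = FALSE]
  a1 <- a1[, keep, drop = FALSE]; a2 <- a2[, keep, drop = FALSE]
  m <- nrow(map)
  geno <- matrix(NA_integer_, n, m)
  allele_a <- character(m); allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    present <- obs != "0"
    alleles <- sort(unique(obs[present]))
    if (length(alleles) > 2L) {
      stop(sprintf("ped format error: marker %s has >2 alleles (%s)",
                   map$id[j], paste(alleles, collapse = ",")))
    }
    aa <- if (length(alleles) >= 1L) alleles[1L] else "A"
    bb <- if (length(alleles) == 2L) alleles[2L] else "B"
    allele_a[j] <- aa; allele_b[j] <- bb
    ok <- a1[, j] != "0" & a2[, j] != "0"
    geno[ok, j] <- (a1[ok, j] == bb) + (a2[ok, j] == bb)
  }
  map$allele_a <- allele_a; map$allele_b <- allele_b
  ord <- order(map$chrom, map$bp)
  map <- map[ord, c("chrom", "id", "bp", "allele_a", "allele_b")]
  geno <- geno[, ord, drop = FALSE]
  for (ch in unique(map$chrom)) {
    pos <- map$bp[map$chrom == ch]
    if (any(diff(pos) <= 0)) {
      stop(sprintf("map format error: duplicate position on chromosome %s", ch))
    }
  }
  geno_dataset(iid, fam, map, geno)
}

#' Write PLINK text .ped/.map files
#'
#' @param dataset A [geno_dataset()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(dataset, ped_path, map_path) {
  stopifnot(inherits(dataset, "geno_dataset"))
  map <- dataset$map
  writeLines(sprintf("%s\t%s\t0\t%d", map$chrom, map$id, as.integer(map$bp)), map_path)
  g <- dataset$genotypes
  n <- nrow(g)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    gi <- g[i, ]
    h1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, map$allele_b, map$allele_a))
    h2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, map$allele_b, map$allele_a))
    al <- character(2L * length(gi))
    al[c(TRUE, FALSE)] <- h1; al[c(FALSE, TRUE)] <- h2
    writeLines(paste(c(dataset$populations[i], dataset$ids[i], "0", "0", "0", "-9", al),
                     collapse = "\t"), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}
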