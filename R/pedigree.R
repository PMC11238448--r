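#' Pedigree of parentage records
#'
#' Validates and topologically sorts a table of parentage records so
#' that parents always precede their offspring.  Unknown parents are
#' `NA`.  Founders may carry a `breed` label (used as the founder breed
#' fraction: a unit vector on that breed) and optionally a `foreign_pct`
#' override for pedigree-based admixture.
#'
#' @param records Data frame with columns `id`, `sire`, `dam` and
#'   optionally `birth_year`, `breed`, plus any extra columns (kept).
#' @return Object of class `pedigree` (a sorted data frame).
#' @export
pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) {
    if (!col %in% names(records)) stop("pedigree records lack column '", col, "'")
    records[[col]] <- as.character(records[[col]])
  }
  records$sire[records$sire %in% c("0", "")] <- NA_character_
  records$dam[records$dam %in% c("0", "")] <- NA_character_
  if (anyDuplicated(records$id)) {
    stop("duplicate pedigree ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  known <- c(records$sire, records$dam)
  known <- known[!is.na(known)]
  unknown_parents <- setdiff(known, records$id)
  if (length(unknown_parents)) {
    stop("parents absent from the pedigree: ",
         paste(unknown_parents, collapse = ", "))
  }
  # Kahn topological sort; cycles are an error
  n <- nrow(records)
  idx <- stats::setNames(seq_len(n), records$id)
  si <- idx[records$sire]; di <- idx[records$dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order_out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) != n) {
    stop("pedigree contains a cycle involving: ",
         paste(records$id[indeg > 0], collapse = ", "))
  }
  out <- records[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- is.na(x$sire) & is.na(x$dam)
  cat(sprintf("pedigree: %d individuals (%d founders)\n", nrow(x), sum(founders)))
  if ("generation" %in% names(x)) {
    cat("generations:", paste(range(x$generation), collapse = "-"), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a pedigree from a TSV file
#'
#' Expects at least the columns `id`, `sire`, `dam` (tab-separated with
#' a header); `birth_year` and `breed` are used when present.
#'
#' @param path File path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  pedigree(utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character"))
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes F_PED for every individual as the kinship of its parents
#' using the Meuwissen-Luo tabular algorithm: the additive relationship
#' matrix factorisation A = L D L' is traced ancestor-by-ancestor, so
#' F_i = sum_j L_ij^2 D_j - 1 without forming A.  Unknown parents are
#' treated as unrelated, non-inbred founders.
#'
#' @param ped A [pedigree()].
#' @return Named numeric vector of inbreeding coefficients in `[0, 1]`.
#' @export
pedigree_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  Fv <- numeric(n)
  # D_j = 0.5 - 0.25 (F_s + F_d); unknown parents contribute as unrelated
  # non-inbred founders
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) { D[i] <- 1; Fv[i] <- 0; next }
    if (is.na(s) || is.na(d)) {
      p <- if (is.na(s)) d else s
      D[i] <- 0.75 - 0.25 * Fv[p]
      Fv[i] <- 0
      next
    }
    D[i] <- 0.5 - 0.25 * (Fv[s] + Fv[d])
    # trace ancestor contributions of the row of L for individual i
    L <- numeric(n)
    L[i] <- 1
    acc <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      acc <- acc + L[j]^2 * D[j]
      if (!is.na(si[j])) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (!is.na(di[j])) L[di[j]] <- L[di[j]] + 0.5 * L[j]
    }
    Fv[i] <- acc - 1
  }
  stats::setNames(Fv, ped$id)
}

#' Pedigree-based admixture percentage (A_PED)
#'
#' Assigns every founder a percentage of foreign (non home-breed)
#' ancestry and propagates it down the pedigree as the parental mean.
#' Founders labelled with the home breed, or born before
#' `purebred_cutoff_year`, count as 0% foreign; all other founders count
#' as 100% foreign unless they carry an explicit `foreign_pct` column
#' value.  Unknown parents of non-founders are treated as purebred
#' (0% foreign).
#'
#' @param ped A [pedigree()] with `breed` and (if the cutoff rule is
#'   used) `birth_year` columns.
#' @param home_breed Label of the home breed.
#' @param purebred_cutoff_year Birth-year convention: founders born
#'   strictly before this year are purebred regardless of label
#'   (default 1950).
#' @return Named numeric vector of A_PED percentages in `[0, 100]`.
#' @export
pedigree_admixture <- function(ped, home_breed, purebred_cutoff_year = 1950) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  is_founder <- is.na(si) & is.na(di)
  by <- if ("birth_year" %in% names(ped)) suppressWarnings(as.numeric(ped$birth_year))
        else rep(NA_real_, n)
  breed <- if ("breed" %in% names(ped)) ped$breed else rep(NA_character_, n)
  override <- if ("foreign_pct" %in% names(ped))
    suppressWarnings(as.numeric(ped$foreign_pct)) else rep(NA_real_, n)
  a <- numeric(n)
  for (i in seq_len(n)) {
    if (is_founder[i]) {
      if (!is.na(override[i])) { a[i] <- override[i]; next }
      if (!is.na(by[i]) && by[i] < purebred_cutoff_year) { a[i] <- 0; next }
      if (is.na(breed[i])) {
        stop("founder '", ped$id[i],
             "' has no breed label and is not born before the cutoff year")
      }
      a[i] <- if (breed[i] == home_breed) 0 else 100
    } else {
      as_ <- if (is.na(si[i])) 0 else a[si[i]]
      ad_ <- if (is.na(di[i])) 0 else a[di[i]]
      a[i] <- (as_ + ad_) / 2
    }
  }
  stats::setNames(a, ped$id)
}

# Ordinary least squares on an explicit design matrix (QR solve).
.ols <- function(y, X) {
  qr_ <- qr(X)
  beta <- qr.coef(qr_, y)
  beta[is.na(beta)] <- 0
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(coef = beta, r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Compare genomic and pedigree-based inbreeding/admixture
#'
#' For each supplied pair (F_ROH vs F_PED, A_GEN vs A_PED) computes the
#' Pearson correlation and the least-squares slope, intercept and R^2
#' via an explicit design matrix.  When `parent_factors` is given,
#' additionally fits the genomic value on the pedigree value plus sire
#' and dam as categorical factors and reports that model's R^2.
#'
#' @param froh,fped Named numeric vectors (ids as names); either both or
#'   neither.
#' @param agen,aped Named numeric vectors; either both or neither.
#' @param parent_factors Optional data frame `id`, `sire`, `dam` for the
#'   factor-augmented model of F_ROH on F_PED.
#' @return Object of class `genomic_pedigree_comparison`: a data frame
#'   of per-pair statistics, with the factor-model R^2 as attribute
#'   `"factor_r_squared"` when computed.
#' @export
compare_genomic_pedigree <- function(froh = NULL, fped = NULL,
                                     agen = NULL, aped = NULL,
                                     parent_factors = NULL) {
  one_pair <- function(y, x, label) {
    ids <- intersect(names(y), names(x))
    if (length(ids) < 3) stop(label, ": fewer than 3 paired observations")
    y <- y[ids]; x <- x[ids]
    fit <- .ols(y, cbind(intercept = 1, x = x))
    data.frame(pair = label, n = length(ids),
               pearson_r = stats::cor(x, y),
               slope = unname(fit$coef["x"]),
               intercept = unname(fit$coef["intercept"]),
               r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (!is.null(froh) || !is.null(fped)) {
    if (is.null(froh) || is.null(fped)) stop("supply both froh and fped, or neither")
    rows$f <- one_pair(froh, fped, "F_ROH ~ F_PED")
  }
  if (!is.null(agen) || !is.null(aped)) {
    if (is.null(agen) || is.null(aped)) stop("supply both agen and aped, or neither")
    rows$a <- one_pair(agen, aped, "A_GEN ~ A_PED")
  }
  if (!length(rows)) stop("nothing to compare")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(parent_factors) && !is.null(froh)) {
    ids <- intersect(intersect(names(froh), names(fped)), parent_factors$id)
    if (length(ids) >= 3) {
      pf <- parent_factors[match(ids, parent_factors$id), ]
      X <- cbind(intercept = 1, fped = fped[ids])
      for (fac in c("sire", "dam")) {
        lev <- unique(pf[[fac]])
        if (length(lev) > 1) {
          M <- outer(pf[[fac]], lev[-1], `==`) * 1
          colnames(M) <- paste0(fac, "_", lev[-1])
          X <- cbind(X, M)
        }
      }
      attr(out, "factor_r_squared") <- .ols(froh[ids], X)$r_squared
    }
  }
  class(out) <- c("genomic_pedigree_comparison", "data.frame")
  out
}

#' @export
print.genomic_pedigree_comparison <- function(x, ...) {
  cat("genomic vs pedigree comparison\n")
  print.data.frame(x, digits = 4)
  fr2 <- attr(x, "factor_r_squared")
  if (!is.null(fr2)) cat(sprintf("R^2 with sire/dam factors: %.4f\n", fr2))
  invisible(x)
}
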