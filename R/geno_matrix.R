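#' Diploid genotype matrix
#'
#' The central container consumed by every analysis stage: an accessions x
#' loci matrix of unordered diploid calls at biallelic loci, stored as the
#' alt-allele dosage (0 = ref/ref, 1 = het, 2 = alt/alt, `NA` = missing),
#' together with a locus table describing each marker.
#'
#' Allele 0 is always the reference allele and allele 1 the alternate;
#' genotypes are unordered (phase is never retained). Missingness is the
#' dedicated `NA` sentinel, never an allele value, so no arithmetic can
#' silently include missing calls.
#'
#' @param geno integer matrix (accessions x loci) with entries 0, 1, 2 or
#'   `NA`; rownames are accession ids, colnames locus ids. A numeric matrix
#'   of whole numbers is accepted and stored as integer.
#' @param loci optional data.frame describing the loci, one row per column
#'   of `geno`, with at least a `locus_id` column; columns `chromosome`,
#'   `position`, `ref`, `alt`, `maf` are used when present. If `NULL`, a
#'   minimal table is built from the colnames of `geno`.
#' @return an object of class `geno_matrix`: a list with elements `geno`
#'   (integer matrix) and `loci` (data.frame).
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'   dimnames = list(c("a1", "a2"), c("L1", "L2"))))
#' n_loci(g)
geno_matrix <- function(geno, loci = NULL) {
  if (!is.matrix(geno)) stop("`geno` must be a matrix")
  ## zero-extent matrices (e.g. every locus filtered away) are legal
  if (is.null(rownames(geno))) {
    if (nrow(geno) > 0) stop("`geno` must have accession rownames")
    rownames(geno) <- character(0)
  }
  if (is.null(colnames(geno))) {
    if (ncol(geno) > 0) stop("`geno` must have locus colnames")
    colnames(geno) <- character(0)
  }
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(geno)))
    stop("accession ids must be unique")
  if (anyDuplicated(colnames(geno)))
    stop("locus ids must be unique")
  if (is.null(loci)) {
    loci <- data.frame(locus_id = colnames(geno), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(loci) || is.null(loci$locus_id))
    stop("`loci` must be a data.frame with a locus_id column")
  if (nrow(loci) != ncol(geno) ||
      (ncol(geno) > 0 && !identical(as.character(loci$locus_id),
                                    colnames(geno))))
    stop("`loci` must describe exactly the columns of `geno`, in order")
  rownames(loci) <- NULL
  structure(list(geno = geno, loci = loci), class = "geno_matrix")
}

#' @rdname geno_matrix
#' @param x a `geno_matrix`
#' @export
n_accessions <- function(x) nrow(x$geno)

#' @rdname geno_matrix
#' @export
n_loci <- function(x) ncol(x$geno)

#' @rdname geno_matrix
#' @export
accession_ids <- function(x) rownames(x$geno)

#' @rdname geno_matrix
#' @export
locus_ids <- function(x) colnames(x$geno)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d accessions x %d loci (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`
#' @param i accession selector (indices, names or logical)
#' @param j locus selector (indices, names or logical)
#' @param ... ignored
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  g <- x$geno[i, j, drop = FALSE]
  jj <- match(colnames(g), x$loci$locus_id)
  geno_matrix(g, x$loci[jj, , drop = FALSE])
}

## per-locus summaries used throughout ----------------------------------

#' Per-locus alternate-allele frequency
#'
#' Computed over non-missing calls only: `p = sum(dosage) / (2 * n_called)`.
#' Loci with no non-missing call return `NA`.
#'
#' @param x a `geno_matrix`
#' @return numeric vector named by locus id
#' @export
locus_alt_freq <- function(x) {
  called <- colSums(!is.na(x$geno))
  p <- colSums(x$geno, na.rm = TRUE) / (2 * called)
  p[called == 0] <- NA_real_
  p
}

#' Per-locus minor allele frequency
#' @param x a `geno_matrix`
#' @return numeric vector named by locus id; `NA` where all calls missing
#' @export
locus_maf <- function(x) {
  p <- locus_alt_freq(x)
  pmin(p, 1 - p)
}

#' Per-locus fraction of missing calls
#' @param x a `geno_matrix`
#' @export
locus_missing_rate <- function(x) colMeans(is.na(x$geno))

#' Per-locus monomorphism flag
#'
#' A locus is monomorphic when exactly one allele is observed among its
#' non-missing calls (all 0-dosage or all 2-dosage, no heterozygote). A
#' locus with no non-missing call is not monomorphic by this definition.
#'
#' @param x a `geno_matrix`
#' @export
locus_monomorphic <- function(x) {
  apply(x$geno, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(FALSE)
    all(col == 0L) || all(col == 2L)
  })
}
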