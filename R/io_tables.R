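## Genotype CSV dialects -------------------------------------------------
##
## Two cell dialects are accepted, auto-detected per file (never per cell):
##   "AB" dialect:  AA, AB, BB, NA        (A = ref allele 0, B = alt allele 1)
##   "VCF" dialect: 0/0, 0/1, 1/1, ./.
## Mixing dialects within one file is a format error.

.ab_codes <- c(AA = 0L, AB = 1L, BB = 2L)
.vcf_codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

#' Read a genotype matrix from CSV
#'
#' Expects a header row of locus ids, a first column of accession ids, and
#' genotype cells in one of two dialects: `AA`/`AB`/`BB`/`NA` or
#' `0/0`/`0/1`/`1/1`/`./.`. The dialect is detected once per file; a file
#' mixing dialects is rejected.
#'
#' @param path CSV file
#' @return a [geno_matrix]
#' @export
read_genotype_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("genotype CSV has no data rows: ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1)
    stop("ragged genotype CSV (rows of differing width): ", path)
  header <- parts[[1]]
  loci <- header[-1]
  if (length(loci) == 0) stop("genotype CSV has no locus columns: ", path)
  rows <- parts[-1]
  ids <- vapply(rows, `[`, character(1), 1)
  cells <- do.call(rbind, lapply(rows, function(r) r[-1]))
  cells <- trimws(cells)

  is_ab <- cells %in% c(names(.ab_codes), "NA")
  is_vcf <- cells %in% c(names(.vcf_codes), "./.")
  if (all(is_ab)) {
    dos <- .ab_codes[cells]
  } else if (all(is_vcf)) {
    dos <- .vcf_codes[cells]
  } else if (any(is_ab & !cells %in% "NA") && any(is_vcf & !cells %in% "./.")) {
    stop("mixed genotype dialects in one file: ", path)
  } else {
    bad <- cells[!(is_ab | is_vcf)][1]
    stop("unrecognised genotype cell '", bad, "' in ", path)
  }
  g <- matrix(unname(dos), nrow = length(ids),
              dimnames = list(ids, loci))
  geno_matrix(g)
}

#' Write a genotype matrix as CSV
#'
#' @param g a [geno_matrix]
#' @param path output file
#' @param dialect `"AB"` (cells `AA`/`AB`/`BB`/`NA`, default) or `"VCF"`
#'   (cells `0/0`/`0/1`/`1/1`/`./.`)
#' @export
write_genotype_csv <- function(g, path, dialect = c("AB", "VCF")) {
  dialect <- match.arg(dialect)
  codes <- if (dialect == "AB") c("AA", "AB", "BB") else c("0/0", "0/1", "1/1")
  miss <- if (dialect == "AB") "NA" else "./."
  cells <- matrix(ifelse(is.na(g$geno), miss, codes[g$geno + 1L]),
                  nrow = nrow(g$geno))
  out <- c(paste(c("accession", locus_ids(g)), collapse = ","),
           vapply(seq_len(nrow(cells)), function(i)
             paste(c(accession_ids(g)[i], cells[i, ]), collapse = ","),
             character(1)))
  writeLines(out, path)
  invisible(path)
}

## STRUCTURE two-row format ----------------------------------------------

#' Write a genotype matrix in STRUCTURE two-row format
#'
#' Two whitespace-separated rows per individual, one column per locus,
#' alleles coded 0 (ref) / 1 (alt), missing coded -9 in both rows; a header
#' row of locus ids. Within an individual the two allele rows are sorted
#' (heterozygotes are written 0 then 1), since genotypes are unordered.
#'
#' @param g a [geno_matrix]
#' @param path output file
#' @export
write_structure_format <- function(g, path) {
  n <- n_accessions(g)
  out <- character(2 * n + 1)
  out[1] <- paste(locus_ids(g), collapse = " ")
  for (i in seq_len(n)) {
    dos <- g$geno[i, ]
    a1 <- ifelse(is.na(dos), -9L, ifelse(dos == 2L, 1L, 0L))
    a2 <- ifelse(is.na(dos), -9L, ifelse(dos >= 1L, 1L, 0L))
    id <- accession_ids(g)[i]
    out[2 * i] <- paste(c(id, a1), collapse = " ")
    out[2 * i + 1] <- paste(c(id, a2), collapse = " ")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read the STRUCTURE two-row format written by [write_structure_format]
#'
#' @param path file
#' @return a [geno_matrix]
#' @export
read_structure_format <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  loci <- strsplit(lines[1], "[ \t]+")[[1]]
  body <- strsplit(lines[-1], "[ \t]+")
  if (length(body) %% 2 != 0)
    stop("STRUCTURE file must have two rows per individual: ", path)
  n <- length(body) / 2
  g <- matrix(NA_integer_, n, length(loci))
  ids <- character(n)
  for (i in seq_len(n)) {
    r1 <- body[[2 * i - 1]]; r2 <- body[[2 * i]]
    if (r1[1] != r2[1])
      stop("paired rows disagree on individual id near row ", 2 * i, ": ",
           path)
    ids[i] <- r1[1]
    a1 <- as.integer(r1[-1]); a2 <- as.integer(r2[-1])
    dos <- a1 + a2
    dos[a1 == -9L | a2 == -9L] <- NA_integer_
    g[i, ] <- dos
  }
  dimnames(g) <- list(ids, loci)
  geno_matrix(g)
}

## Accession metadata ------------------------------------------------------

.status_vocab <- c("old_cultivar", "modern_cultivar", "hybrid", "wild")
.origin_vocab <- c("GD", "GX", "FJ", "HN", "SC", "YN", "DX-GX", "BB-GX",
                   "TW", "VN", "TL", "-")
.maturation_vocab <- c("EEM", "EM", "MLM")

#' Read an accession metadata table
#'
#' CSV with columns `name,status,origin,maturation`. `status` must be one
#' of `old_cultivar`, `modern_cultivar`, `hybrid`, `wild`; `maturation` one
#' of the fruit maturation classes `EEM` (extremely early), `EM` (early),
#' `MLM` (middle-to-late); `origin` a province/region code or `-`.
#'
#' The packaged fixture `system.file("extdata", "litchi_accessions.csv",
#' package = "snpdiv")` describes the 84-accession litchi germplasm panel
#' (37 old cultivars, 18 modern cultivars, 12 hybrids of known parents,
#' 17 wild accessions).
#'
#' @param path CSV file
#' @return data.frame with columns name, status, origin, maturation
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "status", "origin", "maturation")
  if (!all(need %in% names(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  df <- df[, need]
  for (i in seq_len(nrow(df))) {
    if (!df$status[i] %in% .status_vocab)
      stop("row ", i, " ('", df$name[i], "'): unknown status '",
           df$status[i], "'")
    if (!df$maturation[i] %in% .maturation_vocab)
      stop("row ", i, " ('", df$name[i], "'): unknown maturation '",
           df$maturation[i], "'")
    if (!df$origin[i] %in% .origin_vocab)
      stop("row ", i, " ('", df$name[i], "'): unknown origin '",
           df$origin[i], "'")
  }
  if (anyDuplicated(df$name))
    stop("duplicate accession names in metadata")
  df
}

## Distance matrix CSV -----------------------------------------------------

#' Write / read a labelled square distance matrix as CSV
#' @param d a `dist_matrix` (see [allele_sharing_distance]) or square matrix
#' @param path file
#' @export
write_distance_csv <- function(d, path) {
  m <- if (inherits(d, "dist_matrix")) d$d else d
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("not a labelled square distance matrix: ", path)
  structure(list(ids = rownames(m), d = m, comparable_loci = NULL),
            class = "dist_matrix")
}
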