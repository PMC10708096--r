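#' Read a minimal VCF of candidate SNPs
#'
#' Parses the subset of VCF v4.x needed for marker panel design: CHROM,
#' POS, REF, ALT and the per-sample GT field. Phased ("|") and unphased
#' ("/") separators are treated identically and phase is discarded;
#' "./." (or ".") becomes a missing call. `##contig` header lines are
#' parsed for chromosome lengths when present.
#'
#' This is deliberately not a full VCF reader (no INFO parsing, no
#' structural variants, no compressed or indexed access); it exists so the
#' panel-design stage has line-number-accurate errors and an explicit
#' skipped-record count, which general-purpose readers do not expose.
#'
#' @param path VCF text file
#' @param biallelic_snps_only if `TRUE` (default), records whose REF or ALT
#'   is not a single nucleotide, or with more than one ALT allele, are
#'   skipped and counted rather than returned.
#' @return a list with elements:
#'   * `genotypes`: a [geno_matrix] (samples x loci) whose locus table has
#'     `locus_id`, `chromosome`, `position`, `ref`, `alt` and the realised
#'     sample `maf`;
#'   * `n_skipped`: number of records skipped by the biallelic-SNP filter;
#'   * `contig_lengths`: named numeric vector from `##contig` lines (may be
#'     empty).
#' @export
read_vcf <- function(path, biallelic_snps_only = TRUE) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty VCF: ", path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1)
    stop("malformed VCF header: expected exactly one #CHROM line in ", path)
  meta <- lines[seq_len(hdr - 1)]
  if (length(meta) == 0 || !grepl("^##fileformat=VCF", meta[1]))
    stop("malformed VCF header: missing ##fileformat line in ", path)

  contig_lengths <- numeric(0)
  cl <- grep("^##contig=<", meta, value = TRUE)
  if (length(cl)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", cl)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", cl)))
    keep <- !is.na(lens)
    contig_lengths <- stats::setNames(lens[keep], ids[keep])
  }

  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10)
    stop("VCF has no sample columns: ", path)
  samples <- cols[-(1:9)]

  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n_skipped <- 0L
  loci <- list()
  calls <- list()
  for (k in seq_along(body)) {
    lineno <- hdr + k
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 + length(samples))
      stop("VCF line ", lineno, ": expected ", 9 + length(samples),
           " fields, found ", length(f))
    ref <- f[4]; alt <- f[5]
    alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
    snp_ok <- nchar(ref) == 1 && length(alts) == 1 && nchar(alts[1]) == 1 &&
      ref %in% c("A", "C", "G", "T") && alts[1] %in% c("A", "C", "G", "T")
    if (biallelic_snps_only && !snp_ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    n_alleles <- 1L + length(alts)
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i))
      stop("VCF line ", lineno, ": FORMAT has no GT field")
    gts <- vapply(f[-(1:9)], function(cell) {
      strsplit(cell, ":", fixed = TRUE)[[1]][gt_i]
    }, character(1), USE.NAMES = FALSE)
    dos <- vapply(gts, function(gt) {
      if (gt %in% c("./.", ".", ".|.")) return(NA_integer_)
      al <- strsplit(gt, "[/|]")[[1]]
      if (any(al == ".")) return(NA_integer_)
      ai <- suppressWarnings(as.integer(al))
      if (anyNA(ai) || length(ai) != 2)
        stop("VCF line ", lineno, ": cannot parse GT '", gt, "'")
      if (any(ai < 0 | ai >= n_alleles))
        stop("VCF line ", lineno, ": GT allele index out of range in '",
             gt, "'")
      sum(ai > 0L)
    }, integer(1))
    id <- f[3]
    if (id == ".") id <- paste0(f[1], "_", f[2])
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = id, chromosome = f[1], position = as.integer(f[2]),
      ref = ref, alt = alts[1], stringsAsFactors = FALSE)
    calls[[length(calls) + 1L]] <- dos
  }
  if (length(loci) == 0)
    stop("no usable variant records in ", path)
  ldf <- do.call(rbind, loci)
  if (anyDuplicated(ldf$locus_id))
    ldf$locus_id <- make.unique(ldf$locus_id)
  g <- do.call(cbind, calls)
  dimnames(g) <- list(samples, ldf$locus_id)
  gm <- geno_matrix(g, ldf)
  gm$loci$maf <- unname(locus_maf(gm))
  list(genotypes = gm, n_skipped = n_skipped, contig_lengths = contig_lengths)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Inverse of [read_vcf] for matrices whose locus table carries chromosome,
#' position, ref and alt. Dosage 0/1/2 is written as 0/0, 0/1, 1/1; missing
#' as "./.".
#'
#' @param g a [geno_matrix] with `chromosome`, `position`, `ref`, `alt`
#'   columns in its locus table
#' @param path output file
#' @param contig_lengths optional named vector written as `##contig` lines
#' @export
write_vcf <- function(g, path, contig_lengths = NULL) {
  lt <- g$loci
  need <- c("chromosome", "position", "ref", "alt")
  if (!all(need %in% names(lt)))
    stop("locus table lacks columns: ",
         paste(setdiff(need, names(lt)), collapse = ", "))
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>",
                     names(contig_lengths), as.integer(contig_lengths)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", accession_ids(g)), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(lt)), function(j) {
    dos <- g$geno[, j]
    gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1L])
    paste(c(lt$chromosome[j], lt$position[j], lt$locus_id[j], lt$ref[j],
            lt$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  ## VCF convention: records sorted by chromosome then position
  ord <- order(lt$chromosome, lt$position)
  writeLines(c(hdr, rows[ord]), path)
  invisible(path)
}
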