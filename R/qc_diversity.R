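#' Post-genotyping quality-control filter cascade
#'
#' Loci are removed in a fixed order, each locus counted in exactly one
#' category — the first it triggers: (1) assay design failure (supplied as
#' ids, since primer design is not a genotype property), (2) monomorphism
#' (exactly one allele observed among non-missing calls), (3) missingness
#' strictly above `missing_max`, (4) MAF strictly below `maf_min`. The
#' report's arithmetic identity
#' `n_input - n_design_failed - n_monomorphic - n_high_missing - n_low_maf =
#' n_retained` holds on every input.
#'
#' @param g a [geno_matrix]
#' @param design_failed_ids character vector of locus ids that failed assay
#'   design (may be empty)
#' @param missing_max maximum tolerated missing-call fraction (default 0.10;
#'   loci with missingness > `missing_max` are removed)
#' @param maf_min minimum tolerated minor allele frequency (default 0.05;
#'   loci with MAF < `maf_min` are removed)
#' @return list with `genotypes` (the filtered [geno_matrix], survivors
#'   only) and `report` (a `filter_report`: counts per category plus
#'   `retained_locus_ids` and a per-locus `category` vector)
#' @export
apply_filter_cascade <- function(g, design_failed_ids = character(0),
                                 missing_max = 0.10, maf_min = 0.05) {
  stopifnot(missing_max >= 0, missing_max <= 1, maf_min >= 0, maf_min <= 1)
  ids <- locus_ids(g)
  unknown <- setdiff(design_failed_ids, ids)
  if (length(unknown))
    stop("design_failed_ids not in matrix: ", paste(unknown, collapse = ", "))
  mono <- locus_monomorphic(g)
  miss <- locus_missing_rate(g)
  maf <- locus_maf(g)

  category <- rep("retained", length(ids))
  category[!is.na(maf) & maf < maf_min] <- "low_maf"
  category[miss > missing_max] <- "high_missing"
  category[mono] <- "monomorphic"
  category[ids %in% design_failed_ids] <- "design_failed"
  ## all-missing loci have undefined MAF; they always exceed missing_max > 0
  ## unless missing_max = 1, in which case they are retained by definition
  category[is.na(maf) & miss <= missing_max] <- "retained"

  retained <- ids[category == "retained"]
  report <- structure(list(
    n_input = length(ids),
    n_design_failed = sum(category == "design_failed"),
    n_monomorphic = sum(category == "monomorphic"),
    n_high_missing = sum(category == "high_missing"),
    n_low_maf = sum(category == "low_maf"),
    retained_locus_ids = retained,
    category = stats::setNames(category, ids),
    missing_max = missing_max, maf_min = maf_min), class = "filter_report")
  list(genotypes = g[, retained], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d loci in: %d design-failed, ",
                     "%d monomorphic, %d missing > %g%%, %d MAF < %g%% ",
                     "-> %d retained\n"),
              x$n_input, x$n_design_failed, x$n_monomorphic,
              x$n_high_missing, 100 * x$missing_max, x$n_low_maf,
              100 * x$maf_min, length(x$retained_locus_ids)))
  invisible(x)
}

#' Expected and observed heterozygosity
#'
#' Per locus, with `p` the alternate-allele frequency over non-missing
#' calls: `He = 2p(1-p)` (the uncorrected expected heterozygosity; the
#' unbiased `2N/(2N-1)` variant is available via `unbiased = TRUE`) and
#' `Ho` = heterozygous calls / non-missing calls. Group summaries are
#' unweighted means over loci of the group-restricted per-locus values,
#' always over the same locus set (no re-filtering within groups); loci with
#' no non-missing call inside a group are excluded from that group's mean.
#'
#' @param g a [geno_matrix]
#' @param groups optional named character vector or factor mapping accession
#'   id to a group label; when given, per-group summaries are added
#' @param unbiased apply the `2N/(2N-1)` small-sample correction to He
#' @return list with `per_locus` (data.frame locus_id/p/He/Ho) and `summary`
#'   (data.frame group/n_accessions/n_loci_used/mean_He/mean_Ho; group
#'   "overall" uses all accessions)
#' @export
heterozygosity <- function(g, groups = NULL, unbiased = FALSE) {
  if (n_loci(g) < 1) stop("genotype matrix has no loci")
  per_group_stats <- function(sub) {
    called <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / (2 * called)
    p[called == 0] <- NA_real_
    he <- 2 * p * (1 - p)
    if (unbiased) he <- he * (2 * called) / pmax(2 * called - 1, 1)
    ho <- colSums(sub == 1L, na.rm = TRUE) / called
    ho[called == 0] <- NA_real_
    data.frame(locus_id = colnames(sub), p = unname(p), He = unname(he),
               Ho = unname(ho), stringsAsFactors = FALSE)
  }
  overall <- per_group_stats(g$geno)
  summ <- data.frame(group = "overall", n_accessions = n_accessions(g),
                     n_loci_used = sum(!is.na(overall$He)),
                     mean_He = mean(overall$He, na.rm = TRUE),
                     mean_Ho = mean(overall$Ho, na.rm = TRUE),
                     stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    groups <- groups[accession_ids(g)]
    if (anyNA(groups)) stop("`groups` must cover every accession")
    for (lab in unique(groups)) {
      sub <- g$geno[groups == lab, , drop = FALSE]
      st <- per_group_stats(sub)
      summ <- rbind(summ, data.frame(
        group = lab, n_accessions = nrow(sub),
        n_loci_used = sum(!is.na(st$He)),
        mean_He = mean(st$He, na.rm = TRUE),
        mean_Ho = mean(st$Ho, na.rm = TRUE)))
    }
  }
  list(per_locus = overall, summary = summ)
}

#' Pairwise multilocus match analysis
#'
#' For every accession pair, mismatches are counted over comparable loci
#' (both calls non-missing). A pair is matched iff it has zero mismatches
#' and at least one comparable locus; with `require_complete = TRUE` a pair
#' is matched only when additionally every locus is comparable (no missing
#' call in either profile). Synonym groups are the connected components
#' (transitive closure) of the matched relation with two or more members.
#'
#' @param g a [geno_matrix] with >= 2 accessions
#' @param require_complete demand complete shared profiles for a match
#'   (default `FALSE`: missing-tolerant matching)
#' @return a `match_report`: list with `mismatches` and `comparable_loci`
#'   (symmetric integer matrices, zero/`n_loci` diagonal), `matched`
#'   (logical matrix), and `synonym_groups` (list of character vectors)
#' @export
multilocus_match <- function(g, require_complete = FALSE) {
  n <- n_accessions(g)
  if (n < 2) stop("need >= 2 accessions")
  X <- g$geno
  ids <- accession_ids(g)
  mism <- matrix(0L, n, n, dimnames = list(ids, ids))
  comp <- matrix(0L, n, n, dimnames = list(ids, ids))
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  for (i in seq_len(n - 1)) {
    both <- obs[rep(i, n - i), , drop = FALSE] & obs[(i + 1):n, , drop = FALSE]
    diffs <- (X0[rep(i, n - i), , drop = FALSE] !=
                X0[(i + 1):n, , drop = FALSE]) & both
    mism[i, (i + 1):n] <- as.integer(rowSums(diffs))
    comp[i, (i + 1):n] <- as.integer(rowSums(both))
  }
  mism <- mism + t(mism)
  comp <- comp + t(comp)
  diag(comp) <- n_loci(g)
  matched <- mism == 0L & comp >= 1L
  if (require_complete) matched <- matched & comp == n_loci(g)
  diag(matched) <- TRUE
  ## connected components of the matched relation
  comp_id <- seq_len(n)
  repeat {
    new_id <- comp_id
    for (i in seq_len(n))
      new_id[i] <- min(comp_id[matched[i, ]])
    if (identical(new_id, comp_id)) break
    comp_id <- new_id
  }
  groups <- split(ids, comp_id)
  synonym_groups <- unname(groups[lengths(groups) >= 2])
  structure(list(mismatches = mism, comparable_loci = comp,
                 matched = matched, synonym_groups = synonym_groups,
                 require_complete = require_complete),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d accessions, %d synonym group(s)\n",
              nrow(x$mismatches), length(x$synonym_groups)))
  for (g in x$synonym_groups)
    cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Can a set of accessions be told apart?
#'
#' `TRUE` iff every pair among `ids` differs at one or more comparable
#' loci (vacuously true for a single id).
#'
#' @param g a [geno_matrix]
#' @param ids accession ids to test
#' @export
discriminate_set <- function(g, ids) {
  unknown <- setdiff(ids, accession_ids(g))
  if (length(unknown))
    stop("unknown accession ids: ", paste(unknown, collapse = ", "))
  if (length(ids) < 2) return(TRUE)
  mr <- multilocus_match(g[ids, ])
  all(mr$mismatches[upper.tri(mr$mismatches)] >= 1L)
}
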