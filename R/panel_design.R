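#' Panel design configuration
#'
#' The three marker-selection criteria: even spacing across chromosomes
#' (operationalised as equal-length bins per chromosome, `per_chromosome_quota`
#' bins each, nearest-eligible-to-bin-midpoint choice), flank isolation (no
#' other candidate within `flank_bp` on the same chromosome; a neighbour at
#' exactly `flank_bp` violates isolation), and minor allele frequency
#' strictly greater than `maf_min`.
#'
#' @param per_chromosome_quota markers to select per chromosome (default 10)
#' @param flank_bp isolation window in bp up- and downstream (default 150)
#' @param maf_min MAF eligibility threshold, exclusive (default 0.05)
#' @param n_chromosomes_expected expected chromosome count (default 15);
#'   informational, used for reporting only
#' @export
panel_config <- function(per_chromosome_quota = 10, flank_bp = 150,
                         maf_min = 0.05, n_chromosomes_expected = 15) {
  stopifnot(per_chromosome_quota >= 1, flank_bp >= 0,
            maf_min >= 0, maf_min < 0.5)
  structure(list(per_chromosome_quota = as.integer(per_chromosome_quota),
                 flank_bp = as.numeric(flank_bp), maf_min = maf_min,
                 n_chromosomes_expected = as.integer(n_chromosomes_expected)),
            class = "panel_config")
}

#' Minor allele frequency of one locus
#'
#' `min(p, 1 - p)` with `p` the alternate-allele frequency over non-missing
#' calls; missing calls are excluded from numerator and denominator.
#'
#' @param calls integer vector of dosages (0/1/2, `NA` missing)
#' @return MAF in `[0, 0.5]`
#' @export
compute_maf <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("MAF undefined: all calls missing")
  p <- sum(calls) / (2 * length(calls))
  min(p, 1 - p)
}

#' Flank isolation flags
#'
#' A locus is isolated iff no other candidate locus on the same chromosome
#' lies within `flank_bp` (inclusive: a neighbour at exactly `flank_bp` is
#' too close).
#'
#' @param loci data.frame with `chromosome` and `position` columns
#' @param flank_bp isolation window in bp
#' @return logical vector in the input row order
#' @export
flank_isolated <- function(loci, flank_bp) {
  key <- paste(loci$chromosome, loci$position)
  if (anyDuplicated(key))
    stop("duplicate (chromosome, position): ",
         key[duplicated(key)][1])
  iso <- rep(TRUE, nrow(loci))
  for (ch in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == ch)
    if (length(idx) < 2) next
    ord <- idx[order(loci$position[idx])]
    pos <- loci$position[ord]
    gap_left <- c(Inf, diff(pos))
    gap_right <- c(diff(pos), Inf)
    iso[ord] <- gap_left > flank_bp & gap_right > flank_bp
  }
  iso
}

#' Select a genome-wide marker panel
#'
#' Eligibility is flank isolation and MAF strictly above `cfg$maf_min`.
#' Each chromosome is partitioned into `per_chromosome_quota` equal-length
#' bins; within each bin the eligible candidate nearest the bin midpoint is
#' selected (ties: higher MAF, then lower position). When every bin holds an
#' eligible candidate the panel has exactly quota x n_chromosomes loci;
#' otherwise fewer, with unfilled bins reported. Selection is invariant to
#' the input ordering of candidates.
#'
#' @param candidates a [geno_matrix] of candidate loci (e.g. from
#'   [read_vcf]) whose locus table has `chromosome` and `position`
#' @param chromosome_lengths named vector of chromosome lengths in bp; for
#'   chromosomes absent from it the maximum candidate position is used
#' @param cfg a [panel_config]
#' @return data.frame of selected loci (locus_id, chromosome, position,
#'   ref, alt, maf, bin_index), ordered by chromosome and position, with an
#'   `unfilled` attribute (data.frame chromosome/bin_index) listing bins
#'   with no eligible candidate
#' @export
select_panel <- function(candidates, chromosome_lengths = NULL,
                         cfg = panel_config()) {
  lt <- candidates$loci
  if (!all(c("chromosome", "position") %in% names(lt)))
    stop("candidate loci need chromosome and position")
  maf <- locus_maf(candidates)
  iso <- flank_isolated(lt, cfg$flank_bp)
  eligible <- iso & !is.na(maf) & maf > cfg$maf_min

  chroms <- sort(unique(lt$chromosome))
  sel <- integer(0)
  bin_of <- integer(0)
  unfilled <- data.frame(chromosome = character(0), bin_index = integer(0),
                         stringsAsFactors = FALSE)
  quota <- cfg$per_chromosome_quota
  for (ch in chroms) {
    len <- if (!is.null(chromosome_lengths) && ch %in% names(chromosome_lengths))
      as.numeric(chromosome_lengths[[ch]])
    else max(lt$position[lt$chromosome == ch])
    w <- len / quota
    for (b in seq_len(quota)) {
      mid <- (b - 0.5) * w
      in_bin <- lt$chromosome == ch & lt$position > (b - 1) * w &
        (lt$position <= b * w | b == quota)
      cand <- which(in_bin & eligible)
      if (length(cand) == 0) {
        unfilled <- rbind(unfilled,
                          data.frame(chromosome = ch, bin_index = b))
        next
      }
      o <- order(abs(lt$position[cand] - mid), -maf[cand],
                 lt$position[cand])
      sel <- c(sel, cand[o[1]])
      bin_of <- c(bin_of, b)
    }
  }
  out <- data.frame(locus_id = lt$locus_id[sel],
                    chromosome = lt$chromosome[sel],
                    position = lt$position[sel],
                    ref = if ("ref" %in% names(lt)) lt$ref[sel] else NA,
                    alt = if ("alt" %in% names(lt)) lt$alt[sel] else NA,
                    maf = unname(maf[sel]), bin_index = bin_of,
                    stringsAsFactors = FALSE)
  ord <- order(out$chromosome, out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unfilled") <- unfilled
  out
}
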