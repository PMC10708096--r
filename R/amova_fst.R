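## AMOVA on squared Euclidean dosage distances ----------------------------
##
## Individuals are coded per locus by alt-allele dosage (0/1/2). Viewing
## each individual as its two allele copies gives a three-level hierarchy
## (among groups / among individuals within groups / within individuals).
## All sums of squares come from the standard distance-partition identities
## over allele-copy pairs; per-pair locus sets with missing calls are
## excluded and rescaled by the loci-count ratio.
##
## Per locus, for individuals with dosages x and y:
##   sum over the 4 cross allele pairs of (a - b)^2 = 2x + 2y - 2xy
##   distance between an individual's own two copies     = [dosage == 1]

.amova_parts <- function(g) {
  X <- g$geno
  n <- nrow(X); L <- ncol(X)
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  ## W[i, j] = rescaled sum over loci of cross-copy squared differences
  ## 2x + 2y - 2xy with missing loci excluded
  XY <- X0 %*% t(X0)                       # sum x_l y_l over shared support?
  ## careful: x_l y_l only counts when both observed; X0 zeroes missing so ok
  rs <- function(M) M + t(M)
  Sx <- X0 %*% t(obs)                      # sum of x over loci observed in j
  comp <- obs %*% t(obs)                   # comparable loci counts
  W_raw <- rs(Sx) * 2 - 2 * XY
  scale <- ifelse(comp > 0, L / comp, NA_real_)
  W <- W_raw * scale
  diag(W) <- 0
  het <- X == 1L
  het[!obs] <- FALSE
  s_raw <- rowSums(het)
  n_i <- rowSums(obs)
  s <- s_raw * (L / pmax(n_i, 1))
  if (any(comp[upper.tri(comp)] == 0))
    stop("a pair of individuals shares no called locus")
  list(W = W, s = s, n = n, L = L)
}

.amova_ss <- function(W, s, groups) {
  n <- length(s)
  M <- 2 * n
  P_all <- sum(W[upper.tri(W)]) + sum(s)
  ss_total <- P_all / M
  ss_wg <- 0
  for (lab in unique(groups)) {
    idx <- which(groups == lab)
    Wg <- W[idx, idx, drop = FALSE]
    ss_wg <- ss_wg + (sum(Wg[upper.tri(Wg)]) + sum(s[idx])) / (2 * length(idx))
  }
  ss_wi <- sum(s) / 2
  c(among = ss_total - ss_wg, among_indiv = ss_wg - ss_wi,
    within_indiv = ss_wi, total = ss_total)
}

.amova_components <- function(ss, groups) {
  n <- length(groups)
  G <- length(unique(groups))
  m_g <- 2 * table(groups)
  M <- 2 * n
  df <- c(among = G - 1, among_indiv = n - G, within_indiv = n)
  ms <- ss[1:3] / df
  n_c <- (M - sum(m_g^2) / M) / (G - 1)
  sigma_c <- ms[["within_indiv"]]
  sigma_b <- (ms[["among_indiv"]] - sigma_c) / 2
  sigma_a <- (ms[["among"]] - ms[["among_indiv"]]) / n_c
  c(among = sigma_a, among_indiv = sigma_b, within_indiv = sigma_c)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Three-level AMOVA (among groups, among individuals within groups, within
#' individuals) on squared Euclidean allele-dosage distances, with
#' permutation significance for the among-group component obtained by
#' randomly reassigning whole individuals to groups. Percent variation
#' floors negative variance components at zero (the convention of the
#' standard codominant-AMOVA tools); raw components are reported unfloored.
#' The observed arrangement is included in the permutation numerator and
#' denominator.
#'
#' @param g a [geno_matrix]
#' @param grouping named character vector (accession id -> group label)
#'   or unnamed vector in accession order
#' @param n_permutations permutations for the among-group p-value
#'   (default 999; the conventional full analysis uses 9999)
#' @param seed RNG seed for the permutations
#' @return an `amova_result`: data.frame `table` (stratum, df, SS, MS,
#'   variance, pct), `phi` (Phi_AP, Phi_IS, Phi_IT), `p_value` (among-group
#'   component), `n_permutations`
#' @export
amova <- function(g, grouping, n_permutations = 999, seed = 1) {
  groups <- .check_grouping(g, grouping)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  parts <- .amova_parts(g)
  ss <- .amova_ss(parts$W, parts$s, groups)
  comp <- .amova_components(ss, groups)
  n <- parts$n; G <- length(unique(groups))
  df <- c(G - 1, n - G, n)
  floored <- pmax(comp, 0)
  pct <- 100 * floored / sum(floored)
  tot <- sum(floored)
  phi <- c(Phi_AP = unname(floored[1] / tot),
           Phi_IS = unname(if (floored[2] + floored[3] > 0)
             floored[2] / (floored[2] + floored[3]) else NA_real_),
           Phi_IT = unname((floored[1] + floored[2]) / tot))
  set.seed(seed)
  hits <- 1L
  for (b in seq_len(n_permutations)) {
    perm <- sample(groups)
    ss_p <- .amova_ss(parts$W, parts$s, perm)
    comp_p <- .amova_components(ss_p, perm)
    if (comp_p[1] >= comp[1] - 1e-12) hits <- hits + 1L
  }
  p <- hits / (n_permutations + 1)
  tab <- data.frame(
    stratum = c("among_groups", "among_indiv_within_groups",
                "within_indiv", "total"),
    df = c(df, sum(df)),
    SS = c(unname(ss[1:3]), unname(ss[4])),
    MS = c(unname(ss[1:3] / df), NA),
    variance = c(unname(comp), sum(comp)),
    pct = c(unname(pct), 100),
    stringsAsFactors = FALSE)
  structure(list(table = tab, phi = phi, p_value = p,
                 n_permutations = n_permutations),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (squared Euclidean dosage distances)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Phi_AP = %.4f (p = %.4g, %d permutations)\n",
              x$phi[["Phi_AP"]], x$p_value, x$n_permutations))
  invisible(x)
}

.check_grouping <- function(g, grouping) {
  ids <- accession_ids(g)
  if (!is.null(names(grouping))) {
    miss <- setdiff(ids, names(grouping))
    if (length(miss))
      stop("grouping lacks accessions: ", paste(miss, collapse = ", "))
    grouping <- grouping[ids]
  } else if (length(grouping) != length(ids)) {
    stop("unnamed grouping must have one label per accession")
  }
  groups <- as.character(grouping)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 accessions")
  groups
}

## two-level (among groups / within groups) AMOVA on squared dosage
## distances between individuals; the Phi-statistic F_ST analogue
.fst_pair <- function(D2, groups) {
  n <- length(groups)
  G <- length(unique(groups))
  ss_t <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (lab in unique(groups)) {
    idx <- which(groups == lab)
    Dg <- D2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(Dg[upper.tri(Dg)]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  ms_a <- ss_a / (G - 1)
  sigma_w <- ss_w / (n - G)
  n_c <- (n - sum(table(groups)^2) / n) / (G - 1)
  sigma_a <- (ms_a - sigma_w) / n_c
  if (sigma_a + sigma_w <= 0) return(0)
  sigma_a / (sigma_a + sigma_w)
}

#' Pairwise F_ST between groups with permutation significance
#'
#' For each pair of groups, a two-level AMOVA on squared Euclidean
#' allele-dosage distances gives the distance-based Phi-statistic analogue
#' of F_ST (`method = "phi"`, default); `method = "wc"` instead uses the
#' Weir-Cockerham theta estimator as an independent cross-check. P-values
#' come from permuting individuals between the two groups (observed
#' arrangement included in numerator and denominator).
#'
#' @param g a [geno_matrix]
#' @param grouping named character vector (accession -> group) or unnamed
#'   vector in accession order
#' @param n_permutations permutations per pair (default 999)
#' @param seed RNG seed
#' @param method `"phi"` (distance-based, default) or `"wc"`
#'   (Weir-Cockerham theta)
#' @return an `fst_matrix`: list with `fst` (symmetric matrix, NA diagonal),
#'   `p_values`, `method`, `n_permutations`
#' @export
pairwise_fst <- function(g, grouping, n_permutations = 999, seed = 1,
                         method = c("phi", "wc")) {
  method <- match.arg(method)
  groups <- .check_grouping(g, grouping)
  labs <- unique(groups)
  K <- length(labs)
  fst <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  pv <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  ## squared Euclidean dosage distance with pairwise-deletion rescaling
  X <- g$geno; L <- ncol(X)
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  G2 <- (X0^2) %*% t(obs)
  D2_raw <- G2 + t(G2) - 2 * (X0 %*% t(X0))
  compn <- obs %*% t(obs)
  D2 <- D2_raw * ifelse(compn > 0, L / compn, NA_real_)
  diag(D2) <- 0
  set.seed(seed)
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    idx <- which(groups %in% c(labs[a], labs[b]))
    gg <- groups[idx]
    stat <- function(labels) {
      if (method == "phi") .fst_pair(D2[idx, idx], labels)
      else wc_theta(g[idx, ], labels)
    }
    obs_fst <- stat(gg)
    hits <- 1L
    for (p in seq_len(n_permutations)) {
      if (stat(sample(gg)) >= obs_fst - 1e-12) hits <- hits + 1L
    }
    fst[a, b] <- fst[b, a] <- obs_fst
    pv[a, b] <- pv[b, a] <- hits / (n_permutations + 1)
  }
  structure(list(fst = fst, p_values = pv, method = method,
                 n_permutations = n_permutations), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("Pairwise F_ST (%s estimator, %d permutations)\n",
              x$method, x$n_permutations))
  print(round(x$fst, 4))
  invisible(x)
}

#' Multi-locus Weir-Cockerham theta
#'
#' The classic ANOVA-based F_ST estimator, combined over loci as the ratio
#' of summed variance components a / (a + b + c). Exposed as an independent
#' cross-check on the distance-based Phi estimator.
#'
#' @param g a [geno_matrix]
#' @param grouping group labels (named by accession or in accession order)
#' @return scalar theta (can be slightly negative near zero differentiation)
#' @export
wc_theta <- function(g, grouping) {
  groups <- .check_grouping(g, grouping)
  labs <- unique(groups)
  r <- length(labs)
  X <- g$geno
  num <- den <- 0
  for (l in seq_len(ncol(X))) {
    x <- X[, l]
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      xk <- x[groups == labs[k]]
      xk <- xk[!is.na(xk)]
      ni[k] <- length(xk)
      if (ni[k] == 0) next
      pi[k] <- sum(xk) / (2 * ni[k])
      hi[k] <- mean(xk == 1L)
    }
    if (any(ni < 2)) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(0)
  num / den
}
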