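#' MCMC configuration for admixture-model clustering
#'
#' Two natural scales exist: the conventional full analysis (burn-in
#' 10,000, run length 100,000, 10 replicates, K from 1 to 10) and a desk
#' scale for testing and simulation studies (burn-in 2,000, run length
#' 5,000, 3 replicates, K from 1 to 4), selected with `scale`.
#'
#' @param K_range inclusive integer range of K values to sweep
#' @param n_replicates replicate runs per K
#' @param burn_in discarded sweeps per run
#' @param run_length retained sweeps per run
#' @param alpha Dirichlet concentration for the membership prior (fixed,
#'   not sampled; default 1)
#' @param correlated_frequencies use the F-model (correlated allele
#'   frequencies) prior instead of independent Beta(1,1)
#' @param seed master seed; per-run seeds are derived from it
#' @param scale `"test"` or `"full"` presets, overridden by any explicitly
#'   supplied argument
#' @export
mcmc_config <- function(K_range = NULL, n_replicates = NULL, burn_in = NULL,
                        run_length = NULL, alpha = 1,
                        correlated_frequencies = FALSE, seed = 1,
                        scale = c("test", "full")) {
  scale <- match.arg(scale)
  preset <- if (scale == "full")
    list(K_range = 1:10, n_replicates = 10L, burn_in = 10000L,
         run_length = 100000L)
  else
    list(K_range = 1:4, n_replicates = 3L, burn_in = 2000L,
         run_length = 5000L)
  cfg <- list(
    K_range = if (is.null(K_range)) preset$K_range else as.integer(K_range),
    n_replicates = if (is.null(n_replicates)) preset$n_replicates
      else as.integer(n_replicates),
    burn_in = if (is.null(burn_in)) preset$burn_in else as.integer(burn_in),
    run_length = if (is.null(run_length)) preset$run_length
      else as.integer(run_length),
    alpha = alpha, correlated_frequencies = isTRUE(correlated_frequencies),
    seed = as.integer(seed))
  stopifnot(length(cfg$K_range) >= 1, all(cfg$K_range >= 1),
            cfg$n_replicates >= 1, cfg$burn_in >= 0, cfg$run_length >= 1,
            alpha > 0)
  class(cfg) <- "mcmc_config"
  cfg
}

#' One admixture-model Gibbs run
#'
#' Standard admixture-model Gibbs sampler: the cluster of origin of each
#' allele copy is sampled from its full conditional (proportional to
#' `q_ik` times the cluster allele frequency), cluster allele frequencies
#' from their Beta full conditional, and each accession's membership vector
#' `q_i` from Dirichlet(alpha + copy counts). Missing calls contribute no
#' allele copies. Posterior means are accumulated after burn-in, and the
#' model log-evidence is estimated as `lnP_D = mean(LL) - var(LL)/2` over
#' retained sweeps (the harmonic-approximation estimator conventionally
#' reported as Ln P(D)).
#'
#' @param g a [geno_matrix] with no all-missing accession
#' @param K number of clusters (>= 1)
#' @param cfg an [mcmc_config] supplying burn-in, run length, alpha and the
#'   frequency prior
#' @param seed run seed (defaults to `cfg$seed`)
#' @return an `admixture_replicate`: list with `K`, `q_mean` (accessions x
#'   K, rows summing to 1), `freq_mean` (K x loci), `lnP_D`, `loglik`
#'   (retained trace) and `seed`
#' @export
gibbs_admixture <- function(g, K, cfg = mcmc_config(), seed = cfg$seed) {
  if (K < 1) stop("K must be >= 1")
  if (any(rowSums(!is.na(g$geno)) == 0))
    stop("accession with all calls missing")
  set.seed(seed)
  res <- .gibbs_admixture_cpp(g$geno, as.integer(K), cfg$burn_in,
                              cfg$run_length, cfg$alpha,
                              cfg$correlated_frequencies)
  q <- res$q_mean
  dimnames(q) <- list(accession_ids(g), paste0("cluster", seq_len(K)))
  p <- res$freq_mean
  dimnames(p) <- list(paste0("cluster", seq_len(K)), locus_ids(g))
  ll <- res$loglik
  lnP_D <- mean(ll) - stats::var(ll) / 2
  if (length(ll) < 2) lnP_D <- mean(ll)
  structure(list(K = as.integer(K), q_mean = q, freq_mean = p,
                 lnP_D = lnP_D, loglik = ll, seed = as.integer(seed)),
            class = "admixture_replicate")
}

#' @export
print.admixture_replicate <- function(x, ...) {
  cat(sprintf("<admixture_replicate> K = %d, lnP(D) = %.2f (seed %d)\n",
              x$K, x$lnP_D, x$seed))
  invisible(x)
}

## per-run seed derived from (master seed, K, replicate); kept inside the
## 32-bit integer range
.derive_seed <- function(seed, K, rep) {
  as.integer((as.numeric(seed) + 100003 * K + 7919 * rep) %% 2147483647L)
}

#' Replicate admixture runs across a range of K
#'
#' Runs `cfg$n_replicates` independent chains for every K in `cfg$K_range`,
#' each with a distinct seed derived deterministically from the master seed,
#' K and the replicate index. Results are ordered by K then replicate.
#'
#' @param g a [geno_matrix]
#' @param cfg an [mcmc_config]
#' @return list of `admixture_replicate`
#' @export
run_K_sweep <- function(g, cfg = mcmc_config()) {
  out <- list()
  for (K in cfg$K_range) {
    for (r in seq_len(cfg$n_replicates)) {
      out[[length(out) + 1L]] <-
        gibbs_admixture(g, K, cfg, seed = .derive_seed(cfg$seed, K, r))
    }
  }
  out
}

#' Evanno delta-K table and optimal K
#'
#' From replicate `lnP_D` values per K: `L'(K) = mean_LK(K) - mean_LK(K-1)`,
#' `|L''(K)| = |L'(K+1) - L'(K)|`, and `deltaK = |L''(K)| / sd_LK`, defined
#' only for interior K (both neighbours present) with positive replicate
#' standard deviation. `chosen_K` maximises deltaK; when every deltaK is
#' zero or undefined, `chosen_K` is `NA` (undetermined).
#'
#' @param replicates list of `admixture_replicate` covering >= 3 consecutive
#'   K values with >= 2 replicates each
#' @return an `evanno_table`: data.frame (K, n_replicates, mean_LK, sd_LK,
#'   Lprime, abs_Lsecond, deltaK) with attribute/element `chosen_K`
#' @export
evanno <- function(replicates) {
  Ks <- vapply(replicates, function(r) as.integer(r$K), integer(1))
  lnp <- vapply(replicates, function(r) as.numeric(r$lnP_D), numeric(1))
  uK <- sort(unique(Ks))
  if (length(uK) < 3 || !all(diff(uK) == 1))
    stop("need >= 3 consecutive K values")
  cnt <- vapply(uK, function(k) sum(Ks == k), integer(1))
  if (any(cnt < 2)) stop("need >= 2 replicates at every K")
  mean_LK <- vapply(uK, function(k) mean(lnp[Ks == k]), numeric(1))
  sd_LK <- vapply(uK, function(k) stats::sd(lnp[Ks == k]), numeric(1))
  nK <- length(uK)
  Lp <- c(NA, diff(mean_LK))                       # L'(K), defined for K >= 2
  Ls <- rep(NA_real_, nK)                          # |L''(K)|, interior only
  Ls[2:(nK - 1)] <- abs(diff(Lp[-1]))
  dK <- Ls / sd_LK
  dK[!is.na(Ls) & sd_LK == 0] <- NA_real_
  if (any(!is.na(Ls) & sd_LK == 0))
    warning("sd(lnP_D) = 0 at some K; deltaK undefined there")
  tab <- data.frame(K = uK, n_replicates = cnt, mean_LK = mean_LK,
                    sd_LK = sd_LK, Lprime = Lp, abs_Lsecond = Ls,
                    deltaK = dK)
  chosen <- if (all(is.na(dK)) || all(dK[!is.na(dK)] == 0)) NA_integer_
            else uK[which.max(dK)]
  structure(list(table = tab, chosen_K = chosen), class = "evanno_table")
}

#' @export
print.evanno_table <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 5)
  if (is.na(x$chosen_K)) cat("chosen K: undetermined (flat deltaK)\n")
  else cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}

## best column permutation of q against a reference, by total |dq|;
## exhaustive for small K, greedy beyond
.best_perm <- function(q_ref, q) {
  K <- ncol(q_ref)
  cost <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    cost[a, b] <- sum(abs(q_ref[, a] - q[, b]))
  if (K <= 7) {
    perms <- .permutations(K)
    costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(K), p)]))
    perms[which.min(costs), ]
  } else {
    perm <- integer(K)
    used <- logical(K)
    for (a in order(apply(cost, 1, min))) {
      b <- which.min(ifelse(used, Inf, cost[a, ]))
      perm[a] <- b
      used[b] <- TRUE
    }
    perm
  }
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(K - 1)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Align replicate q-matrices across label switching
#'
#' Cluster labels are arbitrary within each MCMC run. Replicates at the
#' same K are aligned to the first by the column permutation minimising the
#' summed absolute membership difference (exhaustive over permutations for
#' K <= 7, greedy beyond), and a consensus (mean) q-matrix is computed over
#' the aligned replicates.
#'
#' @param replicates list of `admixture_replicate`, all at the same K
#' @return list with `replicates` (aligned copies) and `consensus_q`
#' @export
align_replicates <- function(replicates) {
  if (length(replicates) < 1) stop("need >= 1 replicate")
  Ks <- vapply(replicates, function(r) r$K, integer(1))
  if (length(unique(Ks)) != 1) stop("replicates mix different K")
  ref <- replicates[[1]]
  aligned <- lapply(replicates, function(r) {
    perm <- .best_perm(ref$q_mean, r$q_mean)
    r$q_mean <- r$q_mean[, perm, drop = FALSE]
    r$freq_mean <- r$freq_mean[perm, , drop = FALSE]
    colnames(r$q_mean) <- colnames(ref$q_mean)
    rownames(r$freq_mean) <- rownames(ref$freq_mean)
    r
  })
  qs <- lapply(aligned, function(r) r$q_mean)
  consensus <- Reduce(`+`, qs) / length(qs)
  list(replicates = aligned, consensus_q = consensus)
}
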