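# shared helpers: small constructors and independent oracles used across
# test files; everything here is built in code at test time

gm <- function(m, ids = NULL, loci = NULL) {
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(m)))
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, loci)
  geno_matrix(m)
}

# reference fixture is deterministic; build once per test run
fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- reference_fixture()
  fixture_env$fx
}

# independent O(n^3) UPGMA oracle: cluster distances recomputed each step
# as the mean over all original-member pairs (no running update), merges
# tie-broken the same declared way
upgma_oracle <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- lapply(seq_len(n), function(i) labels[i])
  heights <- numeric(0)
  merges <- list()
  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    for (i in seq_len(k)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      take <- FALSE
      if (dd < best_d - 1e-15) take <- TRUE
      else if (abs(dd - best_d) <= 1e-15) {
        key <- function(a, b) {
          sa <- sort(a); sb <- sort(b)
          if (lex_less(sb, sa)) list(sb, sa) else list(sa, sb)
        }
        cur <- key(clusters[[i]], clusters[[j]])
        win <- key(clusters[[best[1]]], clusters[[best[2]]])
        if (lex_less(cur[[1]], win[[1]]) ||
            (identical(cur[[1]], win[[1]]) && lex_less(cur[[2]], win[[2]])))
          take <- TRUE
      }
      if (take) { best <- c(i, j); best_d <- min(best_d, dd) }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_d / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(merge_members = merges, heights = heights)
}

# member sets per merge row of a upgma_tree, for oracle comparison
tree_merge_members <- function(tree) {
  members <- vector("list", nrow(tree$merge))
  get <- function(id) if (id < 0) tree$labels[-id] else members[[id]]
  for (r in seq_len(nrow(tree$merge))) {
    members[[r]] <- sort(c(get(tree$merge[r, 1]), get(tree$merge[r, 2])))
  }
  members
}

# brute-force three-level AMOVA sums of squares via explicit double loops
# over individuals and loci (independent of the package's matrix algebra)
amova_ss_oracle <- function(g, groups) {
  X <- g$geno
  n <- nrow(X); L <- ncol(X)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- 0; nc <- 0
    for (l in seq_len(L)) {
      x <- X[i, l]; y <- X[j, l]
      if (is.na(x) || is.na(y)) next
      ai <- c(rep(1, x), rep(0, 2 - x))
      aj <- c(rep(1, y), rep(0, 2 - y))
      for (u in 1:2) for (v in 1:2) tot <- tot + (ai[u] - aj[v])^2
      nc <- nc + 1
    }
    W[i, j] <- W[j, i] <- tot * L / nc
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    x <- X[i, ]; x <- x[!is.na(x)]
    s[i] <- sum(x == 1) * L / length(x)
  }
  M <- 2 * n
  pair_sum <- function(idx) {
    tot <- sum(s[idx])
    if (length(idx) > 1) {
      cb <- utils::combn(idx, 2)
      tot <- tot + sum(W[cbind(cb[1, ], cb[2, ])])
    }
    tot
  }
  ss_total <- pair_sum(seq_len(n)) / M
  ss_wg <- sum(vapply(unique(groups), function(lab) {
    idx <- which(groups == lab)
    pair_sum(idx) / (2 * length(idx))
  }, numeric(1)))
  ss_wi <- sum(s) / 2
  c(among = ss_total - ss_wg, among_indiv = ss_wg - ss_wi,
    within_indiv = ss_wi, total = ss_total)
}

# quick two-population simulation used in several files
two_pop_sim <- function(seed, n = 84, L = 91, F = 0.3) {
  simulate_genotypes(sim_config(K_true = 2, F = F, n_accessions = n,
                                n_loci = L, seed = seed))
}
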