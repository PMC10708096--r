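#' Allele-sharing distance between accessions
#'
#' Per locus with both calls non-missing, the distance between two diploid
#' genotypes is `|dosage_i - dosage_j| / 2` (equivalently 1 minus half the
#' shared-allele count: identical homozygotes 0, homozygote vs heterozygote
#' 0.5, opposite homozygotes 1, heterozygote pairs 0); the pairwise distance
#' is the mean over comparable loci. This is the standard missing-tolerant
#' genotype analogue of a per-site mismatch proportion (p-distance).
#'
#' @param g a [geno_matrix] with >= 2 accessions
#' @return a `dist_matrix`: list with `ids`, `d` (symmetric matrix in
#'   `[0, 1]`, zero diagonal) and `comparable_loci` (integer matrix)
#' @export
allele_sharing_distance <- function(g) {
  n <- n_accessions(g)
  if (n < 2) stop("need >= 2 accessions")
  X <- g$geno
  ids <- accession_ids(g)
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  comp <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    rows <- (i + 1):n
    both <- obs[rep(i, length(rows)), , drop = FALSE] & obs[rows, , drop = FALSE]
    dd <- abs(X0[rep(i, length(rows)), , drop = FALSE] -
                X0[rows, , drop = FALSE]) / 2
    dd[!both] <- 0
    nc <- rowSums(both)
    if (any(nc == 0))
      stop("zero comparable loci for pair (", ids[i], ", ",
           ids[rows[which(nc == 0)[1]]], ")")
    d[i, rows] <- rowSums(dd) / nc
    comp[i, rows] <- as.integer(nc)
  }
  d <- d + t(d)
  comp <- comp + t(comp)
  diag(comp) <- n_loci(g)
  structure(list(ids = ids, d = d, comparable_loci = comp),
            class = "dist_matrix")
}

## lexicographic comparison of two character vectors (shorter prefix wins)
.lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration: repeatedly merge the pair of clusters at
#' minimal distance, updating distances to other clusters as the
#' size-weighted arithmetic mean. The merge node's height is half the merge
#' distance, so the tree is ultrametric (all leaves equidistant from the
#' root). Ties are broken deterministically and order-invariantly: among
#' minimal pairs, the pair whose (sorted) member-id sets are
#' lexicographically smallest is merged.
#'
#' @param d a `dist_matrix` (see [allele_sharing_distance]) or a labelled
#'   symmetric matrix / `dist` object
#' @return a `upgma_tree`: list with hclust-style `merge` matrix, `height`
#'   (node heights = merge distance / 2, nondecreasing) and `labels`
#' @export
upgma <- function(d) {
  m <- if (inherits(d, "dist_matrix")) d$d else as.matrix(d)
  if (!all(is.finite(m))) stop("non-finite distances")
  n <- nrow(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  ## active clusters: id (hclust convention: -leaf or merge row), size,
  ## sorted member labels
  active <- lapply(seq_len(n), function(i)
    list(id = -i, size = 1L, members = labels[i]))
  D <- m
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dij <- D[i, j]
      if (dij < best_d - 1e-15) {
        best <- c(i, j); best_d <- dij
      } else if (abs(dij - best_d) <= 1e-15 && !is.null(best)) {
        ## tie: compare (smaller set, larger set) pairs lexicographically
        pair_key <- function(a, b) {
          if (.lex_less(active[[b]]$members, active[[a]]$members))
            list(active[[b]]$members, active[[a]]$members)
          else list(active[[a]]$members, active[[b]]$members)
        }
        cur <- pair_key(i, j); win <- pair_key(best[1], best[2])
        if (.lex_less(cur[[1]], win[[1]]) ||
            (identical(cur[[1]], win[[1]]) && .lex_less(cur[[2]], win[[2]]))) {
          best <- c(i, j); best_d <- min(best_d, dij)
        }
      }
    }
    i <- best[1]; j <- best[2]
    ## children ordered by lexicographically smaller member set, so the
    ## serialised tree is deterministic
    if (.lex_less(active[[j]]$members, active[[i]]$members)) {
      tmp <- i; i <- j; j <- tmp
    }
    merge[step, ] <- c(active[[i]]$id, active[[j]]$id)
    height[step] <- best_d / 2
    ni <- active[[i]]$size; nj <- active[[j]]$size
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    new_cluster <- list(id = step, size = ni + nj,
                        members = sort(c(active[[i]]$members,
                                         active[[j]]$members)))
    active <- c(active[keep], list(new_cluster))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 n = n), class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.4g\n",
              x$n, max(x$height)))
  invisible(x)
}

#' Convert a UPGMA tree to an ape phylo object
#'
#' Branch lengths are differences of node heights, so leaf-to-root path
#' lengths equal the root height (ultrametric).
#'
#' @param tree a `upgma_tree`
#' @return an `ape::phylo`
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- tree$n
  if (n == 1) stop("cannot build a phylo from a single leaf")
  n_nodes <- n - 1
  ## phylo numbering: tips 1..n, internal n+1..2n-1; root = n+1 is the
  ## last merge, so merge row r -> phylo node n + (n_nodes - r + 1)
  node_of <- function(id) if (id < 0) -id else n + (n_nodes - id + 1L)
  edges <- matrix(0L, 2 * n_nodes, 2)
  lens <- numeric(2 * n_nodes)
  h_of <- function(id) if (id < 0) 0 else tree$height[id]
  for (r in seq_len(n_nodes)) {
    parent <- node_of(r)
    for (s in 1:2) {
      child_id <- tree$merge[r, s]
      e <- 2 * (r - 1) + s
      edges[e, ] <- c(parent, node_of(child_id))
      lens[e] <- tree$height[r] - h_of(child_id)
    }
  }
  phy <- list(edge = edges, edge.length = lens, tip.label = tree$labels,
              Nnode = n_nodes)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Cut an ultrametric tree into k groups
#'
#' Removes the `k - 1` highest internal nodes (for the monotone UPGMA tree,
#' equivalently undoes the last `k - 1` merges) and returns the leaf blocks.
#'
#' @param tree a `upgma_tree`
#' @param k number of groups, `1 <= k <=` number of leaves
#' @return named integer vector: group index (1..k) per leaf label
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- tree$n
  if (k < 1 || k > n) stop("k must be in 1..", n)
  comp <- seq_len(n)
  if (k < n) {
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    cluster_rep <- integer(n - 1)
    for (r in seq_len(n - k)) {
      ids <- tree$merge[r, ]
      reps <- vapply(ids, function(id)
        if (id < 0) find(-id) else find(cluster_rep[id]), integer(1))
      comp[reps[2]] <- reps[1]
      cluster_rep[r] <- reps[1]
    }
    comp <- vapply(seq_len(n), function(i) { while (comp[i] != i) i <- comp[i]; i },
                   integer(1))
  }
  grp <- as.integer(factor(comp, levels = unique(comp)))
  stats::setNames(grp, tree$labels)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are excluded
#' from the percent-variance denominator and reported separately; no
#' Cailliez/Lingoes correction is applied.
#'
#' @param d a `dist_matrix`, `dist`, or labelled symmetric matrix
#' @param n_axes number of axes to return (truncated with a warning if it
#'   exceeds the positive-eigenvalue count)
#' @return a `pcoa_result`: list with `coordinates` (accessions x axes),
#'   `eigenvalues` (all, descending), `pct_variance` (per returned axis, %
#'   of the positive-eigenvalue total) and `negative_eigenvalues`
#' @export
pcoa <- function(d, n_axes = 2) {
  m <- if (inherits(d, "dist_matrix")) d$d else as.matrix(d)
  n <- nrow(m)
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  if (length(pos) == 0) stop("no positive eigenvalues: degenerate input")
  if (n_axes > length(pos)) {
    warning("n_axes = ", n_axes, " exceeds positive-eigenvalue count (",
            length(pos), "); truncated")
    n_axes <- length(pos)
  }
  axes <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(vals[axes]), n_axes, n_axes)
  dimnames(coords) <- list(rownames(m), paste0("PC", seq_len(n_axes)))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 pct_variance = 100 * vals[axes] / sum(vals[pos]),
                 negative_eigenvalues = vals[vals < -tol]),
            class = "pcoa_result")
}
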