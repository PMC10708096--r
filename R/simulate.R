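#' Simulation configuration for F-model genotype data
#'
#' Describes a synthetic diploid SNP dataset drawn from `K_true` ancestral
#' populations whose allele frequencies are linked to a shared ancestral
#' frequency through the F-model: at each locus the ancestral frequency
#' `p_A ~ Uniform(0.1, 0.9)` and each population's frequency is
#' `Beta(p_A (1-F)/F, (1-p_A) (1-F)/F)`, so `F` acts as a drift /
#' differentiation knob (larger `F`, more differentiated populations).
#' Individual admixture proportions `q` are Dirichlet(`alpha`, ...);
#' by convention `alpha = 0` means pure (one-hot) population membership,
#' assigned round-robin across populations.
#'
#' Defective loci of three classes can be injected on disjoint locus sets
#' after genotypes are drawn: monomorphic loci (all calls ref/ref),
#' high-missingness loci (missing fraction drawn Uniform(0.11, 0.5)), and
#' low-MAF loci (resampled so the realised sample MAF is below 0.05 but
#' above zero). `n_design_failed` loci are flagged in the truth record
#' only (assay design failure is a metadata property, not a genotype one).
#' Clean loci are guaranteed post hoc to be polymorphic with MAF >= 0.05
#' and missingness <= 10%, so quality-control filter counts are exact.
#'
#' @param K_true number of ancestral populations (>= 1)
#' @param F drift intensity in (0, 1); scalar or one value per population
#' @param n_accessions,n_loci dataset dimensions
#' @param n_chromosomes,chromosome_length_bp genome layout for locus placement
#' @param admixture_alpha Dirichlet concentration for q; 0 = one-hot
#' @param missing_rate baseline per-call missingness fraction
#' @param n_monomorphic,n_high_missing,n_low_maf,n_design_failed defect counts
#' @param n_clone_pairs number of clone (synonym) pairs to inject by copying
#'   rows verbatim; ignored when `clone_map` is given
#' @param hybrid_specs list of `c(child, mother, father)` accession-id
#'   triples; the child row is overwritten with one random transmitted
#'   allele per locus from each parent (missing parent call gives a missing
#'   transmitted allele)
#' @param seed integer RNG seed; the whole dataset is reproducible from it
#' @param accession_ids optional character vector of accession names
#' @param q_matrix optional n x K matrix of membership proportions
#'   overriding `admixture_alpha`
#' @param clone_map optional named character vector `copy = source` giving
#'   explicit clone pairs
#' @return a validated `sim_config` list
#' @export
sim_config <- function(K_true = 2, F = 0.3, n_accessions = 84, n_loci = 91,
                       n_chromosomes = 15, chromosome_length_bp = 30e6,
                       admixture_alpha = 0, missing_rate = 0,
                       n_monomorphic = 0, n_high_missing = 0, n_low_maf = 0,
                       n_design_failed = 0, n_clone_pairs = 0,
                       hybrid_specs = list(), seed = 1,
                       accession_ids = NULL, q_matrix = NULL,
                       clone_map = NULL) {
  stopifnot(K_true >= 1, n_accessions >= 2, n_loci >= 1,
            n_chromosomes >= 1, chromosome_length_bp >= n_loci,
            admixture_alpha >= 0, missing_rate >= 0, missing_rate <= 1)
  if (any(F <= 0) || any(F >= 1)) stop("F must lie in (0, 1)")
  n_def <- n_monomorphic + n_high_missing + n_low_maf + n_design_failed
  if (n_def > n_loci)
    stop("defect counts exceed n_loci (", n_def, " > ", n_loci, ")")
  if (n_low_maf > 0 && n_accessions < 11)
    stop("low-MAF injection needs >= 11 accessions to realise 0 < MAF < 0.05")
  if (!is.null(accession_ids) && length(accession_ids) != n_accessions)
    stop("accession_ids must have length n_accessions")
  if (!is.null(q_matrix)) {
    q_matrix <- as.matrix(q_matrix)
    if (nrow(q_matrix) != n_accessions || ncol(q_matrix) != K_true)
      stop("q_matrix must be n_accessions x K_true")
    if (any(abs(rowSums(q_matrix) - 1) > 1e-9))
      stop("q_matrix rows must sum to 1")
  }
  cfg <- list(K_true = as.integer(K_true), F = rep_len(F, K_true),
              n_accessions = as.integer(n_accessions),
              n_loci = as.integer(n_loci),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              admixture_alpha = admixture_alpha,
              missing_rate = missing_rate,
              n_monomorphic = as.integer(n_monomorphic),
              n_high_missing = as.integer(n_high_missing),
              n_low_maf = as.integer(n_low_maf),
              n_design_failed = as.integer(n_design_failed),
              n_clone_pairs = as.integer(n_clone_pairs),
              hybrid_specs = hybrid_specs, seed = as.integer(seed),
              accession_ids = accession_ids, q_matrix = q_matrix,
              clone_map = clone_map)
  class(cfg) <- "sim_config"
  cfg
}

## draw one transmitted allele (0/1 count) from a parent dosage
.transmit <- function(dos) {
  out <- integer(length(dos))
  out[is.na(dos)] <- NA_integer_
  out[!is.na(dos) & dos == 0L] <- 0L
  out[!is.na(dos) & dos == 2L] <- 1L
  het <- !is.na(dos) & dos == 1L
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

## draw a fresh dosage for accession i at loci l from the model
.model_dosage <- function(q_i, P, l) {
  K <- nrow(P)
  dos <- integer(length(l))
  for (copy in 1:2) {
    z <- if (K == 1) rep(1L, length(l)) else
      sample.int(K, length(l), replace = TRUE, prob = q_i)
    dos <- dos + stats::rbinom(length(l), 1L, P[cbind(z, l)])
  }
  dos
}

#' Simulate a genotype dataset with known truth
#'
#' Draws genotypes under the F-model described in [sim_config], applies
#' baseline missingness, then overwrites hybrid rows (Mendelian transmission
#' from named parents) and clone rows (verbatim copies), and finally injects
#' the configured defective loci on disjoint locus sets. Repairs needed to
#' make defect classes exactly verifiable post hoc (e.g. keeping clean loci
#' polymorphic with MAF >= 0.05) only ever touch rows that are neither
#' clones nor hybrids, so clone identity and pedigrees stay intact.
#'
#' @param cfg a [sim_config]
#' @return a list with elements `genotypes` (a [geno_matrix]), `metadata`
#'   (data.frame name/status/origin/maturation), and `truth` (list with
#'   `ancestral_freqs`, `population_freqs` (K x loci), `q_true`,
#'   `pop_assignment`, `defect_labels`, `design_failed_ids`, `clone_map`,
#'   `pedigree`, `seed`)
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions; L <- cfg$n_loci; K <- cfg$K_true
  ids <- if (is.null(cfg$accession_ids)) sprintf("ACC%03d", seq_len(n)) else
    cfg$accession_ids

  ## locus placement: uniform random distinct (chromosome, position)
  chrom <- sort(sample.int(cfg$n_chromosomes, L, replace = TRUE))
  pos <- integer(L)
  repeat {
    pos <- sample.int(cfg$chromosome_length_bp, L, replace = TRUE)
    if (!anyDuplicated(paste(chrom, pos))) break
  }
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  loci <- data.frame(locus_id = sprintf("SNP%03d", seq_len(L)),
                     chromosome = paste0("chr", chrom), position = pos,
                     ref = ref, alt = unname(alt), stringsAsFactors = FALSE)

  ## F-model frequencies
  p_anc <- stats::runif(L, 0.1, 0.9)
  P <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    Fk <- cfg$F[k]
    P[k, ] <- stats::rbeta(L, p_anc * (1 - Fk) / Fk,
                           (1 - p_anc) * (1 - Fk) / Fk)
  }
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)

  ## membership proportions
  if (!is.null(cfg$q_matrix)) {
    q <- cfg$q_matrix
  } else if (cfg$admixture_alpha == 0) {
    pop <- rep_len(seq_len(K), n)
    q <- matrix(0, n, K); q[cbind(seq_len(n), pop)] <- 1
  } else {
    gm <- matrix(stats::rgamma(n * K, shape = cfg$admixture_alpha), n, K)
    q <- gm / rowSums(gm)
  }
  pop_assignment <- max.col(q, ties.method = "first")

  ## genotype draw
  g <- matrix(NA_integer_, n, L, dimnames = list(ids, loci$locus_id))
  for (i in seq_len(n)) g[i, ] <- .model_dosage(q[i, ], P, seq_len(L))

  ## baseline missingness (before cloning so clones share the pattern)
  if (cfg$missing_rate > 0)
    g[stats::runif(n * L) < cfg$missing_rate] <- NA_integer_

  ## hybrids
  pedigree <- data.frame(child = character(0), mother = character(0),
                         father = character(0), stringsAsFactors = FALSE)
  for (hs in cfg$hybrid_specs) {
    hs <- unlist(hs, use.names = FALSE)
    if (length(hs) != 3) stop("hybrid_specs entries must be (child, mother, father)")
    if (!all(hs %in% ids))
      stop("hybrid spec names unknown accession: ",
           paste(setdiff(hs, ids), collapse = ", "))
    child <- hs[1]; mo <- hs[2]; fa <- hs[3]
    t1 <- .transmit(g[mo, ]); t2 <- .transmit(g[fa, ])
    g[child, ] <- ifelse(is.na(t1) | is.na(t2), NA_integer_, t1 + t2)
    pedigree <- rbind(pedigree, data.frame(child = child, mother = mo,
                                           father = fa))
  }

  ## clones
  clone_map <- cfg$clone_map
  if (is.null(clone_map) && cfg$n_clone_pairs > 0) {
    pool <- setdiff(ids, pedigree$child)
    picks <- sample(pool, 2 * cfg$n_clone_pairs)
    clone_map <- stats::setNames(picks[seq(1, length(picks), 2)],
                                 picks[seq(2, length(picks), 2)])
  }
  if (!is.null(clone_map)) {
    if (!all(c(names(clone_map), clone_map) %in% ids))
      stop("clone_map names unknown accession")
    for (copy in names(clone_map)) g[copy, ] <- g[clone_map[[copy]], ]
  }

  ## rows safe to modify during repairs
  clone_rows <- unique(c(names(clone_map), unname(clone_map)))
  free_rows <- which(!(ids %in% c(clone_rows, pedigree$child)))
  if (length(free_rows) == 0) free_rows <- seq_len(n)

  ## defect injection on disjoint locus sets
  defect_labels <- rep("clean", L)
  n_def <- cfg$n_monomorphic + cfg$n_high_missing + cfg$n_low_maf +
    cfg$n_design_failed
  if (n_def > 0) {
    pick <- sample.int(L, n_def)
    sets <- split(pick, rep(c("monomorphic", "high_missing", "low_maf",
                              "design_failed"),
                            c(cfg$n_monomorphic, cfg$n_high_missing,
                              cfg$n_low_maf, cfg$n_design_failed)))
    for (l in sets$monomorphic) {
      g[, l] <- 0L
      defect_labels[l] <- "monomorphic"
    }
    for (l in sets$high_missing) {
      frac <- stats::runif(1, 0.11, 0.5)
      g[sample.int(n, ceiling(frac * n)), l] <- NA_integer_
      ## must stay polymorphic so the cascade counts it as high-missing
      obs <- g[, l][!is.na(g[, l])]
      if (length(obs) == 0 || all(obs == 0L) || all(obs == 2L)) {
        cand <- free_rows[!is.na(g[free_rows, l])]
        if (length(cand) == 0) cand <- which(!is.na(g[, l]))
        g[cand[1], l] <- 1L
      }
      defect_labels[l] <- "high_missing"
    }
    for (l in sets$low_maf) {
      g[, l] <- 0L
      m_max <- max(1L, as.integer(floor(0.05 * 2 * n - 1e-9)) - 1L)
      m <- sample.int(m_max, 1)
      rows <- if (length(free_rows) >= m) sample(free_rows, m) else
        sample.int(n, m)
      g[rows, l] <- 1L
      defect_labels[l] <- "low_maf"
    }
    for (l in sets$design_failed) defect_labels[l] <- "design_failed"
  }

  ## repair clean loci so the cascade retains exactly the clean set:
  ## polymorphic, missingness <= 10%, MAF >= 0.05
  clean <- which(defect_labels == "clean")
  for (l in clean) {
    miss <- which(is.na(g[, l]))
    over <- length(miss) - floor(0.10 * n)
    if (over > 0) {
      fill <- intersect(miss, free_rows)
      if (length(fill) < over) fill <- miss
      fill <- fill[seq_len(over)]
      for (i in fill) g[i, l] <- .model_dosage(q[i, ], P, l)
    }
    guard <- 0L
    repeat {
      col <- g[, l]
      called <- which(!is.na(col))
      p <- sum(col[called]) / (2 * length(called))
      if (min(p, 1 - p) >= 0.05) break
      maj <- if (p < 0.5) 0L else 2L
      cand <- intersect(free_rows, called[col[called] == maj])
      if (length(cand) == 0) cand <- called[col[called] == maj]
      g[cand[1], l] <- 1L
      guard <- guard + 1L
      if (guard > 2L * n) stop("could not repair clean locus ", l)
    }
  }

  gm <- geno_matrix(g, loci)
  gm$loci$maf <- unname(locus_maf(gm))

  mat_class <- c("EEM", "MLM", "EM")
  metadata <- data.frame(
    name = ids,
    status = ifelse(ids %in% pedigree$child, "hybrid", "old_cultivar"),
    origin = "-",
    maturation = mat_class[((pop_assignment - 1) %% 3) + 1],
    stringsAsFactors = FALSE)

  truth <- list(ancestral_freqs = p_anc, population_freqs = P,
                q_true = q, pop_assignment = pop_assignment,
                defect_labels = defect_labels,
                design_failed_ids = loci$locus_id[defect_labels ==
                                                    "design_failed"],
                clone_map = clone_map, pedigree = pedigree,
                seed = cfg$seed)
  list(genotypes = gm, metadata = metadata, truth = truth)
}

#' Deterministic reference dataset mirroring the litchi germplasm study design
#'
#' A fixed-seed synthetic dataset of 84 accessions x 150 loci on 15
#' chromosomes, built on the packaged accession metadata: two differentiated
#' source populations (extremely-early- vs middle-to-late-maturing
#' accessions, F = 0.3) with the early-maturing accessions as an admixed
#' intermediate set (q = 0.5/0.5); six clone (synonym) relationships
#' reproducing the five documented synonym groups; all twelve hybrids drawn
#' from named parents (stand-in parents, noted below, are used where a true
#' parent is not part of the panel); and exactly 1 design-failed, 28
#' monomorphic, 10 high-missingness (> 10%) and 20 low-MAF (< 5%) loci on
#' disjoint sets, leaving 91 clean loci.
#'
#' The genotypes are synthetic: only the metadata, dataset shape, defect
#' counts and relationship structure mirror the real panel. Stand-in
#' parents: 'A16' uses 'Yuanzao' for its unavailable seed parent; '05-4'
#' and '08-7' use middle-to-late cultivar pairs.
#'
#' @return as [simulate_genotypes]: list(genotypes, metadata, truth)
#' @export
reference_fixture <- function() {
  meta <- read_metadata(system.file("extdata", "litchi_accessions.csv",
                                    package = "snpdiv"))
  qmap <- c(EEM = 1, EM = NA, MLM = 2)
  q <- matrix(0, nrow(meta), 2)
  for (i in seq_len(nrow(meta))) {
    k <- qmap[[meta$maturation[i]]]
    if (is.na(k)) q[i, ] <- c(0.5, 0.5) else q[i, k] <- 1
  }
  clone_map <- c(Yuhebao = "Sanyuehong",
                 Nanxizaosheng = "Shuidong",
                 Dahongpao = "Dazao",
                 Siyuehong = "Dazao",
                 Lanzhu = "Zengchengjinfeng",
                 Dachenzi = "Yuanhong")
  hybrids <- list(
    c("Guinuo-1", "Guiwei", "Nuomici"),
    c("Guinuo-2", "Guiwei", "Nuomici"),
    c("Guinuo-3", "Guiwei", "Nuomici"),
    c("Zaogui", "Zaoli1hao", "Guiwei"),
    c("Zaonuo", "Zaoli1hao", "Nuomici"),
    c("Honggui", "Hongxiuqiu", "Guiwei"),
    c("Guihong", "Guiwei", "Hongxiuqiu"),
    c("06-9", "Heiye", "Feizixiao"),
    c("A16", "Yuanzao", "Sanyuehong"),
    c("08-1", "YNW01", "Feizixiao"),
    c("05-4", "Huaizhi", "Nuomici"),
    c("08-7", "Guiwei", "Huaizhi"))
  cfg <- sim_config(K_true = 2, F = 0.3, n_accessions = 84, n_loci = 150,
                    n_chromosomes = 15, chromosome_length_bp = 30e6,
                    missing_rate = 0.03, n_monomorphic = 28,
                    n_high_missing = 10, n_low_maf = 20, n_design_failed = 1,
                    hybrid_specs = hybrids, seed = 4242,
                    accession_ids = meta$name, q_matrix = q,
                    clone_map = clone_map)
  out <- simulate_genotypes(cfg)
  out$metadata <- meta
  out
}
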