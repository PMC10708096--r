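test_that("amova SS match the brute-force pairwise-distance oracle", {
  set.seed(3)
  m <- matrix(sample(c(0:2, NA), 24, TRUE, prob = c(.3, .3, .3, .1)), 6, 4)
  g <- gm(m)
  groups <- rep(c("A", "B", "C"), each = 2)
  am <- amova(g, groups, n_permutations = 9, seed = 1)
  want <- amova_ss_oracle(g, groups)
  expect_equal(am$table$SS, unname(want[c("among", "among_indiv",
                                          "within_indiv", "total")]),
               tolerance = 1e-9)
  # df identity: 2N - 1
  expect_equal(am$table$df[4], 2 * 6 - 1)
})

test_that("SS partition identity holds on random inputs", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(c(6, 8, 10), 1)
    m <- matrix(sample(c(0:2, NA), n * 12, TRUE,
                       prob = c(.35, .25, .25, .15)), n, 12)
    g <- gm(m)
    groups <- sample(rep(c("x", "y"), length.out = n))
    if (min(table(groups)) < 2) next
    am <- amova(g, groups, n_permutations = 1, seed = s)
    expect_equal(am$table$SS[4], sum(am$table$SS[1:3]), tolerance = 1e-9)
  }
})

test_that("maximally differentiated groups put 100% of variance among groups", {
  g <- gm(matrix(c(rep(0L, 16), rep(2L, 16)), 8, 4, byrow = TRUE))
  groups <- rep(c("A", "B"), each = 4)
  am <- amova(g, groups, n_permutations = 99, seed = 1)
  expect_equal(am$table$pct[1], 100, tolerance = 1e-9)
  expect_equal(am$table$pct[2], 0, tolerance = 1e-9)
  expect_equal(am$table$pct[3], 0, tolerance = 1e-9)
  expect_equal(am$phi[["Phi_AP"]], 1, tolerance = 1e-9)
  expect_lte(am$p_value, 0.05)
})

test_that("null splits of one population give ~0% among-group variance", {
  pcts <- numeric(10); ps <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_genotypes(sim_config(K_true = 1, F = 0.1,
                                         n_accessions = 40, n_loci = 60,
                                         seed = s))
    groups <- rep(c("A", "B"), 20)
    am <- amova(sim$genotypes, groups, n_permutations = 99, seed = s)
    pcts[s] <- am$table$pct[1]
    ps[s] <- am$p_value
  }
  expect_true(all(pcts < 3))
  expect_gte(sum(ps >= 0.05), 8L)
})

test_that("permutation p-values are seeded and label-name invariant", {
  sim <- two_pop_sim(5, n = 24, L = 30)
  groups <- c("A", "B")[sim$truth$pop_assignment]
  a <- amova(sim$genotypes, groups, n_permutations = 99, seed = 11)
  b <- amova(sim$genotypes, groups, n_permutations = 99, seed = 11)
  expect_identical(a$p_value, b$p_value)
  renamed <- c(A = "pop_red", B = "pop_blue")[groups]
  c_ <- amova(sim$genotypes, unname(renamed), n_permutations = 99, seed = 11)
  expect_equal(a$table$SS, c_$table$SS)
  expect_identical(a$p_value, c_$p_value)
})

test_that("amova rejects degenerate groupings", {
  g <- gm(matrix(0:2, 3, 4))
  expect_error(amova(g, c("A", "A", "B"), 9), ">= 2 accessions")
  expect_error(amova(g, c("A", "A", "A"), 9), ">= 2 groups")
  g2 <- gm(matrix(rep(0:2, 4), 4, 3))
  expect_error(amova(g2, c("A", "A", "B", "B"), 0), "n_permutations")
})

test_that("pairwise F_ST hits the fixation bound and the null", {
  g <- gm(matrix(c(rep(0L, 16), rep(2L, 16)), 8, 4, byrow = TRUE))
  groups <- rep(c("A", "B"), each = 4)
  fst <- pairwise_fst(g, groups, n_permutations = 19, seed = 1)
  expect_equal(fst$fst["A", "B"], 1, tolerance = 1e-12)
  expect_equal(wc_theta(g, groups), 1, tolerance = 1e-9)
  # identical duplicated groups: F_ST ~ 0 at 84 x 91 scale
  vals <- vapply(1:10, function(s) {
    sim <- simulate_genotypes(sim_config(K_true = 1, F = 0.1,
                                         n_accessions = 84, n_loci = 91,
                                         seed = s))
    X <- sim$genotypes$geno
    dup <- rbind(X, X)
    rownames(dup) <- c(paste0("a_", rownames(X)), paste0("b_", rownames(X)))
    gd <- geno_matrix(dup)
    groups <- rep(c("A", "B"), each = 84)
    pairwise_fst(gd, groups, n_permutations = 1, seed = s)$fst["A", "B"]
  }, numeric(1))
  expect_true(all(abs(vals) < 0.02))
  # split halves of one group centre on zero across seeds
  split_vals <- vapply(1:10, function(s) {
    sim <- simulate_genotypes(sim_config(K_true = 1, F = 0.1,
                                         n_accessions = 44, n_loci = 60,
                                         seed = 100 + s))
    groups <- rep(c("A", "B"), 22)
    pairwise_fst(sim$genotypes, groups, n_permutations = 1,
                 seed = s)$fst["A", "B"]
  }, numeric(1))
  expect_lt(abs(mean(split_vals)), 0.02)
})

test_that("estimated F_ST increases with simulated drift and orders pairs", {
  est <- vapply(c(0.05, 0.30), function(F) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_genotypes(sim_config(K_true = 2, F = F,
                                           n_accessions = 40, n_loci = 60,
                                           seed = s))
      groups <- c("A", "B")[sim$truth$pop_assignment]
      pairwise_fst(sim$genotypes, groups, n_permutations = 1,
                   seed = 1)$fst["A", "B"]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(est[2], est[1])
  # 3 populations with unequal drift: pair with the high-drift population
  # shows larger F_ST in >= 9 of 10 seeds
  wins <- 0L
  for (s in 1:10) {
    sim <- simulate_genotypes(sim_config(K_true = 3, F = c(0.05, 0.05, 0.4),
                                         n_accessions = 45, n_loci = 91,
                                         seed = s))
    groups <- c("A", "B", "C")[sim$truth$pop_assignment]
    fst <- pairwise_fst(sim$genotypes, groups, n_permutations = 1, seed = 1)
    wins <- wins + (fst$fst["A", "C"] > fst$fst["A", "B"])
  }
  expect_gte(wins, 9L)
})

test_that("phi and Weir-Cockerham estimators broadly agree away from 0", {
  sim <- two_pop_sim(9, n = 60, L = 80, F = 0.3)
  groups <- c("A", "B")[sim$truth$pop_assignment]
  phi <- pairwise_fst(sim$genotypes, groups, n_permutations = 1,
                      seed = 1)$fst["A", "B"]
  wc <- pairwise_fst(sim$genotypes, groups, n_permutations = 1, seed = 1,
                     method = "wc")$fst["A", "B"]
  # the two estimators differ by construction (allele-level ANOVA with a
  # heterozygosity correction vs dosage-distance variance ratio); require
  # broad agreement only
  expect_lt(abs(phi - wc), 0.2)
  expect_gt(phi, 0.15)
  expect_gt(wc, 0.15)
})
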