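test_that("filter cascade reproduces the fixture's category counts", {
  fx <- get_fixture()
  res <- apply_filter_cascade(fx$genotypes, fx$truth$design_failed_ids,
                              missing_max = 0.10, maf_min = 0.05)
  rep <- res$report
  expect_equal(rep$n_design_failed, 1L)
  expect_equal(rep$n_monomorphic, 28L)
  expect_equal(rep$n_high_missing, 10L)
  expect_equal(rep$n_low_maf, 20L)
  expect_equal(length(rep$retained_locus_ids), 91L)
  expect_equal(n_loci(res$genotypes), 91L)
})

test_that("cascade assigns each locus to its first triggering category", {
  # no defects: everything retained
  sim <- simulate_genotypes(sim_config(n_accessions = 30, n_loci = 20,
                                       seed = 2))
  rep0 <- apply_filter_cascade(sim$genotypes)$report
  expect_equal(length(rep0$retained_locus_ids), 20L)
  expect_equal(rep0$n_monomorphic + rep0$n_high_missing + rep0$n_low_maf +
                 rep0$n_design_failed, 0L)
  # a locus both monomorphic and 50% missing counts as monomorphic only
  m <- matrix(1L, 4, 2)
  m[, 1] <- c(0L, 0L, NA, NA)
  g <- gm(m)
  rep1 <- apply_filter_cascade(g, missing_max = 0.10)$report
  expect_equal(rep1$n_monomorphic, 1L)
  expect_equal(rep1$n_high_missing, 0L)
  # design-failed takes precedence over everything
  rep2 <- apply_filter_cascade(g, design_failed_ids = "L01")$report
  expect_equal(rep2$n_design_failed, 1L)
  expect_equal(rep2$n_monomorphic, 0L)
})

test_that("filter report arithmetic identity holds on random matrices", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:30, 1); L <- sample(3:40, 1)
    m <- matrix(sample(c(0:2, NA), n * L, TRUE,
                       prob = c(.4, .2, .2, .2)), n, L)
    g <- gm(m)
    df <- sample(locus_ids(g), sample(0:2, 1))
    rep <- apply_filter_cascade(g, df)$report
    expect_equal(rep$n_input - rep$n_design_failed - rep$n_monomorphic -
                   rep$n_high_missing - rep$n_low_maf,
                 length(rep$retained_locus_ids))
    expect_equal(sum(table(rep$category)), rep$n_input)
  }
})

test_that("heterozygosity matches definitions and the 1 - sum(p_i^2) identity", {
  # p = 0.5 gives He = 0.5; all-het column gives Ho = 1
  g <- gm(matrix(c(0L, 2L, 1L, 1L), 2, 2))
  h <- heterozygosity(g)
  expect_equal(h$per_locus$He, c(0.5, 0.5))
  expect_equal(h$per_locus$Ho, c(0, 1))
  # identity oracle on the fixture: He = 2p(1-p) = 1 - p^2 - (1-p)^2
  fx <- get_fixture()
  gf <- apply_filter_cascade(fx$genotypes,
                             fx$truth$design_failed_ids)$genotypes
  h2 <- heterozygosity(gf)
  oracle <- vapply(seq_len(n_loci(gf)), function(j) {
    x <- gf$geno[, j]; x <- x[!is.na(x)]
    n_alt <- sum(x); n_tot <- 2 * length(x)
    p <- n_alt / n_tot
    1 - p^2 - (1 - p)^2
  }, numeric(1))
  expect_equal(h2$per_locus$He, oracle, tolerance = 1e-12)
  # biallelic bound
  expect_true(all(h2$per_locus$He <= 0.5 + 1e-12))
  # unbiased option increases He for polymorphic loci
  h3 <- heterozygosity(gf, unbiased = TRUE)
  poly <- h2$per_locus$He > 0
  expect_true(all(h3$per_locus$He[poly] > h2$per_locus$He[poly]))
})

test_that("group summaries exclude group-missing loci and cover all groups", {
  m <- matrix(c(0L, 1L, 2L, NA,
                NA, 1L, 0L, 0L), 4, 2)
  g <- gm(m)
  grp <- stats::setNames(c("a", "a", "b", "b"), accession_ids(g))
  h <- heterozygosity(g, grp)
  expect_setequal(h$summary$group, c("overall", "a", "b"))
  # group b at locus 1: calls 2, NA -> p = 1, He = 0; still counted
  expect_equal(h$summary$n_loci_used[h$summary$group == "b"], 2L)
})

test_that("multilocus matching finds clones, counts mismatches, is a partition", {
  fx <- get_fixture()
  gf <- apply_filter_cascade(fx$genotypes,
                             fx$truth$design_failed_ids)$genotypes
  mr <- multilocus_match(gf)
  expect_identical(mr$mismatches, t(mr$mismatches))
  expect_true(all(diag(mr$mismatches) == 0))
  # every injected clone pair is in one synonym group
  for (copy in names(fx$truth$clone_map)) {
    src <- fx$truth$clone_map[[copy]]
    grp <- Filter(function(s) copy %in% s, mr$synonym_groups)
    expect_length(grp, 1L)
    expect_true(src %in% grp[[1]])
  }
  # synonym groups are disjoint (partition property)
  all_members <- unlist(mr$synonym_groups)
  expect_false(any(duplicated(all_members)))
  # pair differing at exactly one locus
  g2 <- gm(matrix(c(0L, 0L, 1L, 1L, 2L, 1L), 2, 3))
  mr2 <- multilocus_match(g2)
  expect_equal(mr2$mismatches[1, 2], 1L)
  expect_length(mr2$synonym_groups, 0L)
})

test_that("removing loci never unmatches a matched pair", {
  set.seed(6)
  for (s in 1:5) {
    m <- matrix(sample(c(0:2, NA), 8 * 20, TRUE), 8, 20)
    m[2, ] <- m[1, ]  # force one clone pair
    g <- gm(m)
    mr_full <- multilocus_match(g)
    keep <- sample(20, 12)
    mr_sub <- multilocus_match(g[, keep])
    was_matched <- mr_full$matched & mr_full$comparable_loci >= 1
    still_comparable <- mr_sub$comparable_loci >= 1
    expect_true(all(mr_sub$matched[was_matched & still_comparable]))
  }
})

test_that("full siblings are discriminated; clones are not", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(K_true = 2, F = 0.3, n_accessions = 10, n_loci = 91,
                      hybrid_specs = list(c("ACC005", "ACC001", "ACC002"),
                                          c("ACC006", "ACC001", "ACC002"),
                                          c("ACC007", "ACC001", "ACC002")),
                      seed = s)
    sim <- simulate_genotypes(cfg)
    hits <- hits + discriminate_set(sim$genotypes,
                                    c("ACC005", "ACC006", "ACC007"))
  }
  expect_equal(hits, 20L)
  # a clone pair is never discriminated
  cfg2 <- sim_config(n_accessions = 6, n_loci = 30,
                     clone_map = c(ACC002 = "ACC001"), seed = 3)
  sim2 <- simulate_genotypes(cfg2)
  expect_false(discriminate_set(sim2$genotypes, c("ACC001", "ACC002")))
  # vacuous single id
  expect_true(discriminate_set(sim2$genotypes, "ACC001"))
  expect_error(discriminate_set(sim2$genotypes, "nope"), "unknown")
})

test_that("require_complete demands complete shared profiles", {
  # rows agree on the two comparable loci but one call is missing
  m <- matrix(c(0L, 0L, 1L, 1L, NA, 2L), 2, 3)
  g <- gm(m)
  tolerant <- multilocus_match(g, require_complete = FALSE)
  strict <- multilocus_match(g, require_complete = TRUE)
  expect_equal(tolerant$mismatches[1, 2], 0L)
  expect_equal(tolerant$comparable_loci[1, 2], 2L)
  expect_length(tolerant$synonym_groups, 1L)
  expect_length(strict$synonym_groups, 0L)
})
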