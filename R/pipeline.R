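#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline]. Exactly one genotype
#' source must be given: a genotype CSV path, a [geno_matrix], or a
#' [sim_config] (including the packaged [reference_fixture] via
#' `use_reference_fixture = TRUE`).
#'
#' @param genotypes genotype CSV path or a [geno_matrix]
#' @param metadata metadata CSV path or a data.frame (name/status/origin/
#'   maturation); required unless simulating (simulation supplies its own)
#' @param sim a [sim_config] to generate the input data
#' @param use_reference_fixture use [reference_fixture] as the input
#' @param vcf optional VCF path; when given, panel design runs first and
#'   genotypes are taken from the VCF samples restricted to the panel
#' @param panel a [panel_config]
#' @param design_failed_ids locus ids that failed assay design
#' @param missing_max,maf_min QC cascade thresholds
#' @param groupings metadata columns used for AMOVA / F_ST (default the two
#'   standard schemes: status and maturation period)
#' @param n_permutations permutations for AMOVA / F_ST
#' @param mcmc an [mcmc_config]
#' @param out_dir output directory (created if needed)
#' @param seed master seed; stage seeds are derived from it
#' @export
pipeline_config <- function(genotypes = NULL, metadata = NULL, sim = NULL,
                            use_reference_fixture = FALSE, vcf = NULL,
                            panel = panel_config(),
                            design_failed_ids = character(0),
                            missing_max = 0.10, maf_min = 0.05,
                            groupings = c("status", "maturation"),
                            n_permutations = 199,
                            mcmc = mcmc_config(), out_dir = tempfile("run"),
                            seed = 1) {
  sources <- sum(!is.null(genotypes), !is.null(sim), use_reference_fixture,
                 !is.null(vcf))
  if (sources != 1)
    stop("exactly one genotype source required (genotypes, sim, ",
         "use_reference_fixture or vcf)")
  structure(list(genotypes = genotypes, metadata = metadata, sim = sim,
                 use_reference_fixture = use_reference_fixture, vcf = vcf,
                 panel = panel, design_failed_ids = design_failed_ids,
                 missing_max = missing_max, maf_min = maf_min,
                 groupings = groupings, n_permutations = n_permutations,
                 mcmc = mcmc, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest/simulate (optionally panel design from a VCF) ->
#' QC filter cascade -> diversity (He/Ho overall and per grouping) ->
#' multilocus matching -> UPGMA tree and PCoA -> AMOVA and pairwise F_ST
#' per grouping scheme -> admixture K sweep with Evanno delta-K. Every
#' intermediate artifact is written to `cfg$out_dir` as it is produced, so
#' a failing stage leaves all completed artifacts behind, and a JSON
#' manifest records configuration, seeds, per-stage locus/accession counts
#' and artifact checksums.
#'
#' @param cfg a [pipeline_config]
#' @return the manifest, invisibly (a list; also written as manifest.json)
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(seed = cfg$seed, stages = list(),
                   groupings = cfg$groupings)

  ## -- ingest -------------------------------------------------------------
  res <- .stage("ingest", {
    if (cfg$use_reference_fixture) {
      reference_fixture()
    } else if (!is.null(cfg$sim)) {
      simulate_genotypes(cfg$sim)
    } else if (!is.null(cfg$vcf)) {
      v <- read_vcf(cfg$vcf)
      panel <- select_panel(v$genotypes, v$contig_lengths, cfg$panel)
      utils::write.csv(panel, out("panel.csv"), row.names = FALSE)
      list(genotypes = v$genotypes[, panel$locus_id],
           metadata = NULL, truth = NULL, panel = panel)
    } else {
      g <- if (inherits(cfg$genotypes, "geno_matrix")) cfg$genotypes
           else read_genotype_csv(cfg$genotypes)
      list(genotypes = g, metadata = NULL, truth = NULL)
    }
  })
  g <- res$genotypes
  meta <- res$metadata
  if (!is.null(cfg$metadata)) {
    meta <- if (is.data.frame(cfg$metadata)) cfg$metadata
            else read_metadata(cfg$metadata)
  }
  design_failed <- cfg$design_failed_ids
  if (length(design_failed) == 0 && !is.null(res$truth))
    design_failed <- res$truth$design_failed_ids

  ## validate grouping columns before any computation
  .stage("validate", {
    if (is.null(meta))
      stop("no metadata available; supply `metadata` or simulate")
    missing_cols <- setdiff(cfg$groupings, names(meta))
    if (length(missing_cols))
      stop("grouping column(s) not in metadata: ",
           paste(missing_cols, collapse = ", "))
    absent <- setdiff(accession_ids(g), meta$name)
    if (length(absent))
      stop("accessions without metadata: ", paste(absent, collapse = ", "))
  })
  write_genotype_csv(g, out("genotypes_input.csv"))
  utils::write.csv(meta, out("metadata.csv"), row.names = FALSE)
  manifest$stages$ingest <- list(n_accessions = n_accessions(g),
                                 n_loci = n_loci(g))

  ## -- QC cascade ----------------------------------------------------------
  qc <- .stage("qc", apply_filter_cascade(g, design_failed,
                                          cfg$missing_max, cfg$maf_min))
  rep <- qc$report
  utils::write.csv(data.frame(locus_id = names(rep$category),
                              category = unname(rep$category)),
                   out("filter_report.csv"), row.names = FALSE)
  gf <- qc$genotypes
  write_genotype_csv(gf, out("genotypes_filtered.csv"))
  manifest$stages$qc <- list(
    n_input = rep$n_input, n_design_failed = rep$n_design_failed,
    n_monomorphic = rep$n_monomorphic, n_high_missing = rep$n_high_missing,
    n_low_maf = rep$n_low_maf, n_retained = length(rep$retained_locus_ids))

  grouping_of <- function(col) stats::setNames(meta[[col]], meta$name)

  ## -- diversity -----------------------------------------------------------
  div <- .stage("diversity", {
    groups <- grouping_of(cfg$groupings[1])
    heterozygosity(gf, groups)
  })
  utils::write.csv(div$per_locus, out("diversity_per_locus.csv"),
                   row.names = FALSE)
  utils::write.csv(div$summary, out("diversity_summary.csv"),
                   row.names = FALSE)
  manifest$stages$diversity <- list(mean_He = div$summary$mean_He[1],
                                    mean_Ho = div$summary$mean_Ho[1])

  ## -- multilocus matching ---------------------------------------------------
  mr <- .stage("match", multilocus_match(gf))
  syn <- vapply(mr$synonym_groups, paste, character(1), collapse = ";")
  writeLines(c("synonym_group", syn), out("synonym_groups.csv"))
  utils::write.csv(mr$mismatches, out("mismatch_matrix.csv"))
  manifest$stages$match <- list(n_synonym_groups = length(mr$synonym_groups))

  ## -- tree and PCoA ----------------------------------------------------------
  d <- .stage("distance", allele_sharing_distance(gf))
  write_distance_csv(d, out("distances.csv"))
  tree <- .stage("upgma", upgma(d))
  write_newick(tree, out("upgma.nwk"))
  pc <- .stage("pcoa", pcoa(d, n_axes = min(5, n_accessions(gf) - 1)))
  utils::write.csv(pc$coordinates, out("pcoa_coordinates.csv"))
  utils::write.csv(data.frame(axis = seq_along(pc$eigenvalues),
                              eigenvalue = pc$eigenvalues),
                   out("pcoa_eigenvalues.csv"), row.names = FALSE)
  manifest$stages$pcoa <- list(pct_pc1 = pc$pct_variance[1])

  ## -- AMOVA / F_ST per grouping scheme ---------------------------------------
  manifest$stages$amova <- list()
  for (col in cfg$groupings) {
    grp <- grouping_of(col)
    am <- .stage(paste0("amova_", col),
                 amova(gf, grp, cfg$n_permutations,
                       seed = .derive_seed(cfg$seed, 1, match(col, cfg$groupings))))
    utils::write.csv(am$table, out(paste0("amova_", col, ".csv")),
                     row.names = FALSE)
    fst <- .stage(paste0("fst_", col),
                  pairwise_fst(gf, grp, cfg$n_permutations,
                               seed = .derive_seed(cfg$seed, 2,
                                                   match(col, cfg$groupings))))
    utils::write.csv(fst$fst, out(paste0("fst_", col, ".csv")))
    manifest$stages$amova[[col]] <- list(pct_among = am$table$pct[1],
                                         p_value = am$p_value)
  }

  ## -- admixture sweep ---------------------------------------------------------
  mc <- cfg$mcmc
  mc$seed <- .derive_seed(cfg$seed, 3, 0)
  reps <- .stage("admixture", run_K_sweep(gf, mc))
  lnp <- data.frame(K = vapply(reps, function(r) r$K, integer(1)),
                    seed = vapply(reps, function(r) r$seed, integer(1)),
                    lnP_D = vapply(reps, function(r) r$lnP_D, numeric(1)))
  utils::write.csv(lnp, out("lnpd_table.csv"), row.names = FALSE)
  ev <- .stage("evanno", evanno(reps))
  utils::write.csv(ev$table, out("evanno.csv"), row.names = FALSE)
  kq <- if (!is.na(ev$chosen_K)) ev$chosen_K else
    lnp$K[which.max(lnp$lnP_D)]
  cons <- align_replicates(reps[lnp$K == kq])$consensus_q
  utils::write.csv(cons, out("membership_q.csv"))
  manifest$stages$admixture <- list(chosen_K = ev$chosen_K,
                                    q_matrix_K = kq)

  ## -- manifest ------------------------------------------------------------------
  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest$artifacts <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(out(f))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
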