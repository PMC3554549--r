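#' Estimate power of the BOMP test under a simulation scenario
#'
#' Simulates independent case-control studies under a scenario (each with
#' a seed derived deterministically from the master seed), runs the full
#' BOMP test on each study with all genes of the scenario forming one
#' functional group, and reports the fraction of replicates whose
#' combined-statistic permutation p-value is at or below \code{alpha}.
#'
#' @param scenario A \code{\link{bomp_scenario}}.
#' @param n_replicates Number of simulated studies.
#' @param alpha Significance level (default 0.05).
#' @param B Permutations per study (default 199).
#' @param seed Master seed; identical (scenario, seed) pairs reproduce
#'   identical estimates.
#' @param config_args Named list of overrides passed to
#'   \code{\link{bomp_config}} (e.g. \code{weight_mode},
#'   \code{combine}).
#' @return List of class \code{"power_estimate"}: \code{power},
#'   \code{se} (binomial standard error), \code{n_replicates},
#'   \code{alpha}, and the per-replicate \code{p_values} (combined,
#'   burden, position).
#' @export
estimate_power <- function(scenario, n_replicates, alpha = 0.05, B = 199L,
                           seed = 1L, config_args = list()) {
  stopifnot(inherits(scenario, "bomp_scenario"),
            n_replicates >= 1, alpha > 0, alpha < 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  p_comb <- p_burd <- p_pos <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    study <- simulate_study(scenario, seed = rep_seeds[2L * i - 1L])
    cfg <- do.call(bomp_config,
                   c(list(permutations = B, seed = rep_seeds[2L * i]),
                     config_args))
    groups <- functional_groups(
      study$genotypes, study$gene_lengths,
      sets = list(scenario_set = names(study$gene_lengths)))
    res <- bomp_test(study$genotypes, study$sample_table, groups, cfg)
    p_comb[i] <- res$p_combined[1L]
    p_burd[i] <- res$p_burden[1L]
    p_pos[i] <- res$p_position[1L]
  }
  power <- mean(p_comb <= alpha)
  structure(list(power = power,
                 se = sqrt(power * (1 - power) / n_replicates),
                 n_replicates = n_replicates, alpha = alpha,
                 p_values = data.frame(p_combined = p_comb,
                                       p_burden = p_burd,
                                       p_position = p_pos)),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power %.3f (se %.3f) at alpha %.3g over %d replicates\n",
              x$power, x$se, x$alpha, x$n_replicates))
  invisible(x)
}

#' Preset power-analysis scenarios
#'
#' Two canonical study designs for power estimation.
#' \code{single_gene_power_scenario}: one 500-codon gene under a single
#' etiology, extreme-phenotype sampling (1\% prevalence, lower 25\%
#' controls) from a population of 100,000 (the smallest population whose
#' affected pool supports 1000 cases at 1\% prevalence).
#' \code{gene_set_power_scenario}: a candidate gene set tested as one
#' functional group, with per-gene etiologies drawn from
#' \code{\link{mixed_etiology_sampler}}, sampled from a population of
#' 20,000.
#'
#' @param n_case,n_ctrl Study arm sizes.
#' @param etiology Etiology for the causal gene(s).
#' @param afs An \code{\link{afs_model}}.
#' @param n_genes,n_causal Gene-set composition (default 100 genes, 25
#'   causal: a 1:3 causal to non-causal ratio).
#' @return A \code{\link{bomp_scenario}}.
#' @export
single_gene_power_scenario <- function(n_case = 1000L, n_ctrl = 1000L,
                                       etiology = etiology_config("rare"),
                                       afs = afs_model("AA-like")) {
  bomp_scenario(n_genes = 1L, n_causal = 1L, etiology = etiology,
                afs = afs, population_size = 100000L,
                n_case = n_case, n_ctrl = n_ctrl)
}

#' @rdname single_gene_power_scenario
#' @export
gene_set_power_scenario <- function(n_genes = 100L, n_causal = 25L,
                                    n_case = 100L, n_ctrl = 100L,
                                    etiology = mixed_etiology_sampler(),
                                    afs = afs_model("AA-like")) {
  bomp_scenario(n_genes = n_genes, n_causal = n_causal,
                etiology = etiology, afs = afs,
                population_size = 20000L,
                n_case = n_case, n_ctrl = n_ctrl)
}

#' File-based association run
#'
#' Reads genotypes, gene models, gene sets, phenotypes, and optional
#' variant scores from disk, runs \code{\link{bomp_test}} on every
#' resolvable functional group, and (optionally) writes the result table
#' as TSV.  Gene-set genes without a coding model are logged and
#' skipped; a run resolving zero groups is an error.
#'
#' @param vcf,genes,pheno Paths to the VCF, gene model TSV and phenotype
#'   TSV (see \code{\link{read_vcf_genotypes}},
#'   \code{\link{read_gene_models}}, \code{\link{read_phenotypes}}).
#' @param sets Optional GMT path; NULL tests every gene separately.
#' @param scores Optional variant score TSV path.
#' @param config A \code{\link{bomp_config}}.
#' @param out Optional output TSV path.
#' @return The result data.frame from \code{\link{bomp_test}}
#'   (invisibly when \code{out} is given).
#' @export
run_association <- function(vcf, genes, pheno, sets = NULL, scores = NULL,
                            config = bomp_config(), out = NULL) {
  sample_table <- read_phenotypes(pheno)
  gene_models <- read_gene_models(genes)
  score_vec <- if (!is.null(scores)) read_variant_scores(scores) else NULL
  genotypes <- read_vcf_genotypes(vcf, sample_table, gene_models,
                                  scores = score_vec)
  lens <- gene_lengths_codons(gene_models)
  set_list <- if (!is.null(sets)) read_gene_sets(sets) else NULL
  groups <- functional_groups(genotypes, lens, set_list)
  if (!length(groups)) stop("no resolvable functional group")
  message("testing ", length(groups), " group(s): ",
          length(sample_table$sample), " samples, ",
          nrow(genotypes$variants), " variants")
  res <- bomp_test(genotypes, sample_table, groups, config)
  if (!is.null(out)) {
    write_bomp_results(res, out)
    return(invisible(res))
  }
  res
}
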