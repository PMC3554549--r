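#' Allele-frequency-spectrum model
#'
#' A mixture of log-uniform minor-allele-frequency components emulating
#' the site-frequency spectrum of a population at linkage equilibrium.
#' Two presets are shipped: \code{"AA-like"}, a wide spectrum with rare,
#' low-frequency and common mass (70\% of sites with MAF in [1e-4, 0.01],
#' 20\% in [0.01, 0.05], 10\% in [0.05, 0.5]), and \code{"EA-like"}, a
#' spectrum consisting almost entirely of rare variants (92\% of sites
#' with MAF in [5e-5, 1e-3], 8\% in [1e-3, 5e-3]).
#'
#' @param name \code{"AA-like"}, \code{"EA-like"}, or \code{"custom"}.
#' @param weights,ranges For \code{"custom"}: mixture weights and a list
#'   of c(lo, hi) MAF ranges (each within (0, 0.5]).
#' @param sites_per_gene Segregating sites simulated per standard gene.
#' @param gene_length_codons Standard gene coding length (500 codons,
#'   i.e. 1500 bases).
#' @return An object of class \code{"afs_model"}.
#' @export
afs_model <- function(name = c("AA-like", "EA-like", "custom"),
                      weights = NULL, ranges = NULL,
                      sites_per_gene = 60L, gene_length_codons = 500L) {
  name <- match.arg(name)
  if (name == "AA-like") {
    weights <- c(0.7, 0.2, 0.1)
    ranges <- list(c(1e-4, 0.01), c(0.01, 0.05), c(0.05, 0.5))
  } else if (name == "EA-like") {
    weights <- c(0.92, 0.08)
    ranges <- list(c(5e-5, 1e-3), c(1e-3, 5e-3))
  } else {
    if (is.null(weights) || is.null(ranges) ||
        length(weights) != length(ranges))
      stop("custom model needs matching weights and ranges")
  }
  if (any(weights <= 0)) stop("mixture weights must be positive")
  for (r in ranges)
    if (r[1] <= 0 || r[2] > 0.5 || r[1] >= r[2])
      stop("MAF ranges must satisfy 0 < lo < hi <= 0.5")
  structure(list(name = name, weights = weights / sum(weights),
                 ranges = ranges,
                 sites_per_gene = as.integer(sites_per_gene),
                 gene_length_codons = as.integer(gene_length_codons)),
            class = "afs_model")
}

#' Sample per-site minor allele frequencies
#'
#' Draws independent per-site MAFs from the configured mixture: a
#' component is chosen by its weight, then the MAF is drawn log-uniformly
#' within the component's range.
#'
#' @param model An \code{\link{afs_model}}.
#' @param n_sites Number of sites.
#' @param seed Optional integer seed (omit to use the current RNG state).
#' @return Numeric vector of MAFs in (0, 0.5].
#' @export
sample_site_frequencies <- function(model, n_sites, seed = NULL) {
  stopifnot(inherits(model, "afs_model"), n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(model$weights), n_sites, replace = TRUE,
                     prob = model$weights)
  lo <- vapply(model$ranges, `[`, numeric(1), 1L)[comp]
  hi <- vapply(model$ranges, `[`, numeric(1), 2L)[comp]
  exp(stats::runif(n_sites, log(lo), log(hi)))
}

#' Simulate genotypes at linkage equilibrium
#'
#' Genotypes at each site are Binomial(2, maf), independent across sites
#' and individuals (random mating, no linkage disequilibrium).
#'
#' @param maf_vector Per-site minor allele frequencies in (0, 0.5].
#' @param n_individuals Number of diploid individuals (>= 2).
#' @param seed Optional integer seed.
#' @return Integer matrix (individuals x sites) with values in {0, 1, 2}.
#' @export
simulate_genotypes <- function(maf_vector, n_individuals, seed = NULL) {
  if (n_individuals < 2) stop("need at least 2 individuals")
  if (any(maf_vector <= 0) || any(maf_vector > 0.5))
    stop("MAF must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  S <- length(maf_vector)
  matrix(stats::rbinom(n_individuals * S, 2L,
                       rep(maf_vector, each = n_individuals)),
         nrow = n_individuals, ncol = S)
}

#' Disease etiology configuration
#'
#' Eight preset disease models plus a null model, defined by the MAF
#' class of causal variants, per-variant trait effects, positional
#' clustering, and the presence of protective modifiers.  Variants whose
#' MAF falls in the causal range (and, for key-region etiologies, whose
#' codon lies in a designated key segment) are \emph{eligible}; a
#' \code{null_fraction} of eligible variants is randomly assigned no
#' effect, modeling heterogeneity within an etiology.  The common-variant
#' etiologies designate a single randomly chosen eligible common variant
#' as causal (always effective); their protective modifiers, when
#' present, are drawn from the rare spectrum.
#'
#' @param name Etiology name: \code{"rare"}, \code{"low_frequency"},
#'   \code{"key_region"}, \code{"common"}, \code{"rare_protect"},
#'   \code{"lowfreq_protect"}, \code{"keyregion_protect"},
#'   \code{"common_protect"}, or \code{"null"}.
#' @param causal_maf_range,effect_size_deleterious,effect_size_protective,
#'   protective_fraction,null_fraction Overrides of the preset defaults
#'   (rare: MAF < 0.01, effect 0.5; low frequency: MAF 0.01-0.05, effect
#'   0.25; key region: rare effect 1.0; common: single variant MAF >
#'   0.05, effect 0.25; protective effect -0.5 on 25\% of causal
#'   variants; null_fraction 0.25).
#' @return An object of class \code{"etiology_config"}.
#' @export
etiology_config <- function(name = c("rare", "low_frequency", "key_region",
                                     "common", "rare_protect",
                                     "lowfreq_protect", "keyregion_protect",
                                     "common_protect", "null"),
                            causal_maf_range = NULL,
                            effect_size_deleterious = NULL,
                            effect_size_protective = -0.5,
                            protective_fraction = 0.25,
                            null_fraction = NULL) {
  name <- match.arg(name)
  base <- switch(name,
                 rare = , rare_protect = "rare",
                 low_frequency = , lowfreq_protect = "low_frequency",
                 key_region = , keyregion_protect = "key_region",
                 common = , common_protect = "common",
                 "null" = "null")
  defaults <- switch(base,
    rare = list(range = c(0, 0.01), c = 0.5, key = FALSE, single = FALSE),
    low_frequency = list(range = c(0.01, 0.05), c = 0.25, key = FALSE,
                         single = FALSE),
    key_region = list(range = c(0, 0.01), c = 1.0, key = TRUE,
                      single = FALSE),
    common = list(range = c(0.05, 0.5), c = 0.25, key = FALSE,
                  single = TRUE),
    "null" = list(range = c(0, 0), c = 0, key = FALSE, single = FALSE))
  protective <- grepl("protect", name)
  if (is.null(causal_maf_range)) causal_maf_range <- defaults$range
  if (is.null(effect_size_deleterious)) effect_size_deleterious <- defaults$c
  if (is.null(null_fraction))
    null_fraction <- if (base == "null") 0 else 0.25
  if (protective && effect_size_protective >= 0)
    stop("protective effect size must be negative")
  structure(list(name = name,
                 causal_maf_range = causal_maf_range,
                 effect_size_deleterious = effect_size_deleterious,
                 protective = protective,
                 effect_size_protective = if (protective)
                   effect_size_protective else NA_real_,
                 protective_fraction = if (protective)
                   protective_fraction else 0,
                 protective_maf_range = if (protective && defaults$single)
                   c(0, 0.01) else causal_maf_range,
                 key_region = defaults$key,
                 single_variant = defaults$single,
                 null_fraction = null_fraction),
            class = "etiology_config")
}

#' Assign per-variant trait effects under a disease etiology
#'
#' @param variants data.frame with a \code{maf} column and, for
#'   key-region etiologies, a logical \code{in_key} column marking
#'   variants inside designated key segments.
#' @param etiology An \code{\link{etiology_config}}.
#' @param seed Optional integer seed.
#' @return Numeric effect vector (per-variant mean trait shift): the
#'   deleterious effect, the protective (negative) effect, or 0.
#' @export
assign_causal_effects <- function(variants, etiology, seed = NULL) {
  stopifnot(inherits(etiology, "etiology_config"))
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(variants)
  effects <- numeric(nv)
  if (etiology$name == "null") return(effects)
  r <- etiology$causal_maf_range
  eligible <- variants$maf > r[1] & variants$maf <= r[2]
  if (etiology$key_region) {
    if (is.null(variants$in_key))
      stop("key-region etiology requires an 'in_key' variant column")
    eligible <- eligible & variants$in_key
  }
  if (etiology$single_variant) {
    if (!any(eligible)) {
      warning("no variant eligible under etiology ", etiology$name)
    } else {
      pick <- if (sum(eligible) == 1L) which(eligible) else
        sample(which(eligible), 1L)
      effects[pick] <- etiology$effect_size_deleterious
    }
    if (etiology$protective) {
      ## protective modifiers accompany the single causal variant, drawn
      ## from the rare spectrum; null_fraction thins them as usual
      pr <- etiology$protective_maf_range
      pool <- which(variants$maf > pr[1] & variants$maf <= pr[2] &
                      effects == 0)
      keep <- stats::runif(length(pool)) >= etiology$null_fraction
      prot <- stats::runif(length(pool)) < etiology$protective_fraction
      effects[pool[keep & prot]] <- etiology$effect_size_protective
    }
    return(effects)
  }
  idx <- which(eligible)
  if (!length(idx)) {
    warning("no variant eligible under etiology ", etiology$name)
    return(effects)
  }
  active <- stats::runif(length(idx)) >= etiology$null_fraction
  eff <- rep(etiology$effect_size_deleterious, length(idx))
  if (etiology$protective) {
    prot <- stats::runif(length(idx)) < etiology$protective_fraction
    eff[prot] <- etiology$effect_size_protective
  }
  effects[idx[active]] <- eff[active]
  effects
}

#' Simulate Gaussian liability traits
#'
#' Each individual's trait is Normal(mean = sum of carried effect copies,
#' sd = 1); individuals with no causal variants follow a standard normal,
#' which also defines the null study.
#'
#' @param genotypes Integer matrix (individuals x sites) or a single row.
#' @param effect_vector Per-site effects (mean trait shift per allele
#'   copy).
#' @param seed Optional integer seed.
#' @return Numeric trait vector, one value per individual.
#' @export
simulate_trait <- function(genotypes, effect_vector, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(genotypes)) genotypes <- matrix(genotypes, nrow = 1)
  mu <- as.numeric(genotypes %*% effect_vector)
  stats::rnorm(length(mu), mean = mu, sd = 1)
}

#' Draw an extreme-phenotype case-control study from a population
#'
#' The top \code{prevalence} fraction of the population by trait value
#' forms the affected pool and the bottom \code{control_tail} fraction
#' the unaffected pool; cases and controls are sampled from the pools
#' without replacement, and intermediate individuals are never selected.
#'
#' @param population Integer genotype matrix (individuals x sites).
#' @param traits Numeric trait vector, one per individual.
#' @param n_case,n_ctrl Study arm sizes.
#' @param prevalence Affected fraction (default 0.01).
#' @param control_tail Unaffected fraction (default 0.25).
#' @param seed Optional integer seed.
#' @return List with the study genotype matrix \code{G}, a
#'   \code{sample_table} (case rows first), the selected population
#'   indices, and \code{monomorphic}, a logical flag per site with no
#'   alternate allele within the study.
#' @export
draw_case_control_study <- function(population, traits, n_case, n_ctrl,
                                    prevalence = 0.01, control_tail = 0.25,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(population)
  stopifnot(length(traits) == n)
  n_aff <- floor(n * prevalence)
  n_unaff <- floor(n * control_tail)
  if (n_aff < n_case)
    stop("affected pool (", n_aff, ") smaller than requested cases (",
         n_case, ")")
  if (n_unaff < n_ctrl)
    stop("unaffected pool (", n_unaff, ") smaller than requested controls (",
         n_ctrl, ")")
  ord <- order(traits, decreasing = TRUE)
  affected <- ord[seq_len(n_aff)]
  unaffected <- ord[seq.int(n - n_unaff + 1L, n)]
  case_idx <- sample(affected, n_case)
  ctrl_idx <- sample(unaffected, n_ctrl)
  sel <- c(case_idx, ctrl_idx)
  G <- population[sel, , drop = FALSE]
  sample_table <- data.frame(
    sample = sprintf("S%04d", seq_along(sel)),
    status = rep(c("case", "control"), c(n_case, n_ctrl)),
    stratum = NA_character_, stringsAsFactors = FALSE)
  rownames(G) <- sample_table$sample
  list(G = G, sample_table = sample_table,
       case_idx = case_idx, ctrl_idx = ctrl_idx,
       monomorphic = colSums(G) == 0L)
}

## geometry of one simulated gene under an etiology
.gene_geometry <- function(gene_id, etiology, afs) {
  if (!is.null(etiology) && etiology$key_region) {
    L <- 1000L   # 100 segments x 10 codons (30 bases each)
    n_sites <- 2L * afs$sites_per_gene
    key_segments <- sort(sample.int(100L, 10L))
    key_codons <- as.integer(outer(0:9, (key_segments - 1L) * 10L, "+"))
  } else {
    L <- afs$gene_length_codons
    n_sites <- afs$sites_per_gene
    key_codons <- integer(0)
  }
  list(gene = gene_id, length_codons = L, n_sites = n_sites,
       key_codons = key_codons)
}

## variant table for one gene: MAFs, uniform codon positions, key flags
.gene_variants <- function(geom, afs) {
  maf <- sample_site_frequencies(afs, geom$n_sites)
  codon <- sample.int(geom$length_codons, geom$n_sites,
                      replace = TRUE) - 1L
  data.frame(id = paste0(geom$gene, "_v", seq_len(geom$n_sites)),
             gene = geom$gene, codon_index = codon, maf = maf,
             in_key = if (length(geom$key_codons))
               codon %in% geom$key_codons else FALSE,
             stringsAsFactors = FALSE)
}

#' Build a multi-gene population with etiology-driven traits
#'
#' Materializes a full population in which each individual carries
#' several genes: independent per-gene genotype blocks are concatenated,
#' an etiology is drawn for each causal gene from the supplied sampler,
#' non-causal genes receive all-zero effects, and the Gaussian liability
#' trait is generated from the union of effects.
#'
#' @param n_genes Number of genes per individual.
#' @param n_individuals Population size.
#' @param causal_flags Logical vector marking which genes carry causal
#'   variants.
#' @param etiology_sampler Zero-argument function returning an
#'   \code{\link{etiology_config}} for a causal gene (e.g.
#'   \code{\link{mixed_etiology_sampler}}), or a single
#'   \code{etiology_config} used for every causal gene.
#' @param afs An \code{\link{afs_model}}.
#' @param seed Optional integer seed.
#' @return List with genotype matrix \code{G}, \code{variants} table
#'   (id, gene, codon_index, maf, in_key), \code{effects},
#'   \code{traits}, \code{gene_lengths}, and the per-gene
#'   \code{etiologies}.
#' @export
build_gene_set_population <- function(n_genes, n_individuals, causal_flags,
                                      etiology_sampler,
                                      afs = afs_model("AA-like"),
                                      seed = NULL) {
  if (n_genes < 1L) stop("need at least one gene")
  stopifnot(length(causal_flags) == n_genes)
  if (!is.null(seed)) set.seed(seed)
  draw_etiology <- if (inherits(etiology_sampler, "etiology_config"))
    function() etiology_sampler else etiology_sampler
  etios <- vector("list", n_genes)
  geoms <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    if (causal_flags[g]) etios[[g]] <- draw_etiology()
    geoms[[g]] <- .gene_geometry(sprintf("gene%03d", g), etios[[g]], afs)
  }
  vars <- do.call(rbind, lapply(geoms, .gene_variants, afs = afs))
  G <- simulate_genotypes(vars$maf, n_individuals)
  effects <- numeric(nrow(vars))
  for (g in seq_len(n_genes)) {
    if (!causal_flags[g]) next
    vi <- which(vars$gene == geoms[[g]]$gene)
    effects[vi] <- assign_causal_effects(vars[vi, , drop = FALSE],
                                         etios[[g]])
  }
  traits <- simulate_trait(G, effects)
  lens <- vapply(geoms, `[[`, integer(1), "length_codons")
  names(lens) <- vapply(geoms, `[[`, character(1), "gene")
  list(G = G, variants = vars, effects = effects, traits = traits,
       gene_lengths = lens, etiologies = etios)
}

#' Etiology sampler over weighted categories
#'
#' Draws etiologies in three categories with the given weights: (1) the
#' rare-variant-dominated etiologies (rare, low frequency, key region),
#' (2) the common-variant etiology, (3) the protective-containing
#' etiologies; within a category each member is equally likely.
#'
#' @param category_weights Numeric length-3 weights (default 10:1:1).
#' @return A zero-argument function returning an
#'   \code{\link{etiology_config}}.
#' @export
mixed_etiology_sampler <- function(category_weights = c(10, 1, 1)) {
  force(category_weights)
  function() {
    cat <- sample.int(3L, 1L, prob = category_weights)
    nm <- switch(cat,
                 sample(c("rare", "low_frequency", "key_region"), 1L),
                 "common",
                 sample(c("rare_protect", "lowfreq_protect",
                          "keyregion_protect", "common_protect"), 1L))
    etiology_config(nm)
  }
}

#' Simulation scenario
#'
#' Bundles everything that defines one simulated study design: the gene
#' architecture, the disease etiology (or per-gene etiology sampler), the
#' allele-frequency-spectrum model, the population size and the
#' extreme-phenotype sampling design.
#'
#' @param n_genes,n_causal Genes per individual and how many carry causal
#'   variants (the first \code{n_causal} genes).
#' @param etiology An \code{\link{etiology_config}} applied to every
#'   causal gene, or a zero-argument sampler function.
#' @param afs An \code{\link{afs_model}}.
#' @param population_size Simulated population size.
#' @param n_case,n_ctrl Study arm sizes.
#' @param prevalence,control_tail Extreme-phenotype pool fractions
#'   (defaults 1\% / lower 25\%).
#' @return An object of class \code{"bomp_scenario"}.
#' @export
bomp_scenario <- function(n_genes = 1L, n_causal = n_genes,
                          etiology = etiology_config("rare"),
                          afs = afs_model("AA-like"),
                          population_size = 50000L,
                          n_case = 500L, n_ctrl = 500L,
                          prevalence = 0.01, control_tail = 0.25) {
  if (n_causal > n_genes) stop("n_causal cannot exceed n_genes")
  if (floor(population_size * prevalence) < n_case)
    stop("affected pool (", floor(population_size * prevalence),
         ") smaller than requested cases (", n_case, ")")
  if (floor(population_size * control_tail) < n_ctrl)
    stop("unaffected pool (", floor(population_size * control_tail),
         ") smaller than requested controls (", n_ctrl, ")")
  structure(list(n_genes = as.integer(n_genes),
                 n_causal = as.integer(n_causal),
                 etiology = etiology, afs = afs,
                 population_size = as.integer(population_size),
                 n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
                 prevalence = prevalence, control_tail = control_tail),
            class = "bomp_scenario")
}

#' Simulate one extreme-phenotype case-control study
#'
#' Generates a study under a \code{\link{bomp_scenario}}.  Genotypes are
#' sampled in two stages that are statistically identical to
#' materializing the full population (sites are independent): genotypes
#' at effect-carrying sites are drawn for every individual to generate
#' traits and select the phenotypic extremes, and genotypes at the
#' remaining sites are then drawn only for the sampled individuals.
#' Monomorphic sites within the study are retained and flagged.
#'
#' @param scenario A \code{\link{bomp_scenario}}.
#' @param seed Integer seed; the study is a deterministic function of
#'   (scenario, seed).
#' @return List with \code{genotypes} (a \code{\link{bomp_genotypes}}
#'   with per-variant \code{maf} and effect annotation),
#'   \code{sample_table}, \code{gene_lengths}, \code{effects},
#'   \code{etiologies}, \code{traits} (of the sampled individuals) and
#'   \code{monomorphic} flags.
#' @export
simulate_study <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "bomp_scenario"))
  set.seed(seed)
  sc <- scenario
  draw_etiology <- if (inherits(sc$etiology, "etiology_config"))
    function() sc$etiology else sc$etiology
  causal_flags <- seq_len(sc$n_genes) <= sc$n_causal
  etios <- vector("list", sc$n_genes)
  geoms <- vector("list", sc$n_genes)
  for (g in seq_len(sc$n_genes)) {
    if (causal_flags[g]) etios[[g]] <- draw_etiology()
    geoms[[g]] <- .gene_geometry(sprintf("gene%03d", g), etios[[g]], sc$afs)
  }
  vars <- do.call(rbind, lapply(geoms, .gene_variants, afs = sc$afs))
  rownames(vars) <- NULL
  effects <- numeric(nrow(vars))
  for (g in seq_len(sc$n_genes)) {
    if (!causal_flags[g]) next
    vi <- which(vars$gene == geoms[[g]]$gene)
    effects[vi] <- assign_causal_effects(vars[vi, , drop = FALSE],
                                         etios[[g]])
  }
  N <- sc$population_size
  causal_sites <- which(effects != 0)
  ## stage 1: population genotypes at effect-carrying sites -> traits.
  ## Equivalent to per-individual Binomial(2, maf) draws: the 2N
  ## chromosomes are iid Bernoulli(maf), so the total allele count is
  ## Binomial(2N, maf) and carriers are a uniform draw of chromosomes.
  mu <- numeric(N)
  carriers <- vector("list", length(causal_sites))
  for (j in seq_along(causal_sites)) {
    s <- causal_sites[j]
    m <- stats::rbinom(1L, 2L * N, vars$maf[s])
    if (m > 0L)
      carriers[[j]] <- (sample.int(2L * N, m) - 1L) %/% 2L + 1L
  }
  if (length(causal_sites)) {
    ind_all <- unlist(carriers)
    eff_all <- rep(effects[causal_sites],
                   vapply(carriers, length, integer(1)))
    if (length(ind_all)) {
      agg <- rowsum(eff_all, ind_all)
      mu[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  traits <- stats::rnorm(N, mean = mu, sd = 1)
  ## stage 2: select phenotypic extremes
  n_aff <- floor(N * sc$prevalence)
  n_unaff <- floor(N * sc$control_tail)
  ord <- order(traits, decreasing = TRUE)
  case_idx <- sample(ord[seq_len(n_aff)], sc$n_case)
  ctrl_idx <- sample(ord[seq.int(N - n_unaff + 1L, N)], sc$n_ctrl)
  sel <- c(case_idx, ctrl_idx)
  ## stage 3: remaining (zero-effect) sites for sampled individuals only
  G <- matrix(0L, length(sel), nrow(vars))
  if (length(causal_sites)) {
    sel_map <- integer(N)
    sel_map[sel] <- seq_along(sel)
    for (j in seq_along(causal_sites)) {
      ind <- carriers[[j]]
      if (is.null(ind)) next
      pos <- sel_map[ind]
      pos <- pos[pos > 0L]
      if (length(pos))
        G[, causal_sites[j]] <- tabulate(pos, nbins = length(sel))
    }
  }
  other <- setdiff(seq_len(nrow(vars)), causal_sites)
  if (length(other))
    G[, other] <- simulate_genotypes(vars$maf[other], length(sel))
  sample_table <- data.frame(
    sample = sprintf("S%04d", seq_along(sel)),
    status = rep(c("case", "control"), c(sc$n_case, sc$n_ctrl)),
    stratum = NA_character_, stringsAsFactors = FALSE)
  vars$effect <- effects
  genotypes <- bomp_genotypes(G, vars, samples = sample_table$sample)
  lens <- vapply(geoms, `[[`, integer(1), "length_codons")
  names(lens) <- vapply(geoms, `[[`, character(1), "gene")
  list(genotypes = genotypes, sample_table = sample_table,
       gene_lengths = lens, effects = effects, etiologies = etios,
       traits = traits[sel], monomorphic = colSums(G) == 0L)
}

#' Export a simulated study to analysis input files
#'
#' Writes a simulated study as the plain-text files the association
#' front-end consumes: a VCF with GT genotypes (each gene on its own
#' contig, variants at the first base of their codon), a phenotype TSV, a
#' gene model TSV, and a GMT file with one set spanning all genes.
#'
#' @param study A study from \code{\link{simulate_study}}.
#' @param dir Output directory (created if needed).
#' @param set_name Name of the exported gene set.
#' @return Named list of file paths (vcf, phenotypes, genes, sets).
#' @export
export_study <- function(study, dir, set_name = "simulated_set") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt_codes <- c("0/0", "0/1", "1/1")
  v <- study$genotypes$variants
  G <- study$genotypes$G
  samples <- study$genotypes$samples
  vcf_path <- file.path(dir, "study.vcf")
  con <- file(vcf_path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=bomp_simulated_study",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  body <- cbind(v$gene, v$codon_index * 3L + 1L, v$id, "A", "G", ".", ".",
                ".", "GT", t(matrix(gt_codes[G + 1L], nrow = nrow(G))))
  ord <- order(v$gene, v$codon_index * 3L + 1L)
  writeLines(apply(body[ord, , drop = FALSE], 1L, paste,
                   collapse = "\t"), con)
  close(con)
  pheno_path <- file.path(dir, "phenotypes.tsv")
  utils::write.table(study$sample_table, pheno_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  genes_path <- file.path(dir, "genes.tsv")
  gm <- data.frame(gene = names(study$gene_lengths),
                   chrom = names(study$gene_lengths),
                   start = 0L,
                   end = 3L * as.integer(study$gene_lengths),
                   strand = "+", frame = 0L, stringsAsFactors = FALSE)
  utils::write.table(gm, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sets_path <- file.path(dir, "sets.gmt")
  writeLines(paste(c(set_name, "simulated", names(study$gene_lengths)),
                   collapse = "\t"), sets_path)
  list(vcf = vcf_path, phenotypes = pheno_path, genes = genes_path,
       sets = sets_path)
}
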