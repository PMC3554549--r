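#' Weighting configuration for the burden statistic
#'
#' Bundles the per-variant weighting mode, the genetic model, and the beta
#' prior used when estimating allele frequencies.  Weights are applied in
#' the burden statistic only; the position statistic always uses
#' unweighted counts.
#'
#' @param mode Weighting mode: \code{"none"} (unit weights, raw counting),
#'   \code{"af"} (allele-frequency weights, rare variants up-weighted),
#'   \code{"score"} (externally supplied functional scores in [0,1]), or
#'   \code{"product"} (allele-frequency weight times functional score).
#' @param genetic_model \code{"additive"} (a homozygote contributes twice
#'   a heterozygote) or \code{"dominant"} (any carrier contributes once).
#' @param beta_prior Length-2 positive numeric: pseudocounts (alpha, beta)
#'   of the beta prior behind \code{\link{estimate_allele_frequency}}.
#' @return An object of class \code{"weight_config"}.
#' @seealso \code{\link{variant_weights}}
#' @export
weight_config <- function(mode = c("none", "af", "score", "product"),
                          genetic_model = c("additive", "dominant"),
                          beta_prior = c(1, 1)) {
  mode <- match.arg(mode)
  genetic_model <- match.arg(genetic_model)
  if (length(beta_prior) != 2L || any(!is.finite(beta_prior)) ||
      any(beta_prior <= 0)) {
    stop("beta_prior must be two positive finite numbers")
  }
  structure(list(mode = mode, genetic_model = genetic_model,
                 beta_prior = as.numeric(beta_prior)),
            class = "weight_config")
}

#' Posterior mean allele frequency under a beta prior
#'
#' Estimates the population allele frequency of a variant from its pooled
#' case and control allele counts, shrunk toward the prior mean by beta
#' pseudocounts so the estimate is always strictly inside (0, 1).
#'
#' @param a_case,a_ctrl Alternate allele counts in cases and controls.
#' @param n_samples Total number of individuals (cases plus controls).
#' @param prior Beta pseudocounts (alpha, beta); default \code{c(1, 1)}.
#' @return Estimated allele frequency, \code{(a_case + a_ctrl + alpha) /
#'   (2 * n_samples + alpha + beta)}.  Vectorized over the counts.
#' @examples
#' estimate_allele_frequency(0, 0, 50)    # 1/102
#' @export
estimate_allele_frequency <- function(a_case, a_ctrl, n_samples,
                                      prior = c(1, 1)) {
  if (any(n_samples <= 0)) stop("n_samples must be >= 1")
  if (any(a_case < 0) || any(a_ctrl < 0)) stop("allele counts must be >= 0")
  (a_case + a_ctrl + prior[1L]) / (2 * n_samples + prior[1L] + prior[2L])
}

#' Allele-frequency weight (Madsen-Browning style)
#'
#' Weight \code{1 / sqrt(2 * n * q * (1 - q))}, the reciprocal standard
#' deviation of the allele count under binomial sampling of \code{2n}
#' chromosomes; strictly decreasing in \code{q} on (0, 0.5], so rare
#' variants receive larger weights.
#'
#' @param q_hat Estimated allele frequency in (0, 1).
#' @param n_samples Total number of individuals.
#' @return Positive weight; vectorized over \code{q_hat}.
#' @export
af_weight <- function(q_hat, n_samples) {
  if (any(q_hat <= 0) || any(q_hat >= 1)) stop("q_hat must be in (0, 1)")
  1 / sqrt(2 * n_samples * q_hat * (1 - q_hat))
}

#' Weighted genotype contribution under a genetic model
#'
#' @param g Genotype allele count in {0, 1, 2}.
#' @param score Per-variant weight (functional score or composite weight).
#' @param genetic_model \code{"additive"} or \code{"dominant"}.
#' @return \code{g * score} (additive) or \code{score * (g >= 1)}
#'   (dominant).  Vectorized.
#' @export
effective_genotype_score <- function(g, score,
                                     genetic_model = c("additive", "dominant")) {
  genetic_model <- match.arg(genetic_model)
  if (any(!(g %in% c(0, 1, 2)))) stop("genotypes must be in {0, 1, 2}")
  if (genetic_model == "additive") g * score else score * (g >= 1)
}

#' Per-variant burden weights for a genotype set
#'
#' Computes the weight vector used by the burden statistic under a
#' \code{\link{weight_config}}.  Allele-frequency weights are estimated
#' from the pooled study allele counts (which are invariant under
#' case-control label permutation, so weights need not be recomputed in
#' the permutation null).  Variants lacking a functional score under the
#' \code{"score"}/\code{"product"} modes default to score 1 with a
#' warning.
#'
#' @param genotypes A \code{\link{bomp_genotypes}} object.
#' @param config A \code{\link{weight_config}}.
#' @return Numeric vector of positive weights, one per variant.
#' @export
variant_weights <- function(genotypes, config = weight_config()) {
  stopifnot(inherits(genotypes, "bomp_genotypes"))
  v <- genotypes$variants
  nv <- nrow(v)
  if (config$mode == "none") return(rep(1, nv))
  scores <- v$score
  if (config$mode %in% c("score", "product")) {
    if (is.null(scores)) scores <- rep(NA_real_, nv)
    if (anyNA(scores)) {
      warning(sum(is.na(scores)),
              " variant(s) without a functional score; defaulting to 1.0")
      scores[is.na(scores)] <- 1
    }
  }
  if (config$mode == "score") return(scores)
  n <- length(genotypes$samples)
  a_tot <- colSums(genotypes$G)
  q <- estimate_allele_frequency(a_tot, 0, n, prior = config$beta_prior)
  w <- af_weight(q, n)
  if (config$mode == "product") w * scores else w
}
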