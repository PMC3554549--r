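#' Individual variant burden
#'
#' Sums weighted genotype contributions across the variants of a
#' functional group for each individual.  For a gene set the burden is
#' aggregated over all member genes, i.e. over all variant columns passed
#' in.
#'
#' @param genotype_row Integer vector of allele counts in {0,1,2} (one
#'   individual, all group variants), or a samples-by-variants matrix to
#'   compute all individuals at once.
#' @param weights Positive per-variant weights (same length as columns).
#' @param genetic_model \code{"additive"} or \code{"dominant"}.
#' @return Nonnegative burden (scalar per row).
#' @export
individual_burden <- function(genotype_row, weights,
                              genetic_model = c("additive", "dominant")) {
  genetic_model <- match.arg(genetic_model)
  if (is.matrix(genotype_row)) {
    if (ncol(genotype_row) != length(weights))
      stop("genotype columns and weights differ in length")
    g <- if (genetic_model == "dominant") (genotype_row >= 1) + 0L else genotype_row
    return(as.numeric(g %*% weights))
  }
  if (length(genotype_row) != length(weights))
    stop("genotype row and weights differ in length")
  sum(effective_genotype_score(genotype_row, weights, genetic_model))
}

## Bernoulli log-likelihood with raw counts k of n at parameter p
.bern_ll <- function(k, n, p) k * log(p) + (n - k) * log1p(-p)

#' Smoothed signed Bernoulli burden log-likelihood ratio
#'
#' Compares the probability of exceeding a burden threshold in cases and
#' controls.  Exceedance probabilities are estimated with add-one
#' smoothing, \code{p = (k + 1) / (n + 2)}, while the likelihoods keep the
#' raw counts.  The statistic is directional, returned as a signed
#' magnitude: positive when the smoothed case probability exceeds the
#' control probability, negative when it falls below it, and exactly 0
#' when the two are equal, so case-enriched groups score high and
#' control-enriched groups score low and a label swap negates the value.
#'
#' @param k_case,n_case Cases at/above the threshold, total cases.
#' @param k_ctrl,n_ctrl Controls at/above the threshold, total controls.
#' @return Signed log-likelihood ratio.  Vectorized over the counts.
#' @examples
#' smoothed_bernoulli_llr(3, 4, 1, 4)   # about +0.9152
#' smoothed_bernoulli_llr(1, 4, 3, 4)   # about -0.9152
#' @export
smoothed_bernoulli_llr <- function(k_case, n_case, k_ctrl, n_ctrl) {
  if (any(k_case > n_case) || any(k_ctrl > n_ctrl))
    stop("k must not exceed n")
  if (any(k_case < 0) || any(k_ctrl < 0)) stop("counts must be >= 0")
  p_case <- (k_case + 1) / (n_case + 2)
  p_ctrl <- (k_ctrl + 1) / (n_ctrl + 2)
  p_pool <- (k_case + k_ctrl + 1) / (n_case + n_ctrl + 2)
  v <- .bern_ll(k_case, n_case, p_case) + .bern_ll(k_ctrl, n_ctrl, p_ctrl) -
    .bern_ll(k_case, n_case, p_pool) - .bern_ll(k_ctrl, n_ctrl, p_pool)
  ## signed magnitude: case-enriched groups score +|v|, control-enriched
  ## -|v|, equal smoothed probabilities exactly 0 -- this preserves
  ## label-swap antisymmetry even where the smoothed ratio itself would
  ## not vanish
  sign(p_case - p_ctrl) * abs(v)
}

#' Optimize the burden threshold of a functional group
#'
#' Scans every distinct positive burden value observed in either group as
#' a candidate threshold T, counts the samples with burden >= T in each
#' group, and returns the threshold maximizing the signed Bernoulli
#' log-likelihood ratio (\code{\link{smoothed_bernoulli_llr}}).  Ties are
#' broken toward the smallest (most inclusive) threshold.  If no sample
#' has positive burden the statistic is 0 and the threshold undefined.
#'
#' @param burdens_case,burdens_ctrl Numeric burden vectors.
#' @return A list of class \code{"burden_result"} with elements
#'   \code{threshold}, \code{llr}, \code{n_case_exceed},
#'   \code{n_ctrl_exceed}, \code{p_case}, \code{p_ctrl}, \code{p_pooled}.
#' @examples
#' optimize_burden_threshold(c(2, 2, 1, 0), c(1, 0, 0, 0))
#' @export
optimize_burden_threshold <- function(burdens_case, burdens_ctrl) {
  n_case <- length(burdens_case)
  n_ctrl <- length(burdens_ctrl)
  if (n_case + n_ctrl == 0L) stop("both groups empty")
  if (any(!is.finite(c(burdens_case, burdens_ctrl))))
    stop("burdens must be finite")
  cand <- sort(unique(c(burdens_case, burdens_ctrl)))
  cand <- cand[cand > 0]
  if (length(cand) == 0L) {
    return(structure(list(threshold = NA_real_, llr = 0,
                          n_case_exceed = 0L, n_ctrl_exceed = 0L,
                          p_case = NA_real_, p_ctrl = NA_real_,
                          p_pooled = NA_real_),
                     class = "burden_result"))
  }
  k_case <- vapply(cand, function(t) sum(burdens_case >= t), integer(1))
  k_ctrl <- vapply(cand, function(t) sum(burdens_ctrl >= t), integer(1))
  llr <- smoothed_bernoulli_llr(k_case, n_case, k_ctrl, n_ctrl)
  best <- which.max(llr)  # first max = smallest threshold on ties
  structure(list(threshold = cand[best], llr = llr[best],
                 n_case_exceed = k_case[best], n_ctrl_exceed = k_ctrl[best],
                 p_case = (k_case[best] + 1) / (n_case + 2),
                 p_ctrl = (k_ctrl[best] + 1) / (n_ctrl + 2),
                 p_pooled = (k_case[best] + k_ctrl[best] + 1) /
                   (n_case + n_ctrl + 2)),
            class = "burden_result")
}
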