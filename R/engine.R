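#' BOMP run configuration
#'
#' @param permutations Number of label permutations B (default 10000;
#'   larger values sharpen the attainable p-value floor 1/(B+1)).
#' @param seed Integer seed controlling the permutation stream.
#' @param combine Combination rule for the two component statistics:
#'   \code{"sum"} (default; additive on the log-likelihood scale) or
#'   \code{"max"}.
#' @param genetic_model,weight_mode,beta_prior Passed to
#'   \code{\link{weight_config}} (weights affect the burden statistic
#'   only).
#' @param count_mode Position-statistic counting: \code{"mutations"}
#'   (allele copies) or \code{"positions"} (distinct mutated codons).
#' @param stratified Permute case-control labels only within each sample
#'   stratum.
#' @param ws_pairs Segmentation grid; see
#'   \code{\link{enumerate_segmentations}}.
#' @return An object of class \code{"bomp_config"}.
#' @export
bomp_config <- function(permutations = 10000L, seed = 1L,
                        combine = c("sum", "max"),
                        genetic_model = c("additive", "dominant"),
                        weight_mode = c("af", "none", "score", "product"),
                        beta_prior = c(1, 1),
                        count_mode = c("mutations", "positions"),
                        stratified = FALSE,
                        ws_pairs = default_ws_pairs()) {
  if (permutations < 1L) stop("permutations must be >= 1")
  structure(list(permutations = as.integer(permutations),
                 seed = as.integer(seed),
                 combine = match.arg(combine),
                 genetic_model = match.arg(genetic_model),
                 weight_mode = match.arg(weight_mode),
                 beta_prior = beta_prior,
                 count_mode = match.arg(count_mode),
                 stratified = isTRUE(stratified),
                 ws_pairs = ws_pairs),
            class = "bomp_config")
}

#' Combine the burden and position statistics
#'
#' @param llr_burden,llr_position Component log-likelihood ratios.
#' @param combine_rule \code{"sum"} (default) or \code{"max"}.
#' @return Combined log-likelihood ratio.  Vectorized.
#' @export
bomp_statistic <- function(llr_burden, llr_position,
                           combine_rule = c("sum", "max")) {
  combine_rule <- match.arg(combine_rule)
  if (combine_rule == "sum") llr_burden + llr_position
  else pmax(llr_burden, llr_position)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment across a family of p-values (delegating to
#' \code{stats::p.adjust}).
#'
#' @param p_values Numeric p-values in (0, 1].
#' @return Adjusted values, in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) < 1L) stop("need at least one p-value")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

## ---- permutation label matrix ------------------------------------------

## columns: observed labels, then B permutations (within strata when
## requested); values are 0/1 case indicators
.label_matrix <- function(labels, B, strata = NULL) {
  n <- length(labels)
  L <- matrix(0L, n, B + 1L)
  L[, 1L] <- labels
  if (is.null(strata)) {
    for (b in seq_len(B)) L[, b + 1L] <- sample(labels)
  } else {
    groups <- split(seq_len(n), strata)
    degenerate <- vapply(groups, function(i) {
      length(unique(labels[i])) == 1L
    }, logical(1))
    if (any(degenerate))
      warning("stratum with all-case or all-control membership: ",
              paste(names(groups)[degenerate], collapse = ", "))
    for (b in seq_len(B)) {
      col <- labels
      for (i in groups) col[i] <- labels[i[sample.int(length(i))]]
      L[, b + 1L] <- col
    }
  }
  L
}

## ---- vectorized burden statistic over label columns --------------------

## b: per-sample burden; Lmat: n x (B+1) 0/1 case labels.
## Returns llr per column plus the observed column's threshold/counts.
.burden_stats_cols <- function(b, Lmat) {
  n <- length(b)
  n_case <- sum(Lmat[, 1L])
  n_ctrl <- n - n_case
  ncol_ <- ncol(Lmat)
  cand <- sort(unique(b[b > 0]))
  if (length(cand) == 0L) {
    return(list(llr = rep(0, ncol_), threshold = NA_real_,
                n_case_exceed = 0L, n_ctrl_exceed = 0L))
  }
  ord <- order(b, decreasing = TRUE)
  bs <- b[ord]
  ## candidates ascending; m[t] = #{samples with burden >= cand[t]}
  m <- vapply(cand, function(t) sum(bs >= t), integer(1))
  CS <- apply(Lmat[ord, , drop = FALSE], 2L, cumsum)  # n x cols
  Kc <- CS[m, , drop = FALSE]                         # cases >= T, C x cols
  Kt <- m - Kc                                        # controls >= T
  ## log tables over the integer count ranges
  lp_c <- log((0:n_case + 1) / (n_case + 2))
  l1p_c <- log(1 - (0:n_case + 1) / (n_case + 2))
  lp_t <- log((0:n_ctrl + 1) / (n_ctrl + 2))
  l1p_t <- log(1 - (0:n_ctrl + 1) / (n_ctrl + 2))
  lp_p <- log((m + 1) / (n + 2))        # pooled: depends on candidate only
  l1p_p <- log(1 - (m + 1) / (n + 2))
  v <- Kc * lp_c[Kc + 1L] + (n_case - Kc) * l1p_c[Kc + 1L] +
    Kt * lp_t[Kt + 1L] + (n_ctrl - Kt) * l1p_t[Kt + 1L] -
    (Kc + Kt) * lp_p - (n - Kc - Kt) * l1p_p   # lp_p recycles over rows
  ## signed magnitude, sign of (p_case - p_ctrl) via cross-multiplication
  v <- sign((Kc + 1) * (n_ctrl + 2) - (Kt + 1) * (n_case + 2)) * abs(v)
  best <- max.col(t(v), ties.method = "first")  # first max = smallest T
  llr <- v[cbind(best, seq_len(ncol_))]
  list(llr = llr, threshold = cand[best[1L]],
       n_case_exceed = Kc[best[1L], 1L], n_ctrl_exceed = Kt[best[1L], 1L])
}

## ---- vectorized position statistic over label columns ------------------

## f(x) = x * log(x + 1), the per-window likelihood kernel
.xlog1p <- function(x) x * log1p(x)

## Precompute the segmentation layout of one gene: for each enumerated
## segmentation, the window index of each codon and the window count K.
.gene_seg_layout <- function(codons, L, ws_pairs) {
  segs <- enumerate_segmentations(L, ws_pairs)
  K <- vapply(segs, function(s) length(s$breaks), integer(1))
  idx <- lapply(segs, function(s) .window_index(codons, s))
  ## globally unique window ids across the stacked segmentations
  off <- cumsum(c(0L, K))[seq_along(segs)]
  stacked <- unlist(Map(function(i, o) i + o, idx, off))
  seg_of_window <- rep(seq_along(segs), K)
  list(segs = segs, K = K, stacked = stacked,
       seg_of_window = seg_of_window, n_seg = length(segs))
}

## Position llr per label column for one gene.
## U, Uc: unit count matrices (units x cols) for cases / controls, where a
## unit is a variant (mutations mode) or a distinct codon (positions
## mode); layout from .gene_seg_layout on the units' codon positions.
.gene_position_cols <- function(U, Uc, layout, pool_constant = TRUE) {
  nc <- ncol(U)
  nunit <- nrow(U)
  rep_idx <- rep(seq_len(nunit), layout$n_seg)
  gid <- layout$stacked
  Wc <- rowsum(U[rep_idx, , drop = FALSE], gid)
  seg_of <- layout$seg_of_window[as.integer(rownames(Wc))]
  if (pool_constant) {
    ## mutations mode: pooled window counts do not depend on the labels,
    ## so one vector serves every column and the control counts follow by
    ## subtraction
    u_pool <- U[, 1L] + Uc[, 1L]
    wp <- rowsum(u_pool[rep_idx], gid)[, 1L]
    Wt <- wp - Wc
    kern <- .xlog1p(Wc) + .xlog1p(Wt)
    core <- rowsum(kern, seg_of) - rowsum(.xlog1p(wp), seg_of)[, 1L]
    Xc <- colSums(U)
    Xt <- sum(u_pool) - Xc
  } else {
    ## positions mode: a codon present in both groups counts once per
    ## group, so the pooled counts are label-dependent
    Wt <- rowsum(Uc[rep_idx, , drop = FALSE], gid)
    kern <- .xlog1p(Wc) + .xlog1p(Wt) - .xlog1p(Wc + Wt)
    core <- rowsum(kern, seg_of)
    Xc <- colSums(U)
    Xt <- colSums(Uc)
  }
  ## rowsum over occupied windows only: empty windows contribute 0 to the
  ## kernel but their number K still enters the normalizing totals below
  full <- matrix(0, layout$n_seg, nc)
  full[as.integer(rownames(core)), ] <- core
  Kv <- layout$K
  ## llr(seg, col) = core - Xc*log(Xc+K) - Xt*log(Xt+K) + (Xc+Xt)*log(Xc+Xt+K)
  llr <- full -
    sweep(log(outer(Kv, Xc, "+")), 2L, Xc, "*") -
    sweep(log(outer(Kv, Xt, "+")), 2L, Xt, "*") +
    sweep(log(outer(Kv, Xc + Xt, "+")), 2L, Xc + Xt, "*")
  best <- max.col(t(llr), ties.method = "first")
  list(llr = llr[cbind(best, seq_len(nc))], best_seg = best[1L])
}

## Unit count matrices for one gene under the counting mode.
## Gsub: samples x gene variants; Lmat: samples x cols labels.
.gene_units <- function(Gsub, codons, Lmat, count_mode) {
  if (count_mode == "mutations") {
    U <- crossprod(Gsub, Lmat)            # case allele counts
    Uc <- colSums(Gsub) - U               # control allele counts
    list(U = U, Uc = Uc, codons = codons)
  } else {
    ## collapse variants to distinct codons; presence of >= 1 alt allele
    carrier <- t(rowsum(t(Gsub >= 1L) + 0L, group = codons)) >= 1L
    ucod <- as.integer(colnames(carrier))
    U <- (crossprod(carrier + 0L, Lmat) > 0) + 0L
    Uc <- (crossprod(carrier + 0L, 1L - Lmat) > 0) + 0L
    list(U = U, Uc = Uc, codons = ucod)
  }
}

## ---- per-group permutation test ----------------------------------------

.group_test <- function(genotypes, group, Lmat, weights, config) {
  G <- genotypes$G
  idx_all <- unlist(lapply(group$genes, `[[`, "variant_idx"))
  n <- nrow(G)
  ncol_ <- ncol(Lmat)
  ## burden: aggregated over all genes of the group
  if (length(idx_all)) {
    b <- individual_burden(G[, idx_all, drop = FALSE], weights[idx_all],
                           config$genetic_model)
  } else b <- rep(0, n)
  bres <- .burden_stats_cols(b, Lmat)
  ## position: per-gene best segmentation, summed across genes
  pos <- rep(0, ncol_)
  best_segs <- list()
  for (gene in group$genes) {
    vi <- gene$variant_idx
    if (!length(vi)) next
    codons <- genotypes$variants$codon_index[vi]
    units <- .gene_units(G[, vi, drop = FALSE], codons, Lmat,
                         config$count_mode)
    layout <- .gene_seg_layout(units$codons, gene$length_codons,
                               config$ws_pairs)
    gres <- .gene_position_cols(units$U, units$Uc, layout,
                                pool_constant = config$count_mode == "mutations")
    pos <- pos + gres$llr
    best_segs[[gene$gene]] <- layout$segs[[gres$best_seg]]
  }
  comb <- bomp_statistic(bres$llr, pos, config$combine)
  B <- ncol_ - 1L
  pval <- function(stat) (sum(stat[-1L] >= stat[1L]) + 1) / (B + 1)
  list(llr_burden = bres$llr[1L], llr_position = pos[1L],
       llr_combined = comb[1L],
       p_burden = pval(bres$llr), p_position = pval(pos),
       p_combined = pval(comb),
       burden_threshold = bres$threshold,
       n_case_exceed = bres$n_case_exceed,
       n_ctrl_exceed = bres$n_ctrl_exceed,
       segmentations = best_segs,
       n_genes = length(group$genes), n_variants = length(idx_all))
}

#' Run the BOMP permutation test on functional groups
#'
#' Computes the burden, position, and combined log-likelihood-ratio
#' statistics for each functional group and assigns each a permutation
#' p-value \code{(r + 1) / (B + 1)}, where r counts permuted statistics
#' at least as large as the observed one.  The full data-driven
#' optimization (burden threshold scan and per-gene segmentation
#' selection) is re-run on every permutation; one shared permutation
#' stream scores all three statistics.  Benjamini-Hochberg FDR across the
#' tested groups is appended.
#'
#' @param genotypes A \code{\link{bomp_genotypes}} object.
#' @param sample_table data.frame with columns sample, status, and
#'   optional stratum (see \code{\link{read_phenotypes}}).
#' @param groups Functional groups from \code{\link{functional_groups}};
#'   NULL tests each gene with loaded variants separately (using the
#'   maximum observed codon index + 1 as a fallback gene length when no
#'   models are supplied).
#' @param config A \code{\link{bomp_config}}.
#' @return data.frame with one row per group: \code{group},
#'   \code{n_genes}, \code{n_variants}, \code{llr_burden},
#'   \code{llr_position}, \code{llr_combined}, \code{p_burden},
#'   \code{p_position}, \code{p_combined}, \code{fdr},
#'   \code{burden_threshold}.  Per-group details (exceedance counts and
#'   chosen segmentations) are in \code{attr(, "details")}.
#' @export
bomp_test <- function(genotypes, sample_table, groups = NULL,
                      config = bomp_config()) {
  stopifnot(inherits(genotypes, "bomp_genotypes"),
            inherits(config, "bomp_config"))
  missing_s <- setdiff(genotypes$samples, sample_table$sample)
  if (length(missing_s))
    stop("phenotype table lacks sample(s): ",
         paste(missing_s, collapse = ", "))
  sample_table <- sample_table[match(genotypes$samples,
                                     sample_table$sample), ]
  labels <- as.integer(sample_table$status == "case")
  if (sum(labels) < 1L || sum(1L - labels) < 1L)
    stop("need at least one case and one control")
  if (is.null(groups)) {
    lens <- tapply(genotypes$variants$codon_index, genotypes$variants$gene,
                   function(ci) max(ci) + 1L)
    groups <- functional_groups(genotypes, lens)
  }
  strata <- NULL
  if (config$stratified) {
    if (anyNA(sample_table$stratum))
      stop("stratified permutation requires a stratum for every sample")
    strata <- sample_table$stratum
  }
  wcfg <- weight_config(config$weight_mode, config$genetic_model,
                        config$beta_prior)
  weights <- variant_weights(genotypes, wcfg)
  set.seed(config$seed)
  Lmat <- .label_matrix(labels, config$permutations, strata)
  rows <- lapply(groups, function(gr)
    .group_test(genotypes, gr, Lmat, weights, config))
  res <- data.frame(
    group = vapply(groups, `[[`, character(1), "name"),
    n_genes = vapply(rows, `[[`, integer(1), "n_genes"),
    n_variants = vapply(rows, `[[`, integer(1), "n_variants"),
    llr_burden = vapply(rows, `[[`, numeric(1), "llr_burden"),
    llr_position = vapply(rows, `[[`, numeric(1), "llr_position"),
    llr_combined = vapply(rows, `[[`, numeric(1), "llr_combined"),
    p_burden = vapply(rows, `[[`, numeric(1), "p_burden"),
    p_position = vapply(rows, `[[`, numeric(1), "p_position"),
    p_combined = vapply(rows, `[[`, numeric(1), "p_combined"),
    stringsAsFactors = FALSE, row.names = NULL)
  res$fdr <- bh_adjust(res$p_combined)
  res$burden_threshold <- vapply(rows, `[[`, numeric(1), "burden_threshold")
  attr(res, "details") <- rows
  attr(res, "n_permutations") <- config$permutations
  attr(res, "seed") <- config$seed
  res
}

#' Write a BOMP result table to TSV
#'
#' @param result data.frame from \code{\link{bomp_test}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bomp_results <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
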