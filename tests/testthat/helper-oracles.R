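# Independent oracles: likelihoods through stats::dbinom / stats::dmultinom
# (binomial and multinomial coefficients cancel in each ratio), optimizers
# through plain exhaustive loops.

oracle_bernoulli_llr <- function(k_case, n_case, k_ctrl, n_ctrl) {
  p_case <- (k_case + 1) / (n_case + 2)
  p_ctrl <- (k_ctrl + 1) / (n_ctrl + 2)
  p_pool <- (k_case + k_ctrl + 1) / (n_case + n_ctrl + 2)
  v <- dbinom(k_case, n_case, p_case, log = TRUE) +
    dbinom(k_ctrl, n_ctrl, p_ctrl, log = TRUE) -
    dbinom(k_case, n_case, p_pool, log = TRUE) -
    dbinom(k_ctrl, n_ctrl, p_pool, log = TRUE)
  sign(p_case - p_ctrl) * abs(v)
}

oracle_multinomial_llr <- function(x_case, x_ctrl) {
  K <- length(x_case)
  th_case <- (x_case + 1) / (sum(x_case) + K)
  th_ctrl <- (x_ctrl + 1) / (sum(x_ctrl) + K)
  th_pool <- (x_case + x_ctrl + 1) / (sum(x_case) + sum(x_ctrl) + K)
  dmultinom(x_case, prob = th_case, log = TRUE) +
    dmultinom(x_ctrl, prob = th_ctrl, log = TRUE) -
    dmultinom(x_case, prob = th_pool, log = TRUE) -
    dmultinom(x_ctrl, prob = th_pool, log = TRUE)
}

# exhaustive threshold search over every observed value (no other real
# threshold can change the exceedance counts)
oracle_best_threshold <- function(burdens_case, burdens_ctrl) {
  cand <- sort(unique(c(burdens_case, burdens_ctrl)))
  cand <- cand[cand > 0]
  if (!length(cand)) return(list(threshold = NA_real_, llr = 0))
  best <- list(threshold = NA_real_, llr = -Inf)
  for (t in cand) {
    llr <- oracle_bernoulli_llr(sum(burdens_case >= t), length(burdens_case),
                                sum(burdens_ctrl >= t), length(burdens_ctrl))
    if (llr > best$llr) best <- list(threshold = t, llr = llr)
  }
  best
}

# exhaustive segmentation search with naive per-window counting
oracle_best_segmentation <- function(codons, a_case, a_ctrl, L,
                                     ws_pairs = default_ws_pairs()) {
  best <- -Inf
  for (seg in enumerate_segmentations(L, ws_pairs)) {
    win <- segmentation_windows(seg, L)
    x_case <- x_ctrl <- numeric(nrow(win))
    for (w in seq_len(nrow(win))) {
      inw <- codons >= win[w, 1] & codons < win[w, 2]
      x_case[w] <- sum(a_case[inw])
      x_ctrl[w] <- sum(a_ctrl[inw])
    }
    best <- max(best, oracle_multinomial_llr(x_case, x_ctrl))
  }
  best
}

# small hand-buildable genotype fixture: n_case + n_ctrl samples
tiny_genotypes <- function(G, codons, gene = "geneA") {
  n <- nrow(G)
  variants <- data.frame(id = paste0("v", seq_len(ncol(G))),
                         gene = gene, codon_index = codons,
                         stringsAsFactors = FALSE)
  bomp_genotypes(G, variants, samples = sprintf("S%02d", seq_len(n)))
}

tiny_sample_table <- function(n_case, n_ctrl, strata = NULL) {
  n <- n_case + n_ctrl
  data.frame(sample = sprintf("S%02d", seq_len(n)),
             status = rep(c("case", "control"), c(n_case, n_ctrl)),
             stratum = if (is.null(strata)) NA_character_ else strata,
             stringsAsFactors = FALSE)
}
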