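#' Enumerate candidate window segmentations of a gene
#'
#' For each (window size w, shift increment s) pair, generates one
#' segmentation per offset in {0, s, 2s, ..., w - s} (w/s offsets).  A
#' segmentation with offset o partitions the codons [0, L) into a leading
#' partial window [0, o) (when o > 0), full windows of length w starting
#' at o, and a trailing partial window holding any remainder, so every
#' codon belongs to exactly one window.  The default grid (8,1), (16,2),
#' (32,4), (64,8) yields 32 candidate segmentations.
#'
#' @param gene_length_codons Gene coding length L in codons (>= 1).
#' @param ws_pairs List of c(w, s) integer pairs; s must divide w.
#' @return List of segmentations; each is a list with \code{window_size},
#'   \code{shift}, \code{offset}, and \code{breaks} (window start
#'   positions, 0-based, suitable for \code{findInterval}).
#' @examples
#' length(enumerate_segmentations(500))                      # 32
#' length(enumerate_segmentations(24, list(c(8, 1))))        # 8
#' @export
enumerate_segmentations <- function(gene_length_codons,
                                    ws_pairs = default_ws_pairs()) {
  L <- as.integer(gene_length_codons)
  if (L < 1L) stop("gene length must be >= 1 codon")
  out <- list()
  for (p in ws_pairs) {
    w <- as.integer(p[1L]); s <- as.integer(p[2L])
    if (s < 1L || s > w) stop("shift must satisfy 1 <= s <= w")
    if (w %% s != 0L) stop("shift must divide window size")
    for (o in seq.int(0L, w - s, by = s)) {
      full <- if (o < L) seq.int(o, L - 1L, by = w) else integer(0)
      starts <- sort(unique(c(0L, full)))  # leading partial window if o > 0
      out[[length(out) + 1L]] <- list(window_size = w, shift = s,
                                      offset = o, breaks = starts)
    }
  }
  out
}

## window index (1-based) of each codon position under a segmentation
.window_index <- function(codons, segmentation) {
  findInterval(codons, segmentation$breaks)
}

#' Window boundaries of a segmentation
#'
#' @param segmentation A segmentation from
#'   \code{\link{enumerate_segmentations}}.
#' @param gene_length_codons Gene length L in codons.
#' @return Two-column matrix of half-open codon intervals [start, end).
#' @export
segmentation_windows <- function(segmentation, gene_length_codons) {
  starts <- segmentation$breaks
  cbind(start = starts,
        end = c(starts[-1L], as.integer(gene_length_codons)))
}

#' Default window-size / shift-increment grid
#'
#' @return \code{list(c(8,1), c(16,2), c(32,4), c(64,8))}.
#' @export
default_ws_pairs <- function() list(c(8L, 1L), c(16L, 2L), c(32L, 4L), c(64L, 8L))

#' Aggregated window mutation counts
#'
#' Counts mutations per window for cases and controls under one
#' segmentation.  In \code{"mutations"} mode every allele copy at a codon
#' adds 1 to the carrier group's window count; in \code{"positions"} mode
#' each distinct mutated codon adds 1 per group regardless of how many
#' samples or alleles carry it.
#'
#' @param codons Integer codon position (0-based) of each variant.
#' @param a_case,a_ctrl Per-variant alternate allele counts in cases and
#'   controls.
#' @param segmentation A segmentation from
#'   \code{\link{enumerate_segmentations}}.
#' @param gene_length_codons Gene length L; positions must be < L.
#' @param count_mode \code{"mutations"} or \code{"positions"}.
#' @return List with integer vectors \code{x_case}, \code{x_ctrl},
#'   \code{x_pooled}, one entry per window.
#' @export
window_counts <- function(codons, a_case, a_ctrl, segmentation,
                          gene_length_codons,
                          count_mode = c("mutations", "positions")) {
  count_mode <- match.arg(count_mode)
  L <- as.integer(gene_length_codons)
  if (length(codons) && (any(codons < 0) || any(codons >= L)))
    stop("codon position outside [0, L)")
  K <- length(segmentation$breaks)
  if (count_mode == "positions" && length(codons)) {
    ## collapse to distinct codons, presence per group
    pc <- rowsum(cbind(a_case, a_ctrl), group = codons)
    codons <- as.integer(rownames(pc))
    a_case <- as.integer(pc[, 1L] > 0)
    a_ctrl <- as.integer(pc[, 2L] > 0)
  }
  x_case <- integer(K); x_ctrl <- integer(K)
  if (length(codons)) {
    wi <- .window_index(codons, segmentation)
    for (i in seq_along(codons)) {
      x_case[wi[i]] <- x_case[wi[i]] + a_case[i]
      x_ctrl[wi[i]] <- x_ctrl[wi[i]] + a_ctrl[i]
    }
  }
  list(x_case = x_case, x_ctrl = x_ctrl, x_pooled = x_case + x_ctrl)
}

#' Smoothed multinomial position log-likelihood ratio
#'
#' Compares the distribution of mutations over windows between cases and
#' controls.  Multinomial parameters use add-one smoothing per window,
#' \code{theta_w = (x_w + 1) / (X + K)}, while the likelihood exponents
#' keep the raw counts, so identical case and control distributions score
#' exactly 0.  The statistic is symmetric under exchanging the case and
#' control labels.
#'
#' @param x_case,x_ctrl Nonnegative integer window count vectors of equal
#'   length K.
#' @return Log-likelihood ratio
#'   \code{sum(x_case * log(theta_case / theta_pool) +
#'              x_ctrl * log(theta_ctrl / theta_pool))}.
#' @examples
#' multinomial_llr(c(4, 0), c(0, 4))   # 8 * log(5/3)
#' @export
multinomial_llr <- function(x_case, x_ctrl) {
  if (length(x_case) != length(x_ctrl)) stop("count vectors differ in length")
  if (any(x_case < 0) || any(x_ctrl < 0)) stop("counts must be >= 0")
  K <- length(x_case)
  if (K < 1L) stop("need at least one window")
  th_case <- (x_case + 1) / (sum(x_case) + K)
  th_ctrl <- (x_ctrl + 1) / (sum(x_ctrl) + K)
  th_pool <- (x_case + x_ctrl + 1) / (sum(x_case) + sum(x_ctrl) + K)
  sum(x_case * log(th_case / th_pool)) + sum(x_ctrl * log(th_ctrl / th_pool))
}

#' Smoothed multinomial parameter estimates
#'
#' The add-one-smoothed window distribution estimates underlying
#' \code{\link{multinomial_llr}}; each vector sums to 1.
#'
#' @inheritParams multinomial_llr
#' @return List with numeric vectors \code{theta_case},
#'   \code{theta_ctrl}, \code{theta_pooled}.
#' @export
multinomial_thetas <- function(x_case, x_ctrl) {
  if (length(x_case) != length(x_ctrl)) stop("count vectors differ in length")
  K <- length(x_case)
  list(theta_case = (x_case + 1) / (sum(x_case) + K),
       theta_ctrl = (x_ctrl + 1) / (sum(x_ctrl) + K),
       theta_pooled = (x_case + x_ctrl + 1) /
         (sum(x_case) + sum(x_ctrl) + K))
}

#' Select the best segmentation of a gene
#'
#' Evaluates \code{\link{multinomial_llr}} for every enumerated
#' segmentation of a gene and returns the maximizer (ties resolved toward
#' the first segmentation in enumeration order: (w, s) pairs in listed
#' order, offsets ascending).
#'
#' @param codons,a_case,a_ctrl Per-variant codon positions and group
#'   allele counts, as in \code{\link{window_counts}}.
#' @param gene_length_codons Gene length L in codons.
#' @param ws_pairs Segmentation grid (see
#'   \code{\link{enumerate_segmentations}}).
#' @param count_mode \code{"mutations"} or \code{"positions"}.
#' @return List with \code{llr}, \code{segmentation}, and the winning
#'   \code{counts}.
#' @export
best_segmentation <- function(codons, a_case, a_ctrl, gene_length_codons,
                              ws_pairs = default_ws_pairs(),
                              count_mode = c("mutations", "positions")) {
  count_mode <- match.arg(count_mode)
  segs <- enumerate_segmentations(gene_length_codons, ws_pairs)
  best <- NULL; best_llr <- -Inf; best_counts <- NULL
  for (seg in segs) {
    xc <- window_counts(codons, a_case, a_ctrl, seg, gene_length_codons,
                        count_mode)
    llr <- multinomial_llr(xc$x_case, xc$x_ctrl)
    if (llr > best_llr) {
      best_llr <- llr; best <- seg; best_counts <- xc
    }
  }
  list(llr = best_llr, segmentation = best, counts = best_counts)
}
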