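#' Genotype matrix container
#'
#' The substrate of all statistics: an integer samples-by-variants matrix
#' of alternate allele counts in {0, 1, 2} plus a per-variant annotation
#' table.
#'
#' @param G Integer matrix (samples x variants), values in {0, 1, 2}.
#' @param variants data.frame with columns \code{id}, \code{gene},
#'   \code{codon_index} (0-based codon offset within the gene's
#'   concatenated coding sequence) and optionally \code{score} (functional
#'   score in [0, 1]).
#' @param samples Character vector of sample identifiers (row order of
#'   \code{G}).
#' @return An object of class \code{"bomp_genotypes"}.
#' @export
bomp_genotypes <- function(G, variants, samples = rownames(G)) {
  G <- as.matrix(G)
  if (is.null(samples)) stop("sample identifiers required")
  if (!is.numeric(G) || anyNA(G)) stop("genotype values must be in {0, 1, 2}")
  rg <- range(G)
  if (rg[1L] < 0 || rg[2L] > 2 ||
      (!is.integer(G) && any(G != as.integer(G))))
    stop("genotype values must be in {0, 1, 2}")
  if (nrow(variants) != ncol(G))
    stop("variant table and genotype columns differ in length")
  need <- c("id", "gene", "codon_index")
  if (!all(need %in% names(variants)))
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  if (any(variants$codon_index < 0)) stop("codon_index must be >= 0")
  storage.mode(G) <- "integer"
  rownames(G) <- samples
  colnames(G) <- variants$id
  structure(list(G = G, variants = variants, samples = samples),
            class = "bomp_genotypes")
}

#' @export
print.bomp_genotypes <- function(x, ...) {
  cat("bomp_genotypes:", length(x$samples), "samples x",
      nrow(x$variants), "variants in",
      length(unique(x$variants$gene)), "gene(s)\n")
  invisible(x)
}

#' Map a CDS base offset to a codon index
#'
#' @param cds_offset_bases 0-based offset within the gene's concatenated
#'   coding sequence, in bases.
#' @param gene_length_bases Gene coding length in bases.  A final partial
#'   codon (length not divisible by 3) is still indexed.
#' @return Integer codon index \code{floor(offset / 3)}.  Vectorized.
#' @examples
#' map_variant_to_codon(1499, 1500)   # 499: a 1500-base gene has 500 codons
#' @export
map_variant_to_codon <- function(cds_offset_bases, gene_length_bases) {
  if (any(cds_offset_bases < 0) ||
      any(cds_offset_bases >= gene_length_bases))
    stop("CDS offset outside [0, gene length)")
  as.integer(cds_offset_bases %/% 3)
}

#' Read a sample phenotype table
#'
#' @param path 3-column TSV with header columns \code{sample},
#'   \code{status} (case/control) and optional \code{stratum}.
#' @return data.frame with columns sample, status, stratum.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "status") %in% names(tab)))
    stop("phenotype file needs 'sample' and 'status' columns: ", path)
  if (!all(tab$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (sum(tab$status == "case") < 1L || sum(tab$status == "control") < 1L)
    stop("need at least one case and one control")
  if (anyDuplicated(tab$sample)) stop("duplicated sample identifiers")
  if (is.null(tab$stratum)) tab$stratum <- NA_character_
  tab[, c("sample", "status", "stratum")]
}

#' Read gene coding models
#'
#' @param path 6-column TSV with header: \code{gene}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open CDS intervals),
#'   \code{strand} (+/-), \code{frame}.  A gene may span several rows
#'   (exons); its concatenated CDS defines the codon coordinate system
#'   (minus-strand intervals are walked in reverse genomic order).
#' @return data.frame of intervals, ordered by gene and CDS position.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end", "strand", "frame")
  if (!all(need %in% names(tab)))
    stop("gene model file needs columns: ", paste(need, collapse = ", "))
  if (any(tab$end <= tab$start)) stop("empty or inverted CDS interval")
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tab
}

#' Coding length of each gene in codons
#'
#' @param gene_models data.frame from \code{\link{read_gene_models}}.
#' @return Named integer vector of per-gene coding lengths, in codons
#'   (partial trailing codons are counted).
#' @export
gene_lengths_codons <- function(gene_models) {
  bases <- tapply(gene_models$end - gene_models$start, gene_models$gene, sum)
  lens <- as.integer(ceiling(bases / 3))
  names(lens) <- names(bases)
  lens
}

#' Read gene sets in GMT format
#'
#' Standard GMT lines: set name, description, then tab-separated gene
#' identifiers.
#'
#' @param gmt_path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene set names in ", gmt_path)
  sets <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(f) < 3L || length(genes) < 1L)
      stop("gene set line with fewer than one gene in ", gmt_path)
    genes
  })
  names(sets) <- names_
  sets
}

#' Read per-variant functional scores
#'
#' @param path 2-column TSV with header: variant id, score in [0, 1]
#'   (e.g. precomputed bioinformatics impact scores; protein-truncating
#'   variants conventionally score 1).
#' @return Named numeric vector of scores.
#' @export
read_variant_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("score file needs two columns: id, score")
  sc <- as.numeric(tab[[2L]])
  if (any(!is.finite(sc)) || any(sc < 0) || any(sc > 1))
    stop("scores must lie in [0, 1]")
  names(sc) <- as.character(tab[[1L]])
  sc
}

## map VCF records (chrom, 1-based pos) to (gene, codon_index); NA if the
## position falls outside every modeled CDS interval
.map_positions_to_genes <- function(chrom, pos, gene_models) {
  gene <- rep(NA_character_, length(pos))
  codon <- rep(NA_integer_, length(pos))
  pos0 <- pos - 1L  # to 0-based
  for (g in unique(gene_models$gene)) {
    gm <- gene_models[gene_models$gene == g, , drop = FALSE]
    minus <- gm$strand[1L] == "-"
    gm <- gm[order(gm$start, decreasing = minus), , drop = FALSE]
    width <- gm$end - gm$start
    cum <- cumsum(c(0L, width))[seq_len(nrow(gm))]
    glen <- sum(width)
    for (i in seq_len(nrow(gm))) {
      hit <- which(chrom == gm$chrom[i] & pos0 >= gm$start[i] &
                     pos0 < gm$end[i] & is.na(gene))
      if (!length(hit)) next
      off_in <- pos0[hit] - gm$start[i]
      if (minus) off_in <- width[i] - 1L - off_in
      cds_off <- cum[i] + off_in
      gene[hit] <- g
      codon[hit] <- map_variant_to_codon(cds_off, glen)
    }
  }
  list(gene = gene, codon_index = codon)
}

## parse one GT string into an alt-k allele count; "." alleles (and fully
## missing calls, which vcfR reads as NA) count 0
.gt_allele_count <- function(gt, k) {
  gt[is.na(gt)] <- "."
  gt <- sub(":.*", "", gt)
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) sum(a == as.character(k)), integer(1))
}

#' Read genotypes from a VCF into a genotype matrix
#'
#' Reads the GT field for the samples listed in a phenotype table,
#' splitting multiallelic records into one biallelic variant per
#' alternate allele, and maps each variant into gene codon coordinates
#' via the supplied gene models.  Missing genotypes ("./.") are imputed
#' as 0 copies with a reported per-variant missingness count; half-calls
#' contribute the called alleles.  Variants falling outside every gene
#' model, or with no alternate allele observed in the selected samples,
#' are dropped with a message.
#'
#' @param vcf_path Path to a VCF (v4.x) file with GT data.
#' @param sample_table data.frame from \code{\link{read_phenotypes}}.
#' @param gene_models data.frame from \code{\link{read_gene_models}}.
#' @param scores Optional named score vector from
#'   \code{\link{read_variant_scores}}.
#' @return A \code{\link{bomp_genotypes}} object whose rows follow
#'   \code{sample_table} order; attribute \code{"missingness"} holds the
#'   per-variant missing genotype counts.
#' @export
read_vcf_genotypes <- function(vcf_path, sample_table, gene_models,
                               scores = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  vcf_samples <- colnames(gt)[-1L]
  missing_samples <- setdiff(sample_table$sample, vcf_samples)
  if (length(missing_samples))
    stop("sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt <- gt[, sample_table$sample, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, sample_table$sample))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  alt <- fix[, "ALT"]
  id <- fix[, "ID"]

  cols <- list(); ids <- character(); genes <- character()
  codons <- integer(); missing_n <- integer()
  n_outside <- 0L
  map <- .map_positions_to_genes(chrom, pos, gene_models)
  for (r in seq_along(pos)) {
    if (is.na(alt[r]) || alt[r] == ".") next
    if (is.na(map$gene[r])) { n_outside <- n_outside + 1L; next }
    alts <- strsplit(alt[r], ",", fixed = TRUE)[[1L]]
    gts <- gt[r, ]
    miss <- sum(is.na(gts) | grepl("^\\.([/|]\\.)?(:.*)?$", gts))
    for (k in seq_along(alts)) {
      ac <- .gt_allele_count(gts, k)
      if (sum(ac) < 1L) next  # alt allele unobserved in these samples
      vid <- if (!is.na(id[r]) && id[r] != ".") {
        if (length(alts) > 1L) paste0(id[r], "_", alts[k]) else id[r]
      } else paste0(chrom[r], ":", pos[r], "_", alts[k])
      cols[[length(cols) + 1L]] <- ac
      ids <- c(ids, vid)
      genes <- c(genes, map$gene[r])
      codons <- c(codons, map$codon_index[r])
      missing_n <- c(missing_n, miss)
    }
  }
  if (!length(cols)) stop("no biallelic variant records retained")
  if (n_outside > 0L)
    message(n_outside, " record(s) outside all gene models dropped")
  if (sum(missing_n) > 0L)
    message(sum(missing_n), " missing genotype call(s) imputed as 0 copies")
  G <- do.call(cbind, cols)
  variants <- data.frame(id = ids, gene = genes, codon_index = codons,
                         stringsAsFactors = FALSE)
  if (!is.null(scores)) variants$score <- unname(scores[variants$id])
  gm <- bomp_genotypes(G, variants, samples = sample_table$sample)
  attr(gm, "missingness") <- missing_n
  gm
}

#' Write / read a genotype matrix as TSV
#'
#' Plain-text round-trippable export: a variant annotation block followed
#' by the sample-by-variant allele count matrix.
#'
#' @param genotypes A \code{\link{bomp_genotypes}} object.
#' @param path Output TSV path.
#' @return \code{write_genotypes_tsv}: the path, invisibly;
#'   \code{read_genotypes_tsv}: a \code{\link{bomp_genotypes}} object.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  v <- genotypes$variants
  hdr <- data.frame(sample = c("#id", "#gene", "#codon_index", "#score"),
                    rbind(v$id, v$gene, v$codon_index,
                          if (is.null(v$score)) rep(NA, nrow(v)) else v$score),
                    stringsAsFactors = FALSE)
  body <- data.frame(sample = genotypes$samples, genotypes$G,
                     check.names = FALSE, stringsAsFactors = FALSE)
  names(hdr) <- names(body)
  utils::write.table(rbind(hdr, body), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  meta <- tab[startsWith(tab$sample, "#"), -1L, drop = FALSE]
  body <- tab[!startsWith(tab$sample, "#"), , drop = FALSE]
  variants <- data.frame(
    id = as.character(meta[1L, ]),
    gene = as.character(meta[2L, ]),
    codon_index = as.integer(meta[3L, ]),
    stringsAsFactors = FALSE)
  sc <- suppressWarnings(as.numeric(meta[4L, ]))
  if (!all(is.na(sc))) variants$score <- sc
  G <- as.matrix(body[, -1L, drop = FALSE])
  storage.mode(G) <- "integer"
  bomp_genotypes(G, variants, samples = body$sample)
}

#' Build functional groups from gene sets
#'
#' Resolves gene sets against the loaded genotypes and gene lengths.  Set
#' genes with no loaded variants are retained with empty variant lists
#' (contributing nothing to the statistics); set genes with no coding
#' model are dropped with a message.  With \code{sets = NULL}, one
#' single-gene group per modeled gene with variants is returned.
#'
#' @param genotypes A \code{\link{bomp_genotypes}} object.
#' @param gene_lengths Named vector of gene coding lengths in codons
#'   (see \code{\link{gene_lengths_codons}}).
#' @param sets Named list of gene-id vectors (see
#'   \code{\link{read_gene_sets}}), or NULL.
#' @return Named list of functional groups; each has \code{name} and
#'   \code{genes}, a list of per-gene entries with \code{gene},
#'   \code{length_codons} and \code{variant_idx} (column indices into the
#'   genotype matrix).
#' @export
functional_groups <- function(genotypes, gene_lengths, sets = NULL) {
  stopifnot(inherits(genotypes, "bomp_genotypes"))
  vg <- genotypes$variants$gene
  if (is.null(sets)) {
    sets <- as.list(unique(vg))
    names(sets) <- unique(vg)
  }
  out <- lapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    if (anyDuplicated(genes)) stop("duplicate gene ids in group ", nm)
    known <- genes[genes %in% names(gene_lengths)]
    if (length(known) < length(genes))
      message("group ", nm, ": ", length(genes) - length(known),
              " gene(s) without a coding model skipped")
    if (!length(known)) return(NULL)
    glist <- lapply(known, function(g) {
      list(gene = g, length_codons = unname(gene_lengths[[g]]),
           variant_idx = which(vg == g))
    })
    list(name = nm, genes = glist)
  })
  names(out) <- names(sets)
  out[!vapply(out, is.null, logical(1))]
}
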