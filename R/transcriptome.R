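#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count / (length_kb * mapped_reads_millions)`.
#'
#' @param counts Integer matrix, genes x samples (rownames are gene ids).
#' @param gene_lengths Numeric vector of transcript lengths in bp, aligned
#'   to the rows of `counts` (or named by gene id).
#' @param library_sizes Mapped reads per sample; defaults to column sums.
#' @return Numeric matrix of RPKM values, same shape as `counts`.
#' @examples
#' rpkm(matrix(10, 1, 1), 2000, 1e6)  # 5
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (any(gene_lengths <= 0) || anyNA(gene_lengths)) {
    abort("gene lengths must be positive")
  }
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  sweep(counts / (gene_lengths / 1e3), 2, library_sizes / 1e6, "/")
}

#' Log-expression with precision weights
#'
#' Removes genes without a read in any sample (they carry no information for
#' the linear model) and computes log2 counts-per-million together with
#' per-observation precision weights from the mean-variance trend
#' (the voom approach implemented in limma, which this wraps).
#'
#' @param counts Genes x samples count matrix.
#' @param design Design matrix for the planned linear model.
#' @return A limma `EList`: `E` (log2-CPM), `weights`, plus the `design`.
#' @export
precision_weights <- function(counts, design) {
  if (nrow(design) != ncol(counts)) {
    abort("design rows must match count columns")
  }
  if (ncol(counts) - ncol(design) < 1) {
    abort("fewer than 1 residual degree of freedom")
  }
  keep <- rowSums(counts) > 0
  v <- limma::voom(counts[keep, , drop = FALSE], design)
  v$design <- design
  v
}

#' Moderated differential expression for one contrast
#'
#' Weighted least squares per gene followed by empirical-Bayes moderation of
#' the gene-wise variances (shrinkage toward a pooled prior), giving
#' moderated t statistics and two-sided p values; Benjamini-Hochberg
#' adjustment across genes. Implemented on limma (`lmFit`,
#' `contrasts.fit`, `eBayes`).
#'
#' @param v `EList` from [precision_weights()] (or a list with `E`,
#'   `weights`, `design`).
#' @param contrast Character contrast in terms of design column names, e.g.
#'   `"grouptm_zvad_t72 - grouptm_t72"`, or a numeric contrast vector.
#' @param design Optional design matrix (defaults to `v$design`).
#' @return Tibble: `gene`, `log_fc`, `fold_change` (linear, signed by
#'   direction: `2^log_fc`), `t`, `p_value`, `adj_p`.
#' @export
moderated_fit <- function(v, contrast, design = NULL) {
  design <- design %||% v$design
  if (is.null(design)) abort("a design matrix is required")
  if (qr(design)$rank < ncol(design)) abort("design matrix is not full rank")
  fit <- limma::lmFit(v, design)
  cm <- if (is.numeric(contrast)) {
    matrix(contrast, ncol = 1, dimnames = list(colnames(design), "c1"))
  } else {
    limma::makeContrasts(contrasts = contrast, levels = design)
  }
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  tt <- limma::topTable(fit2, coef = 1, number = Inf, sort.by = "none")
  tibble(gene = rownames(tt),
         log_fc = tt$logFC,
         fold_change = 2^tt$logFC,
         t = tt$t,
         p_value = tt$P.Value,
         adj_p = tt$adj.P.Val)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up adjustment (the default "adjusted p value" convention of the
#' limma workflow). Permutation-invariant in the input order.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression between treatment arms at one time point
#'
#' Convenience wrapper composing [precision_weights()] and
#' [moderated_fit()] for the matched-time contrast of the inhibitor arm
#' against the stress-only arm (the design used to find genes whose
#' expression caspase activity suppresses).
#'
#' @param counts Genes x samples count matrix.
#' @param samples Sample table (`sample`, `treatment`, `time_h`) aligned to
#'   the columns of `counts`.
#' @param time_h Time point of the contrast (default 72).
#' @param treatments Length-2: (numerator arm, denominator arm); defaults to
#'   inhibitor vs stress-only as ordered in the sample table.
#' @return Tibble as [moderated_fit()].
#' @export
fit_de <- function(counts, samples, time_h = 72, treatments = NULL) {
  stopifnot(all(samples$sample == colnames(counts)))
  if (is.null(treatments)) {
    u <- unique(samples$treatment)
    if (length(u) < 2) abort("two treatment arms are required")
    treatments <- c(u[2], u[1])  # inhibitor arm vs stress-only
  }
  group <- factor(paste0(samples$treatment, "_t", samples$time_h))
  design <- stats::model.matrix(~ 0 + group)
  colnames(design) <- levels(group)
  a <- paste0(treatments[1], "_t", time_h)
  b <- paste0(treatments[2], "_t", time_h)
  if (!all(c(a, b) %in% colnames(design))) {
    abort(sprintf("contrast groups '%s' and '%s' not found in the design",
                  a, b))
  }
  v <- precision_weights(counts, design)
  moderated_fit(v, paste(a, "-", b))
}

#' Significant genes under the paper-style thresholds
#'
#' Strict filters: adjusted p below `p_cut` and linear fold change above
#' `fc_cut` in either direction (`max(FC, 1/FC) > fc_cut`); values exactly
#' at a threshold are excluded. Direction-split counts are attached as the
#' `"counts"` attribute.
#'
#' @param de DE tibble ([moderated_fit()]).
#' @param p_cut Adjusted-p threshold (default 0.05).
#' @param fc_cut Linear fold-change threshold (default 2).
#' @return Filtered tibble with a `direction` column (`"up"`/`"down"`).
#' @export
significant_genes <- function(de, p_cut = 0.05, fc_cut = 2) {
  ratio <- pmax(de$fold_change, 1 / de$fold_change)
  keep <- de$adj_p < p_cut & ratio > fc_cut
  out <- de[keep, ]
  out$direction <- ifelse(out$log_fc > 0, "up", "down")
  attr(out, "counts") <- c(up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}

#' Hierarchical clustering of samples on variance-stabilized counts
#'
#' Variance-stabilizes the counts (default `log2(count + pseudo)`; the full
#' dispersion-based DESeq2 transform is available behind `vst = "deseq"`),
#' selects the `top_n` most variable genes, and applies Ward clustering on
#' Euclidean sample distances.
#'
#' @param counts Genes x samples count matrix.
#' @param top_n Number of most-variable genes (capped at the gene count,
#'   with a warning).
#' @param vst `"log"` (default) or `"deseq"` (requires DESeq2).
#' @param pseudo Pseudo-count for the log transform.
#' @return An `hclust` tree of the samples.
#' @export
sample_cluster <- function(counts, top_n = 500, vst = c("log", "deseq"),
                           pseudo = 1) {
  vst <- match.arg(vst)
  if (ncol(counts) < 3) abort("at least 3 samples are required")
  x <- if (vst == "log") {
    log2(counts + pseudo)
  } else {
    if (!requireNamespace("DESeq2", quietly = TRUE)) {
      abort("vst = 'deseq' requires the DESeq2 package")
    }
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = counts,
      colData = data.frame(row.names = colnames(counts),
                           cond = factor(rep(1, ncol(counts)))),
      design = ~ 1)
    SummarizedExperiment::assay(DESeq2::varianceStabilizingTransformation(dds))
  }
  if (top_n > nrow(x)) {
    warn("top_n exceeds the number of genes; using all genes")
    top_n <- nrow(x)
  }
  vars <- apply(x, 1, var)
  sel <- order(vars, decreasing = TRUE)[seq_len(top_n)]
  hclust(dist(t(x[sel, , drop = FALSE])), method = "ward.D2")
}

#' Newick export of a linkage tree
#'
#' @param hc An `hclust` object.
#' @return A single newick string (requires the ape package).
#' @export
linkage_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("linkage_newick requires the ape package")
  }
  ape::write.tree(ape::as.phylo(hc))
}
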