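# Per-sample normalization factors from a reference-gene set, applied on
# the log2 scale by subtraction (geometric-mean division on the linear
# scale).

#' Per-sample normalization factors from a reference-gene set
#'
#' `nf_s` is the arithmetic mean over the reference genes of their log2
#' quantities in sample s (the log2 of the geometric mean on the linear
#' scale). Shifting a reference gene's row by a constant shifts every
#' `nf_s` by the same amount over the set size, so normalized
#' *differences* are unaffected.
#'
#' @param q a [logq_matrix()] or genes x samples matrix.
#' @param ref_genes non-empty character vector of genes present in `q`
#'   with no missing values (an rRNA column such as "28s" is treated like
#'   any other gene).
#' @return object of class `norm_factors`: named numeric vector of
#'   `nf_s` with attribute `ref_genes`.
#' @export
normalization_factors <- function(q, ref_genes) {
  q <- as.matrix(q)
  ref_genes <- unique(as.character(ref_genes))
  if (length(ref_genes) == 0)
    rs_stop("ref_genes must be non-empty", "refsel_validation_error")
  unknown <- setdiff(ref_genes, rownames(q))
  if (length(unknown) > 0)
    rs_stop(paste0("reference gene(s) absent from matrix: ",
                   paste(unknown, collapse = ", ")),
            "refsel_validation_error")
  sub <- q[ref_genes, , drop = FALSE]
  if (anyNA(sub)) {
    idx <- which(is.na(sub), arr.ind = TRUE)[1, ]
    rs_stop(sprintf("missing reference value: gene '%s', sample '%s'",
                    ref_genes[idx[1]], colnames(q)[idx[2]]),
            "refsel_missing_error")
  }
  structure(colMeans(sub), ref_genes = ref_genes, class = "norm_factors")
}

#' Apply normalization factors to a log2 quantity matrix
#'
#' Subtracts `nf_s` from every gene in sample s, cancelling per-sample
#' loading. Reference genes are dropped from the result by default: their
#' post-normalization stability is an inevitable consequence of their use
#' and keeping them in downstream differential tests would be circular.
#'
#' @param q a [logq_matrix()] or genes x samples matrix.
#' @param nf a [normalization_factors()] result covering all samples of
#'   `q` (or a named numeric vector).
#' @param keep_refs keep the reference-gene rows (default `FALSE`).
#' @return a [logq_matrix()] of normalized values.
#' @export
apply_normalization <- function(q, nf, keep_refs = FALSE) {
  q <- as.matrix(q)
  miss <- setdiff(colnames(q), names(nf))
  if (length(miss) > 0)
    rs_stop(paste0("samples without a normalization factor: ",
                   paste(head(miss, 5), collapse = ", ")),
            "refsel_validation_error")
  out <- sweep(q, 2, as.numeric(nf[colnames(q)]))
  refs <- attr(nf, "ref_genes")
  if (!keep_refs && !is.null(refs))
    out <- out[setdiff(rownames(out), refs), , drop = FALSE]
  logq_matrix(out)
}
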