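# End-to-end workflow: quantify -> (optional gene exclusion) ->
# geNorm + NormFinder (+ nested) -> choose reference set -> normalize ->
# group statistics -> reports.

#' Build a workflow configuration
#'
#' Every argument has a CLI twin in the `refsel` command-line script.
#' Inputs may be file paths (CSV, as documented in the readers) or
#' in-memory objects.
#'
#' @param ct a [ct_table()] or path to a Ct CSV.
#' @param annotation annotation data frame or path to an annotation CSV.
#' @param curves standard-curve dilution table (data frame with `gene`,
#'   `log2_rel_conc`, `ct`, or a path), or `NULL` to use `fixed_slope`
#'   for every gene.
#' @param fixed_slope fallback slope for genes without a curve
#'   (default -1).
#' @param exclude_genes genes dropped from the candidate panel *before*
#'   stability analysis (e.g. a clearly differentially expressed
#'   candidate, or an rRNA assay); they stay in the matrix for
#'   normalization targets.
#' @param method reference selection method for the default reference
#'   set: `"genorm"` or `"normfinder"`.
#' @param cutoff geNorm pairwise-variation inclusion cutoff
#'   (default 0.15).
#' @param n_refs number of reference genes; `NULL` = geNorm's
#'   `include_count` (for `method = "normfinder"`, `NULL` means 4).
#' @param refs explicit reference-gene override (skips selection).
#' @param baseline baseline group for [relative_expression()]; `NULL`
#'   skips that report.
#' @param genorm_input `"logq"` (slope-adjusted quantities, default) or
#'   `"ct"` (raw Ct values, as when all slopes are taken as equal).
#' @param min_stability,max_rank filters for [nested_normfinder()];
#'   `run_nested` enables the nested-loop ledger.
#' @param run_nested run the nested-loop selection (default `FALSE`).
#' @param keep_refs keep reference genes in the normalized matrix.
#' @param out_dir if non-`NULL`, write every intermediate as CSV there.
#' @return list of class `workflow_config`.
#' @export
workflow_config <- function(ct, annotation, curves = NULL, fixed_slope = -1,
                            exclude_genes = character(0),
                            method = c("genorm", "normfinder"),
                            cutoff = 0.15, n_refs = NULL, refs = NULL,
                            baseline = NULL,
                            genorm_input = c("logq", "ct"),
                            min_stability = NULL, max_rank = NULL,
                            run_nested = FALSE, keep_refs = FALSE,
                            out_dir = NULL) {
  structure(list(ct = ct, annotation = annotation, curves = curves,
                 fixed_slope = fixed_slope, exclude_genes = exclude_genes,
                 method = match.arg(method), cutoff = cutoff,
                 n_refs = n_refs, refs = refs, baseline = baseline,
                 genorm_input = match.arg(genorm_input),
                 min_stability = min_stability, max_rank = max_rank,
                 run_nested = run_nested, keep_refs = keep_refs,
                 out_dir = out_dir),
            class = "workflow_config")
}

#' Run the complete reference-gene workflow
#'
#' Executes quantification, stability analysis with both methods,
#' reference-set choice, normalization and group statistics, optionally
#' writing every intermediate table as CSV. Re-running with identical
#' config and inputs is bit-identical.
#'
#' @param config a [workflow_config()].
#' @return list of class `workflow_result`: `curve_summary`, `logq`,
#'   `genorm`, `normfinder`, `nested` (or `NULL`), `refs`, `normq`,
#'   `contrasts`, `relative` (or `NULL`), `files` (paths written).
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      rs_stop(paste0("workflow stage '", what, "': ", conditionMessage(e)),
              "refsel_workflow_error")
    })
  }
  ct <- stage("read ct", if (inherits(config$ct, "ct_table")) config$ct
              else read_ct_table(config$ct))
  ann <- stage("read annotation",
               if (is.data.frame(config$annotation))
                 validate_annotation(config$annotation)
               else read_annotation(config$annotation))
  curves <- NULL; csum <- NULL
  if (!is.null(config$curves)) {
    ctab <- stage("read curves", if (is.data.frame(config$curves))
      config$curves else
        read.csv(config$curves, stringsAsFactors = FALSE))
    curves <- stage("fit curves", fit_standard_curves(ctab))
    csum <- curve_summary(curves)
  }
  logq <- stage("quantify",
                ct_to_log2_quantity(ct, curves,
                                    fixed_slope = config$fixed_slope))
  panel <- setdiff(rownames(logq), config$exclude_genes)
  unknown <- setdiff(config$exclude_genes, rownames(logq))
  if (length(unknown) > 0)
    rs_stop(paste0("excluded gene(s) not in panel: ",
                   paste(unknown, collapse = ", ")),
            "refsel_validation_error")
  stab_in <- if (config$genorm_input == "ct") {
    cm <- merge_replicates(ct)
    m <- matrix(NA_real_, length(ct_genes(cm)), length(ct_samples(cm)),
                dimnames = list(ct_genes(cm), ct_samples(cm)))
    m[cbind(match(cm$gene, rownames(m)), match(cm$sample, colnames(m)))] <- cm$ct
    m[panel, , drop = FALSE]
  } else logq[panel, , drop = FALSE]
  gn <- stage("genorm", genorm(stab_in, cutoff = config$cutoff))
  nf <- stage("normfinder", normfinder(logq[panel, , drop = FALSE], ann))
  nested <- NULL
  if (config$run_nested)
    nested <- stage("nested", nested_normfinder(
      logq[panel, , drop = FALSE], ann,
      min_stability = config$min_stability, max_rank = config$max_rank))
  refs <- config$refs
  if (is.null(refs)) {
    if (config$method == "genorm") {
      n <- if (is.null(config$n_refs)) gn$include_count else config$n_refs
      refs <- gn$ranking[seq_len(n)]
    } else {
      n <- if (is.null(config$n_refs)) 4L else config$n_refs
      refs <- nf$ranking[seq_len(min(n, length(nf$ranking)))]
    }
  }
  if (!all(refs %in% rownames(logq)))
    rs_stop(paste0("reference gene(s) not in matrix: ",
                   paste(setdiff(refs, rownames(logq)), collapse = ", ")),
            "refsel_validation_error")
  nfac <- stage("normalization factors", normalization_factors(logq, refs))
  normq <- stage("normalize",
                 apply_normalization(logq, nfac,
                                     keep_refs = config$keep_refs))
  fit <- stage("group model", fit_group_model(normq, ann))
  contrasts <- stage("contrasts", pairwise_contrasts(fit))
  relative <- NULL
  if (!is.null(config$baseline))
    relative <- stage("relative expression",
                      relative_expression(fit, config$baseline))
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wf <- function(obj, name) {
      p <- file.path(config$out_dir, name)
      write.csv(obj, p, row.names = FALSE, quote = FALSE)
      p
    }
    if (!is.null(csum)) files <- c(files, wf(csum, "curve_summary.csv"))
    p <- file.path(config$out_dir, "logq.csv"); write_logq(logq, p)
    files <- c(files, p)
    files <- c(files, wf(data.frame(gene = names(gn$m_values),
                                    m = as.numeric(gn$m_values)),
                         "genorm_m.csv"))
    files <- c(files, wf(data.frame(step = names(gn$v_series),
                                    v = as.numeric(gn$v_series)),
                         "genorm_v.csv"))
    files <- c(files, wf(data.frame(gene = names(nf$rho),
                                    rho = as.numeric(nf$rho)),
                         "normfinder_rho.csv"))
    if (!is.null(nested)) files <- c(files, wf(nested$ledger, "nested_ledger.csv"))
    p <- file.path(config$out_dir, "normq.csv"); write_logq(normq, p)
    files <- c(files, p)
    files <- c(files, wf(contrasts, "contrasts.csv"))
    if (!is.null(relative)) files <- c(files, wf(relative, "relative_expression.csv"))
  }
  structure(list(curve_summary = csum, logq = logq, genorm = gn,
                 normfinder = nf, nested = nested, refs = refs,
                 norm_factors = nfac, normq = normq, fit = fit,
                 contrasts = contrasts, relative = relative, files = files),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("refsel workflow result\n")
  cat("  reference set:", paste(x$refs, collapse = ", "), "\n")
  cat(sprintf("  geNorm include_count: %d; NormFinder best: %s\n",
              x$genorm$include_count, x$normfinder$ranking[1]))
  cat(sprintf("  %d contrasts (Bonferroni family %d), %d significant at adjusted 0.05\n",
              nrow(x$contrasts), attr(x$contrasts, "family_size"),
              sum(x$contrasts$p_bonferroni < 0.05)))
  if (length(x$files) > 0)
    cat("  files:", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}
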