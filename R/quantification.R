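# Standard-curve fitting in log2 space and Ct -> log2 relative quantity.
#
# Curves are ordinary least squares of Ct on log2 relative template
# concentration; with perfect two-fold amplification per cycle the slope
# is -1 and the efficiency (fold/cycle) is 2. Experimental Cts are divided
# by the gene's slope, giving the log2 of the template amount relative to
# the (arbitrary) threshold amount: only within-gene differences between
# samples are meaningful.

#' Fit a qPCR standard curve in log2 space
#'
#' Ordinary least squares of Ct on the log2 of the relative template
#' concentration of a dilution series (top standard at 0; ten-fold steps
#' are `-log2(10)` = -3.3219 apart). Perfect two-fold amplification per
#' cycle gives slope -1; the per-cycle efficiency is `2^(-1/slope)`.
#'
#' Curves whose efficiency falls outside `eff_range` or whose R-squared is
#' below `min_r_squared` are flagged (not rejected): `flags` in the result
#' lists the conditions. A fitted slope >= 0 is also flagged, since signal
#' must appear earlier with more template for a usable assay.
#'
#' @param log2_conc numeric, log2 relative concentration of each well.
#' @param ct numeric, observed Ct of each well.
#' @param gene gene label carried through to the result.
#' @param eff_range acceptable fold-per-cycle range before flagging.
#' @param min_r_squared minimum R-squared before flagging.
#' @return An object of class `standard_curve`: list with `gene`, `slope`,
#'   `intercept`, `slope_se`, `slope_ci95` (length-2), `r_squared`,
#'   `fold_per_cycle`, `n_points`, `flags`.
#' @examples
#' x <- c(0, -3.32, -6.64, -9.97)
#' fit_standard_curve(x, 30 - 1.0 * x, gene = "ACTB")
#' @export
fit_standard_curve <- function(log2_conc, ct, gene = "",
                               eff_range = c(1.8, 2.2),
                               min_r_squared = 0.98) {
  ok <- !is.na(log2_conc) & !is.na(ct)
  log2_conc <- log2_conc[ok]; ct <- ct[ok]
  if (length(ct) < 3)
    rs_stop(sprintf("standard curve for '%s' needs >= 3 points, got %d",
                    gene, length(ct)), "refsel_validation_error")
  if (length(unique(log2_conc)) < 2)
    rs_stop(sprintf("standard curve for '%s' is degenerate: all wells at one concentration",
                    gene), "refsel_degenerate_design_error")
  fit <- lm(ct ~ log2_conc)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  slope_se <- sm$coefficients[2, 2]
  n <- length(ct)
  tq <- qt(0.975, df = n - 2)
  r2 <- sm$r.squared
  flags <- character(0)
  if (slope >= 0) {
    flags <- c(flags, "nonnegative_slope")
    eff <- NA_real_
  } else {
    eff <- efficiency_from_slope(slope)
    if (eff < eff_range[1] || eff > eff_range[2])
      flags <- c(flags, "efficiency_out_of_range")
  }
  if (r2 < min_r_squared) flags <- c(flags, "low_r_squared")
  structure(list(
    gene = gene, slope = slope, intercept = intercept, slope_se = slope_se,
    slope_ci95 = c(slope - tq * slope_se, slope + tq * slope_se),
    r_squared = r2, fold_per_cycle = eff, n_points = n, flags = flags
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve %s: slope %.4f (SE %.4f, 95%% CI %.4f..%.4f), R2 %.4f, fold/cycle %.4f, n = %d\n",
    x$gene, x$slope, x$slope_se, x$slope_ci95[1], x$slope_ci95[2],
    x$r_squared, x$fold_per_cycle, x$n_points))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `2^(-1/slope)`: the per-cycle template multiplication factor. Slope -1
#' gives 2 (perfect doubling).
#'
#' @param slope slope of Ct vs log2 relative concentration; must be < 0.
#' @return fold-per-cycle efficiency.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || is.na(slope) || slope >= 0)
    rs_stop("efficiency is defined only for negative slopes",
            "refsel_domain_error")
  2^(-1 / slope)
}

#' Fit standard curves for every gene in a dilution table
#'
#' @param df data frame with columns `gene`, `log2_rel_conc`, `ct`
#'   (one row per well).
#' @param ... passed to [fit_standard_curve()].
#' @return named list of `standard_curve` objects, one per gene.
#' @export
fit_standard_curves <- function(df, ...) {
  need <- c("gene", "log2_rel_conc", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    rs_stop(paste0("standard-curve table lacks column(s): ",
                   paste(miss, collapse = ", ")), "refsel_validation_error")
  genes <- unique(as.character(df$gene))
  curves <- lapply(genes, function(g) {
    sub <- df[df$gene == g, ]
    fit_standard_curve(as.numeric(sub$log2_rel_conc), as.numeric(sub$ct),
                       gene = g, ...)
  })
  setNames(curves, genes)
}

#' Summarise fitted standard curves as a data frame
#'
#' One row per gene with the columns written by the `stdcurve` command:
#' slope, its SE and 95% CI, R-squared, efficiency and point count.
#'
#' @param curves named list of `standard_curve` objects.
#' @return data frame.
#' @export
curve_summary <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(gene = cv$gene, slope = cv$slope, slope_se = cv$slope_se,
               ci_lo = cv$slope_ci95[1], ci_hi = cv$slope_ci95[2],
               r_squared = cv$r_squared, fold_per_cycle = cv$fold_per_cycle,
               n_points = cv$n_points,
               flags = paste(cv$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Construct a log2 relative-quantity matrix
#'
#' @param values numeric matrix, genes in rows (rownames) and samples in
#'   columns (colnames).
#' @param provenance optional named character recording which curve or
#'   fixed slope produced each gene row.
#' @return matrix of class `logq_matrix`.
#' @export
logq_matrix <- function(values, provenance = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    rs_stop("logq_matrix needs gene rownames and sample colnames",
            "refsel_validation_error")
  structure(values, provenance = provenance,
            class = c("logq_matrix", class(values)))
}

#' Convert Ct observations to efficiency-corrected log2 quantities
#'
#' Each Ct is divided by the gene's standard-curve slope, giving the log2
#' of the template amount at the start of the assay relative to the
#' threshold amount. With slope exactly -1 this is `-Ct`, so differences
#' between samples reduce to ordinary delta-Cq. The absolute level of a
#' gene row carries no meaning; only within-gene differences (sample
#' ratios) do.
#'
#' @param table a [ct_table()]; technical replicates are averaged first
#'   via [merge_replicates()].
#' @param curves named list of `standard_curve` objects (or a named
#'   numeric vector of slopes); genes without an entry fall back to
#'   `fixed_slope` when that is non-`NULL`.
#' @param fixed_slope slope used for genes without a fitted curve, or for
#'   all genes when `curves` is `NULL`. Default -1 (assumes perfect
#'   doubling). Set to `NULL` to make a missing curve an error.
#' @return a [logq_matrix()] (genes x samples); missing Ct stays missing.
#' @export
ct_to_log2_quantity <- function(table, curves = NULL, fixed_slope = -1) {
  stopifnot(inherits(table, "ct_table"))
  table <- merge_replicates(table)
  genes <- ct_genes(table)
  samples <- ct_samples(table)
  slopes <- setNames(rep(NA_real_, length(genes)), genes)
  if (!is.null(curves)) {
    if (is.numeric(curves)) {
      slopes[intersect(genes, names(curves))] <-
        curves[intersect(genes, names(curves))]
    } else {
      for (g in intersect(genes, names(curves)))
        slopes[g] <- curves[[g]]$slope
    }
  }
  if (any(is.na(slopes))) {
    if (is.null(fixed_slope))
      rs_stop(paste0("no standard curve for gene(s): ",
                     paste(names(slopes)[is.na(slopes)], collapse = ", ")),
              "refsel_validation_error")
    slopes[is.na(slopes)] <- fixed_slope
  }
  if (any(slopes >= 0))
    rs_stop("all slopes must be negative", "refsel_domain_error")
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(table$gene, genes), match(table$sample, samples))] <- table$ct
  q <- m / slopes[genes]
  logq_matrix(q, provenance = setNames(
    sprintf("slope=%.6g", slopes[genes]), genes))
}

#' Write / read a log2 quantity matrix as CSV
#'
#' Genes in rows (first column `gene`), samples as remaining columns.
#' @param q a [logq_matrix()].
#' @param path file path.
#' @return `read_logq` returns a [logq_matrix()]; `write_logq` returns
#'   `path` invisibly.
#' @export
write_logq <- function(q, path) {
  df <- data.frame(gene = rownames(q), as.data.frame(unclass(q)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_logq
#' @export
read_logq <- function(path) {
  if (!file.exists(path))
    rs_stop(paste0("file not found: ", path), "refsel_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene")
    rs_stop("logq CSV must have 'gene' as its first column",
            "refsel_parse_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  logq_matrix(m)
}
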