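# Ct data model and I/O.
#
# A ct_table is a long-format data frame of quantification-cycle (Ct/Cq)
# observations keyed by (sample, gene, replicate), with an attached
# max_cycles attribute. "No signal" wells are NA, never 0 or max_cycles.

#' Construct a Ct table
#'
#' A `ct_table` holds long-format Ct (quantification cycle) observations,
#' one row per well, keyed by `(sample, gene, replicate)`. Wells that gave
#' no signal within `max_cycles` cycles are represented as `NA`, never as
#' 0 or as the cycle limit.
#'
#' @param data data frame with columns `sample`, `gene`, `ct` and
#'   optionally `replicate` (integer >= 1; defaults to 1).
#' @param max_cycles maximum number of cycles run on the instrument;
#'   every non-missing Ct must lie in `(0, max_cycles]`. Default 40.
#' @return A data frame of class `ct_table` with columns
#'   `sample`, `gene`, `ct`, `replicate` and attribute `max_cycles`.
#' @examples
#' ct_table(data.frame(sample = c("s1", "s1"), gene = c("ACTB", "TBP"),
#'                     ct = c(21.5, 29.0)))
#' @export
ct_table <- function(data, max_cycles = 40) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "ct")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    rs_stop(paste0("ct_table is missing column(s): ", paste(miss, collapse = ", ")),
            "refsel_validation_error")
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  data$sample <- as.character(data$sample)
  data$gene <- as.character(data$gene)
  data$ct <- as.numeric(data$ct)
  data$replicate <- as.integer(data$replicate)
  if (anyNA(data$replicate) || any(data$replicate < 1L))
    rs_stop("replicate must be an integer >= 1", "refsel_validation_error")
  bad <- which(!is.na(data$ct) & (data$ct <= 0 | data$ct > max_cycles))
  if (length(bad) > 0)
    rs_stop(sprintf(
      "Ct outside (0, %s] in row(s) %s (e.g. sample '%s', gene '%s', ct = %s)",
      max_cycles, paste(head(bad, 5), collapse = ", "),
      data$sample[bad[1]], data$gene[bad[1]], data$ct[bad[1]]),
      "refsel_validation_error")
  key <- paste(data$sample, data$gene, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    rs_stop(sprintf("duplicate (sample, gene, replicate) record: %s",
                    gsub("\r", ", ", d)), "refsel_validation_error")
  }
  out <- data[, c("sample", "gene", "ct", "replicate")]
  rownames(out) <- NULL
  structure(out, max_cycles = max_cycles, class = c("ct_table", "data.frame"))
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d records, %d samples, %d genes (max %d cycles)\n",
              nrow(x), length(ct_samples(x)), length(ct_genes(x)),
              attr(x, "max_cycles")))
  print(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Ordered, duplicate-free gene and sample lists of a Ct table
#'
#' Order of first appearance in the table.
#' @param x a [ct_table()].
#' @return character vector.
#' @export
ct_genes <- function(x) unique(x$gene)

#' @rdname ct_genes
#' @export
ct_samples <- function(x) unique(x$sample)

#' Read a long-format Ct table from CSV
#'
#' The file must have a header naming (at least) the sample, gene and Ct
#' columns. Cells matching one of `na_strings` (by default `""`,
#' `"Undetermined"` and `"NA"`, the usual instrument exports for wells with
#' no signal) are read as missing.
#'
#' @param path path to a CSV file.
#' @param max_cycles cycle limit used for validation (default 40).
#' @param na_strings character vector of sentinel strings mapped to `NA`.
#' @param columns named list mapping the canonical names `sample`, `gene`,
#'   `ct`, `replicate` to the column names used in the file.
#' @return a [ct_table()].
#' @export
read_ct_table <- function(path, max_cycles = 40,
                          na_strings = c("", "Undetermined", "NA"),
                          columns = list(sample = "sample", gene = "gene",
                                         ct = "ct", replicate = "replicate")) {
  if (!file.exists(path))
    rs_stop(paste0("file not found: ", path), "refsel_io_error")
  columns <- modifyList(list(sample = "sample", gene = "gene",
                             ct = "ct", replicate = "replicate"), columns)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  for (canon in c("sample", "gene", "ct")) {
    if (!columns[[canon]] %in% names(raw))
      rs_stop(sprintf("header of %s lacks required column '%s'",
                      path, columns[[canon]]), "refsel_parse_error")
  }
  ct_chr <- trimws(raw[[columns$ct]])
  is_na <- ct_chr %in% na_strings
  ct_num <- suppressWarnings(as.numeric(ct_chr))
  bad <- which(!is_na & is.na(ct_num))
  if (length(bad) > 0)
    rs_stop(sprintf("malformed Ct value '%s' at %s line %d",
                    ct_chr[bad[1]], path, bad[1] + 1L), "refsel_parse_error")
  ct_num[is_na] <- NA_real_
  df <- data.frame(sample = raw[[columns$sample]],
                   gene = raw[[columns$gene]],
                   ct = ct_num, stringsAsFactors = FALSE)
  if (columns$replicate %in% names(raw))
    df$replicate <- as.integer(raw[[columns$replicate]])
  ct_table(df, max_cycles = max_cycles)
}

#' Write a Ct table to CSV
#'
#' Numeric Ct values are written with full precision so that
#' `read_ct_table(write_ct_table(x, f))` is the identity. Missing Ct is
#' written as the empty string.
#'
#' @param x a [ct_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  out <- as.data.frame(x)
  out$ct <- ifelse(is.na(out$ct), "", format(out$ct, digits = 15, trim = TRUE,
                                             scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample annotation table from CSV
#'
#' Columns `sample` and `group` are required; an optional `unit` column
#' labels the biological replicate (bird, embryo). Every sample must
#' appear exactly once and have a non-empty group.
#'
#' @param path path to a CSV file.
#' @param columns named list mapping `sample`, `group`, `unit` to file
#'   column names.
#' @return data frame with columns `sample`, `group` (and `unit` if given).
#' @export
read_annotation <- function(path, columns = list(sample = "sample",
                                                 group = "group",
                                                 unit = "unit")) {
  if (!file.exists(path))
    rs_stop(paste0("file not found: ", path), "refsel_io_error")
  columns <- modifyList(list(sample = "sample", group = "group", unit = "unit"),
                        columns)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  for (canon in c("sample", "group")) {
    if (!columns[[canon]] %in% names(raw))
      rs_stop(sprintf("header of %s lacks required column '%s'",
                      path, columns[[canon]]), "refsel_parse_error")
  }
  ann <- data.frame(sample = raw[[columns$sample]],
                    group = raw[[columns$group]], stringsAsFactors = FALSE)
  if (columns$unit %in% names(raw)) ann$unit <- raw[[columns$unit]]
  validate_annotation(ann)
}

#' @noRd
validate_annotation <- function(ann) {
  ann$sample <- as.character(ann$sample)
  ann$group <- as.character(ann$group)
  if (anyDuplicated(ann$sample))
    rs_stop(sprintf("duplicate sample in annotation: '%s'",
                    ann$sample[duplicated(ann$sample)][1]),
            "refsel_validation_error")
  empty <- which(is.na(ann$group) | trimws(ann$group) == "")
  if (length(empty) > 0)
    rs_stop(sprintf("missing group for sample '%s'", ann$sample[empty[1]]),
            "refsel_validation_error")
  rownames(ann) <- NULL
  ann
}

#' Average technical replicates of a Ct table
#'
#' Collapses a `ct_table` to one record per `(sample, gene)`. Averaging is
#' done on the Ct scale (arithmetic mean of non-missing replicate Cts),
#' which keeps the data in the logarithmic domain native to qPCR. A
#' `(sample, gene)` whose replicates are all missing stays missing.
#' The operation is idempotent.
#'
#' @param x a [ct_table()].
#' @param method replicate summary; only `"mean_ct"` is defined.
#' @return a [ct_table()] with `replicate` all 1.
#' @export
merge_replicates <- function(x, method = "mean_ct") {
  stopifnot(inherits(x, "ct_table"))
  method <- match.arg(method, "mean_ct")
  key <- paste(x$sample, x$gene, sep = "\r")
  first <- !duplicated(key)
  means <- vapply(split(x$ct, factor(key, levels = key[first])),
                  function(v) {
                    v <- v[!is.na(v)]
                    if (length(v) == 0) NA_real_ else mean(v)
                  }, numeric(1))
  out <- data.frame(sample = x$sample[first], gene = x$gene[first],
                    ct = as.numeric(means), replicate = 1L,
                    stringsAsFactors = FALSE)
  ct_table(out, max_cycles = attr(x, "max_cycles"))
}
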