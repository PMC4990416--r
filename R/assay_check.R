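# In-silico verification of qPCR assay layout: exact primer placement,
# amplicon prediction from mRNA and genomic templates, and exon-junction
# rules. A DNA-refractory TaqMan assay needs each primer wholly within a
# different exon (so the amplicon spans at least one intron-exon
# boundary) and the probe spanning a spanned junction. All coordinates
# are 0-based half-open; reported amplicon lengths include both primers.

#' Validate and normalise a primer/probe DNA sequence
#' @noRd
check_dna <- function(seq, what) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0)
    rs_stop(paste0(what, " sequence must be a non-empty string"),
            "refsel_validation_error")
  if (grepl("[^ACGT]", seq))
    rs_stop(paste0(what, " contains non-ACGT characters (ambiguity codes are not supported): ",
                   seq), "refsel_validation_error")
  seq
}

#' Reverse complement of a DNA string
#'
#' @param seq character string over A/C/G/T (case-insensitive).
#' @return upper-case reverse complement.
#' @export
reverse_complement <- function(seq) {
  seq <- check_dna(seq, "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Construct a primer/probe assay definition
#'
#' @param gene gene label.
#' @param forward,reverse,probe primer and probe sequences written 5'->3'
#'   over A/C/G/T (reporter/quencher annotations must be stripped).
#' @return object of class `assay_design`.
#' @export
assay_design <- function(gene, forward, reverse, probe) {
  structure(list(gene = as.character(gene),
                 forward = check_dna(forward, "forward primer"),
                 reverse = check_dna(reverse, "reverse primer"),
                 probe = check_dna(probe, "probe")),
            class = "assay_design")
}

#' Construct a transcript exon model
#'
#' Exons are given in transcript coordinates (0-based half-open), must be
#' non-overlapping, ascending and cover the transcript without gaps.
#' `intron_length_after` is the genomic intron following each exon
#' (`NA` = length unknown, e.g. missing from the genome assembly); the
#' last exon must have none.
#'
#' @param gene gene label.
#' @param transcript_length length of the transcript in bases.
#' @param exons data frame with columns `transcript_start`,
#'   `transcript_end`, `intron_length_after`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene, transcript_length, exons) {
  exons <- as.data.frame(exons)
  need <- c("transcript_start", "transcript_end", "intron_length_after")
  if (!all(need %in% names(exons)))
    rs_stop(paste0("exon table needs columns: ", paste(need, collapse = ", ")),
            "refsel_validation_error")
  exons$transcript_start <- as.integer(exons$transcript_start)
  exons$transcript_end <- as.integer(exons$transcript_end)
  exons$intron_length_after <- as.numeric(exons$intron_length_after)
  n <- nrow(exons)
  if (n < 1) rs_stop("at least one exon required", "refsel_validation_error")
  if (exons$transcript_start[1] != 0L ||
      exons$transcript_end[n] != transcript_length ||
      (n > 1 && any(exons$transcript_start[-1] != exons$transcript_end[-n])))
    rs_stop("exons must cover the transcript contiguously from 0",
            "refsel_validation_error")
  if (any(exons$transcript_end <= exons$transcript_start))
    rs_stop("every exon must have positive length", "refsel_validation_error")
  if (!is.na(exons$intron_length_after[n]))
    rs_stop("last exon must have no following intron (use NA)",
            "refsel_validation_error")
  if (any(stats::na.omit(exons$intron_length_after[-n]) < 0))
    rs_stop("intron lengths must be >= 0 or NA (unknown)",
            "refsel_validation_error")
  structure(list(gene = as.character(gene),
                 transcript_length = as.integer(transcript_length),
                 exons = exons),
            class = "gene_model")
}

#' All exact-match start positions (0-based) of pattern in subject
#' @noRd
match_starts <- function(subject, pattern) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(subject))
  BiocGenerics::start(hits) - 1L
}

#' Locate the amplicon produced by a primer pair on a template
#'
#' Searches the template for exact matches of the forward primer and of
#' the reverse complement of the reverse primer; a product is any pair of
#' sites where the reverse site lies fully downstream of the forward
#' site. Exactly one product must exist. The reported length counts both
#' primers; coordinates are 0-based half-open.
#'
#' @param template DNA string.
#' @param fwd,rev primer sequences 5'->3'.
#' @return list `start`, `end`, `length`.
#' @section Errors: zero matches of either primer, or no valid pairing,
#'   raises a `refsel_no_product_error`; multiple products raise a
#'   `refsel_nonspecific_error` whose `product_lengths` field lists them.
#' @examples
#' find_amplicon(paste0("ACGTAC", "AAAA", "GGCCAA"), "ACGTAC", "TTGGCC")
#' @export
find_amplicon <- function(template, fwd, rev) {
  template <- check_dna(template, "template")
  fwd <- check_dna(fwd, "forward primer")
  rev <- check_dna(rev, "reverse primer")
  fs <- match_starts(template, fwd)
  rs <- match_starts(template, reverse_complement(rev))
  if (length(fs) == 0 || length(rs) == 0)
    rs_stop("no product: primer site absent from template",
            "refsel_no_product_error")
  prods <- list()
  for (f in fs) for (r in rs) {
    if (r >= f + nchar(fwd))
      prods[[length(prods) + 1L]] <- c(start = f, end = r + nchar(rev))
  }
  if (length(prods) == 0)
    rs_stop("no product: no reverse site downstream of a forward site",
            "refsel_no_product_error")
  if (length(prods) > 1) {
    lens <- vapply(prods, function(p) unname(p["end"] - p["start"]),
                   numeric(1))
    rs_stop(paste0("non-specific primer pair: ", length(prods),
                   " products of length ", paste(lens, collapse = ", ")),
            "refsel_nonspecific_error", product_lengths = lens)
  }
  p <- prods[[1]]
  list(start = unname(p["start"]), end = unname(p["end"]),
       length = unname(p["end"] - p["start"]))
}

#' Exon index (1-based) containing interval [from, to); NA if split
#' @noRd
exon_of_interval <- function(model, from, to) {
  ex <- model$exons
  idx <- which(ex$transcript_start <= from & to <= ex$transcript_end)
  if (length(idx) == 1) idx else NA_integer_
}

#' Check a TaqMan assay layout against a transcript exon model
#'
#' Locates the amplicon on the transcript with [find_amplicon()], maps
#' the primers and probe to exons, and checks the DNA-refractory layout
#' rules: each primer wholly within an exon, the two primers in
#' *different* exons, and the probe spanning one of the exon junctions
#' inside the amplicon (the probe is searched on both strands). The
#' predicted genomic amplicon length is the mRNA length plus the spanned
#' intron lengths; an unknown intron propagates to an unknown DNA length.
#'
#' @param assay an [assay_design()].
#' @param model a [gene_model()].
#' @param transcript_seq transcript sequence; its length must equal
#'   `model$transcript_length`.
#' @return object of class `amplicon_report`: list with `gene`,
#'   `mrna_length`, `dna_length` (`NA` = unknown), `forward_exon`,
#'   `reverse_exon`, `probe_exons`, `probe_strand`,
#'   `probe_spans_junction`, `spanned_introns` (named lengths, `NA` =
#'   unknown), `rule_violations` (character; empty = pass).
#' @export
check_assay_layout <- function(assay, model, transcript_seq) {
  stopifnot(inherits(assay, "assay_design"), inherits(model, "gene_model"))
  transcript_seq <- check_dna(transcript_seq, "transcript")
  if (nchar(transcript_seq) != model$transcript_length)
    rs_stop(sprintf("transcript sequence length %d != model length %d",
                    nchar(transcript_seq), model$transcript_length),
            "refsel_validation_error")
  amp <- find_amplicon(transcript_seq, assay$forward, assay$reverse)
  violations <- character(0)
  f_exon <- exon_of_interval(model, amp$start, amp$start + nchar(assay$forward))
  r_exon <- exon_of_interval(model, amp$end - nchar(assay$reverse), amp$end)
  if (is.na(f_exon))
    violations <- c(violations, "forward primer crosses an exon junction")
  if (is.na(r_exon))
    violations <- c(violations, "reverse primer crosses an exon junction")
  if (!is.na(f_exon) && !is.na(r_exon) && f_exon == r_exon)
    violations <- c(violations, "both primers lie in the same exon")
  # junctions strictly inside the amplicon
  bounds <- model$exons$transcript_end[-nrow(model$exons)]
  spanned_idx <- which(bounds > amp$start & bounds < amp$end)
  spanned <- model$exons$intron_length_after[spanned_idx]
  names(spanned) <- if (length(spanned_idx) > 0)
    paste0("intron_", spanned_idx, "/", spanned_idx + 1L) else character(0)
  # probe placement, either strand
  probe_fwd <- match_starts(transcript_seq, assay$probe)
  probe_rev <- match_starts(transcript_seq, reverse_complement(assay$probe))
  probe_strand <- if (length(probe_fwd) > 0) "forward"
  else if (length(probe_rev) > 0) "reverse" else NA_character_
  probe_start <- c(probe_fwd, probe_rev)
  spans <- FALSE
  probe_exons <- NA_integer_
  if (length(probe_start) == 0) {
    violations <- c(violations, "probe sequence not found on either strand")
  } else {
    ps <- probe_start[1]
    pe <- ps + nchar(assay$probe)
    spans <- length(spanned_idx) > 0 &&
      any(bounds[spanned_idx] > ps & bounds[spanned_idx] < pe)
    probe_exons <- which(model$exons$transcript_start < pe &
                           model$exons$transcript_end > ps)
    if (!spans)
      violations <- c(violations, "probe does not span a junction inside the amplicon")
  }
  dna_length <- if (length(spanned) > 0 && anyNA(spanned)) NA_real_
  else amp$length + sum(spanned)
  structure(list(gene = assay$gene, mrna_length = amp$length,
                 dna_length = dna_length, forward_exon = f_exon,
                 reverse_exon = r_exon, probe_exons = probe_exons,
                 probe_strand = probe_strand, probe_spans_junction = spans,
                 spanned_introns = spanned, rule_violations = violations,
                 amplicon_start = amp$start, amplicon_end = amp$end),
            class = "amplicon_report")
}

#' @export
print.amplicon_report <- function(x, ...) {
  cat(sprintf("amplicon_report %s: mRNA %d bp, DNA %s bp; primers in exons %s/%s; probe spans junction: %s\n",
              x$gene, x$mrna_length,
              ifelse(is.na(x$dna_length), "unknown", x$dna_length),
              x$forward_exon, x$reverse_exon, x$probe_spans_junction))
  if (length(x$rule_violations) > 0)
    cat("violations:\n ", paste(x$rule_violations, collapse = "\n  "), "\n")
  else cat("layout rules: pass\n")
  invisible(x)
}

#' Load the packaged candidate reference-gene assay panel
#'
#' The ten-assay chicken panel manifest shipped with the package:
#' primer/probe sequences, the exon each primer sits in, and the
#' predicted mRNA/DNA amplicon lengths (DNA `NA` where the intron length
#' is unknown in the genome assembly). Public sequence accessions for the
#' transcripts are in the companion manifest
#' (`assay_panel_accessions.csv`); the sequences themselves are not
#' bundled and must be fetched by the user.
#'
#' @return data frame, one row per assay.
#' @export
load_assay_panel <- function() {
  read.csv(system.file("extdata", "assay_panel.csv", package = "refsel"),
           stringsAsFactors = FALSE)
}

#' Read assay definitions from a CSV file
#'
#' Columns: `gene`, `forward`, `reverse`, `probe`.
#' @param path CSV path.
#' @return named list of [assay_design()] objects.
#' @export
read_assays <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "forward", "reverse", "probe")
  if (!all(need %in% names(df)))
    rs_stop(paste0("assay CSV needs columns: ", paste(need, collapse = ", ")),
            "refsel_parse_error")
  setNames(lapply(seq_len(nrow(df)), function(i)
    assay_design(df$gene[i], df$forward[i], df$reverse[i], df$probe[i])),
    df$gene)
}

#' Read exon models from a CSV file
#'
#' Columns: `gene`, `transcript_start`, `transcript_end`,
#' `intron_length_after` (empty = unknown), one row per exon, exons in
#' transcript order.
#' @param path CSV path.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  genes <- unique(df$gene)
  setNames(lapply(genes, function(g) {
    sub <- df[df$gene == g, ]
    gene_model(g, max(sub$transcript_end), sub)
  }), genes)
}

#' Read a FASTA file of transcript sequences
#'
#' @param path FASTA path.
#' @return named character vector of upper-case sequences (names
#'   truncated at the first whitespace).
#' @export
read_transcripts <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
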