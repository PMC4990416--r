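rc <- function(s) chartr("ACGT", "TGCA",
                         paste(rev(strsplit(s, "")[[1]]), collapse = ""))

test_that("reverse complement is an involution", {
  expect_equal(reverse_complement("TTGGCC"), "GGCCAA")
  set.seed(80)
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  expect_equal(reverse_complement(reverse_complement(s)), s)
  expect_error(assay_design("x", "ACGN", "ACGT", "ACGT"),
               class = "refsel_validation_error")
})

test_that("amplicons are located with both primers counted", {
  tpl <- paste0("ACGTAC", "AAAA", "GGCCAA")
  amp <- find_amplicon(tpl, "ACGTAC", "TTGGCC")
  expect_equal(amp$start, 0)
  expect_equal(amp$end, 16)
  expect_equal(amp$length, 16)
  # padding the template does not change the length
  amp2 <- find_amplicon(paste0("TTTTT", tpl, "CGCGC"), "ACGTAC", "TTGGCC")
  expect_equal(amp2$length, 16)
})

test_that("zero or multiple placements raise the documented errors", {
  tpl <- paste0("ACGTAC", "AAAA", "GGCCAA")
  expect_error(find_amplicon(tpl, "ACGTAC", "AAAAAA"),
               class = "refsel_no_product_error")
  # forward primer present twice upstream of one reverse site
  tpl2 <- paste0("ACGTAC", "TTTT", "ACGTAC", "AAAA", "GGCCAA")
  err <- expect_error(find_amplicon(tpl2, "ACGTAC", "TTGGCC"),
                      class = "refsel_nonspecific_error")
  expect_length(err$product_lengths, 2)
  # reverse site only upstream of forward -> no orientation-valid product
  tpl3 <- paste0("GGCCAA", "AAAA", "ACGTAC")
  expect_error(find_amplicon(tpl3, "ACGTAC", "TTGGCC"),
               class = "refsel_no_product_error")
})

test_that("planted primers in a random template match a regex oracle", {
  set.seed(81)
  for (rep in 1:5) {
    bg <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    fwd <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    rev <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    pos_f <- 300; pos_r <- 1200
    tpl <- paste0(substr(bg, 1, pos_f), fwd,
                  substr(bg, pos_f + 1, pos_r), rc(rev),
                  substr(bg, pos_r + 1, 2000))
    f_or <- regexpr(fwd, tpl, fixed = TRUE)[1]
    r_or <- regexpr(rc(rev), tpl, fixed = TRUE)[1]
    if (f_or != pos_f + 1 || r_or != pos_f + 22 + pos_r - pos_f + 1) next
    amp <- find_amplicon(tpl, fwd, rev)
    expect_equal(amp$start, f_or - 1)
    expect_equal(amp$length, (r_or - 1 + 22) - (f_or - 1))
  }
})

test_that("gene models validate exon structure", {
  ok <- gene_model("x", 200, data.frame(
    transcript_start = c(0, 100), transcript_end = c(100, 200),
    intron_length_after = c(300, NA)))
  expect_s3_class(ok, "gene_model")
  expect_error(gene_model("x", 200, data.frame(
    transcript_start = c(0, 120), transcript_end = c(100, 200),
    intron_length_after = c(300, NA))), class = "refsel_validation_error")
  expect_error(gene_model("x", 200, data.frame(
    transcript_start = c(0, 100), transcript_end = c(100, 200),
    intron_length_after = c(300, 50))), class = "refsel_validation_error")
})

two_exon_fixture <- function(junction_in_probe = TRUE) {
  set.seed(82)
  fwd <- "CAGGTCATCACCATTGGCAAT"
  rev <- "GCATACAGATCCTTACGGATA"
  probe <- "CACAGGACTCCATACCCAAGA"
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  if (junction_in_probe) {
    # junction at 100: probe straddles it
    exon1 <- paste0(filler(50), fwd, filler(19), substr(probe, 1, 10))
    exon2 <- paste0(substr(probe, 11, 21), filler(20), rc(rev), filler(48))
  } else {
    exon1 <- paste0(filler(50), fwd, filler(29))
    exon2 <- paste0(probe, filler(11), rc(rev), filler(48))
  }
  tpl <- paste0(exon1, exon2)
  model <- gene_model("toy", nchar(tpl), data.frame(
    transcript_start = c(0, nchar(exon1)),
    transcript_end = c(nchar(exon1), nchar(tpl)),
    intron_length_after = c(300, NA)))
  list(assay = assay_design("toy", fwd, rev, probe), model = model,
       tpl = tpl)
}

test_that("a compliant two-exon assay passes all layout rules", {
  fx <- two_exon_fixture(junction_in_probe = TRUE)
  rep <- check_assay_layout(fx$assay, fx$model, fx$tpl)
  expect_length(rep$rule_violations, 0)
  expect_equal(rep$forward_exon, 1)
  expect_equal(rep$reverse_exon, 2)
  expect_true(rep$probe_spans_junction)
  expect_equal(rep$dna_length, rep$mrna_length + 300)
})

test_that("a probe inside one exon is flagged", {
  fx <- two_exon_fixture(junction_in_probe = FALSE)
  rep <- check_assay_layout(fx$assay, fx$model, fx$tpl)
  expect_false(rep$probe_spans_junction)
  expect_match(paste(rep$rule_violations, collapse = " "),
               "probe does not span")
})

test_that("same-exon primers and unknown introns are handled", {
  set.seed(83)
  fwd <- "CAGGTCATCACCATTGGCAAT"
  rev <- "GCATACAGATCCTTACGGATA"
  probe <- "CACAGGACTCCATACCCAAGA"
  filler <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  one_exon <- paste0(fwd, probe, filler, rc(rev))
  model1 <- gene_model("x", nchar(one_exon), data.frame(
    transcript_start = 0, transcript_end = nchar(one_exon),
    intron_length_after = NA))
  rep1 <- check_assay_layout(assay_design("x", fwd, rev, probe), model1,
                             one_exon)
  expect_match(paste(rep1$rule_violations, collapse = " "), "same exon")
  # unknown spanned intron -> unknown DNA length
  fx <- two_exon_fixture()
  model_u <- gene_model("toy", fx$model$transcript_length, data.frame(
    transcript_start = fx$model$exons$transcript_start,
    transcript_end = fx$model$exons$transcript_end,
    intron_length_after = c(NA, NA)))
  rep_u <- check_assay_layout(fx$assay, model_u, fx$tpl)
  expect_true(is.na(rep_u$dna_length))
})

test_that("the packaged synthetic constructs reproduce the published amplicon geometry", {
  panel <- load_assay_panel()
  fa <- read_transcripts(system.file("extdata", "synthetic_transcripts.fa",
                                     package = "refsel"))
  models <- read_gene_models(system.file("extdata", "synthetic_exons.csv",
                                         package = "refsel"))
  for (g in c("ACTB", "HPRT1")) {
    row <- panel[panel$gene == g, ]
    name <- paste0("synthetic_", g, "_construct")
    assay <- assay_design(g, row$forward, row$reverse, row$probe)
    rep <- check_assay_layout(assay, models[[name]], fa[[name]])
    expect_equal(rep$mrna_length, row$amplicon_mrna)
    expect_equal(rep$dna_length, row$amplicon_dna)
    expect_length(rep$rule_violations, 0)
    expect_true(rep$probe_spans_junction)
    # genomic - mRNA length equals the spanned intron
    expect_equal(rep$dna_length - rep$mrna_length,
                 sum(rep$spanned_introns))
  }
})

test_that("the packaged panel manifest is internally consistent", {
  panel <- load_assay_panel()
  expect_equal(nrow(panel), 10)
  expect_false(any(grepl("[^ACGT]", panel$forward)))
  expect_false(any(grepl("[^ACGT]", panel$probe)))
  # each primer pair sits in different exons, and the known genomic
  # amplicons are all longer than the mRNA amplicons (introns >= 0)
  expect_true(all(panel$forward_exon < panel$reverse_exon))
  known <- !is.na(panel$amplicon_dna)
  expect_true(all(panel$amplicon_dna[known] > panel$amplicon_mrna[known]))
})
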