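# Synthetic qPCR experiment generator with a truth ledger.
#
# Generative model (log2 scale), mirroring the quantification and
# stability models the analysis assumes:
#   true quantity  x_igj = d_ig + b_gj + eps_igj
#     b_gj ~ Normal(group loading offset, tau^2)   (per sample, all genes)
#     eps_igj ~ Normal(0, sigma2_ig)               (per gene x sample)
#   observed Ct    ct = intercept_i + slope_i * x (+ tech noise per well)
# Standard-curve wells come from the same per-gene line over a dilution
# series. Regenerating with the same config and seed is bit-identical.

#' Build a simulation configuration
#'
#' See [simulate_experiment()] for the generative model. The two presets
#' of [sim_preset()] emulate a twelve-tissue panel and a 2x2
#' interferon-by-infection fibroblast experiment.
#'
#' @param genes character vector of gene names.
#' @param groups named integer vector: group sizes `n_g` (>= 2).
#' @param d genes x groups matrix of systematic group deviations (log2
#'   units). Default all 0.
#' @param sigma per-gene intra-group biological noise SD (log2 units);
#'   recycled.
#' @param tau SD of the per-sample loading effect (log2 units).
#' @param group_loading_offsets named numeric, mean loading shift per
#'   group (default 0): e.g. a tissue with systematically less RNA.
#' @param slopes per-gene standard-curve slope (< 0, near -1); recycled.
#' @param intercepts per-gene Ct at log2 relative concentration 0;
#'   recycled.
#' @param dilution_levels number of standard-curve dilution levels.
#' @param dilution_step log2 step between levels (ten-fold =
#'   `-log2(10)`).
#' @param curve_replicates wells per dilution level.
#' @param curve_sd technical SD of standard-curve wells (cycles).
#' @param tech_replicates technical replicate wells per experimental
#'   sample.
#' @param tech_rep_sd technical SD of experimental wells (cycles);
#'   applied only when `tech_replicates > 1`.
#' @param seed integer seed; all randomness flows through it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genes, groups, d = NULL, sigma = 0.2, tau = 0.5,
                       group_loading_offsets = NULL, slopes = -1,
                       intercepts = 26, dilution_levels = 6,
                       dilution_step = -log2(10), curve_replicates = 2,
                       curve_sd = 0.15, tech_replicates = 1,
                       tech_rep_sd = 0.1, seed = 1) {
  k <- length(genes)
  G <- length(groups)
  if (is.null(names(groups)))
    rs_stop("groups must be a named vector of sizes", "refsel_validation_error")
  if (any(groups < 2))
    rs_stop("every group needs n_g >= 2", "refsel_validation_error")
  if (is.null(d)) d <- matrix(0, k, G, dimnames = list(genes, names(groups)))
  d <- as.matrix(d)
  if (!identical(dim(d), c(k, G)))
    rs_stop("d must be a genes x groups matrix", "refsel_validation_error")
  dimnames(d) <- list(genes, names(groups))
  sigma <- rep_len(sigma, k); names(sigma) <- genes
  slopes <- rep_len(slopes, k); names(slopes) <- genes
  intercepts <- rep_len(intercepts, k); names(intercepts) <- genes
  if (any(sigma < 0) || tau < 0)
    rs_stop("sigma and tau must be >= 0", "refsel_validation_error")
  if (any(slopes >= 0))
    rs_stop("slopes must be < 0", "refsel_validation_error")
  offs <- setNames(rep(0, G), names(groups))
  if (!is.null(group_loading_offsets)) {
    offs[names(group_loading_offsets)] <- group_loading_offsets
  }
  structure(list(genes = genes, groups = groups, d = d, sigma = sigma,
                 tau = tau, group_loading_offsets = offs, slopes = slopes,
                 intercepts = intercepts, dilution_levels = dilution_levels,
                 dilution_step = dilution_step,
                 curve_replicates = curve_replicates, curve_sd = curve_sd,
                 tech_replicates = tech_replicates, tech_rep_sd = tech_rep_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a complete qPCR experiment
#'
#' Generates experimental Ct observations, standard-curve wells and
#' sample annotation from a [sim_config()], together with a truth ledger
#' recording every latent quantity (group deviations, per-sample loading
#' effects, noise SDs, slopes/intercepts, the designed stable set), so
#' that every pipeline stage can be validated against known parameters.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_experiment`: `ct` (a [ct_table()]),
#'   `curves` (data frame `gene`, `log2_rel_conc`, `ct`), `annotation`
#'   (data frame `sample`, `group`, `unit`), `truth` (list: `d`, `b`
#'   per-sample loading, `sigma`, `tau`, `slopes`, `intercepts`, `x` true
#'   log2 quantities, `stable_genes`, `seed`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- config$genes
  grp_names <- names(config$groups)
  sample_group <- rep(grp_names, times = config$groups)
  unit <- unlist(lapply(config$groups, seq_len), use.names = FALSE)
  samples <- paste0(sample_group, "_", unit)
  n <- length(samples)
  b <- rnorm(n, mean = config$group_loading_offsets[sample_group],
             sd = config$tau)
  names(b) <- samples
  k <- length(genes)
  eps <- matrix(rnorm(k * n, 0, config$sigma), k, n,
                dimnames = list(genes, samples))
  x <- config$d[, sample_group, drop = FALSE] +
    matrix(b, k, n, byrow = TRUE) + eps
  dimnames(x) <- list(genes, samples)
  ct_mean <- config$intercepts[genes] + config$slopes[genes] * x
  reps <- config$tech_replicates
  recs <- data.frame(
    sample = rep(rep(samples, each = k), times = reps),
    gene = rep(rep(genes, times = n), times = reps),
    replicate = rep(seq_len(reps), each = k * n),
    stringsAsFactors = FALSE)
  base_ct <- rep(as.numeric(ct_mean), times = reps)
  recs$ct <- if (reps > 1)
    base_ct + rnorm(length(base_ct), 0, config$tech_rep_sd) else base_ct
  max_cycles <- max(40, ceiling(max(recs$ct)) + 1)
  ctab <- ct_table(recs[, c("sample", "gene", "ct", "replicate")],
                   max_cycles = max_cycles)
  conc <- (seq_len(config$dilution_levels) - 1) * config$dilution_step
  cw <- expand.grid(gene = genes, log2_rel_conc = conc,
                    well = seq_len(config$curve_replicates),
                    stringsAsFactors = FALSE)
  cw$ct <- config$intercepts[cw$gene] + config$slopes[cw$gene] *
    cw$log2_rel_conc + rnorm(nrow(cw), 0, config$curve_sd)
  curves <- cw[order(match(cw$gene, genes), cw$log2_rel_conc, cw$well),
               c("gene", "log2_rel_conc", "ct")]
  rownames(curves) <- NULL
  stable <- genes[apply(config$d, 1, function(r) all(abs(r) < 0.25))]
  structure(list(
    ct = ctab, curves = curves,
    annotation = data.frame(sample = samples, group = sample_group,
                            unit = as.character(unit),
                            stringsAsFactors = FALSE),
    truth = list(d = config$d, b = b, sigma = config$sigma,
                 tau = config$tau, slopes = config$slopes,
                 intercepts = config$intercepts, x = x,
                 stable_genes = stable, seed = config$seed)),
    class = "sim_experiment")
}

#' Fixed tissue-deviation profiles used by the presets
#'
#' Deterministic constants: generated once from a fixed internal seed,
#' independent of the user seed, so the preset *design* (which gene
#' deviates where, and by how much) is part of the preset definition and
#' identical across runs; only the sampling noise varies with the user
#' seed.
#' @noRd
preset_d_matrix <- function(genes, groups, scales) {
  r <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(20160818L)
    m <- matrix(rnorm(length(genes) * length(groups)), length(genes),
                dimnames = list(genes, groups))
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    m
  })
  d <- r * scales[genes]
  # centre each group across genes so the panel-average-stability
  # assumption of both selection methods holds for the base design
  sweep(d, 2, colMeans(d))
}

#' Preset simulation configurations emulating two study designs
#'
#' `"tissue_panel"`: twelve tissues x six birds, the ten-gene candidate
#' panel plus a ribosomal "28s" column. One gene (PGK1) carries a large
#' extra deviation in heart (muscle), making it designed-unstable; the
#' skin group has a negative loading offset (systematically less RNA);
#' all genes carry modest fixed tissue profiles, larger for the
#' non-selected candidates than for the stable four (HMBS, TBP, RPL13,
#' RPLP0), so panel heterogeneity resembles a real tissue collection.
#'
#' `"fibroblast_2x2"`: four groups (uninfected/infected x with/without
#' interferon pre-treatment: `u_c`, `u_a`, `i_c`, `i_a`) x four embryos.
#' B2M responds to infection (maximum inter-group deviation 1.807 log2,
#' i.e. about 3.5-fold), IL8 responds to treatment, TGFB weakly, and the
#' "28s" column rises in the infected groups; the remaining candidates
#' are near-stable.
#'
#' @param name `"tissue_panel"` or `"fibroblast_2x2"`.
#' @param seed user seed passed through to [sim_config()].
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("tissue_panel", "fibroblast_2x2"), seed = 1) {
  name <- match.arg(name)
  panel <- c("ACTB", "B2M", "HMBS", "HPRT1", "PGK1", "PLA2", "PPIA",
             "RPL13", "RPLP0", "TBP")
  if (name == "tissue_panel") {
    genes <- c(panel, "28s")
    tissues <- c("thymus", "bursa", "spleen", "caecal_tonsil", "heart",
                 "liver", "kidney", "lung", "duodenum", "ileum", "colon",
                 "skin")
    groups <- setNames(rep(6L, 12), tissues)
    scales <- setNames(rep(0.55, length(genes)), genes)
    scales[c("HMBS", "TBP", "RPL13", "RPLP0")] <- 0.4
    scales["28s"] <- 0.7
    d <- preset_d_matrix(genes, tissues, scales)
    d["PGK1", "heart"] <- d["PGK1", "heart"] + 3.5
    sim_config(genes = genes, groups = groups, d = d,
               sigma = ifelse(genes == "28s", 0.25, 0.2), tau = 0.5,
               group_loading_offsets = c(skin = -1.5),
               slopes = -1 + seq(-0.04, 0.04, length.out = length(genes)),
               intercepts = ifelse(genes == "28s", 12,
                                   22 + (seq_along(genes) %% 5)),
               seed = seed)
  } else {
    genes <- c(panel, "28s", "IL8", "TGFB")
    grp <- c("u_c", "u_a", "i_c", "i_a")
    groups <- setNames(rep(4L, 4), grp)
    d <- matrix(0, length(genes), 4, dimnames = list(genes, grp))
    d["B2M", ] <- c(0, 0.2, 1.6, 1.807)
    d["IL8", ] <- c(0, 0.3, 1.0, 1.3)
    d["TGFB", ] <- c(0, 0.1, 0.2, 0.3)
    d["28s", ] <- c(0, 0, 0.5, 0.5)
    sim_config(genes = genes, groups = groups, d = d, sigma = 0.12,
               tau = 0.4, slopes = -1 + seq(-0.03, 0.03,
                                            length.out = length(genes)),
               intercepts = ifelse(genes == "28s", 12,
                                   22 + (seq_along(genes) %% 5)),
               seed = seed)
  }
}

#' Write a simulated experiment to a directory
#'
#' Writes `ct.csv`, `curves.csv`, `annotation.csv` and `truth.json`.
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_table(sim$ct, file.path(dir, "ct.csv"))
  write.csv(sim$curves, file.path(dir, "curves.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(sim$annotation, file.path(dir, "annotation.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$d <- list(genes = rownames(truth$d), groups = colnames(truth$d),
                  values = unname(apply(truth$d, 1, as.numeric,
                                        simplify = FALSE)))
  truth$x <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
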