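# Seeded generators emulating each input the pipeline consumes. Every
# generator is a pure function of its arguments (including the integer
# seed): the global RNG state is never touched (withr::with_seed).
# Ground truth is returned alongside the data so recovery statistics can
# be computed without re-reading generator internals.

new_panel_truth <- function(...) {
  structure(list(...), class = "panel_truth")
}

#' Simulate matched stem-like/differentiated expression pairs
#'
#' Emulates a matched two-group design (e.g. paired stem-like and
#' differentiated cultures derived from the same patient lines): each
#' pair shares a per-gene culture-line effect, on top of a log-normal
#' gene baseline and residual noise, all on the log2(TPM) scale. Shared
#' pair effects dominate the within-group variance -- the realistic
#' structure of patient-derived pairs, where line-to-line heterogeneity
#' far exceeds technical noise -- so an unpaired contrast can still
#' separate planted effects at small n.
#'
#' Planted genes are shifted by `effect_sd_units` within-group pooled
#' standard deviations (`sqrt(pair_sd^2 + residual_sd^2)`): the first
#' half up in group A (stem-like), the second half up in group B.
#'
#' @param n_genes Total genes (default 5000).
#' @param n_pairs Matched pairs, i.e. samples per group (default 3).
#' @param n_planted Planted differential genes, split half up / half
#'   down (default 100); must satisfy `n_planted <= n_genes`.
#' @param effect_sd_units Planted shift in pooled-sd units (default 2).
#' @param baseline_mean,baseline_sd Gene baseline distribution on log2
#'   TPM (defaults 3 and 1).
#' @param pair_sd Sd of the per-gene culture-line effect shared by the
#'   two members of a pair (default 0.5).
#' @param residual_sd Sd of independent residual noise (default 0.1).
#' @param seed Integer RNG seed.
#' @param label_a,label_b Group labels (defaults `"GSC"`, `"DGC"`).
#' @return List with `expr` (an [expression_matrix], log2 units, groups
#'   labelled) and `truth` (a `panel_truth` with `planted_up_genes`,
#'   `planted_down_genes`, `noise_sds`, `seed`).
#' @export
sim_matched_expression <- function(n_genes = 5000, n_pairs = 3,
                                   n_planted = 100, effect_sd_units = 2,
                                   baseline_mean = 3, baseline_sd = 1,
                                   pair_sd = 0.5, residual_sd = 0.1,
                                   seed = 1, label_a = "GSC",
                                   label_b = "DGC") {
  if (n_pairs < 2) stop_ds("'n_pairs' must be >= 2")
  if (n_planted > n_genes)
    stop_ds("'n_planted' (%d) exceeds 'n_genes' (%d)", n_planted, n_genes)
  if (n_planted %% 2 != 0) stop_ds("'n_planted' must be even")

  genes <- sprintf("g%05d", seq_len(n_genes))
  samples_a <- sprintf("%s_%d", label_a, seq_len(n_pairs))
  samples_b <- sprintf("%s_%d", label_b, seq_len(n_pairs))
  n_up <- n_planted %/% 2L
  up_genes <- genes[seq_len(n_up)]
  down_genes <- genes[seq.int(n_up + 1L, n_planted)]
  pooled_sd <- sqrt(pair_sd^2 + residual_sd^2)
  shift <- effect_sd_units * pooled_sd

  vals <- withr::with_seed(seed, {
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    pair_eff <- matrix(stats::rnorm(n_genes * n_pairs, 0, pair_sd),
                       n_genes, n_pairs)
    va <- baseline + pair_eff +
      matrix(stats::rnorm(n_genes * n_pairs, 0, residual_sd),
             n_genes, n_pairs)
    vb <- baseline + pair_eff +
      matrix(stats::rnorm(n_genes * n_pairs, 0, residual_sd),
             n_genes, n_pairs)
    va[seq_len(n_up), ] <- va[seq_len(n_up), ] + shift
    vb[seq.int(n_up + 1L, n_planted), ] <-
      vb[seq.int(n_up + 1L, n_planted), ] + shift
    cbind(va, vb)
  })
  dimnames(vals) <- list(genes, c(samples_a, samples_b))
  groups <- stats::setNames(rep(c(label_a, label_b), each = n_pairs),
                            c(samples_a, samples_b))
  list(expr = expression_matrix(vals, units = "log2", groups = groups),
       truth = new_panel_truth(
         planted_up_genes = up_genes, planted_down_genes = down_genes,
         effect_sd_units = effect_sd_units,
         noise_sds = c(pair = pair_sd, residual = residual_sd),
         seed = seed))
}

#' Simulate a cell-line expression panel with a latent state score
#'
#' Emulates a pan-cancer cell-line panel whose lines vary continuously
#' along a stemness axis: each line draws a latent `state_score` from
#' Uniform(0, 1); genes in the stem-like signature increase linearly
#' with the state score (total swing `score_spread` log2 units across
#' the axis), genes in the differentiated signature decrease, and
#' background genes are pure noise.
#'
#' @param n_lines Number of cell lines (default 60).
#' @param signatures A `signature_pair` ([derive_signatures()]) whose
#'   `high_in_a` set responds positively to the state score.
#' @param n_background Background (non-signature) genes (default 1800).
#' @param score_spread Log2 expression swing of signature genes across
#'   the state axis (default 2).
#' @param noise_sd Per-gene, per-line residual sd (default 0.5).
#' @param baseline_mean,baseline_sd Gene baseline distribution (3, 1).
#' @param seed Integer RNG seed.
#' @return List with `panel` (an [expression_matrix], log2 units) and
#'   `truth` (a `panel_truth` with per-line `state_score` and the
#'   planted gene sets).
#' @export
sim_cell_line_panel <- function(n_lines = 60, signatures,
                                n_background = 1800, score_spread = 2,
                                noise_sd = 0.5, baseline_mean = 3,
                                baseline_sd = 1, seed = 1) {
  stopifnot(inherits(signatures, "signature_pair"))
  up <- signatures$high_in_a$members
  down <- signatures$high_in_b$members
  bg <- sprintf("bg%05d", seq_len(n_background))
  genes <- c(up, down, bg)
  if (anyDuplicated(norm_gene_id(genes)))
    stop_ds("signature and background gene ids collide")
  lines <- sprintf("line_%03d", seq_len(n_lines))
  slope <- c(rep(score_spread, length(up)),
             rep(-score_spread, length(down)),
             rep(0, n_background))

  out <- withr::with_seed(seed, {
    state <- stats::runif(n_lines)
    baseline <- stats::rnorm(length(genes), baseline_mean, baseline_sd)
    vals <- baseline + outer(slope, state - 0.5) +
      matrix(stats::rnorm(length(genes) * n_lines, 0, noise_sd),
             length(genes), n_lines)
    list(state = state, vals = vals)
  })
  dimnames(out$vals) <- list(genes, lines)
  list(panel = expression_matrix(out$vals, units = "log2"),
       truth = new_panel_truth(
         state_score = stats::setNames(out$state, lines),
         planted_up_genes = up, planted_down_genes = down,
         noise_sds = c(residual = noise_sd), seed = seed))
}

#' Simulate a drugs x cell-lines AUC screen with planted associations
#'
#' Emulates a drug-sensitivity portal AUC matrix. Non-associated drugs
#' draw AUC independently of cell state; each associated drug follows
#' `AUC = auc_mean + slope * state_score + Normal(0, noise_sd)`, so a
#' negative slope plants stem-selective sensitivity (lower AUC = more
#' sensitive). The default slope/noise pair (-1, 0.385) gives a
#' population Pearson correlation of about -0.6 against a Uniform(0,1)
#' state score.
#'
#' @param truth A `panel_truth` carrying `state_score` (from
#'   [sim_cell_line_panel()]).
#' @param n_drugs Total drugs (default 100).
#' @param n_assoc Number of associated drugs (default 5), the first
#'   `n_assoc` drug ids.
#' @param slope AUC change per unit state score for associated drugs
#'   (default -1).
#' @param noise_sd Residual AUC sd for associated drugs (default 0.385).
#' @param auc_mean Centre of the AUC distribution (default 10).
#' @param auc_sd Sd of non-associated drugs' AUC; default matches the
#'   marginal sd of associated drugs, `sqrt(slope^2 / 12 + noise_sd^2)`.
#' @param missing_rate Fraction of entries set missing at random
#'   (default 0).
#' @param seed Integer RNG seed.
#' @return List with `auc` (a [drug_response_table]) and `truth` (input
#'   truth extended with `assoc_drugs`, `slope`, `noise_sds`).
#' @export
sim_drug_response <- function(truth, n_drugs = 100, n_assoc = 5,
                              slope = -1, noise_sd = 0.385, auc_mean = 10,
                              auc_sd = NULL, missing_rate = 0, seed = 1) {
  stopifnot(inherits(truth, "panel_truth"))
  if (is.null(truth$state_score))
    stop_ds("'truth' carries no state_score; generate the panel first")
  if (n_assoc > n_drugs) stop_ds("'n_assoc' exceeds 'n_drugs'")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_ds("'missing_rate' must be in [0, 1)")
  if (is.null(auc_sd)) auc_sd <- sqrt(slope^2 / 12 + noise_sd^2)
  state <- truth$state_score
  n_lines <- length(state)
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  assoc <- drugs[seq_len(n_assoc)]

  auc <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_drugs * n_lines, auc_mean + slope / 2,
                             auc_sd),
                n_drugs, n_lines)
    if (n_assoc > 0)
      m[seq_len(n_assoc), ] <-
        matrix(rep(auc_mean + slope * state, each = n_assoc) +
                 stats::rnorm(n_assoc * n_lines, 0, noise_sd),
               n_assoc, n_lines)
    if (missing_rate > 0)
      m[stats::runif(length(m)) < missing_rate] <- NA_real_
    m
  })
  dimnames(auc) <- list(drugs, names(state))
  truth$assoc_drugs <- assoc
  truth$slope <- slope
  truth$noise_sds <- c(truth$noise_sds, auc = noise_sd)
  list(auc = drug_response_table(auc), truth = truth)
}

#' Simulate dose-response viability readouts from a 4PL truth
#'
#' Viability is the four-parameter logistic evaluated at each dose
#' (zero dose gives the upper plateau) plus Gaussian noise per
#' replicate, emulating a viability assay over a 0 to 10,000 nM dose
#' range.
#'
#' @param params Named vector `c(top, bottom, log_ic50, hill)`.
#' @param dose_grid Concentrations (nM) including 0; default the
#'   6-point grid `c(0, 1, 10, 100, 250, 500)`.
#' @param noise_sd Gaussian noise sd in viability percentage points
#'   (default 5).
#' @param n_replicates Wells per dose (default 3).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `dose_nM`, `replicate`, `viability`.
#' @export
sim_dose_response <- function(params = c(top = 100, bottom = 0,
                                         log_ic50 = 2, hill = 1),
                              dose_grid = c(0, 1, 10, 100, 250, 500),
                              noise_sd = 5, n_replicates = 3, seed = 1) {
  if (any(dose_grid < 0)) stop_ds("doses must be >= 0")
  p <- as.list(params[c("top", "bottom", "log_ic50", "hill")])
  truth_mean <- ifelse(dose_grid == 0, p$top,
                       fourpl(log10(pmax(dose_grid, .Machine$double.xmin)),
                              p$top, p$bottom, p$log_ic50, p$hill))
  tab <- expand.grid(replicate = seq_len(n_replicates),
                     dose_nM = dose_grid, KEEP.OUT.ATTRS = FALSE)
  tab <- tab[, c("dose_nM", "replicate")]
  mean_per_row <- rep(truth_mean, each = n_replicates)
  tab$viability <- withr::with_seed(seed,
    mean_per_row + stats::rnorm(nrow(tab), 0, noise_sd))
  rownames(tab) <- NULL
  tab
}

# Monotherapy percent-inhibition curve from a 4PL viability truth,
# normalized to the vehicle response so inhibition(0) = 0 exactly.
mono_inhibition <- function(doses, params) {
  p <- as.list(params[c("top", "bottom", "log_ic50", "hill")])
  v <- ifelse(doses == 0, p$top,
              fourpl(log10(pmax(doses, .Machine$double.xmin)),
                     p$top, p$bottom, p$log_ic50, p$hill))
  100 * (1 - v / p$top)
}

#' Simulate a two-drug combination grid with a planted HSA excess
#'
#' Monotherapy margins follow the two 4PL viability truths (converted to
#' percent inhibition, vehicle-normalized and noiseless so the margins
#' anchor exactly); each combination cell is the HSA expectation
#' `max(mono_a(a), mono_b(b))` plus the planted excess `delta` plus
#' Gaussian noise. `delta = 15, noise_sd = 0` therefore yields an HSA
#' synergy score of exactly 15.
#'
#' @param mono_a,mono_b Named 4PL parameter vectors
#'   `c(top, bottom, log_ic50, hill)` for the two drugs.
#' @param delta Planted excess over the HSA expectation (percentage
#'   points, default 0).
#' @param doses_a,doses_b Dose grids (nM) including 0; defaults follow
#'   the study's combination grids
#'   (`c(0, 1, 10, 25, 50, 100)` and `c(0, 1, 10, 100, 250, 500)`).
#' @param noise_sd Gaussian noise on combination cells only (default 0).
#' @param drug_a,drug_b Drug names.
#' @param seed Integer RNG seed.
#' @return A [combination_matrix].
#' @export
sim_combination <- function(mono_a = c(top = 100, bottom = 0,
                                       log_ic50 = 1, hill = 1),
                            mono_b = c(top = 100, bottom = 0,
                                       log_ic50 = 2, hill = 1),
                            delta = 0,
                            doses_a = c(0, 1, 10, 25, 50, 100),
                            doses_b = c(0, 1, 10, 100, 250, 500),
                            noise_sd = 0, drug_a = "drug_A",
                            drug_b = "drug_B", seed = 1) {
  inh_a <- mono_inhibition(doses_a, mono_a)
  inh_b <- mono_inhibition(doses_b, mono_b)
  na <- length(doses_a); nb <- length(doses_b)
  m <- matrix(0, na, nb)
  m[, 1L] <- inh_a
  m[1L, ] <- inh_b
  combo <- outer(inh_a[-1L], inh_b[-1L], pmax) + delta
  if (noise_sd > 0)
    combo <- combo + withr::with_seed(seed,
      matrix(stats::rnorm((na - 1) * (nb - 1), 0, noise_sd),
             na - 1, nb - 1))
  m[-1L, -1L] <- combo
  combination_matrix(doses_a, doses_b, m, drug_a = drug_a, drug_b = drug_b)
}
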