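# Builds a complete synthetic input bundle on disk and drives the cmd_*
# stage functions the way the command-line dispatcher does.
write_bundle <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  matched <- sim_matched_expression(n_genes = 600, n_planted = 40,
                                    seed = seed)
  write_expression(matched$expr, p("matched.tsv"))
  pair <- make_sig_pair(30)
  panel <- sim_cell_line_panel(n_lines = 60, signatures = pair,
                               n_background = 300, seed = seed + 1)
  write_expression(panel$panel, p("panel.tsv"))
  write_gmt(pair, p("signatures.gmt"))
  dr <- sim_drug_response(panel$truth, n_drugs = 30, n_assoc = 3,
                          seed = seed + 2)
  write_drug_response(dr$auc, p("auc.csv"))
  dose <- sim_dose_response(noise_sd = 3, seed = seed + 3)
  dose$drug <- "belinostat"
  utils::write.csv(dose[, c("drug", "dose_nM", "replicate", "viability")],
                   p("dose.csv"), row.names = FALSE, quote = FALSE)
  write_combination(sim_combination(delta = 15, noise_sd = 1,
                                    seed = seed + 4), p("combo.csv"))
  tpm <- withr::with_seed(seed + 5, {
    m <- matrix(rlnorm(300 * 6, 4, 1), 300, 6,
                dimnames = list(sprintf("g%03d", 1:300),
                                c(paste0("ctrl_", 1:3), paste0("trt_", 1:3))))
    m[1:5, 4:6] <- m[1:5, 4:6] * 5
    m
  })
  write_expression(expression_matrix(tpm, units = "TPM"), p("tpm.tsv"))
  utils::write.csv(data.frame(sample = colnames(tpm),
                              group = rep(c("control", "treated"), each = 3)),
                   p("manifest.csv"), row.names = FALSE, quote = FALSE)
  list(dir = dir, matched = matched, pair = pair)
}

run_all_cmds <- function(in_dir, out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pin <- function(f) file.path(in_dir, f)
  pout <- function(f) file.path(out_dir, f)
  suppressMessages({
    cmd_signatures(list(
      expression_path = pin("matched.tsv"),
      group_a_samples = paste0("GSC_", 1:3),
      group_b_samples = paste0("DGC_", 1:3),
      group_a_label = "GSC", group_b_label = "DGC",
      n_signature = 30,
      out_ranked_tsv = pout("ranked.rnk"),
      out_signatures_gmt = pout("derived.gmt")))
    cmd_screen(list(
      panel_path = pin("panel.tsv"), signatures_gmt = pin("signatures.gmt"),
      auc_path = pin("auc.csv"),
      out_scores_tsv = pout("scores.tsv"),
      out_screen_csv = pout("screen.csv"),
      out_topk_csv = pout("topk.csv")))
    cmd_pharm(list(
      dose_response_csv = pin("dose.csv"),
      combination_csv = pin("combo.csv"),
      combo_drug_a = "dasatinib", combo_drug_b = "belinostat",
      out_fits_csv = pout("fits.csv"),
      out_synergy_csv = pout("synergy.csv"),
      out_excess_tsv = pout("excess.tsv"),
      seed = seed))
    cmd_degs(list(
      tpm_path = pin("tpm.tsv"), manifest_csv = pin("manifest.csv"),
      control_group = "control", treatment_group = "treated",
      out_degs_csv = pout("degs.csv")))
  })
  list.files(out_dir, full.names = TRUE)
}

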