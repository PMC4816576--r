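#!/usr/bin/env Rscript
# Condition ERPs and the behavioral/ERP statistics on a 40-subject
# cohort: Ne and Pe windowed means per subject x task x response, 2x2
# repeated-measures ANOVAs (task x response), the error-rate bootstrap
# t-test, and an RT-sorted ERP image of one subject's FCz activity.

library(errclass)

out <- "results/erp"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- make_default_config(n_subjects = 40)
cond <- cohort_condition_table(cfg)
write.table(cond, file.path(out, "condition_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# accuracy effects: error - correct windowed means
wide <- merge(cond[cond$response == "error", c("subject", "task", "ne", "pe", "rt")],
              cond[cond$response == "correct", c("subject", "task", "ne", "pe", "rt")],
              by = c("subject", "task"), suffixes = c("_err", "_cor"))
cat("Grand-average accuracy effects (uV):\n")
cat(sprintf("  Ne (FCz, 20-100 ms): %.2f (flanker %.2f, rotation %.2f)\n",
            mean(wide$ne_err - wide$ne_cor),
            mean((wide$ne_err - wide$ne_cor)[wide$task == "flanker"]),
            mean((wide$ne_err - wide$ne_cor)[wide$task == "rotation"])))
cat(sprintf("  Pe (Cz, 180-250 ms): %.2f (flanker %.2f, rotation %.2f)\n",
            mean(wide$pe_err - wide$pe_cor),
            mean((wide$pe_err - wide$pe_cor)[wide$task == "flanker"]),
            mean((wide$pe_err - wide$pe_cor)[wide$task == "rotation"])))

anova <- do.call(rbind, lapply(c("ne", "pe", "rt"), function(m) {
  res <- rm_anova_2x2(data.frame(subject = cond$subject, a = cond$task,
                                 b = cond$response, value = cond[[m]]))
  res$measure <- m
  res
}))
anova$p_adj_by <- adjust_fdr_by(anova$p)
cat("\n2x2 rm-ANOVA (task x response), BY-adjusted p-values:\n")
print(anova, row.names = FALSE, digits = 3)
write.table(anova, file.path(out, "anova.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

er <- unique(cond[, c("subject", "task", "error_rate")])
x <- er$error_rate[er$task == "flanker"]
y <- er$error_rate[er$task == "rotation"]
bt <- bootstrap_ttest_paired(x, y, n_boot = 2000, seed = 1)
cat(sprintf("\nError rates: flanker %.1f%%, rotation %.1f%%; t_obs = %.2f, p_boot = %.4f, d_rm = %.2f\n",
            100 * mean(x), 100 * mean(y), bt$t_obs, bt$p_boot, cohens_d_rm(x, y)))

# RT-sorted single-trial image at FCz for subject 1's flanker task
ep <- simulate_subject(cfg, 1, cfg$tasks$flanker, seed = derive_seed(cfg$seed, 1, 1))
img <- erp_image(rt_filter(ep), "FCz", ma_window = 40)
write.table(round(img$image, 4), file.path(out, "erp_image_fcz.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = sprintf("t%+d", round(img$times)))
png(file.path(out, "erp_image_fcz.png"), width = 700, height = 500)
image(x = img$times, y = seq_len(nrow(img$image)), z = t(img$image),
      col = hcl.colors(64, "RdBu", rev = TRUE), xlab = "time (ms)",
      ylab = "trials (RT-sorted)",
      main = "Single-trial FCz activity, RT-sorted, MA = 40")
lines(img$rt[seq_len(nrow(img$image))], seq_len(nrow(img$image)))
abline(v = 0, lty = 2)
dev.off()
cat("\nERP image written to", file.path(out, "erp_image_fcz.png"), "\n")
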