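#!/usr/bin/env Rscript

# Behavioural learning curves: session x group (wireless vs sham) two-way
# ANOVAs on initial errors, repetitive errors and latencies, following the
# standard double-H analysis. Expect strong session effects and no group
# effect (the instrumented rats learn just as well).

library(mazelfp)

beh <- read.csv("results/data/behavior.csv")
dir.create("results", showWarnings = FALSE)

summ <- aggregate(cbind(initial_errors, repetitive_errors,
                        goal_arm_latency, platform_latency)
                  ~ session + group, beh, mean)
write.csv(summ, "results/behavior_summary.csv", row.names = FALSE)
cat("== session means by group ==\n")
print(summ, digits = 3)

cat("\n== two-way ANOVA (A = session, B = group) ==\n")
for (m in c("initial_errors", "repetitive_errors",
            "goal_arm_latency", "platform_latency")) {
  res <- two_way_anova(beh[[m]], factor(beh$session), factor(beh$group))
  cat(sprintf("%-18s session F(%d,%d) = %6.2f p = %-9.3g  group F = %5.2f p = %.3g\n",
              m,
              res$df_num[1], res$df_den[1], res$F[1], res$p[1],
              res$F[2], res$p[2]))
  if (res$p[1] < 0.05) {
    g <- split(beh[[m]], beh$session)
    bp <- bonferroni_pairwise(g)
    sig <- bp[bp$significant, c("group1", "group2", "p_adj")]
    if (nrow(sig)) {
      cat("  Bonferroni-significant session pairs:\n")
      print(sig, digits = 2, row.names = FALSE)
    }
  }
}
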