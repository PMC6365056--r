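#!/usr/bin/env Rscript
# Stage 2 — signal-detection summaries and behavioural permutation tests.
#
# Criterion c and d-prime per subject and condition, pooled across blocks,
# followed by two-sided paired permutation tests (10,000 permutations) of
# the liberal-conservative differences. The bias induction should show up
# as a large criterion shift (liberal below conservative) with a much
# smaller sensitivity change.

suppressPackageStartupMessages(library(driftgain))

trials <- read_trials("results/trials.csv")
sdt <- sdt_table(trials)
write.csv(sdt, "results/sdt.csv", row.names = FALSE)

wide <- function(col) {
  lib <- sdt[sdt$condition == "liberal", ]
  con <- sdt[sdt$condition == "conservative", ]
  con <- con[match(lib$subject, con$subject), ]
  cbind(lib = lib[[col]], con = con[[col]])
}

tests <- list()
for (m in c("criterion", "dprime", "h", "fa")) {
  w <- wide(m)
  pt <- perm_test_paired(w[, "lib"], w[, "con"], n_perm = 10000,
                         seed = child_seed(1, paste0("sdt_", m)))
  tests[[m]] <- list(mean_liberal = mean(w[, "lib"]),
                     mean_conservative = mean(w[, "con"]),
                     difference = pt$statistic, p = pt$p)
  cat(sprintf("%-10s liberal %7.3f conservative %7.3f  p = %g\n",
              m, mean(w[, "lib"]), mean(w[, "con"]), pt$p))
}
jsonlite::write_json(tests, "results/sdt_tests.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/sdt.csv, results/sdt_tests.json\n")
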