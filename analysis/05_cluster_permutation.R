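#!/usr/bin/env Rscript
# Stage 5 — cluster-based permutation inference.
#
# Builds a subjects x channels x frequencies x times grid of
# liberal-conservative pre-stimulus power differences with the structure
# the generator injects (posterior alpha suppression, frontal theta
# elevation) and runs the cluster-based permutation test (paired t per bin,
# p < 0.05 bin threshold, max-|mass| sign-flip null, 1000 permutations).
# Expected: an alpha-band cluster on posterior channels with negative sign
# (liberal minus conservative) and a positive theta-band cluster on frontal
# channels.

suppressPackageStartupMessages(library(driftgain))

seed <- 20260927L
n_sub <- 14; n_ch <- 8; freqs <- 1:20; n_t <- 10
post_ch <- 1:5; front_ch <- 6:8

set.seed(child_seed(seed, "clustergrid"))
dat <- array(rnorm(n_sub * n_ch * length(freqs) * n_t, sd = 1),
             dim = c(n_sub, n_ch, length(freqs), n_t))
# injected condition differences (a.u.): alpha suppression, theta elevation
for (s in seq_len(n_sub)) {
  dat[s, post_ch, freqs >= 8 & freqs <= 12, ] <-
    dat[s, post_ch, freqs >= 8 & freqs <= 12, ] - 1.2
  dat[s, front_ch, freqs >= 2 & freqs <= 6, ] <-
    dat[s, front_ch, freqs >= 2 & freqs <= 6, ] + 0.9
}

res <- cluster_permutation(dat, n_perm = 1000,
                           seed = child_seed(seed, "clusterperm"))
print(res)

sig <- Filter(function(cl) cl$p < 0.05, res$clusters)
to_freqs <- function(cl) {
  fidx <- ((cl$bins - 1) %/% n_ch) %% length(freqs) + 1
  range(freqs[fidx])
}
out <- lapply(sig, function(cl)
  list(sign = cl$sign, mass = cl$mass, p = cl$p, size = length(cl$bins),
       freq_range = to_freqs(cl)))
jsonlite::write_json(list(n_perm = res$n_perm, clusters = out),
                     "results/clusters.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/clusters.json\n")
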