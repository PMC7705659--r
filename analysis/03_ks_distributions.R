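#!/usr/bin/env Rscript
# Step 3: Ks distributions from the collinear anchors.
#
# Filters the per-anchor NG86 estimates to [0.005, 3.0], reports exclusion
# counts, and writes the three distributions plus fixed-width histogram
# tables for plotting.

suppressMessages(library(wgdclock))

syn <- "results/synteny"
out <- "results/ks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (nm in c("paralog_L", "paralog_C", "ortholog_LC")) {
  rec <- read_tsv(file.path(syn, paste0(nm, "_ks.tsv")))
  d <- build_distribution(rec, source = nm)
  write_tsv(data.frame(Ks = d$values), file.path(out, paste0(nm, "_dist.tsv")))
  br <- seq(0, 3, by = 0.05)
  h <- hist(d$values, breaks = br, plot = FALSE)
  write_tsv(data.frame(bin_lo = utils::head(br, -1), bin_hi = br[-1],
                       count = h$counts),
            file.path(out, paste0(nm, "_hist.tsv")))
  cat(nm, ":", length(d$values), "values kept; excluded",
      paste(names(d$n_excluded), d$n_excluded, collapse = ", "), "\n")
}
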