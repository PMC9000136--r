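#!/usr/bin/env Rscript
# Generates the canonical synthetic fixture suite (trace tables + JSON
# manifests for every figure-variant run) under results/fixtures/.

suppressPackageStartupMessages(library(gjcamp))
man <- make_fixture_suite(seed = 1, dir = "results/fixtures")
cat("wrote", nrow(man), "fixtures to results/fixtures/\n")
print(man, row.names = FALSE)
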