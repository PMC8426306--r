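#!/usr/bin/env Rscript
# Step 4 — study report.
#
# Bundles the group summary (mean +/- SEM per group and session), the
# fold-change / correlation / comparison tables and the time-course
# figures under results/report/.

suppressMessages(library(fibroPET))

metrics <- read.csv("results/metrics.csv", stringsAsFactors = FALSE)
rep <- build_report(metrics, "results/report")
message("Report written to results/report (",
        length(list.files("results/report")), " files, ",
        rep$warnings, " missing study cells)")
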