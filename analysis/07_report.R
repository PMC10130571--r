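#!/usr/bin/env Rscript
# Stage 7: assemble the Markdown report and the run manifest.

suppressMessages(library(parasnv))

run <- "results/run"
cfg <- read_config(file.path(run, "sim", "config.yaml"))
render_report(run)
manifest <- write_manifest(run, cfg)
cat("report:", file.path(run, "report.md"), "\n")
cat("manifest lists", nrow(manifest$files), "files\n")
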