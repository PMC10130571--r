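#!/usr/bin/env Rscript
# Stage 2: curated SNV calling, each population against its own genome.
#
# Read pairs pass the filter chain (pair identity >= 0.90, both-mate mapQ >=
# 1, insert in [50 bp, 3x median]); pileups are called per site with the
# highest-mean-mapQ consensus validation, a 2-read / 0.05-frequency variant
# floor, and the >= 0.40 consensus-SNV discard; calls are then restricted to
# ORFs. Writes per-MAG SNV tables and the filter/call logs.

suppressMessages(library(parasnv))

run <- "results/run"
sim <- file.path(run, "sim")
dir.create(file.path(run, "snvs"), showWarnings = FALSE)
cfg <- read_config(file.path(sim, "config.yaml"))

filter_logs <- list(); call_logs <- list(); totals_tab <- list()
for (id in cfg$mag_ids) {
  mag <- read_mag_fasta(file.path(sim, paste0(id, ".fna")), id,
                        orfs = read_orfs_gff3(file.path(sim, paste0(id, ".gff3"))))
  pairs <- read_tsv(file.path(sim, paste0(id, "_pairs.tsv")))
  filt <- filter_read_pairs(pairs)
  called <- call_snvs(build_pileup(filt$pairs, mag))
  restricted <- restrict_to_orfs(called$snvs, mag$orfs)
  write_tsv(collate_snv_table(restricted$snvs, mag),
            file.path(run, "snvs", paste0(id, "_snv_table.tsv")))
  filter_logs[[id]] <- cbind(mag_id = id, filt$log)
  call_logs[[id]] <- cbind(mag_id = id, called$log)
  totals_tab[[id]] <- data.frame(mag_id = id,
                                 n_total = unname(restricted$totals["n_total"]),
                                 n_in_orf = unname(restricted$totals["n_in_orf"]))
  cat(sprintf("%s: %d pairs in, %d retained; %d SNVs, %d in ORFs\n", id,
              nrow(pairs), nrow(filt$pairs),
              restricted$totals[["n_total"]], restricted$totals[["n_in_orf"]]))
}
write_tsv(do.call(rbind, filter_logs), file.path(run, "snvs", "filter_log.tsv"))
write_tsv(do.call(rbind, call_logs), file.path(run, "snvs", "call_log.tsv"))
write_tsv(do.call(rbind, totals_tab), file.path(run, "snvs", "snv_totals.tsv"))
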