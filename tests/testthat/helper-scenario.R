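# Shared fixtures: small deterministic configurations and a truth-level
# replicate runner (polymorphisms analysed directly from the truth tables,
# bypassing read simulation, so many replicates stay cheap).

tiny_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_contigs = 2L, contig_lengths = 8000L,
             coverage = 15, read_length = 100L, insert_median = 250,
             insert_sd = 25, tract_length_mean = 2000, tract_length_sd = 200,
             n_recomb_tracts = 1L, ...)
}

small_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_contigs = 3L, contig_lengths = 10000L,
             coverage = 30, tract_length_mean = 3000, tract_length_sd = 300,
             ...)
}

# collated truth-level SNV tables for a scenario (one row per truth SNV)
truth_snv_tables <- function(scenario, clusters = NULL) {
  tr <- scenario$truth$snvs
  do.call(rbind, lapply(names(scenario$mags), function(id) {
    mag <- scenario$mags[[id]]
    t1 <- tr[tr$mag_id == id, , drop = FALSE]
    raw <- data.frame(contig = t1$contig, pos = t1$pos,
                      consensus_base = t1$consensus_base,
                      variant_base = t1$variant_base,
                      variant_count = 10L, depth = 50L,
                      variant_frequency = t1$frequency,
                      stringsAsFactors = FALSE)
    collate_snv_table(restrict_to_orfs(raw, mag$orfs)$snvs, mag, clusters)
  }))
}

all_proteins <- function(mags) {
  unlist(lapply(names(mags), function(id) {
    p <- as.character(mag_proteins(mags[[id]]))
    stats::setNames(p, paste0(id, "|", names(p)))
  }))
}

all_orf_seqs <- function(mags) {
  unlist(lapply(names(mags), function(id) {
    s <- as.character(mag_orf_seqs(mags[[id]]))
    stats::setNames(s, paste0(id, "|", names(s)))
  }))
}

# one truth-level replicate at the generator's default scale (100 kb genome,
# 10 kb tracts): simulate populations, find shared SNVs from the truth
# tables, return the convergence evidence table plus (optionally)
# tract-recovery sensitivity and the ANI contrast for the recombined pair
run_truth_replicate <- function(seed, recombination = TRUE, ani = FALSE) {
  cfg <- sim_config(seed = seed, mges = list(),
                    n_recomb_tracts = if (recombination) 2L else 0L)
  sc <- simulate_scenario(cfg)
  cl <- cluster_proteins(all_proteins(sc$mags))
  snvs <- truth_snv_tables(sc, cl)
  shared <- find_shared_snvs(snvs, cl, all_orf_seqs(sc$mags))
  ctab <- convergence_table(summarize_groups(shared, names(sc$mags)))
  out <- list(config = cfg, scenario = sc, shared = shared, convergence = ctab)
  # truth shared same-substitution entries for the donor/recipient pair
  # (coordinates are comparable across MAGs: no per-MAG indels in this config)
  tr <- sc$truth$snvs
  dn <- cfg$recomb_pairs[[1]][1]; rc <- cfg$recomb_pairs[[1]][2]
  td <- tr[tr$mag_id == dn, ]; tc <- tr[tr$mag_id == rc, ]
  key <- function(x) paste(x$contig, x$pos, x$consensus_base, x$variant_base)
  truth_shared <- intersect(key(td), key(tc))
  out$n_truth_shared <- length(truth_shared)
  if (length(truth_shared)) {
    p <- shared$participants
    found <- intersect(
      paste(p$contig[p$mag_id == dn], p$pos[p$mag_id == dn]),
      paste(p$contig[p$mag_id == rc], p$pos[p$mag_id == rc]))
    truth_pos <- sub("^(\\S+ \\S+).*", "\\1", truth_shared)
    out$sensitivity <- mean(truth_pos %in% found)
  }
  if (ani && recombination) {
    df <- mag_pair_ani(sc$mags[[dn]], sc$mags[[rc]])
    flags <- label_shared_contigs(shared$participants, dn, rc)
    df$has_shared_snv <- paste(df$contig_a, df$contig_b) %in%
      paste(flags$contig_a, flags$contig_b)
    cmp <- compare_ani_groups(df)
    sh <- cmp$means$mean_ani[cmp$means$group == "shared_snv"]
    no <- cmp$means$mean_ani[cmp$means$group == "no_shared_snv"]
    out$ani_shared <- if (length(sh)) sh else NA_real_
    out$ani_unshared <- if (length(no)) no else NA_real_
  }
  out
}

# evidence calls for the cross-clade pairs of a convergence table
cross_clade_evidence <- function(ctab, clades = c(`S-30` = "S", `S-65` = "S",
                                                  `S-132` = "S", `D-30` = "D",
                                                  `D-65` = "D", `D-132` = "D")) {
  pairs <- ctab[ctab$kind == "pair", ]
  mm <- strsplit(pairs$mag_set, ",", fixed = TRUE)
  cross <- vapply(mm, function(m) clades[m[1]] != clades[m[2]], logical(1))
  stats::setNames(pairs$evidence[cross], pairs$mag_set[cross])
}

# random protein family generator for clustering tests
random_protein <- function(n) {
  paste(sample(Biostrings::AA_STANDARD, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(s, n_subs) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), n_subs)
  ch[idx] <- vapply(ch[idx], function(a)
    sample(setdiff(Biostrings::AA_STANDARD, a), 1), character(1))
  paste(ch, collapse = "")
}
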