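# Genome-size normalization, per-MAG summary tables, end-to-end orchestration
# of simulate -> call -> cluster -> shared -> convergence -> ANI -> MGE, a
# run manifest with content hashes, and a human-readable Markdown report.

#' Normalize assembled genome size by completeness
#'
#' Estimated genome size = assembled size / completeness, where completeness
#' is the proportion of expected housekeeping genes recovered (an upstream
#' input, never computed here).
#'
#' @param assembled_size assembled MAG size in bp.
#' @param completeness fraction in (0, 1].
#' @return estimated genome size in bp.
#' @export
normalize_genome_size <- function(assembled_size, completeness) {
  if (any(is.na(completeness)) || any(completeness <= 0) ||
      any(completeness > 1))
    stop("completeness must be in (0, 1]")
  if (any(assembled_size < 0)) stop("assembled_size must be >= 0")
  assembled_size / completeness
}

#' Per-MAG summary table
#'
#' The per-population overview: abundance class, completeness-normalized
#' genome size (Mbp), protein-gene count, and the SNV burden metrics.
#'
#' @param mags named list of `mag_record`s.
#' @param snv_stats data.frame from [mag_snv_stats()].
#' @param abundance optional named numeric (% of binned community), an
#'   upstream input.
#' @return data.frame, one row per MAG.
#' @export
mag_summary <- function(mags, snv_stats, abundance = NULL) {
  rows <- lapply(names(mags), function(id) {
    mag <- mags[[id]]
    st <- snv_stats[snv_stats$mag_id == id, , drop = FALSE]
    data.frame(
      mag_id = id, clade = mag$clade, depth_interval = mag$depth_interval,
      abundance_pct = if (!is.null(abundance)) abundance[[id]] else NA_real_,
      abundance_class = mag$abundance_class,
      assembled_size_bp = mag_size(mag),
      completeness = mag$completeness,
      estimated_genome_size_mbp =
        normalize_genome_size(mag_size(mag), mag$completeness) / 1e6,
      n_protein_genes = nrow(mag$orfs),
      total_snvs = st$total_snvs, snvs_in_orfs = st$snvs_in_orfs,
      orfs_with_snv = st$orfs_with_snv,
      mean_snvs_per_orf = st$mean_snvs_per_orf,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates, under one output directory: scenario simulation (or loading
#' of real inputs), per-MAG read-pair filtering, pileup and SNV calling,
#' restriction to ORFs, cross-MAG protein clustering, hierarchical shared-SNV
#' identification, the convergence evidence table, contig-pair ANI comparison
#' for MAG pairs with shared SNVs, MGE identity matrices with congruence
#' calls, per-MAG summaries and group t-tests, a manifest with content hashes
#' of every emitted file, and a Markdown report. Reruns with the same config
#' produce byte-identical tables.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param simulate logical; `FALSE` requires `inputs`.
#' @param inputs for `simulate = FALSE`: list with named character vectors
#'   `mag_fasta`, `orfs_gff3`, `pairs_tsv` (one path per MAG id), optional
#'   `mge_tsv`, and `metadata` (data.frame: mag_id, clade, depth_interval,
#'   abundance_class, completeness). Missing files fail before any stage runs.
#' @param run_ani,run_mge logicals to skip the slower comparative stages.
#' @return invisibly, a list with the principal in-memory results.
#' @export
run_pipeline <- function(config, out_dir, simulate = TRUE, inputs = NULL,
                         run_ani = TRUE, run_mge = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!simulate) {
    missing <- preflight_inputs(inputs)
    if (length(missing))
      stop("missing inputs for a non-simulated run:\n  ",
           paste(missing, collapse = "\n  "))
  }
  if (simulate) {
    scenario <- simulate_scenario(config)
    write_scenario(scenario, file.path(out_dir, "sim"))
    mags <- scenario$mags
    truth <- scenario$truth
    pairs_by_mag <- lapply(mags, function(m)
      simulate_read_pairs(m, truth$snvs[truth$snvs$mag_id == m$mag_id, ,
                                        drop = FALSE], config))
    mge_ann <- truth$mges
  } else {
    md <- inputs$metadata
    mags <- stats::setNames(lapply(md$mag_id, function(id) {
      m <- read_mag_fasta(inputs$mag_fasta[[id]], id,
                          orfs = read_orfs_gff3(inputs$orfs_gff3[[id]]))
      m$clade <- md$clade[md$mag_id == id]
      m$depth_interval <- md$depth_interval[md$mag_id == id]
      m$abundance_class <- md$abundance_class[md$mag_id == id]
      m$completeness <- md$completeness[md$mag_id == id]
      m
    }), md$mag_id)
    pairs_by_mag <- stats::setNames(lapply(md$mag_id, function(id)
      read_tsv(inputs$pairs_tsv[[id]])), md$mag_id)
    mge_ann <- if (!is.null(inputs$mge_tsv)) read_tsv(inputs$mge_tsv) else NULL
    scenario <- NULL; truth <- NULL
  }
  snv_dir <- file.path(out_dir, "snvs")
  dir.create(snv_dir, showWarnings = FALSE)
  orf_snvs <- list(); totals <- list(); filter_logs <- list(); call_logs <- list()
  for (id in names(mags)) {
    filt <- filter_read_pairs(pairs_by_mag[[id]])
    pile <- build_pileup(filt$pairs, mags[[id]])
    called <- call_snvs(pile)
    restricted <- restrict_to_orfs(called$snvs, mags[[id]]$orfs)
    orf_snvs[[id]] <- restricted$snvs
    totals[[id]] <- restricted$totals
    filter_logs[[id]] <- cbind(mag_id = id, filt$log)
    call_logs[[id]] <- cbind(mag_id = id, called$log)
    write_tsv(restricted$snvs, file.path(snv_dir, paste0(id, "_orf_snvs.tsv")))
  }
  write_tsv(do.call(rbind, filter_logs), file.path(snv_dir, "filter_log.tsv"))
  write_tsv(do.call(rbind, call_logs), file.path(snv_dir, "call_log.tsv"))
  # cross-MAG protein clustering and the collated SNV table
  prot <- unlist(lapply(names(mags), function(id) {
    p <- as.character(mag_proteins(mags[[id]]))
    stats::setNames(p, paste0(id, "|", names(p)))
  }))
  clusters <- cluster_proteins(prot)
  write_tsv(clusters, file.path(out_dir, "protein_clusters.tsv"))
  orf_seqs <- unlist(lapply(names(mags), function(id) {
    s <- as.character(mag_orf_seqs(mags[[id]]))
    stats::setNames(s, paste0(id, "|", names(s)))
  }))
  snv_table <- do.call(rbind, lapply(names(mags), function(id)
    collate_snv_table(orf_snvs[[id]], mags[[id]], clusters)))
  write_tsv(snv_table, file.path(out_dir, "snv_table.tsv"))
  # shared SNVs, group summaries, convergence evidence
  shared <- find_shared_snvs(snv_table, clusters, orf_seqs)
  write_tsv(shared$sites, file.path(out_dir, "shared_sites.tsv"))
  write_tsv(shared$participants, file.path(out_dir, "shared_participants.tsv"))
  groups <- summarize_groups(shared, names(mags))
  ctab <- convergence_table(groups)
  write_tsv(ctab, file.path(out_dir, "convergence_table.tsv"))
  ancestral <- flag_ancestral(shared, n_mags_total = length(mags))
  write_tsv(ancestral, file.path(out_dir, "ancestral_sites.tsv"))
  stats_df <- mag_snv_stats(snv_table, totals, mags)
  ttests <- compare_group_counts(stats_df)
  write_tsv(ttests, file.path(out_dir, "group_ttests.tsv"))
  summary_df <- mag_summary(mags, stats_df)
  write_tsv(summary_df, file.path(out_dir, "mag_summary.tsv"))
  # contig-pair ANI for MAG pairs that share SNVs
  ani_results <- NULL
  if (run_ani) {
    ani_dir <- file.path(out_dir, "ani")
    dir.create(ani_dir, showWarnings = FALSE)
    ani_rows <- list()
    for (pr in utils::combn(sort(names(mags)), 2, simplify = FALSE)) {
      flags <- label_shared_contigs(shared$participants, pr[1], pr[2])
      if (nrow(flags) == 0) next
      df <- mag_pair_ani(mags[[pr[1]]], mags[[pr[2]]])
      df$has_shared_snv <- paste(df$contig_a, df$contig_b) %in%
        paste(flags$contig_a, flags$contig_b)
      cmp <- compare_ani_groups(df)
      write_tsv(df, file.path(ani_dir, paste0(pr[1], "_", pr[2],
                                              "_contig_ani.tsv")))
      sh <- cmp$means$mean_ani[cmp$means$group == "shared_snv"]
      no <- cmp$means$mean_ani[cmp$means$group == "no_shared_snv"]
      ani_rows[[paste(pr, collapse = "_")]] <- data.frame(
        mag_a = pr[1], mag_b = pr[2],
        mean_ani_shared = if (length(sh)) sh else NA_real_,
        mean_ani_unshared = if (length(no)) no else NA_real_,
        stringsAsFactors = FALSE)
    }
    if (length(ani_rows)) {
      ani_results <- do.call(rbind, ani_rows)
      rownames(ani_results) <- NULL
      write_tsv(ani_results, file.path(out_dir, "ani_group_comparison.tsv"))
    }
  }
  # MGE identity matrices and congruence
  mge_results <- NULL
  if (run_mge && !is.null(mge_ann) && nrow(mge_ann) > 0) {
    mge_dir <- file.path(out_dir, "mge")
    dir.create(mge_dir, showWarnings = FALSE)
    mge_results <- mge_comparison(mags, mge_ann)
    for (nm in names(mge_results$matrices)) {
      m <- mge_results$matrices[[nm]]
      write_tsv(data.frame(mag_id = rownames(m), round(m, 4),
                           check.names = FALSE),
                file.path(mge_dir, paste0(nm, "_identity.tsv")))
    }
    write_tsv(mge_results$congruence, file.path(out_dir, "mge_congruence.tsv"))
  }
  render_report(out_dir)
  write_manifest(out_dir, config)
  invisible(list(mags = mags, truth = truth, snv_table = snv_table,
                 clusters = clusters, shared = shared,
                 convergence = ctab, mag_summary = summary_df,
                 ttests = ttests, ani = ani_results, mge = mge_results))
}

preflight_inputs <- function(inputs) {
  missing <- character(0)
  if (is.null(inputs) || is.null(inputs$metadata))
    return("inputs$metadata (mag_id, clade, depth_interval, abundance_class, completeness)")
  for (field in c("mag_fasta", "orfs_gff3", "pairs_tsv")) {
    for (id in inputs$metadata$mag_id) {
      p <- if (is.null(inputs[[field]])) NA_character_
           else unname(inputs[[field]][id])
      if (is.na(p)) missing <- c(missing, paste0(field, " for ", id))
      else if (!file.exists(p)) missing <- c(missing, p)
    }
  }
  if (!is.null(inputs$mge_tsv) && !file.exists(inputs$mge_tsv))
    missing <- c(missing, inputs$mge_tsv)
  missing
}

#' Write the run manifest
#'
#' Lists every file under the run directory (except the manifest itself) with
#' its MD5 content hash, plus the package version and seed, as JSON. Reruns
#' with the same config produce identical manifests.
#'
#' @param out_dir run directory.
#' @param config the [sim_config()] that produced the run (for the seed).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(out_dir, config) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  hashes <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    package = "parasnv",
    package_version = as.character(utils::packageVersion("parasnv")),
    seed = config$seed,
    files = data.frame(path = files, md5 = hashes, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

md_table <- function(df, digits = 4) {
  if (is.null(df) || nrow(df) == 0) return("_no data_\n")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r)
    paste0("| ", paste(ifelse(is.na(r), "NA", r), collapse = " | "), " |"))
  paste(c(hdr, sep, body, ""), collapse = "\n")
}

#' Render the Markdown run report
#'
#' Assembles the per-MAG summary, the shared-SNV / convergence evidence table
#' (with the "<1" convention for sub-unit expectations shown alongside the
#' numeric value), the ANI group comparison and the MGE congruence calls into
#' `report.md` under the run directory. An empty run yields a report that
#' says so.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return the report path, invisibly.
#' @export
render_report <- function(out_dir) {
  get_tsv <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) read_tsv(p) else NULL
  }
  lines <- c("# Gene-flow analysis run report", "")
  summary_df <- get_tsv("mag_summary.tsv")
  ctab <- get_tsv("convergence_table.tsv")
  if (is.null(summary_df) && is.null(ctab)) {
    lines <- c(lines, "no data", "")
    writeLines(lines, file.path(out_dir, "report.md"))
    return(invisible(file.path(out_dir, "report.md")))
  }
  lines <- c(lines, "## Per-MAG summary", "", md_table(summary_df))
  if (!is.null(ctab)) {
    show <- ctab[c("mag_set", "kind", "n_same_site", "n_same_substitution",
                   "expected_display", "evidence")]
    names(show)[5] <- "expected_convergent"
    lines <- c(lines, "## Shared SNVs and convergence evidence", "",
               md_table(show))
  }
  ani <- get_tsv("ani_group_comparison.tsv")
  if (!is.null(ani))
    lines <- c(lines, "## Contig-pair ANI: shared-SNV vs other contigs", "",
               md_table(ani))
  mge <- get_tsv("mge_congruence.tsv")
  if (!is.null(mge))
    lines <- c(lines, "## MGE clade congruence", "", md_table(mge))
  tt <- get_tsv("group_ttests.tsv")
  if (!is.null(tt))
    lines <- c(lines, "## Group comparisons (two-tailed t-tests)", "",
               md_table(tt))
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(file.path(out_dir, "report.md"))
}
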