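# Hierarchical identification of SNVs shared between MAGs: first, SNVs present
# in more than one MAG at the same homologous site (through protein clusters
# and site maps); second, those with the same substitution (identical
# consensus and variant base). Tabulated per MAG pair, per designated triplet,
# and across all six MAGs (presumed ancestral).

#' Find SNVs shared across MAGs at homologous sites
#'
#' SNV positions are projected onto the cluster representative's ORF
#' coordinates through nucleotide site maps; any representative coordinate
#' carrying an SNV in two or more MAGs yields a shared-SNV site. A site's
#' level is `same_substitution` when every participating MAG has the identical
#' (consensus, variant) base pair, else `same_site`.
#'
#' @param snv_tables collated SNV table ([collate_snv_table()] rows, all MAGs
#'   concatenated) with at least mag_id, orf_id, position_in_orf,
#'   consensus_base, variant_base and cluster_id.
#' @param clusters cluster table from [cluster_proteins()].
#' @param orf_seqs named character vector / `DNAStringSet` of coding-strand
#'   ORF nucleotide sequences keyed `"<mag_id>|<orf_id>"`.
#' @return list with `sites` (one row per shared site: cluster_id, site,
#'   n_mags, level, mags) and `participants` (one row per participating SNV:
#'   cluster_id, site, mag_id, consensus_base, variant_base). SNVs whose
#'   position projects into an alignment gap cannot be shared and are dropped.
#' @export
find_shared_snvs <- function(snv_tables, clusters, orf_seqs) {
  orf_seqs <- stats::setNames(as.character(orf_seqs), names(orf_seqs))
  snv <- snv_tables
  if (is.null(snv$cluster_id) || all(is.na(snv$cluster_id))) {
    key <- paste(snv$mag_id, snv$orf_id)
    snv$cluster_id <- clusters$cluster_id[match(
      key, paste(clusters$mag_id, clusters$orf_id))]
  }
  if (any(is.na(snv$cluster_id)))
    stop("SNV references an ORF absent from the cluster table")
  reps <- clusters[clusters$is_representative, , drop = FALSE]
  rep_key <- stats::setNames(paste0(reps$mag_id, "|", reps$orf_id),
                             reps$cluster_id)
  # only clusters with SNVs from >= 2 MAGs can produce shared sites
  tab <- unique(snv[c("cluster_id", "mag_id")])
  multi <- names(which(table(tab$cluster_id) >= 2))
  parts <- list()
  for (cl in multi) {
    rows <- snv[snv$cluster_id == cl, , drop = FALSE]
    rk <- rep_key[[cl]]
    if (is.null(orf_seqs[[rk]]))
      stop("no ORF sequence for cluster representative ", rk)
    rows$key <- paste0(rows$mag_id, "|", rows$orf_id)
    rows$site <- NA_integer_
    for (mk in unique(rows$key)) {
      sel <- rows$key == mk
      if (mk == rk) { rows$site[sel] <- rows$position_in_orf[sel]; next }
      if (is.null(orf_seqs[[mk]]))
        stop("no ORF sequence for cluster member ", mk)
      map <- map_site_pair(orf_seqs[[mk]], orf_seqs[[rk]])
      rows$site[sel] <- project_positions(map, rows$position_in_orf[sel], "a")
    }
    rows <- rows[!is.na(rows$site), , drop = FALSE]
    parts[[cl]] <- rows[c("cluster_id", "site", "mag_id", "contig", "pos",
                          "consensus_base", "variant_base")]
  }
  if (length(parts) == 0) {
    return(list(sites = empty_shared_sites(), participants = empty_participants()))
  }
  participants <- do.call(rbind, parts)
  rownames(participants) <- NULL
  dt <- data.table::as.data.table(participants)
  sites <- dt[, list(
    n_mags = data.table::uniqueN(mag_id),
    level = if (data.table::uniqueN(paste(consensus_base, variant_base)) == 1L)
      "same_substitution" else "same_site",
    mags = paste(sort(unique(mag_id)), collapse = ",")),
    by = c("cluster_id", "site")]
  sites <- as.data.frame(sites[sites$n_mags >= 2L, ])
  participants <- participants[
    paste(participants$cluster_id, participants$site) %in%
      paste(sites$cluster_id, sites$site), , drop = FALSE]
  rownames(sites) <- rownames(participants) <- NULL
  list(sites = sites, participants = participants)
}

empty_shared_sites <- function() {
  data.frame(cluster_id = character(0), site = integer(0), n_mags = integer(0),
             level = character(0), mags = character(0), stringsAsFactors = FALSE)
}

empty_participants <- function() {
  data.frame(cluster_id = character(0), site = integer(0),
             mag_id = character(0), contig = character(0), pos = integer(0),
             consensus_base = character(0), variant_base = character(0),
             stringsAsFactors = FALSE)
}

#' Summarize shared SNVs for every MAG pair and the designated triplets
#'
#' A site counts for a pair when both members carry an SNV there (other MAGs
#' at the site do not matter), and as same-substitution when the two members'
#' (consensus, variant) pairs are identical. A triplet counts a site only when
#' all three members carry an SNV there.
#'
#' @param shared result of [find_shared_snvs()].
#' @param mag_ids character vector of all MAG ids (defines the 15 pairs).
#' @param triplets named list of character triplets to tabulate; defaults to
#'   the study design's two clade triplets plus the abundant ("common") and
#'   rare triplets.
#' @return data.frame with mag_set, kind (pair/triplet), n_same_site,
#'   n_same_substitution; `n_same_substitution <= n_same_site` always.
#' @export
summarize_groups <- function(shared, mag_ids, triplets = NULL) {
  if (is.null(triplets)) triplets <- default_triplets(mag_ids)
  p <- shared$participants
  p$skey <- paste(p$cluster_id, p$site)
  p$sub <- paste(p$consensus_base, p$variant_base)
  rows <- list()
  combs <- utils::combn(sort(mag_ids), 2, simplify = FALSE)
  groups <- c(combs, triplets)
  kinds <- c(rep("pair", length(combs)), rep("triplet", length(triplets)))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    sub <- p[p$mag_id %in% g, , drop = FALSE]
    if (nrow(sub) == 0) { nss <- 0L; nsub <- 0L } else {
      dt <- data.table::as.data.table(sub)
      per <- dt[, list(n = data.table::uniqueN(mag_id),
                       one = data.table::uniqueN(sub) == 1L), by = "skey"]
      nss <- sum(per$n == length(g))
      nsub <- sum(per$n == length(g) & per$one)
    }
    rows[[gi]] <- data.frame(mag_set = paste(g, collapse = ","),
                             kind = kinds[gi], n_same_site = nss,
                             n_same_substitution = nsub,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default triplets for the six-MAG study design
#'
#' The two clade triplets (all-S and all-D) plus the abundant ("common") and
#' rare triplets, when the standard labels are present.
#' @param mag_ids character vector of MAG ids.
#' @return named list of character triplets.
#' @export
default_triplets <- function(mag_ids) {
  cand <- list(
    deep_clade = c("D-30", "D-65", "D-132"),
    shallow_clade = c("S-30", "S-65", "S-132"),
    common = c("S-30", "D-65", "D-132"),
    rare = c("D-30", "S-65", "S-132"))
  Filter(function(g) all(g %in% mag_ids), cand)
}

#' Flag shared SNVs presumed ancestral
#'
#' Sites carried by all six MAG populations are presumed ancestral - present
#' in the founder population from which the populations descend.
#'
#' @param shared result of [find_shared_snvs()].
#' @param n_mags_total number of MAGs in the analysis (default 6).
#' @return the `sites` rows with `n_mags == n_mags_total`, with an
#'   `ancestral = TRUE` column.
#' @export
flag_ancestral <- function(shared, n_mags_total = 6L) {
  out <- shared$sites[shared$sites$n_mags == n_mags_total, , drop = FALSE]
  if (nrow(out)) out$ancestral <- TRUE
  else out$ancestral <- logical(0)
  rownames(out) <- NULL
  out
}

#' Compare per-MAG SNV statistics between groups
#'
#' Two-tailed t-tests (Student by default, Welch optionally) comparing the
#' per-MAG SNV burden metrics between MAG groupings: abundance class
#' (abundant vs rare), clade, and each pair of depth intervals.
#'
#' @param mag_stats data.frame with one row per MAG: mag_id, clade,
#'   depth_interval, abundance_class, and the metrics `total_snvs`,
#'   `snvs_in_orfs`, `orfs_with_snv`, `mean_snvs_per_orf`.
#' @param metrics which per-MAG columns to compare (defaults to the four
#'   burden metrics).
#' @param welch logical; use Welch's unequal-variance t-test instead of
#'   Student's (default FALSE).
#' @return tidy data.frame: grouping, group1, group2, metric, n1, n2, t, df,
#'   p_value (NA with a note when a group has < 2 members or zero variance
#'   makes the statistic undefined).
#' @export
compare_group_counts <- function(mag_stats,
                                 metrics = c("total_snvs", "snvs_in_orfs",
                                             "orfs_with_snv",
                                             "mean_snvs_per_orf"),
                                 welch = FALSE) {
  groupings <- list(
    abundance = list(col = "abundance_class", levels = list(
      c("abundant"), c("rare"))),
    clade = list(col = "clade", levels = list(c("S"), c("D"))))
  depths <- unique(mag_stats$depth_interval)
  if (length(depths) > 1) {
    dp <- utils::combn(sort(depths), 2, simplify = FALSE)
    for (d in dp) {
      groupings[[paste0("depth_", d[1], "_vs_", d[2])]] <-
        list(col = "depth_interval", levels = list(d[1], d[2]))
    }
  }
  rows <- list()
  for (gn in names(groupings)) {
    g <- groupings[[gn]]
    x_idx <- mag_stats[[g$col]] %in% g$levels[[1]]
    y_idx <- mag_stats[[g$col]] %in% g$levels[[2]]
    for (m in metrics) {
      x <- mag_stats[[m]][x_idx]; y <- mag_stats[[m]][y_idx]
      if (length(x) < 2 || length(y) < 2 ||
          (stats::sd(x) == 0 && stats::sd(y) == 0)) {
        tt <- list(statistic = NA_real_, parameter = NA_real_,
                   p.value = NA_real_)
        if (length(x) >= 2 && length(y) >= 2 && all(x == y[seq_along(x)]) &&
            stats::sd(c(x, y)) == 0) {
          # identical constant groups: no evidence of difference
          tt <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                     p.value = 1)
        }
      } else {
        ht <- stats::t.test(x, y, var.equal = !welch)
        tt <- list(statistic = unname(ht$statistic),
                   parameter = unname(ht$parameter), p.value = ht$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        grouping = gn,
        group1 = paste(g$levels[[1]], collapse = "/"),
        group2 = paste(g$levels[[2]], collapse = "/"),
        metric = m, n1 = length(x), n2 = length(y),
        t = tt$statistic, df = tt$parameter, p_value = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-MAG SNV burden statistics
#'
#' @param snv_tables collated SNV tables for all MAGs (in-ORF SNVs).
#' @param totals named list (by mag_id) of the `totals` vectors from
#'   [restrict_to_orfs()]; supplies the all-SNV counts.
#' @param mags named list of `mag_record`s (for labels and ORF counts).
#' @return data.frame suitable for [compare_group_counts()].
#' @export
mag_snv_stats <- function(snv_tables, totals, mags) {
  rows <- lapply(names(mags), function(id) {
    mag <- mags[[id]]
    s <- snv_tables[snv_tables$mag_id == id, , drop = FALSE]
    n_orfs <- nrow(mag$orfs)
    per_orf <- table(s$orf_id)
    data.frame(mag_id = id, clade = mag$clade,
               depth_interval = mag$depth_interval,
               abundance_class = mag$abundance_class,
               total_snvs = unname(totals[[id]]["n_total"]),
               snvs_in_orfs = nrow(s),
               orfs_with_snv = length(per_orf),
               mean_snvs_per_orf = if (n_orfs > 0) nrow(s) / n_orfs else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
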