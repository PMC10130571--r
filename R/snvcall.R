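# SNV identification and curation from mapped read-pair observations, with
# each MAG used as its own reference: read-pair filters (pair identity, mapQ,
# insert size), pileup construction, per-site calling with consensus-SNV
# discard and mapQ validation of the consensus, restriction to ORFs, and the
# collated per-SNV table.

#' Filter read pairs before pileup
#'
#' Two-pass curation: (1) discard pairs with pair identity below
#' `min_pair_identity` or either mate's mapQ below `min_mapq`; (2) compute the
#' median insert size over the survivors and discard pairs with insert size
#' below `min_insert` or above `max_insert_factor` times that median. Both
#' insert bounds are inclusive (a pair at exactly 3x the median is retained).
#'
#' @param pairs read-pair data.frame ([simulate_read_pairs()] format).
#' @param min_pair_identity minimum pair-to-reference identity (default 0.90;
#'   a pair at 0.89 is discarded, at 0.90 retained).
#' @param min_mapq minimum mapQ required of *both* mates (default 1).
#' @param min_insert minimum insert size in bp (default 50).
#' @param max_insert_factor maximum insert size as a multiple of the median
#'   insert of identity/mapQ-passing pairs (default 3).
#' @return list with `pairs` (retained) and `log`, a data.frame of per-filter
#'   removal counts satisfying input = retained + sum(removed).
#' @export
filter_read_pairs <- function(pairs, min_pair_identity = 0.90, min_mapq = 1,
                              min_insert = 50, max_insert_factor = 3.0) {
  n_in <- nrow(pairs)
  ok_ident <- pairs$pair_identity >= min_pair_identity
  n_ident <- sum(!ok_ident)
  p1 <- pairs[ok_ident, , drop = FALSE]
  ok_mapq <- p1$mapq1 >= min_mapq & p1$mapq2 >= min_mapq
  n_mapq <- sum(!ok_mapq)
  p2 <- p1[ok_mapq, , drop = FALSE]
  if (nrow(p2) == 0) {
    warning("no read pairs survive the identity/mapQ filters")
    med <- NA_real_
    p4 <- p2; n_min <- 0L; n_max <- 0L
  } else {
    med <- stats::median(p2$insert_size)
    ok_min <- p2$insert_size >= min_insert
    n_min <- sum(!ok_min)
    p3 <- p2[ok_min, , drop = FALSE]
    ok_max <- p3$insert_size <= max_insert_factor * med
    n_max <- sum(!ok_max)
    p4 <- p3[ok_max, , drop = FALSE]
  }
  log <- data.frame(
    filter = c("input", "pair_identity", "mapq", "insert_min", "insert_max",
               "retained"),
    count = c(n_in, n_ident, n_mapq, n_min, n_max, nrow(p4)),
    stringsAsFactors = FALSE)
  attr(log, "median_insert") <- med
  list(pairs = p4, log = log)
}

#' Build a per-site pileup from retained read pairs
#'
#' Counts each retained mate base exactly once per covered reference position
#' (overlapping mates of the same pair are both counted). Sites with no
#' coverage are absent from the result.
#'
#' @param pairs retained read pairs.
#' @param mag the reference `mag_record` (contig bounds are checked).
#' @return data.frame with contig, pos, depth, per-base counts `n_A..n_T` and
#'   per-base mean mapQ `mq_A..mq_T` (NA where the count is zero).
#' @export
build_pileup <- function(pairs, mag) {
  if (nrow(pairs) == 0) return(empty_pileup())
  L <- nchar(pairs$seq1[1])
  bad <- !(pairs$contig %in% names(mag$contigs))
  if (any(bad)) stop("read pair maps to unknown contig: ",
                     paste(unique(pairs$contig[bad]), collapse = ", "))
  clen <- nchar(mag$contigs)[pairs$contig]
  if (any(pairs$start1 < 1 | pairs$start2 + L - 1L > clen))
    stop("read position outside contig bounds")
  n <- nrow(pairs)
  mk <- function(seqs, starts, mapq) {
    base <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    data.table::data.table(
      contig = rep(pairs$contig, each = L),
      pos = rep(starts, each = L) + rep.int(0:(L - 1L), n),
      base = base,
      mapq = rep(mapq, each = L))
  }
  dt <- data.table::rbindlist(list(mk(pairs$seq1, pairs$start1, pairs$mapq1),
                                   mk(pairs$seq2, pairs$start2, pairs$mapq2)))
  agg <- dt[, list(count = .N, mqsum = sum(mapq)),
            by = c("contig", "pos", "base")]
  wide <- data.table::dcast(agg, contig + pos ~ base,
                            value.var = c("count", "mqsum"), fill = 0)
  for (b in BASES) {
    cn <- paste0("count_", b); mn <- paste0("mqsum_", b)
    if (!cn %in% names(wide)) wide[[cn]] <- 0L
    if (!mn %in% names(wide)) wide[[mn]] <- 0
  }
  out <- data.frame(contig = wide$contig, pos = wide$pos,
                    stringsAsFactors = FALSE)
  depth <- 0L
  for (b in BASES) {
    out[[paste0("n_", b)]] <- wide[[paste0("count_", b)]]
    depth <- depth + out[[paste0("n_", b)]]
    out[[paste0("mq_", b)]] <- ifelse(out[[paste0("n_", b)]] > 0,
                                      wide[[paste0("mqsum_", b)]] /
                                        out[[paste0("n_", b)]], NA_real_)
  }
  out$depth <- depth
  out[order(out$contig, out$pos), , drop = FALSE]
}

empty_pileup <- function() {
  out <- data.frame(contig = character(0), pos = integer(0),
                    stringsAsFactors = FALSE)
  for (b in BASES) { out[[paste0("n_", b)]] <- integer(0)
                     out[[paste0("mq_", b)]] <- numeric(0) }
  out$depth <- integer(0)
  out
}

#' Call SNVs from a pileup
#'
#' Per site: the consensus is the most frequent base; a tied consensus rejects
#' the site (logged). The consensus must also have the highest mean mapQ among
#' bases present (ties allowed), else the site is rejected. The variant is the
#' most frequent non-consensus base (ties broken by base order A<C<G<T); it
#' must be supported by at least `min_variant_reads` reads and reach a
#' frequency of at least `min_variant_freq`. Sites whose variant frequency
#' reaches `consensus_snv_threshold` (default 0.40) are classified as
#' consensus SNVs - ambiguous allelic heterogeneity - and discarded (logged).
#'
#' @param pileup a [build_pileup()] data.frame.
#' @param min_variant_reads minimum variant-supporting reads (default 2).
#' @param consensus_snv_threshold variant frequency at or above which the site
#'   is discarded as a consensus SNV (default 0.40).
#' @param min_variant_freq minimum variant frequency (default 0.05, the
#'   conventional metagenomic allele-frequency floor; protects precision
#'   against coincident sequencing errors).
#' @return list with `snvs` (data.frame: contig, pos, consensus_base,
#'   variant_base, variant_count, depth, variant_frequency) and `log`
#'   (site-level outcome counts).
#' @export
call_snvs <- function(pileup, min_variant_reads = 2,
                      consensus_snv_threshold = 0.40,
                      min_variant_freq = 0.05) {
  n <- nrow(pileup)
  if (n == 0) {
    return(list(snvs = empty_snvs(), log = call_log(0, 0, 0, 0, 0)))
  }
  cnt <- as.matrix(pileup[paste0("n_", BASES)])
  mq <- as.matrix(pileup[paste0("mq_", BASES)])
  depth <- pileup$depth
  cmax <- apply(cnt, 1L, max)
  n_at_max <- rowSums(cnt == cmax)
  tie <- n_at_max > 1L
  cons_i <- max.col(cnt, ties.method = "first")
  # consensus must carry the highest mean mapQ among bases present
  mq_cons <- mq[cbind(seq_len(n), cons_i)]
  mq_other <- mq; mq_other[cbind(seq_len(n), cons_i)] <- -Inf
  mq_other[is.na(mq_other)] <- -Inf
  mq_best_other <- apply(mq_other, 1L, max)
  mq_reject <- !tie & is.finite(mq_best_other) & mq_cons < mq_best_other
  vcnt <- cnt; vcnt[cbind(seq_len(n), cons_i)] <- -1L
  var_i <- max.col(vcnt, ties.method = "first")
  var_count <- vcnt[cbind(seq_len(n), var_i)]
  var_freq <- ifelse(var_count > 0, var_count / depth, 0)
  eligible <- !tie & !mq_reject & var_count >= min_variant_reads &
    var_freq >= min_variant_freq
  consensus_discard <- eligible & var_freq >= consensus_snv_threshold
  emit <- eligible & !consensus_discard
  snvs <- data.frame(contig = pileup$contig[emit], pos = pileup$pos[emit],
                     consensus_base = BASES[cons_i[emit]],
                     variant_base = BASES[var_i[emit]],
                     variant_count = var_count[emit], depth = depth[emit],
                     variant_frequency = var_freq[emit],
                     stringsAsFactors = FALSE, row.names = NULL)
  list(snvs = snvs,
       log = call_log(n, sum(tie), sum(mq_reject), sum(consensus_discard),
                      sum(emit)))
}

call_log <- function(sites, ties, mq_rejects, consensus_discards, emitted) {
  data.frame(outcome = c("sites", "consensus_tie_reject", "mapq_reject",
                         "consensus_snv_discard", "snv_emitted"),
             count = c(sites, ties, mq_rejects, consensus_discards, emitted),
             stringsAsFactors = FALSE)
}

empty_snvs <- function() {
  data.frame(contig = character(0), pos = integer(0),
             consensus_base = character(0), variant_base = character(0),
             variant_count = integer(0), depth = integer(0),
             variant_frequency = numeric(0), stringsAsFactors = FALSE)
}

#' Call a single pileup site
#'
#' Convenience wrapper around [call_snvs()] for one site, mainly for
#' interactive inspection and tests.
#'
#' @param counts named numeric vector of A/C/G/T read counts.
#' @param mapq_means named numeric vector of per-base mean mapQ (NA where the
#'   count is zero); defaults to equal mapQ.
#' @param ... passed to [call_snvs()].
#' @return list with `call` ("snv", "consensus_snv", "none", or "rejected")
#'   and, for "snv", the one-row SNV data.frame as `snv`.
#' @export
call_site <- function(counts, mapq_means = NULL, ...) {
  counts <- counts[BASES]; counts[is.na(counts)] <- 0
  if (is.null(mapq_means)) mapq_means <- ifelse(counts > 0, 30, NA_real_)
  else { mapq_means <- mapq_means[BASES] }
  site <- data.frame(contig = "c", pos = 1L, stringsAsFactors = FALSE)
  for (b in BASES) {
    site[[paste0("n_", b)]] <- as.integer(counts[[b]])
    site[[paste0("mq_", b)]] <- as.numeric(mapq_means[[b]])
  }
  site$depth <- as.integer(sum(counts))
  res <- call_snvs(site, ...)
  lg <- stats::setNames(res$log$count, res$log$outcome)
  call <- if (nrow(res$snvs) == 1) "snv"
  else if (lg[["consensus_snv_discard"]] == 1) "consensus_snv"
  else if (lg[["consensus_tie_reject"]] == 1 || lg[["mapq_reject"]] == 1) "rejected"
  else "none"
  list(call = call, snv = if (nrow(res$snvs)) res$snvs else NULL)
}

#' Restrict SNVs to ORFs and add within-ORF coordinates
#'
#' Only SNVs inside annotated ORFs are used downstream; totals for both the
#' full and the in-ORF set are reported. `position_in_orf` is 1-based on the
#' coding strand.
#'
#' @param snvs SNV data.frame from [call_snvs()].
#' @param orfs ORF table (orf_id, contig, start, end, strand).
#' @return list with `snvs` (in-ORF, plus orf_id and position_in_orf) and
#'   `totals` (n_total, n_in_orf).
#' @export
restrict_to_orfs <- function(snvs, orfs) {
  n_total <- nrow(snvs)
  if (n_total == 0 || nrow(orfs) == 0) {
    out <- cbind(snvs[0, , drop = FALSE],
                 data.frame(orf_id = character(0), position_in_orf = integer(0)))
    return(list(snvs = out, totals = c(n_total = n_total, n_in_orf = 0L)))
  }
  sdt <- data.table::as.data.table(snvs)
  odt <- data.table::as.data.table(orfs[c("orf_id", "contig", "start", "end",
                                          "strand")])
  sdt[, `:=`(s = pos, e = pos)]
  data.table::setkey(odt, contig, start, end)
  ov <- data.table::foverlaps(sdt, odt, by.x = c("contig", "s", "e"),
                              type = "within", nomatch = NULL)
  ov[, position_in_orf := ifelse(strand == "-", end - pos + 1L,
                                 pos - start + 1L)]
  keep <- c(names(snvs), "orf_id", "position_in_orf")
  out <- as.data.frame(ov)[, keep, drop = FALSE]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  list(snvs = out, totals = c(n_total = n_total, n_in_orf = nrow(out)))
}

#' Collate the per-SNV table
#'
#' One row per curated in-ORF SNV carrying the fields the downstream
#' comparisons need: the SNV and its base frequencies, its location on its
#' ORF, the MAG it came from, the ORF nucleotide sequence and inferred protein
#' sequence, the protein cluster (when a cluster table is supplied), and empty
#' annotation slots (functional annotation is out of scope here). Round-trips
#' losslessly through TSV.
#'
#' @param orf_snvs in-ORF SNVs from [restrict_to_orfs()].
#' @param mag the `mag_record` the SNVs belong to.
#' @param clusters optional cluster table from [cluster_proteins()].
#' @return data.frame, one row per SNV.
#' @export
collate_snv_table <- function(orf_snvs, mag, clusters = NULL) {
  nt <- mag_orf_seqs(mag); aa <- mag_proteins(mag)
  cl <- rep(NA_character_, nrow(orf_snvs))
  if (!is.null(clusters) && nrow(orf_snvs) > 0) {
    key <- clusters$cluster_id[match(
      paste(mag$mag_id, orf_snvs$orf_id),
      paste(clusters$mag_id, clusters$orf_id))]
    cl <- key
  }
  data.frame(
    snv_id = if (nrow(orf_snvs)) sprintf("%s_%s_%d", mag$mag_id,
                                         orf_snvs$contig, orf_snvs$pos)
             else character(0),
    mag_id = rep(mag$mag_id, nrow(orf_snvs)),
    contig = orf_snvs$contig, pos = orf_snvs$pos,
    consensus_base = orf_snvs$consensus_base,
    variant_base = orf_snvs$variant_base,
    variant_frequency = orf_snvs$variant_frequency,
    depth = orf_snvs$depth,
    orf_id = orf_snvs$orf_id,
    position_in_orf = orf_snvs$position_in_orf,
    orf_seq = as.character(nt[orf_snvs$orf_id]),
    protein_seq = as.character(aa[orf_snvs$orf_id]),
    cluster_id = cl,
    kegg_ortholog = rep(NA_character_, nrow(orf_snvs)),
    kegg_pathways = rep(NA_character_, nrow(orf_snvs)),
    stringsAsFactors = FALSE, row.names = NULL)
}
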