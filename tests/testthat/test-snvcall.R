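# The SNV filter chain and caller: read-pair filters with their exact
# boundaries, pileup bookkeeping, per-site calling rules, ORF restriction and
# the collated table.

mk_pairs <- function(identity = 0.95, mapq1 = 30, mapq2 = 30, insert = 300,
                     n = 1) {
  data.frame(pair_id = sprintf("p%03d", seq_len(max(n, length(identity),
                                                    length(insert)))),
             contig = "c1", start1 = 1L, start2 = 151L,
             insert_size = insert, mapq1 = mapq1, mapq2 = mapq2,
             pair_identity = identity,
             seq1 = "ACGT", seq2 = "ACGT", stringsAsFactors = FALSE)
}

test_that("read-pair filters apply their exact boundaries", {
  base <- mk_pairs(identity = c(0.89, 0.90, 0.95), insert = 300)
  res <- filter_read_pairs(base)
  expect_equal(nrow(res$pairs), 2L)              # 0.89 discarded, 0.90 kept
  expect_false("p001" %in% res$pairs$pair_id)
  # a single mapQ-0 mate discards the pair
  mq <- mk_pairs(identity = 0.95, mapq1 = c(0, 1, 40), mapq2 = c(40, 1, 40))
  res <- filter_read_pairs(mq)
  expect_equal(nrow(res$pairs), 2L)
  # insert bounds: 49 out, 50 in, exactly 3x median in, above out
  ins <- mk_pairs(identity = 0.95, insert = c(49, 50, 100, 100, 300, 301))
  res <- filter_read_pairs(ins)
  med <- attr(res$log, "median_insert")
  expect_equal(med, 100)
  expect_true(300 %in% res$pairs$insert_size)    # exactly 3x median retained
  expect_false(301 %in% res$pairs$insert_size)
  expect_false(49 %in% res$pairs$insert_size)
  expect_true(50 %in% res$pairs$insert_size)
})

test_that("filter log counts are conserved", {
  p <- mk_pairs(identity = c(0.85, 0.95, 0.95, 0.95, 0.95),
                mapq1 = c(30, 0, 30, 30, 30),
                insert = c(300, 300, 40, 300, 2000))
  res <- filter_read_pairs(p)
  log <- stats::setNames(res$log$count, res$log$filter)
  expect_equal(log[["input"]],
               log[["retained"]] + log[["pair_identity"]] + log[["mapq"]] +
                 log[["insert_min"]] + log[["insert_max"]])
  # all passing: zero removals
  clean <- mk_pairs(identity = rep(0.95, 4), insert = 300)
  res <- filter_read_pairs(clean)
  expect_equal(res$log$count[res$log$filter == "retained"], 4L)
  expect_true(all(res$log$count[2:5] == 0))
  # nothing survives: warning, empty result
  expect_warning(res0 <- filter_read_pairs(mk_pairs(identity = rep(0.5, 3))),
                 "no read pairs")
  expect_equal(nrow(res0$pairs), 0L)
})

test_that("per-site calling follows the consensus, support and frequency rules", {
  # 95/5: an SNV at frequency 0.05
  r <- call_site(c(A = 95, C = 0, G = 5, T = 0))
  expect_equal(r$call, "snv")
  expect_equal(r$snv$consensus_base, "A")
  expect_equal(r$snv$variant_base, "G")
  expect_equal(r$snv$variant_frequency, 0.05)
  # 55/45: variant frequency 0.45 >= 0.40 -> consensus SNV, discarded
  r <- call_site(c(A = 55, C = 0, G = 45, T = 0))
  expect_equal(r$call, "consensus_snv")
  # 60/40: exactly 0.40 is already a consensus SNV (inclusive boundary)
  r <- call_site(c(A = 60, C = 0, G = 40, T = 0))
  expect_equal(r$call, "consensus_snv")
  # 61/39: 0.39 < 0.40 is an SNV
  r <- call_site(c(A = 61, C = 0, G = 39, T = 0))
  expect_equal(r$call, "snv")
  # monomorphic site: nothing
  expect_equal(call_site(c(A = 100, C = 0, G = 0, T = 0))$call, "none")
  # variant support below the minimum: nothing
  expect_equal(call_site(c(A = 99, C = 0, G = 1, T = 0))$call, "none")
  # consensus tie: rejected
  expect_equal(call_site(c(A = 50, C = 0, G = 50, T = 0))$call, "rejected")
  # consensus lacking the top mean mapQ: rejected
  r <- call_site(c(A = 90, C = 0, G = 10, T = 0),
                 mapq_means = c(A = 20, C = NA, G = 35, T = NA))
  expect_equal(r$call, "rejected")
  # equal mean mapQ is acceptable (ties allowed)
  r <- call_site(c(A = 90, C = 0, G = 10, T = 0),
                 mapq_means = c(A = 30, C = NA, G = 30, T = NA))
  expect_equal(r$call, "snv")
})

test_that("the frequency floor suppresses weakly supported variants at depth", {
  # 2/100 = 0.02 < 0.05: suppressed despite 2 supporting reads
  expect_equal(call_site(c(A = 98, C = 2, G = 0, T = 0))$call, "none")
  # same counts with the floor disabled: emitted
  r <- call_site(c(A = 98, C = 2, G = 0, T = 0), min_variant_freq = 0)
  expect_equal(r$call, "snv")
})

test_that("pileup counts every retained mate base exactly once", {
  mag <- new_mag <- structure(list(
    mag_id = "m", clade = NA, depth_interval = NA, abundance_class = NA,
    contigs = c(c1 = paste(rep("A", 400), collapse = "")),
    orfs = data.frame(orf_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)),
    completeness = 1), class = "mag_record")
  pairs <- data.frame(pair_id = "p1", contig = "c1", start1 = 1L, start2 = 3L,
                      insert_size = 6L, mapq1 = 30L, mapq2 = 20L,
                      pair_identity = 1, seq1 = "AAAA", seq2 = "AGAA",
                      stringsAsFactors = FALSE)
  pile <- build_pileup(pairs, mag)
  expect_equal(nrow(pile), 6L)                        # positions 1..6
  expect_equal(sum(pile$depth), 8L)                   # 2 mates x 4 bases
  # overlap at positions 3,4: both mates counted
  expect_equal(pile$depth[pile$pos == 3], 2L)
  expect_equal(pile$n_G[pile$pos == 4], 1L)           # mate2 position 2 is G
  expect_equal(pile$mq_G[pile$pos == 4], 20)
  expect_equal(pile$mq_A[pile$pos == 3], 25)          # mean of 30 and 20
  # depth equals the base-count row sums everywhere
  expect_true(all(pile$depth ==
                    pile$n_A + pile$n_C + pile$n_G + pile$n_T))
  # a read outside the contig is an input error
  bad <- pairs; bad$start2 <- 399L
  expect_error(build_pileup(bad, mag), "outside contig")
  expect_equal(nrow(build_pileup(pairs[0, ], mag)), 0L)
})

test_that("ORF restriction assigns coding-strand positions and keeps totals", {
  orfs <- data.frame(orf_id = c("o1", "o2"), contig = "c1",
                     start = c(101L, 501L), end = c(400L, 800L),
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  snvs <- data.frame(contig = "c1", pos = c(151L, 50L, 650L),
                     consensus_base = "A", variant_base = "G",
                     variant_count = 5L, depth = 50L,
                     variant_frequency = 0.1, stringsAsFactors = FALSE)
  res <- restrict_to_orfs(snvs, orfs)
  expect_equal(unname(res$totals), c(3L, 2L))
  expect_equal(res$snvs$position_in_orf[res$snvs$pos == 151], 51L)
  # reverse strand: counted from the ORF's 3' genome end
  expect_equal(res$snvs$position_in_orf[res$snvs$pos == 650], 151L)
  expect_false(50 %in% res$snvs$pos)
  # no ORFs at all: zero in-ORF, totals preserved
  res0 <- restrict_to_orfs(snvs, orfs[0, ])
  expect_equal(unname(res0$totals), c(3L, 0L))
})

test_that("the collated SNV table round-trips losslessly through TSV", {
  cfg <- tiny_config(seed = 31)
  sc <- simulate_scenario(cfg)
  mag <- sc$mags[["S-30"]]
  tr <- sc$truth$snvs[sc$truth$snvs$mag_id == "S-30", ][1:3, ]
  raw <- data.frame(contig = tr$contig, pos = tr$pos,
                    consensus_base = tr$consensus_base,
                    variant_base = tr$variant_base, variant_count = 5L,
                    depth = 40L, variant_frequency = tr$frequency,
                    stringsAsFactors = FALSE)
  tab <- collate_snv_table(restrict_to_orfs(raw, mag$orfs)$snvs, mag)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("snv_id", "mag_id", "variant_frequency", "position_in_orf",
                    "orf_seq", "protein_seq", "cluster_id", "kegg_ortholog",
                    "kegg_pathways") %in% names(tab)))
  f <- tempfile(fileext = ".tsv")
  write_tsv(tab, f)
  back <- read_tsv(f)
  expect_equal(back, tab)
})

test_that("tightening any threshold never increases retained or emitted counts", {
  cfg <- sim_config(seed = 41, n_contigs = 2, contig_lengths = 10000,
                    coverage = 25, mapq_zero_fraction = 0.1,
                    tract_length_mean = 3000, tract_length_sd = 300)
  sc <- simulate_scenario(cfg)
  mag <- sc$mags[["D-30"]]
  set.seed(41)
  pairs <- simulate_read_pairs(
    mag, sc$truth$snvs[sc$truth$snvs$mag_id == "D-30", ], cfg)
  last <- Inf
  for (thr in c(0.85, 0.90, 0.95, 0.99)) {
    n <- nrow(filter_read_pairs(pairs, min_pair_identity = thr)$pairs)
    expect_lte(n, last); last <- n
  }
  last <- Inf
  for (mq in c(0, 1, 10, 40)) {
    n <- nrow(filter_read_pairs(pairs, min_mapq = mq)$pairs)
    expect_lte(n, last); last <- n
  }
  last <- Inf
  for (mi in c(0, 50, 150, 260)) {
    n <- nrow(filter_read_pairs(pairs, min_insert = mi)$pairs)
    expect_lte(n, last); last <- n
  }
  pile <- build_pileup(filter_read_pairs(pairs)$pairs, mag)
  last <- Inf
  for (mv in c(1, 2, 4, 8)) {
    n <- nrow(call_snvs(pile, min_variant_reads = mv)$snvs)
    expect_lte(n, last); last <- n
  }
  last <- Inf
  for (fr in c(0, 0.05, 0.1, 0.2)) {
    n <- nrow(call_snvs(pile, min_variant_freq = fr)$snvs)
    expect_lte(n, last); last <- n
  }
})
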