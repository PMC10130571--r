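# The synthetic-data generator: determinism, ORF tiling, realized divergence
# (checked by direct positional comparison), polymorphism statistics,
# recombination tract semantics, MGE construction, read-pair sampling.

test_that("ancestor has the requested layout and ORF fraction", {
  cfg <- sim_config(seed = 7, n_contigs = 5, contig_lengths = 20000,
                    orf_fraction = 0.85)
  anc <- simulate_ancestor(cfg)
  expect_equal(length(anc$contigs), 5L)
  expect_equal(unname(nchar(anc$contigs)), rep(20000L, 5))
  orf_bp <- sum(anc$orfs$end - anc$orfs$start + 1L)
  expect_lt(abs(orf_bp / 100000 - 0.85), 0.02)
  # ORFs are in-frame, non-overlapping, within bounds
  expect_true(all((anc$orfs$end - anc$orfs$start + 1L) %% 3L == 0L))
  for (ci in names(anc$contigs)) {
    o <- anc$orfs[anc$orfs$contig == ci, ]
    o <- o[order(o$start), ]
    if (nrow(o) > 1) expect_true(all(o$start[-1] > o$end[-nrow(o)]))
  }
})

test_that("the generator is bit-identical under seed and config", {
  cfg <- tiny_config(seed = 7)
  a1 <- simulate_ancestor(cfg); a2 <- simulate_ancestor(cfg)
  expect_identical(a1$contigs, a2$contigs)
  expect_identical(a1$orfs, a2$orfs)
  f1 <- tempfile(fileext = ".fna"); f2 <- tempfile(fileext = ".fna")
  write_mag_fasta(a1, f1); write_mag_fasta(a2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s1 <- simulate_scenario(cfg); s2 <- simulate_scenario(cfg)
  expect_identical(lapply(s1$mags, `[[`, "contigs"),
                   lapply(s2$mags, `[[`, "contigs"))
  expect_identical(s1$truth, s2$truth)
})

test_that("orf_fraction 0 yields no ORFs and invalid configs are refused", {
  cfg <- sim_config(seed = 1, n_contigs = 1, contig_lengths = 5000,
                    orf_fraction = 0)
  anc <- simulate_ancestor(cfg)
  expect_equal(nrow(anc$orfs), 0L)
  expect_error(sim_config(orf_fraction = 1.5), "orf_fraction")
  expect_error(sim_config(contig_lengths = -5), "positive")
  expect_error(sim_config(snv_freq_range = c(0, 0.5)), "snv_freq_range")
})

test_that("realized divergence matches the configured rates", {
  cfg <- sim_config(seed = 5, n_contigs = 5, contig_lengths = 20000,
                    clade_divergence = 0.16, within_clade_divergence = 1e-4,
                    mges = list(), n_recomb_tracts = 0)
  anc <- simulate_ancestor(cfg)
  div <- diverge_populations(anc, cfg)
  # zero divergence: all genomes identical to the ancestor
  cfg0 <- sim_config(seed = 5, n_contigs = 2, contig_lengths = 10000,
                     clade_divergence = 0, within_clade_divergence = 0)
  anc0 <- simulate_ancestor(cfg0)
  div0 <- diverge_populations(anc0, cfg0)
  for (m in div0$mags) expect_identical(m$contigs, anc0$contigs)
  # 0.16 between clades: positional identity 84.0% +/- 0.5% over 100 kb
  ident <- function(a, b) {
    mean(unlist(Map(function(x, y)
      strsplit(x, "")[[1]] == strsplit(y, "")[[1]], a, b)))
  }
  between <- ident(div$mags[["S-30"]]$contigs, div$mags[["D-30"]]$contigs)
  expect_lt(abs(between - 0.84), 0.005)
  # within-clade Hamming distance ~ Poisson(10) per 100 kb at 1e-4
  d <- sum(unlist(Map(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
    anc$contigs, div$mags[["S-65"]]$contigs)))
  expect_gte(d, qpois(0.005, 10))
  expect_lte(d, qpois(0.995, 10))
})

test_that("polymorphism injection matches rate, range and consensus", {
  cfg <- sim_config(seed = 3, n_contigs = 5, contig_lengths = 20000,
                    snv_rate = 5e-4, snv_freq_range = c(0.05, 0.35))
  anc <- simulate_ancestor(cfg)
  orf_bp <- sum(anc$orfs$end - anc$orfs$start + 1L)
  res <- inject_polymorphisms(anc, cfg)
  lambda <- 5e-4 * orf_bp
  expect_gte(nrow(res$truth), qpois(0.005, lambda))
  expect_lte(nrow(res$truth), qpois(0.995, lambda))
  expect_true(all(res$truth$frequency >= 0.05 & res$truth$frequency <= 0.35))
  expect_true(all(res$truth$frequency < 0.40))
  expect_true(all(res$truth$variant_base != res$truth$consensus_base))
  # consensus bases genuinely match the genome
  for (i in sample(nrow(res$truth), 20)) {
    r <- res$truth[i, ]
    expect_equal(substr(anc$contigs[[r$contig]], r$pos, r$pos),
                 r$consensus_base)
  }
  # zero rate: nothing injected
  cfg0 <- sim_config(seed = 3, snv_rate = 0)
  expect_equal(nrow(inject_polymorphisms(anc, cfg0)$truth), 0L)
})

test_that("recombination copies donor sequence and donor polymorphisms", {
  cfg <- small_config(seed = 13, n_recomb_tracts = 1L, mges = list())
  anc <- simulate_ancestor(cfg)
  div <- diverge_populations(anc, cfg)
  donor <- div$mags[["D-65"]]; recip <- div$mags[["S-132"]]
  set.seed(101)
  dtruth <- inject_polymorphisms(donor, cfg)$truth
  dtruth$mag_id <- donor$mag_id
  before <- recip$contigs
  res <- inject_recombination(donor, recip, cfg, donor_truth = dtruth)
  tr <- res$tracts
  expect_equal(nrow(tr), 1L)
  # tract region is byte-identical to the donor
  expect_identical(
    substr(res$recipient$contigs[[tr$contig]], tr$start, tr$end),
    substr(donor$contigs[[tr$contig]], tr$start, tr$end))
  # donor polymorphisms inside the tract appear in recipient truth verbatim
  inside <- dtruth[dtruth$contig == tr$contig & dtruth$pos >= tr$start &
                     dtruth$pos <= tr$end, ]
  expect_equal(nrow(res$truth), nrow(inside))
  if (nrow(inside)) {
    got <- res$truth[order(res$truth$pos),
                     c("contig", "pos", "consensus_base", "variant_base")]
    want <- inside[order(inside$pos),
                   c("contig", "pos", "consensus_base", "variant_base")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
  # zero tracts leaves the recipient untouched
  cfg0 <- small_config(seed = 13, n_recomb_tracts = 0L)
  res0 <- inject_recombination(donor, recip, cfg0, donor_truth = dtruth)
  expect_identical(res0$recipient$contigs, before)
})

test_that("MGE construction honors repeats, truncation and identity", {
  set.seed(8)
  el <- make_mge_sequence(1000, 20)
  expect_equal(nchar(el), 1000L)
  expect_equal(substr(el, 981, 1000), revcomp(substr(el, 1, 20)))
  # identical element inserted into two MAGs extracts at identity 1.00
  cfg <- tiny_config(seed = 21, mges = list(
    list(name = "ISx", mode = "transfer", length = 800L, repeat_length = 20L,
         targets = c("S-30", "D-30"))))
  sc <- simulate_scenario(cfg)
  recs <- extract_mge_sequences(sc$mags, sc$truth$mges)
  iss <- recs[recs$mge_name == "ISx", ]
  expect_equal(nrow(iss), 2L)
  expect_identical(iss$sequence[1], iss$sequence[2])
  expect_equal(global_identity(iss$sequence[1], iss$sequence[2]), 1)
  # truncation keeps the configured prefix fraction
  cfg2 <- tiny_config(seed = 22, mges = list(
    list(name = "ISt", mode = "transfer", length = 1000L, repeat_length = 20L,
         targets = c("S-30", "D-30"), truncate = c(`D-30` = 0.6))))
  sc2 <- simulate_scenario(cfg2)
  tr <- sc2$truth$mges
  expect_equal(nchar(tr$sequence[tr$mag_id == "D-30"]), 600L)
  expect_equal(nchar(tr$sequence[tr$mag_id == "S-30"]), 1000L)
})

test_that("read pairs hit the configured depth and clean reads match reference", {
  cfg <- sim_config(seed = 17, n_contigs = 2, contig_lengths = 15000,
                    coverage = 50, error_rate = 0)
  anc <- simulate_ancestor(cfg)
  set.seed(17)
  pairs <- simulate_read_pairs(anc, empty_truth <- data.frame(
    mag_id = character(0), contig = character(0), pos = integer(0),
    consensus_base = character(0), variant_base = character(0),
    frequency = numeric(0)), cfg)
  # no errors, no polymorphisms: perfect identity
  expect_true(all(pairs$pair_identity == 1))
  # realized mean depth within 50 +/- 3
  depth_bp <- 2 * cfg$read_length * nrow(pairs)
  expect_lt(abs(depth_bp / sum(nchar(anc$contigs)) - 50), 3)
  pile <- build_pileup(pairs, anc)
  expect_lt(abs(mean(pile$depth) - 50), 3)
  # coverage zero: no pairs
  cfg0 <- sim_config(seed = 17, n_contigs = 2, contig_lengths = 15000,
                     coverage = 0)
  expect_equal(nrow(simulate_read_pairs(anc, empty_truth, cfg0)), 0L)
  # read longer than the shortest contig is refused
  cfgbad <- sim_config(seed = 17, n_contigs = 1, contig_lengths = 15000,
                       read_length = 200L, insert_median = 420)
  short <- anc; short$contigs <- c(c1 = substr(anc$contigs[[1]], 1, 150))
  short$orfs <- anc$orfs[0, ]
  expect_error(simulate_read_pairs(short, empty_truth, cfgbad), "shortest")
})

test_that("variant read counts follow the truth frequencies binomially", {
  cfg <- sim_config(seed = 23, n_contigs = 2, contig_lengths = 15000,
                    coverage = 50, error_rate = 0, snv_rate = 2e-3)
  anc <- simulate_ancestor(cfg)
  set.seed(23)
  truth <- inject_polymorphisms(anc, cfg)$truth
  pairs <- simulate_read_pairs(anc, truth, cfg)
  pile <- build_pileup(pairs, anc)
  key <- paste(pile$contig, pile$pos)
  ok <- 0L; n <- 0L
  for (i in seq_len(nrow(truth))) {
    row <- pile[key == paste(truth$contig[i], truth$pos[i]), ]
    if (nrow(row) != 1 || row$depth < 10) next
    vc <- row[[paste0("n_", truth$variant_base[i])]]
    band <- qbinom(c(0.0005, 0.9995), row$depth, truth$frequency[i])
    n <- n + 1L
    if (vc >= band[1] && vc <= band[2]) ok <- ok + 1L
  }
  expect_gt(n, 30)
  expect_gte(ok / n, 0.99)
})
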