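# Hierarchical shared-SNV identification, group summaries, ancestral flags
# and group t-tests (checked against the closed-form pooled-variance t).

# build a toy world: one homologous ORF (identical across MAGs) plus per-MAG
# SNV position lists
toy_world <- function(snv_spec, orf_len = 300) {
  set.seed(61)
  orf <- paste(sample(c("A", "C", "G", "T"), orf_len, TRUE), collapse = "")
  mags <- names(snv_spec)
  clusters <- data.frame(
    cluster_id = "PC00001", mag_id = mags, orf_id = "o1",
    identity = 1, is_representative = seq_along(mags) == 1L,
    stringsAsFactors = FALSE)
  orf_seqs <- stats::setNames(rep(orf, length(mags)), paste0(mags, "|o1"))
  snvs <- do.call(rbind, lapply(mags, function(m) {
    s <- snv_spec[[m]]
    if (length(s$pos) == 0) return(NULL)
    data.frame(mag_id = m, contig = "c1", pos = s$pos + 1000L,
               consensus_base = s$cons, variant_base = s$var,
               orf_id = "o1", position_in_orf = s$pos,
               cluster_id = "PC00001", stringsAsFactors = FALSE)
  }))
  list(snvs = snvs, clusters = clusters, orf_seqs = orf_seqs)
}

test_that("pair sharing distinguishes same-site from same-substitution", {
  w <- toy_world(list(
    X = list(pos = 120L, cons = "A", var = "G"),
    Y = list(pos = 120L, cons = "A", var = "G")))
  sh <- find_shared_snvs(w$snvs, w$clusters, w$orf_seqs)
  expect_equal(nrow(sh$sites), 1L)
  expect_equal(sh$sites$level, "same_substitution")
  expect_equal(sh$sites$n_mags, 2L)
  w2 <- toy_world(list(
    X = list(pos = 120L, cons = "A", var = "G"),
    Y = list(pos = 120L, cons = "A", var = "T")))
  sh2 <- find_shared_snvs(w2$snvs, w2$clusters, w2$orf_seqs)
  expect_equal(sh2$sites$level, "same_site")
})

test_that("shared counts match a brute-force position intersection", {
  xpos <- c(10L, 50L, 120L, 200L, 250L)
  ypos <- c(33L, 44L, 55L, 120L, 200L)
  xv <- c("G", "G", "G", "G", "G"); yv <- c("G", "G", "G", "G", "T")
  w <- toy_world(list(
    X = list(pos = xpos, cons = "A", var = xv),
    Y = list(pos = ypos, cons = "A", var = yv)))
  sh <- find_shared_snvs(w$snvs, w$clusters, w$orf_seqs)
  g <- summarize_groups(sh, c("X", "Y"), triplets = list())
  # oracle: exhaustive intersection of the position lists
  both <- intersect(xpos, ypos)
  same_sub <- sum(vapply(both, function(p)
    xv[match(p, xpos)] == yv[match(p, ypos)], logical(1)))
  expect_equal(g$n_same_site, length(both))          # 2
  expect_equal(g$n_same_substitution, same_sub)      # 1
  expect_true(all(g$n_same_substitution <= g$n_same_site))
})

test_that("triplets require all three members at the site", {
  w <- toy_world(list(
    X = list(pos = c(10L, 90L), cons = "A", var = "G"),
    Y = list(pos = c(10L, 90L), cons = "A", var = "G"),
    Z = list(pos = 10L, cons = "A", var = "G")))
  sh <- find_shared_snvs(w$snvs, w$clusters, w$orf_seqs)
  g <- summarize_groups(sh, c("X", "Y", "Z"),
                        triplets = list(xyz = c("X", "Y", "Z")))
  trip <- g[g$kind == "triplet", ]
  expect_equal(trip$n_same_site, 1L)        # site 90 is only in X and Y
  expect_equal(trip$n_same_substitution, 1L)
  pair_xy <- g[g$mag_set == "X,Y", ]
  expect_equal(pair_xy$n_same_site, 2L)
})

test_that("group summaries are symmetric and zero without shared records", {
  w <- toy_world(list(
    X = list(pos = 10L, cons = "A", var = "G"),
    Y = list(pos = 200L, cons = "A", var = "G")))
  sh <- find_shared_snvs(w$snvs, w$clusters, w$orf_seqs)
  expect_equal(nrow(sh$sites), 0L)
  g <- summarize_groups(sh, c("X", "Y"), triplets = list())
  expect_equal(g$n_same_site, 0L)
  # symmetry: MAG order does not matter
  w2 <- toy_world(list(
    X = list(pos = c(10L, 20L), cons = "A", var = "G"),
    Y = list(pos = c(10L, 20L), cons = "A", var = "G")))
  sh2 <- find_shared_snvs(w2$snvs, w2$clusters, w2$orf_seqs)
  g_xy <- summarize_groups(sh2, c("X", "Y"), triplets = list())
  g_yx <- summarize_groups(sh2, c("Y", "X"), triplets = list())
  expect_equal(g_xy, g_yx)
})

test_that("six-way shared sites are flagged ancestral", {
  mags <- paste0("M", 1:6)
  spec <- stats::setNames(rep(list(list(pos = 42L, cons = "C", var = "T")),
                              6), mags)
  w <- toy_world(spec)
  sh <- find_shared_snvs(w$snvs, w$clusters, w$orf_seqs)
  anc <- flag_ancestral(sh, n_mags_total = 6L)
  expect_equal(nrow(anc), 1L)
  expect_true(anc$ancestral)
  # five of six is not ancestral
  spec5 <- spec; spec5$M6 <- list(pos = integer(0), cons = character(0),
                                  var = character(0))
  w5 <- toy_world(spec5)
  sh5 <- find_shared_snvs(w5$snvs, w5$clusters, w5$orf_seqs)
  expect_equal(nrow(flag_ancestral(sh5, 6L)), 0L)
  empty <- list(sites = sh$sites[0, ], participants = sh$participants[0, ])
  expect_equal(nrow(flag_ancestral(empty, 6L)), 0L)
})

test_that("group t-tests agree with the closed-form pooled t to 1e-10", {
  mk_stats <- function(vals) {
    data.frame(mag_id = paste0("M", 1:6),
               clade = c("S", "S", "S", "D", "D", "D"),
               depth_interval = rep(c("0-30", "41-65", "108-132"), 2),
               abundance_class = c("abundant", "rare", "rare",
                                   "rare", "abundant", "abundant"),
               total_snvs = vals, snvs_in_orfs = vals,
               orfs_with_snv = vals, mean_snvs_per_orf = vals / 100,
               stringsAsFactors = FALSE)
  }
  set.seed(71)
  vals <- rnorm(6, 100, 20)
  res <- compare_group_counts(mk_stats(vals))
  row <- res[res$grouping == "clade" & res$metric == "total_snvs", ]
  x <- vals[1:3]; y <- vals[4:6]
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(row$t, t_oracle, tolerance = 1e-10)
  expect_equal(row$p_value, p_oracle, tolerance = 1e-10)
  # identical constant groups: t = 0, p = 1
  res0 <- compare_group_counts(mk_stats(rep(5, 6)))
  row0 <- res0[res0$grouping == "clade" & res0$metric == "total_snvs", ]
  expect_equal(row0$t, 0)
  expect_equal(row0$p_value, 1)
  # extreme separation: tiny p
  sep <- mk_stats(c(1, 1, 1, 100, 100, 100) + rnorm(6, 0, 0.1))
  rs <- compare_group_counts(sep)
  expect_lt(rs$p_value[rs$grouping == "clade" &
                         rs$metric == "total_snvs"], 0.001)
  # Welch option changes the degrees of freedom
  rw <- compare_group_counts(mk_stats(vals), welch = TRUE)
  expect_false(isTRUE(all.equal(
    rw$df[rw$grouping == "clade" & rw$metric == "total_snvs"], 4)))
})
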