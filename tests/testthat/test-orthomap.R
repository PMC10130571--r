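# Greedy protein clustering and nucleotide site maps. The clustering oracle
# is an independent all-vs-all alignment done directly with Biostrings in the
# test, not through the package's clustering path.

test_that("identical and dissimilar proteins cluster as expected", {
  set.seed(51)
  a <- random_protein(120)
  c50 <- mutate_protein(a, 60)  # ~50% identity to a
  prot <- c("X|o1" = a, "Y|o1" = a, "X|o2" = c50)
  cl <- cluster_proteins(prot)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  ab <- cl$cluster_id[cl$orf_id == "o1"]
  expect_equal(ab[1], ab[2])                   # the identical pair co-clusters
  expect_true(all(cl$identity[cl$orf_id == "o1"] == 1))
  expect_error(cluster_proteins(c("X|o1" = "")), "empty")
  expect_error(cluster_proteins(c(a, c50)), "mag_id")
})

test_that("every member matches its representative at threshold, per an
           independent all-vs-all oracle", {
  set.seed(52)
  fams <- lapply(1:6, function(i) random_protein(sample(80:200, 1)))
  prot <- character(0)
  for (i in seq_along(fams)) {
    n <- nchar(fams[[i]])
    for (j in 1:4) {  # members at ~97% identity
      prot[sprintf("M%d|f%d_m%d", j, i, j)] <-
        mutate_protein(fams[[i]], max(1, round(0.03 * n)))
    }
  }
  for (j in 1:6) prot[sprintf("M9|r%d", j)] <- random_protein(100)
  cl <- cluster_proteins(prot, identity_threshold = 0.90)
  # independent oracle: global alignment identity via Biostrings, directly
  oracle_identity <- function(x, y) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y), type = "global",
      substitutionMatrix = local({
        l <- c(Biostrings::AA_STANDARD, "U", "O", "B", "J", "Z", "X", "*")
        m <- matrix(-1, length(l), length(l), dimnames = list(l, l))
        diag(m) <- 2; m
      }), gapOpening = 10, gapExtension = 0.5)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    sum(p == s & p != "-") / length(p)
  }
  key <- paste0(cl$mag_id, "|", cl$orf_id)
  for (cid in unique(cl$cluster_id)) {
    rows <- cl[cl$cluster_id == cid, ]
    rep_seq <- prot[[paste0(rows$mag_id[rows$is_representative], "|",
                            rows$orf_id[rows$is_representative])]]
    for (r in which(!rows$is_representative)) {
      id <- oracle_identity(prot[[paste0(rows$mag_id[r], "|", rows$orf_id[r])]],
                            rep_seq)
      expect_gte(id, 0.90)
      expect_equal(id, rows$identity[r], tolerance = 1e-9)
    }
  }
  # family members co-cluster; unrelated proteins are singletons
  for (i in 1:6) {
    fam_rows <- cl$cluster_id[grepl(sprintf("^f%d_", i), cl$orf_id)]
    expect_equal(length(unique(fam_rows)), 1L)
  }
  singles <- cl$cluster_id[grepl("^r", cl$orf_id)]
  expect_equal(anyDuplicated(singles), 0L)
  # the k-mer prefilter changes nothing
  cl_slow <- cluster_proteins(prot, prefilter = FALSE)
  expect_equal(cl, cl_slow)
})

test_that("clustering is invariant to input permutation", {
  set.seed(53)
  base <- random_protein(150)
  prot <- c("A|x" = base, "B|x" = mutate_protein(base, 5),
            "C|x" = mutate_protein(base, 8), "A|y" = random_protein(90),
            "B|y" = random_protein(90))
  cl1 <- cluster_proteins(prot)
  cl2 <- cluster_proteins(prot[sample(length(prot))])
  expect_equal(cl1, cl2)
})

test_that("site maps are identity for indel-free pairs and shift across indels", {
  set.seed(54)
  a <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  expect_equal(map_site_pair(a, a),
               data.frame(pos_a = 1:600, pos_b = 1:600))
  # one substitution: still the identity map
  b <- a; substr(b, 250, 250) <- setdiff(c("A", "C", "G", "T"),
                                         substr(a, 250, 250))[1]
  expect_equal(map_site_pair(a, b),
               data.frame(pos_a = 1:600, pos_b = 1:600))
  # a 3-bp insertion at position 300 of b shifts the downstream mapping
  ins <- paste0(substr(a, 1, 299), "GCA", substr(a, 300, 600))
  m <- map_site_pair(a, ins)
  expect_equal(m$pos_b[m$pos_a == 100], 100)
  expect_equal(m$pos_b[m$pos_a == 299], 299)
  expect_equal(m$pos_b[m$pos_a == 300], 303)
  expect_equal(m$pos_b[m$pos_a == 600], 603)
  # strictly increasing in both coordinates
  expect_true(all(diff(m$pos_a) > 0))
  expect_true(all(diff(m$pos_b) > 0))
})

test_that("site maps compose consistently on indel-free clusters", {
  set.seed(55)
  a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), n)
    ch[i] <- vapply(ch[i], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(ch, collapse = "")
  }
  b <- mut(a, 10); c <- mut(a, 12)
  mab <- map_site_pair(a, b); mbc <- map_site_pair(b, c)
  mac <- map_site_pair(a, c)
  composed <- mbc$pos_b[match(mab$pos_b, mbc$pos_a)]
  expect_equal(composed, mac$pos_b)
  # map_sites covers every unordered pair and errors on missing members
  maps <- map_sites(c("A|x", "B|x", "C|x"),
                    c("A|x" = a, "B|x" = b, "C|x" = c))
  expect_equal(sort(names(maps)), c("A|x~B|x", "A|x~C|x", "B|x~C|x"))
  expect_error(map_sites(c("A|x", "D|x"), c("A|x" = a)), "D\\|x")
})
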