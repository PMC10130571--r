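# Fragment-based contig-pair average nucleotide identity. The query contig is
# cut into non-overlapping fragments; each fragment is anchored onto the
# subject by a shared-k-mer offset vote and scored against its best window;
# fragments below the identity floor are unmapped; ANI is the mean identity
# of mapped fragments. Values below the floor are unreliable and reported as
# undefined, so the measure is comparative rather than absolute.

subject_kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# identity of a fragment against the subject window starting at `off + 1`;
# positions falling outside the subject count as mismatches (terminal gaps)
window_identity <- function(frag, subject, start) {
  L <- nchar(frag); n <- nchar(subject)
  a <- max(1L, start); b <- min(n, start + L - 1L)
  if (b < a) return(0)
  w <- substr(subject, a, b)
  fa <- 1L + (a - start); fb <- fa + (b - a)
  f <- substr(frag, fa, fb)
  sum(strsplit(f, "", fixed = TRUE)[[1]] ==
        strsplit(w, "", fixed = TRUE)[[1]]) / L
}

#' Fragment-based ANI between two contigs
#'
#' The query is cut into non-overlapping `fragment_length` windows (a contig
#' shorter than one fragment is used whole). Each fragment's placement on the
#' subject is the modal offset of its shared k-mers (fragments with fewer
#' than 3 k-mer anchors are unmapped); its identity is computed over the
#' anchored equal-length window. With `method = "align"` the fragment is
#' instead globally aligned to a padded window (identical on indel-free
#' sequences, much slower). Fragments below `min_identity` are unmapped; ANI
#' is the mean identity of mapped fragments x 100, or NA (undefined) when no
#' fragment maps - pairs below the floor cannot be aligned reliably.
#'
#' @param query,subject contig sequences (character strings).
#' @param fragment_length fragment size in bp (default 3000).
#' @param min_identity per-fragment identity floor (default 0.80).
#' @param method "anchored" (default) or "align".
#' @param k anchor k-mer size (default 16).
#' @return list with `ani` (percent, or NA), `alignable_fraction`,
#'   `n_fragments`, `n_mapped`.
#' @export
contig_pair_ani <- function(query, subject, fragment_length = 3000L,
                            min_identity = 0.80,
                            method = c("anchored", "align"), k = 16L) {
  method <- match.arg(method)
  if (nchar(query) == 0 || nchar(subject) == 0) stop("empty sequence")
  nq <- nchar(query)
  starts <- seq.int(1L, max(1L, nq - fragment_length + 1L), by = fragment_length)
  ends <- pmin(starts + fragment_length - 1L, nq)
  # drop a trailing sliver shorter than half a fragment (unless it is all we have)
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1L) <
        fragment_length %/% 2L) {
    starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
  }
  sk <- subject_kmer_index(subject, k)
  idents <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    frag <- substr(query, starts[i], ends[i])
    fk <- subject_kmer_index(frag, k)
    hit <- match(fk, sk)
    anchored <- which(!is.na(hit))
    if (length(anchored) < 3L) next
    offs <- hit[anchored] - anchored  # subject start of the window, minus 1
    off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
    if (method == "anchored") {
      idents[i] <- window_identity(frag, subject, off + 1L)
    } else {
      pad <- 20L
      a <- max(1L, off + 1L - pad)
      b <- min(nchar(subject), off + nchar(frag) + pad)
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(frag),
        subject = Biostrings::DNAString(substr(subject, a, b)),
        type = "overlap", substitutionMatrix = nt_submat(),
        gapOpening = 10, gapExtension = 0.5)
      idents[i] <- Biostrings::nmatch(aln) / nchar(frag)
    }
  }
  mapped <- which(!is.na(idents) & idents >= min_identity)
  list(ani = if (length(mapped)) 100 * mean(idents[mapped]) else NA_real_,
       alignable_fraction = length(mapped) / length(starts),
       n_fragments = length(starts), n_mapped = length(mapped))
}

#' All contig-pair ANIs between two MAGs
#'
#' Computes [contig_pair_ani()] in both directions for every contig pair and
#' reports the mean of the two directional values (NA if both undefined).
#'
#' @param mag_a,mag_b `mag_record`s.
#' @param ... passed to [contig_pair_ani()].
#' @return data.frame: mag_a, contig_a, mag_b, contig_b, ani,
#'   alignable_fraction, length_a, length_b.
#' @export
mag_pair_ani <- function(mag_a, mag_b, ...) {
  rows <- list()
  for (ca in names(mag_a$contigs)) {
    for (cb in names(mag_b$contigs)) {
      f <- contig_pair_ani(mag_a$contigs[[ca]], mag_b$contigs[[cb]], ...)
      r <- contig_pair_ani(mag_b$contigs[[cb]], mag_a$contigs[[ca]], ...)
      anis <- c(f$ani, r$ani)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_a = mag_a$mag_id, contig_a = ca, mag_b = mag_b$mag_id,
        contig_b = cb,
        ani = if (all(is.na(anis))) NA_real_ else mean(anis, na.rm = TRUE),
        alignable_fraction = mean(c(f$alignable_fraction,
                                    r$alignable_fraction)),
        length_a = nchar(mag_a$contigs[[ca]]),
        length_b = nchar(mag_b$contigs[[cb]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Flag contig pairs that carry a shared SNV
#'
#' A contig pair (one contig from each MAG of the pair) is flagged when at
#' least one shared SNV site has its two participating SNVs on those contigs.
#'
#' @param participants participant table from [find_shared_snvs()] (carries
#'   each participating SNV's contig).
#' @param mag_a,mag_b the MAG pair ids.
#' @return data.frame with contig_a, contig_b (unique flagged pairs).
#' @export
label_shared_contigs <- function(participants, mag_a, mag_b) {
  p <- participants
  pa <- p[p$mag_id == mag_a, c("cluster_id", "site", "contig")]
  pb <- p[p$mag_id == mag_b, c("cluster_id", "site", "contig")]
  m <- merge(pa, pb, by = c("cluster_id", "site"),
             suffixes = c("_a", "_b"))
  unique(m[!is.na(m$contig_a) & !is.na(m$contig_b),
           c("contig_a", "contig_b"), drop = FALSE])
}

#' Compare ANI between shared-SNV and non-shared contig pairs
#'
#' Group means are computed over defined ANI values only; two-tailed t-tests
#' compare contig length and (when supplied) coverage between the groups to
#' check for confounding. Groups with no defined values are reported absent.
#'
#' @param contig_ani data.frame from [mag_pair_ani()] with a logical
#'   `has_shared_snv` column (see [label_shared_contigs()]).
#' @param coverage optional data.frame (contig, mean_coverage) per MAG side,
#'   with columns coverage_a and coverage_b already joined onto `contig_ani`.
#' @param welch use Welch's t-test (default FALSE, Student).
#' @return list with `means` (group, n_pairs, n_defined, mean_ani) and
#'   `confound_tests` (metric, t, df, p_value).
#' @export
compare_ani_groups <- function(contig_ani, welch = FALSE) {
  stopifnot("has_shared_snv" %in% names(contig_ani))
  grp <- split(contig_ani, contig_ani$has_shared_snv)
  means <- do.call(rbind, lapply(names(grp), function(g) {
    x <- grp[[g]]
    def <- x$ani[!is.na(x$ani)]
    data.frame(group = if (g == "TRUE") "shared_snv" else "no_shared_snv",
               n_pairs = nrow(x), n_defined = length(def),
               mean_ani = if (length(def)) mean(def) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- list()
  for (metric in intersect(c("length_a", "length_b", "coverage_a",
                             "coverage_b"), names(contig_ani))) {
    x <- contig_ani[[metric]][contig_ani$has_shared_snv]
    y <- contig_ani[[metric]][!contig_ani$has_shared_snv]
    if (length(x) >= 2 && length(y) >= 2 && (stats::sd(x) > 0 ||
                                             stats::sd(y) > 0)) {
      ht <- stats::t.test(x, y, var.equal = !welch)
      tests[[metric]] <- data.frame(metric = metric,
                                    t = unname(ht$statistic),
                                    df = unname(ht$parameter),
                                    p_value = ht$p.value,
                                    stringsAsFactors = FALSE)
    } else if (length(x) >= 2 && length(y) >= 2) {
      tests[[metric]] <- data.frame(metric = metric, t = 0,
                                    df = length(x) + length(y) - 2,
                                    p_value = 1, stringsAsFactors = FALSE)
    }
  }
  list(means = means,
       confound_tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
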