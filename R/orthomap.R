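# Cross-MAG protein clustering and homologous-site maps. Clustering is greedy
# incremental, longest-first (ties broken lexicographically by id), in the
# style of classic greedy sequence clusterers: a sequence joins the first
# cluster whose representative it matches at or above the identity threshold,
# else founds a new cluster. Identity is global: matches divided by alignment
# length, gap columns included in the denominator.

aa_submat <- function(match = 2, mismatch = -1) {
  letters <- c(Biostrings::AA_STANDARD, "U", "O", "B", "J", "Z", "X", "*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

nt_submat <- function(match = 2, mismatch = -1) {
  letters <- c(BASES, "N")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

aligned_identity <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)
  vapply(seq_along(p), function(i) {
    sum(p[[i]] == s[[i]] & p[[i]] != "-") / length(p[[i]])
  }, numeric(1))
}

#' Global alignment identity between two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment; identity is the number of
#' identical aligned columns divided by the full alignment length, so gap
#' columns (including terminal gaps from length differences) count against
#' identity. This makes a 60% truncation of an element score ~0.60 against the
#' full-length copy.
#'
#' @param a,b sequences (character strings).
#' @param type "aa" or "nt".
#' @return identity in `[0, 1]`.
#' @export
global_identity <- function(a, b, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (identical(a, b)) return(1)
  aln <- global_align(a, b, type)
  aligned_identity(aln)
}

global_align <- function(a, b, type = c("nt", "aa")) {
  type <- match.arg(type)
  mat <- if (type == "aa") aa_submat() else nt_submat()
  Biostrings::pairwiseAlignment(
    pattern = if (type == "aa") Biostrings::AAString(a) else Biostrings::DNAString(a),
    subject = if (type == "aa") Biostrings::AAString(b) else Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
}

# unique k-mers of a protein sequence, as a character vector
seq_kmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Greedy incremental protein clustering across MAGs
#'
#' Sequences are sorted by length descending (ties: lexicographic by
#' `mag_id|orf_id`), then each joins the first existing cluster whose
#' representative it matches at `identity_threshold` or better (global
#' identity, gaps in denominator), else founds a new cluster. Because sorting
#' is canonical, permuting the input yields identical clusters.
#'
#' Two cheap, lossless-in-practice screens run before alignment: an exact
#' length-ratio bound (global identity cannot exceed shorter/longer length)
#' and a k-mer word screen in the style of greedy clustering tools (a
#' candidate is aligned only if it shares at least half of the shorter
#' sequence's k-mers with the representative, a condition implied by
#' identity >= 0.9 with margin to spare). An exact-duplicate hash joins
#' identical sequences without alignment.
#'
#' @param proteins named `AAStringSet` (or named character vector); names must
#'   be `"<mag_id>|<orf_id>"`.
#' @param identity_threshold minimum global identity to the representative
#'   (default 0.90).
#' @param prefilter logical; disable to force full alignment against every
#'   candidate representative (used by the oracle tests).
#' @return data.frame with cluster_id, mag_id, orf_id, identity (to the
#'   representative), is_representative.
#' @export
cluster_proteins <- function(proteins, identity_threshold = 0.90,
                             prefilter = TRUE) {
  seqs <- stats::setNames(as.character(proteins), names(proteins))
  if (length(seqs) == 0) stop("no protein sequences supplied")
  if (any(nchar(seqs) == 0)) stop("empty protein sequence in input")
  ids <- names(seqs)
  if (is.null(ids) || any(!grepl("|", ids, fixed = TRUE)))
    stop("protein names must be '<mag_id>|<orf_id>'")
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  k <- 4L
  reps <- character(0)         # representative sequences, in cluster order
  rep_kmers <- list()
  rep_hash <- new.env(hash = TRUE, parent = emptyenv())
  assign_cluster <- integer(length(seqs))
  identity <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    hit <- mget(s, envir = rep_hash, ifnotfound = list(NA_integer_))[[1]]
    if (!is.na(hit)) { assign_cluster[i] <- hit; identity[i] <- 1; next }
    cand <- seq_along(reps)
    if (prefilter && length(cand)) {
      ls <- nchar(s)
      cand <- cand[ls / nchar(reps[cand]) >= identity_threshold]
      if (length(cand)) {
        km <- seq_kmers(s, k)
        need <- 0.5 * length(km)
        shared <- vapply(cand, function(j) sum(km %in% rep_kmers[[j]]),
                         numeric(1))
        cand <- cand[shared >= need]
      }
    }
    placed <- FALSE
    sch <- NULL
    for (j in cand) {     # candidates in cluster order: first qualifying wins
      r <- reps[j]
      id <- -1
      if (nchar(r) == nchar(s)) {
        # equal-length fast path: positional identity at or above the
        # threshold cannot be improved upon by gapped alignment at these gap
        # penalties; below the threshold fall through to the full alignment
        if (is.null(sch)) sch <- strsplit(s, "", fixed = TRUE)[[1]]
        id <- mean(strsplit(r, "", fixed = TRUE)[[1]] == sch)
      }
      if (id < identity_threshold) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::AAString(r), subject = Biostrings::AAString(s),
          type = "global", substitutionMatrix = aa_submat(),
          gapOpening = 10, gapExtension = 0.5)
        id <- aligned_identity(aln)
      }
      if (id >= identity_threshold) {
        assign_cluster[i] <- j; identity[i] <- id
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      rep_kmers[[length(reps)]] <- seq_kmers(s, k)
      assign(s, length(reps), envir = rep_hash)
      assign_cluster[i] <- length(reps)
      identity[i] <- 1
    }
  }
  parts <- strsplit(ids, "|", fixed = TRUE)
  out <- data.frame(
    cluster_id = sprintf("PC%05d", assign_cluster),
    mag_id = vapply(parts, `[`, character(1), 1L),
    orf_id = vapply(parts, `[`, character(1), 2L),
    identity = identity,
    is_representative = !duplicated(assign_cluster) & identity == 1,
    stringsAsFactors = FALSE)
  # the representative is the founding member (first row of each cluster)
  out$is_representative <- !duplicated(out$cluster_id)
  out[order(out$cluster_id, -out$is_representative, out$mag_id, out$orf_id), ,
      drop = FALSE]
}

#' Map homologous nucleotide positions between two ORFs
#'
#' Global alignment of the coding-strand nucleotide sequences; matched
#' (non-gap/non-gap) columns define the 1-based coordinate correspondence.
#' Identical-length sequences with at least 50% positional identity take the
#' identity-mapping fast path (no compensating-indel pair at that similarity
#' survives a global alignment anyway).
#'
#' @param a,b nucleotide ORF sequences (character strings).
#' @return data.frame with columns pos_a, pos_b, strictly increasing in both.
#' @export
map_site_pair <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == nb) {
    if (identical(a, b))
      return(data.frame(pos_a = seq_len(na), pos_b = seq_len(na)))
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    if (mean(ca == cb) >= 0.5)
      return(data.frame(pos_a = seq_len(na), pos_b = seq_len(na)))
  }
  aln <- global_align(a, b, "nt")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "",
                 fixed = TRUE)[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "",
                 fixed = TRUE)[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  data.frame(pos_a = ia[keep], pos_b = ib[keep])
}

#' Pairwise site maps within a protein cluster
#'
#' @param members character vector of member keys (`"<mag_id>|<orf_id>"`).
#' @param orf_seqs named character vector (or `DNAStringSet`) of coding-strand
#'   nucleotide sequences keyed the same way; every member must be present.
#' @return named list of [map_site_pair()] data.frames, one per unordered
#'   member pair, named `"<a>~<b>"` with a < b in sort order.
#' @export
map_sites <- function(members, orf_seqs) {
  orf_seqs <- stats::setNames(as.character(orf_seqs), names(orf_seqs))
  missing <- setdiff(members, names(orf_seqs))
  if (length(missing))
    stop("no ORF sequence for cluster member(s): ",
         paste(missing, collapse = ", "))
  members <- sort(members)
  out <- list()
  if (length(members) < 2) return(out)
  for (i in seq_len(length(members) - 1L)) {
    for (j in seq.int(i + 1L, length(members))) {
      out[[paste0(members[i], "~", members[j])]] <-
        map_site_pair(orf_seqs[[members[i]]], orf_seqs[[members[j]]])
    }
  }
  out
}

# project positions from one member onto another through a site-map table;
# returns NA where the position falls in a gap column
project_positions <- function(map, pos, from = c("a", "b")) {
  from <- match.arg(from)
  if (from == "a") map$pos_b[match(pos, map$pos_a)]
  else map$pos_a[match(pos, map$pos_b)]
}
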