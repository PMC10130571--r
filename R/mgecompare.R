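# Pairwise percent-identity matrices for named mobile genetic element
# homologs across MAGs, and a congruence call against the clade structure.
# End-to-end (global) alignment identity is used so truncated homologs score
# roughly their retained fraction against full-length copies.

#' Extract MGE sequences from MAG contigs
#'
#' Slices each annotated element from its contig; when an annotation row
#' already carries a `sequence` it is checked against the slice.
#'
#' @param mags named list of `mag_record`s.
#' @param annotations data.frame: mag_id, mge_name, contig, start, end,
#'   optionally kind, truncated, sequence.
#' @return the annotation table with a verified `sequence` column.
#' @export
extract_mge_sequences <- function(mags, annotations) {
  a <- annotations
  seqs <- vapply(seq_len(nrow(a)), function(i) {
    mag <- mags[[a$mag_id[i]]]
    if (is.null(mag)) stop("unknown MAG in MGE annotations: ", a$mag_id[i])
    substr(mag$contigs[[a$contig[i]]], a$start[i], a$end[i])
  }, character(1))
  if ("sequence" %in% names(a) && any(!is.na(a$sequence))) {
    bad <- !is.na(a$sequence) & a$sequence != seqs
    if (any(bad)) stop("MGE annotation sequence does not match its contig slice")
  }
  a$sequence <- seqs
  a
}

#' Pairwise identity matrix for one MGE across MAGs
#'
#' Global (end-to-end) nucleotide alignment identity for every pair of copies;
#' symmetric with unit diagonal; MAGs lacking the element are marked NA.
#'
#' @param records annotation rows for a single `mge_name` with a `sequence`
#'   column (see [extract_mge_sequences()]); at most one copy per MAG is
#'   expected (the first is used otherwise).
#' @param mag_order character vector fixing row/column order; defaults to the
#'   MAGs present.
#' @return numeric matrix (fractions in `[0,1]`, NA for absent MAGs) with an
#'   `mge_name` attribute.
#' @export
mge_identity_matrix <- function(records, mag_order = NULL) {
  stopifnot(length(unique(records$mge_name)) == 1)
  records <- records[!duplicated(records$mag_id), , drop = FALSE]
  present <- records$mag_id
  if (is.null(mag_order)) mag_order <- present
  m <- matrix(NA_real_, length(mag_order), length(mag_order),
              dimnames = list(mag_order, mag_order))
  for (id in intersect(mag_order, present)) m[id, id] <- 1
  if (length(present) >= 2) {
    pres <- intersect(mag_order, present)
    for (i in seq_len(length(pres) - 1L)) {
      for (j in seq.int(i + 1L, length(pres))) {
        a <- records$sequence[records$mag_id == pres[i]]
        b <- records$sequence[records$mag_id == pres[j]]
        id <- global_identity(a, b, "nt")
        m[pres[i], pres[j]] <- id
        m[pres[j], pres[i]] <- id
      }
    }
  }
  attr(m, "mge_name") <- records$mge_name[1]
  m
}

#' Does an MGE identity matrix recapitulate the clade structure?
#'
#' Congruent when the minimum within-clade identity exceeds the maximum
#' between-clade identity (copies are more alike inside clades, as vertical
#' inheritance predicts); incongruent when some between-clade identity
#' exceeds some within-clade identity (as post-divergence transfer predicts);
#' undetermined on exact ties or when fewer than two within-clade and one
#' between-clade comparisons are available.
#'
#' @param mat identity matrix from [mge_identity_matrix()] (NA = absent).
#' @param clades named character vector mapping MAG id to clade label.
#' @return "congruent", "incongruent", or "undetermined".
#' @export
clade_congruence <- function(mat, clades) {
  ids <- rownames(mat)[!is.na(diag(mat))]
  cl <- clades[ids]
  within <- c(); between <- c()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq.int(i + 1L, length(ids))) {
        v <- mat[ids[i], ids[j]]
        if (is.na(v)) next
        if (cl[i] == cl[j]) within <- c(within, v) else between <- c(between, v)
      }
    }
  }
  if (length(within) == 0 || length(between) == 0) return("undetermined")
  if (min(within) > max(between)) return("congruent")
  if (max(between) > min(within)) return("incongruent")
  "undetermined"
}

#' Identity matrices and congruence calls for all annotated MGEs
#'
#' @param mags named list of `mag_record`s.
#' @param annotations MGE annotation table (e.g. a scenario's `truth$mges`).
#' @param clades named character vector mapping MAG id to clade; defaults to
#'   the `clade` field of `mags`.
#' @return list with `matrices` (named list per MGE) and `congruence`
#'   (data.frame: mge_name, n_copies, call).
#' @export
mge_comparison <- function(mags, annotations, clades = NULL) {
  if (is.null(clades))
    clades <- vapply(mags, function(m) m$clade, character(1))
  ann <- extract_mge_sequences(mags, annotations)
  mats <- list(); rows <- list()
  for (nm in unique(ann$mge_name)) {
    rec <- ann[ann$mge_name == nm, , drop = FALSE]
    m <- mge_identity_matrix(rec, mag_order = names(mags))
    mats[[nm]] <- m
    rows[[nm]] <- data.frame(mge_name = nm, n_copies = nrow(rec),
                             call = clade_congruence(m, clades),
                             stringsAsFactors = FALSE)
  }
  list(matrices = mats, congruence = do.call(rbind, rows))
}
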