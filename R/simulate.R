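# Synthetic populations, polymorphisms, recombination tracts, mobile elements
# and read-pair observations with the statistical structure the downstream
# analysis assumes. All coordinates are 1-based, closed.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x a DNA sequence string.
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# substitute each site independently with probability `rate`, uniformly over
# the three alternative bases; returns the mutated string plus a record
mutate_sequence <- function(seq, rate) {
  n <- nchar(seq)
  idx <- which(stats::runif(n) < rate)
  if (length(idx) == 0L) {
    return(list(seq = seq, positions = integer(0),
                from = character(0), to = character(0)))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  from <- chars[idx]
  # ALT[base, k] = k-th alternative base, k in 1..3
  alt <- vapply(from, function(b) sample(setdiff(BASES, b), 1L), character(1))
  chars[idx] <- alt
  list(seq = paste(chars, collapse = ""), positions = idx, from = from, to = alt)
}

new_mag <- function(mag_id, contigs, orfs, clade = NA_character_,
                    depth_interval = NA_character_,
                    abundance_class = NA_character_, completeness = 1) {
  structure(list(mag_id = mag_id, clade = clade,
                 depth_interval = depth_interval,
                 abundance_class = abundance_class,
                 contigs = contigs, orfs = orfs,
                 completeness = completeness),
            class = "mag_record")
}

#' @export
print.mag_record <- function(x, ...) {
  cat(sprintf("<mag_record> %s (clade %s, %s m, %s): %d contigs, %s bp, %d ORFs\n",
              x$mag_id, x$clade, x$depth_interval, x$abundance_class,
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$orfs)))
  invisible(x)
}

#' Total assembled size of a MAG (bp)
#' @param mag a `mag_record`.
#' @return integer, summed contig length.
#' @export
mag_size <- function(mag) sum(nchar(mag$contigs))

#' Check internal consistency of a MAG record
#'
#' Every ORF must lie within its contig with length divisible by 3, and
#' completeness must be in (0, 1].
#' @param mag a `mag_record`.
#' @return the MAG, invisibly; stops on violation.
#' @export
validate_mag <- function(mag) {
  stopifnot(inherits(mag, "mag_record"))
  if (nrow(mag$orfs) > 0) {
    len <- nchar(mag$contigs)[mag$orfs$contig]
    if (any(mag$orfs$start < 1 | mag$orfs$end > len))
      stop("ORF outside contig bounds in ", mag$mag_id)
    if (any((mag$orfs$end - mag$orfs$start + 1L) %% 3L != 0L))
      stop("ORF length not divisible by 3 in ", mag$mag_id)
  }
  if (mag$completeness <= 0 || mag$completeness > 1)
    stop("completeness must be in (0, 1]")
  invisible(mag)
}

#' Simulate the ancestral (founder) genome
#'
#' Generates `n_contigs` random contigs and tiles ORFs along them so that the
#' ORF fraction of the genome matches `orf_fraction`. ORFs are forward-strand,
#' begin with ATG, end with TAA, contain no internal stop codons, and have
#' length divisible by 3. Inter-ORF gaps are sized adaptively so the realized
#' genome-wide ORF fraction tracks the target. Deterministic under
#' `config$seed` (the seed is set here).
#'
#' @param config a [sim_config()].
#' @return a `mag_record` for the ancestor (mag_id "ancestor").
#' @export
simulate_ancestor <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  codons <- setdiff(mkAllStrings_codons(), STOP_CODONS)  # 61 sense codons
  contigs <- character(config$n_contigs)
  names(contigs) <- paste0("c", seq_len(config$n_contigs))
  orf_rows <- list()
  orf_bp <- 0; genome_bp <- 0
  f <- config$orf_fraction
  for (ci in seq_len(config$n_contigs)) {
    clen <- config$contig_lengths[ci]
    pieces <- character(0)
    pos <- 1L; oi <- 0L
    while (f > 0) {
      n_codons <- sample(100:500, 1L)
      orf_len <- 3L * n_codons + 6L  # + start and stop codons
      # adaptive gap: keep genome-wide ORF bp on target
      gap <- max(0L, round((orf_bp + orf_len) / f) - (genome_bp + pos - 1L) - orf_len)
      if (pos + gap + orf_len - 1L > clen) {
        # shrink the last ORF to fit if a reasonable one still fits
        avail <- clen - (pos + gap) + 1L
        n_codons <- (avail - 6L) %/% 3L
        if (n_codons < 50L) break
        orf_len <- 3L * n_codons + 6L
      }
      if (gap > 0) pieces <- c(pieces, random_dna(gap))
      body <- paste(sample(codons, n_codons, replace = TRUE), collapse = "")
      pieces <- c(pieces, paste0("ATG", body, "TAA"))
      oi <- oi + 1L
      start <- pos + gap
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        orf_id = sprintf("%s_orf%03d", names(contigs)[ci], oi),
        contig = names(contigs)[ci], start = start,
        end = start + orf_len - 1L, strand = "+",
        stringsAsFactors = FALSE)
      orf_bp <- orf_bp + orf_len
      pos <- start + orf_len
    }
    if (pos <= clen) pieces <- c(pieces, random_dna(clen - pos + 1L))
    contigs[ci] <- paste(pieces, collapse = "")
    genome_bp <- genome_bp + clen
  }
  orfs <- if (length(orf_rows)) do.call(rbind, orf_rows) else
    data.frame(orf_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  validate_mag(new_mag("ancestor", contigs, orfs))
}

mkAllStrings_codons <- function() {
  g <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

#' Diverge the ancestor into two clades of three populations
#'
#' The first clade's reference genome is the ancestor itself; the second
#' clade's reference is the ancestor substituted at `clade_divergence` per
#' site, so the configured rate equals the realized pairwise between-clade
#' divergence. Each of the three populations per clade is its clade reference
#' substituted at `within_clade_divergence` per site. Substitutions are
#' uniform over the three alternative bases, site-independent. ORF intervals
#' are inherited unchanged (substitution-only evolution).
#'
#' @param ancestor the `mag_record` from [simulate_ancestor()].
#' @param config a [sim_config()].
#' @return list with `mags` (named list of six `mag_record`s) and `lineage`
#'   (data.frame of realized substitution counts per genome).
#' @export
diverge_populations <- function(ancestor, config) {
  validate_config(config)
  clade_names <- unique(config$clades)
  stopifnot(length(clade_names) == 2)
  refs <- list()
  refs[[clade_names[1]]] <- ancestor$contigs
  ref2 <- vapply(ancestor$contigs,
                 function(s) mutate_sequence(s, config$clade_divergence)$seq,
                 character(1))
  names(ref2) <- names(ancestor$contigs)
  refs[[clade_names[2]]] <- ref2
  between_subs <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    refs[[1]], refs[[2]]))
  mags <- list(); lin <- list()
  for (i in seq_along(config$mag_ids)) {
    id <- config$mag_ids[i]
    ref <- refs[[config$clades[i]]]
    nsub <- 0L
    seqs <- vapply(ref, function(s) {
      m <- mutate_sequence(s, config$within_clade_divergence)
      nsub <<- nsub + length(m$positions)
      m$seq
    }, character(1))
    names(seqs) <- names(ref)
    mags[[id]] <- new_mag(id, seqs, ancestor$orfs,
                          clade = config$clades[i],
                          depth_interval = config$depth_intervals[i],
                          abundance_class = config$abundance_class[i],
                          completeness = config$completeness[i])
    lin[[i]] <- data.frame(mag_id = id, clade = config$clades[i],
                           subs_from_clade_ref = nsub,
                           stringsAsFactors = FALSE)
  }
  lineage <- do.call(rbind, lin)
  attr(lineage, "between_clade_subs") <- between_subs
  list(mags = mags, lineage = lineage)
}

#' Inject population-level polymorphic sites into a MAG
#'
#' SNV sites are drawn by independent per-site Bernoulli trials at rate
#' `snv_rate` over all ORF positions (so the site count is binomial,
#' approximately Poisson with mean `snv_rate * ORF bp`). Each site gets a
#' variant base different from the consensus and a frequency drawn uniformly
#' from `snv_freq_range`. The MAG's consensus sequence is unchanged; the
#' polymorphism lives in the truth table (and later on simulated reads).
#'
#' @param mag a `mag_record`.
#' @param config a [sim_config()].
#' @return list with `mag` (unchanged) and `truth` (data.frame: mag_id, contig,
#'   pos, consensus_base, variant_base, frequency).
#' @export
inject_polymorphisms <- function(mag, config) {
  validate_config(config)
  out <- empty_truth_snvs()
  if (config$snv_rate > 0 && nrow(mag$orfs) > 0) {
    rows <- list()
    for (ci in names(mag$contigs)) {
      o <- mag$orfs[mag$orfs$contig == ci, , drop = FALSE]
      if (nrow(o) == 0) next
      pos_all <- unlist(mapply(seq.int, o$start, o$end, SIMPLIFY = FALSE))
      hit <- pos_all[stats::runif(length(pos_all)) < config$snv_rate]
      if (length(hit) == 0) next
      chars <- strsplit(mag$contigs[[ci]], "", fixed = TRUE)[[1]]
      cons <- chars[hit]
      var <- vapply(cons, function(b) sample(setdiff(BASES, b), 1L), character(1))
      rows[[ci]] <- data.frame(
        mag_id = mag$mag_id, contig = ci, pos = hit,
        consensus_base = cons, variant_base = var,
        frequency = stats::runif(length(hit), config$snv_freq_range[1],
                                 config$snv_freq_range[2]),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  list(mag = mag, truth = out)
}

empty_truth_snvs <- function() {
  data.frame(mag_id = character(0), contig = character(0), pos = integer(0),
             consensus_base = character(0), variant_base = character(0),
             frequency = numeric(0), stringsAsFactors = FALSE)
}

#' Transfer recombination tracts from a donor into a recipient population
#'
#' For each tract the recipient's consensus sequence over the tract is replaced
#' by the donor's, and the donor's polymorphic sites inside the tract are
#' copied into the recipient's truth table with identical consensus and
#' variant bases (creating true same-substitution shared SNVs). Recipient
#' polymorphisms previously recorded inside a tract are dropped, since the
#' locus they annotated has been replaced.
#'
#' @param donor,recipient `mag_record`s sharing contig naming and lengths.
#' @param config a [sim_config()]; `n_recomb_tracts`, `tract_length_mean`,
#'   `tract_length_sd` are used.
#' @param donor_truth the donor's truth SNV table ([inject_polymorphisms()]).
#' @param recipient_truth the recipient's truth SNV table; entries inside
#'   tracts are replaced by the donor's.
#' @param avoid optional data.frame (contig, start, end) of intervals tracts
#'   must not overlap (e.g. mobile-element loci whose inheritance is being
#'   studied separately); placement is retried.
#' @return list with `recipient` (modified), `truth` (updated recipient truth),
#'   and `tracts` (data.frame: donor, recipient, contig, start, end).
#' @export
inject_recombination <- function(donor, recipient, config, donor_truth,
                                 recipient_truth = empty_truth_snvs(),
                                 avoid = NULL) {
  validate_config(config)
  stopifnot(identical(names(donor$contigs), names(recipient$contigs)))
  tracts <- data.frame(donor = character(0), recipient = character(0),
                       contig = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  truth <- recipient_truth
  if (config$n_recomb_tracts > 0) {
    clens <- nchar(recipient$contigs)
    for (t in seq_len(config$n_recomb_tracts)) {
      len <- max(1000L, round(stats::rnorm(1, config$tract_length_mean,
                                           config$tract_length_sd)))
      for (try in 1:100) {
        ci <- sample(names(clens), 1L, prob = clens)
        if (len > clens[[ci]])
          stop("recombination tract longer than contig ", ci)
        start <- sample.int(clens[[ci]] - len + 1L, 1L)
        end <- start + len - 1L
        clash <- !is.null(avoid) && nrow(avoid) > 0 &&
          any(avoid$contig == ci & avoid$start <= end & avoid$end >= start)
        clash <- clash || (nrow(tracts) > 0 &&
          any(tracts$contig == ci & tracts$start <= end & tracts$end >= start))
        if (!clash) break
        if (try == 100) stop("could not place recombination tract clear of ",
                             "avoided intervals")
      }
      substr(recipient$contigs[[ci]], start, end) <-
        substr(donor$contigs[[ci]], start, end)
      # recipient polymorphisms at the replaced locus no longer apply
      drop <- truth$contig == ci & truth$pos >= start & truth$pos <= end
      truth <- truth[!drop, , drop = FALSE]
      dsnv <- donor_truth[donor_truth$contig == ci &
                            donor_truth$pos >= start &
                            donor_truth$pos <= end, , drop = FALSE]
      if (nrow(dsnv) > 0) {
        dsnv$mag_id <- recipient$mag_id
        truth <- rbind(truth, dsnv)
      }
      tracts <- rbind(tracts, data.frame(
        donor = donor$mag_id, recipient = recipient$mag_id,
        contig = ci, start = start, end = end, stringsAsFactors = FALSE))
    }
    truth <- truth[order(truth$contig, truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(recipient = recipient, truth = truth, tracts = tracts)
}

#' Construct a mobile-element sequence with inverted terminal repeats
#'
#' The element is left repeat + cargo + right repeat, where the right repeat is
#' the reverse complement of the left.
#' @param length total element length (bp).
#' @param repeat_length inverted repeat length (bp); `2 * repeat_length` must be
#'   less than `length`.
#' @return a DNA string.
#' @export
make_mge_sequence <- function(length, repeat_length) {
  stopifnot(2 * repeat_length < length)
  left <- random_dna(repeat_length)
  cargo <- random_dna(length - 2L * repeat_length)
  paste0(left, cargo, revcomp(left))
}

# insert `elem` into mag's contig before position `at`, shifting downstream
# annotations (ORFs, truth SNVs, tracts, earlier MGE annotations)
insert_element_at <- function(mag, contig, at, elem) {
  s <- mag$contigs[[contig]]
  stopifnot(at >= 1, at <= nchar(s) + 1L)
  inside <- mag$orfs$contig == contig & mag$orfs$start < at & mag$orfs$end >= at
  if (any(inside)) stop("MGE insertion point falls inside an ORF")
  len <- nchar(elem)
  mag$contigs[[contig]] <- paste0(substr(s, 1L, at - 1L), elem,
                                  substr(s, at, nchar(s)))
  shift <- mag$orfs$contig == contig & mag$orfs$start >= at
  mag$orfs$start[shift] <- mag$orfs$start[shift] + len
  mag$orfs$end[shift] <- mag$orfs$end[shift] + len
  mag
}

shift_positions <- function(df, mag_col, mag_id, contig, at, len, cols) {
  if (nrow(df) == 0) return(df)
  hit <- df[[mag_col]] == mag_id & df$contig == contig
  for (cl in cols) {
    up <- hit & df[[cl]] >= at
    df[[cl]][up] <- df[[cl]][up] + len
  }
  df
}

# pick an intergenic insertion point (middle of a gap between ORFs), avoiding
# intervals listed in `avoid` (data.frame contig/start/end), e.g. recomb tracts
pick_intergenic_site <- function(mag, min_gap = 40L, avoid = NULL) {
  cand <- list()
  for (ci in names(mag$contigs)) {
    o <- mag$orfs[mag$orfs$contig == ci, , drop = FALSE]
    o <- o[order(o$start), , drop = FALSE]
    starts <- c(1L, o$end + 1L)
    ends <- c(o$start - 1L, nchar(mag$contigs[[ci]]))
    keep <- (ends - starts + 1L) >= min_gap
    if (!any(keep)) next
    mid <- (starts[keep] + ends[keep]) %/% 2L
    cand[[ci]] <- data.frame(contig = ci, at = mid, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) stop("no intergenic gap wide enough for MGE")
  if (!is.null(avoid) && nrow(avoid) > 0) {
    bad <- vapply(seq_len(nrow(cand)), function(i) {
      any(avoid$contig == cand$contig[i] & avoid$start <= cand$at[i] &
            avoid$end >= cand$at[i])
    }, logical(1))
    if (!all(bad)) cand <- cand[!bad, , drop = FALSE]
  }
  cand[sample.int(nrow(cand), 1L), , drop = FALSE]
}

empty_mge_truth <- function() {
  data.frame(mag_id = character(0), mge_name = character(0),
             contig = character(0), start = integer(0), end = integer(0),
             kind = character(0), truncated = logical(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Insert mobile genetic elements into one or more genomes
#'
#' Each element specification (see [sim_config()] `mges`) is built once as
#' left inverted repeat + cargo + reverse-complement right repeat and inserted
#' at an intergenic site of every target MAG, optionally truncated (a prefix of
#' the configured fraction) for named targets. Insertions shift downstream ORF
#' coordinates, truth SNV positions and tract coordinates, which are updated in
#' place. Requests whose insertion points collide raise an error.
#'
#' @param mags named list of `mag_record`s.
#' @param mge_specs list of element specifications (e.g. `config$mges`,
#'   filtered to the relevant `mode`).
#' @param truth_snvs truth SNV table to keep coordinate-consistent.
#' @param tracts recombination tract table to keep coordinate-consistent
#'   (recipient frame).
#' @param mge_truth existing MGE annotation table to extend (and shift).
#' @return list with `mags`, `truth_snvs`, `tracts` and `mges` (annotation
#'   data.frame including the inserted sequence).
#' @export
insert_mges <- function(mags, mge_specs, truth_snvs = empty_truth_snvs(),
                        tracts = NULL, mge_truth = empty_mge_truth()) {
  if (is.null(tracts))
    tracts <- data.frame(donor = character(0), recipient = character(0),
                         contig = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  for (spec in mge_specs) {
    elem <- make_mge_sequence(spec$length, spec$repeat_length)
    targets <- if (!is.null(spec$targets)) spec$targets else names(mags)
    kind <- if (!is.null(spec$kind)) spec$kind else "insertion_sequence"
    for (tg in targets) {
      if (!tg %in% names(mags)) stop("MGE target not among MAGs: ", tg)
      mag <- mags[[tg]]
      this <- elem; trunc <- FALSE
      if (!is.null(spec$truncate) && tg %in% names(spec$truncate)) {
        this <- substr(elem, 1L, round(spec$truncate[[tg]] * nchar(elem)))
        trunc <- TRUE
      }
      avoid <- rbind(
        tracts[tracts$recipient == tg, c("contig", "start", "end"), drop = FALSE],
        mge_truth[mge_truth$mag_id == tg, c("contig", "start", "end"), drop = FALSE])
      site <- pick_intergenic_site(mag, avoid = avoid)
      prev <- mge_truth$mag_id == tg & mge_truth$contig == site$contig &
        mge_truth$start == site$at
      if (any(prev)) stop("overlapping MGE insertion requests at ",
                          site$contig, ":", site$at)
      mags[[tg]] <- insert_element_at(mag, site$contig, site$at, this)
      len <- nchar(this)
      truth_snvs <- shift_positions(truth_snvs, "mag_id", tg, site$contig,
                                    site$at, len, "pos")
      tracts <- shift_positions(tracts, "recipient", tg, site$contig,
                                site$at, len, c("start", "end"))
      mge_truth <- shift_positions(mge_truth, "mag_id", tg, site$contig,
                                   site$at, len, c("start", "end"))
      mge_truth <- rbind(mge_truth, data.frame(
        mag_id = tg, mge_name = spec$name, contig = site$contig,
        start = site$at, end = site$at + len - 1L, kind = kind,
        truncated = trunc, sequence = this, stringsAsFactors = FALSE))
    }
  }
  list(mags = mags, truth_snvs = truth_snvs, tracts = tracts, mges = mge_truth)
}

#' Translate a MAG's ORFs into protein sequences
#'
#' Forward-strand translation with the standard code; the terminal stop is
#' stripped. Internal stops arising from simulated divergence are kept as `*`
#' (clustering treats them as ordinary mismatches).
#'
#' @param mag a `mag_record`.
#' @return a named `AAStringSet` (names are ORF ids).
#' @export
mag_proteins <- function(mag) {
  if (nrow(mag$orfs) == 0) return(Biostrings::AAStringSet())
  nt <- mag_orf_seqs(mag)
  aa <- Biostrings::translate(nt, no.init.codon = TRUE)
  aa <- Biostrings::AAStringSet(sub("\\*$", "", as.character(aa)))
  names(aa) <- names(nt)
  aa
}

#' Extract a MAG's ORF nucleotide sequences (coding strand)
#' @param mag a `mag_record`.
#' @return a named `DNAStringSet`.
#' @export
mag_orf_seqs <- function(mag) {
  if (nrow(mag$orfs) == 0) return(Biostrings::DNAStringSet())
  seqs <- substring(mag$contigs[mag$orfs$contig], mag$orfs$start, mag$orfs$end)
  rc <- mag$orfs$strand == "-"
  if (any(rc)) seqs[rc] <- vapply(seqs[rc], revcomp, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- mag$orfs$orf_id
  out
}

#' Simulate mapped read-pair observations for one MAG
#'
#' Pairs are sampled to a mean total depth of `config$coverage`; insert sizes
#' are normal (`insert_median`, `insert_sd`) truncated to at least two read
#' lengths; mate 2 ends at the far end of the fragment. At each truth
#' polymorphic site, a fragment carries the variant base with probability equal
#' to the site's truth frequency (both mates of a carrying fragment agree).
#' Per-base substitution errors occur at `error_rate`. Both mates get mapQ
#' `mapq_default`, except a fraction `mapq_zero_fraction` of pairs which get
#' mapQ 0. The pair identity to the reference is computed over both mates.
#'
#' @param mag a `mag_record`.
#' @param truth_snvs truth SNV table for this MAG.
#' @param config a [sim_config()].
#' @return data.frame with columns pair_id, contig, start1, start2,
#'   insert_size, mapq1, mapq2, pair_identity, seq1, seq2 (1-based mate start
#'   positions on the reference).
#' @export
simulate_read_pairs <- function(mag, truth_snvs, config) {
  validate_config(config)
  L <- config$read_length
  clens <- nchar(mag$contigs)
  if (L > min(clens)) stop("read_length exceeds the shortest contig")
  gsize <- sum(clens)
  n <- round(config$coverage * gsize / (2 * L))
  if (n == 0) return(empty_pairs())
  contig <- sample(names(clens), n, replace = TRUE, prob = clens)
  insert <- round(stats::rnorm(n, config$insert_median, config$insert_sd))
  insert <- pmax(insert, 2L * L)
  insert <- pmin(insert, clens[contig])
  start1 <- floor(stats::runif(n) * (clens[contig] - insert + 1)) + 1L
  start2 <- start1 + insert - L
  mapq <- rep(config$mapq_default, n)
  mapq[stats::runif(n) < config$mapq_zero_fraction] <- 0L
  seq1 <- character(n); seq2 <- character(n); ident <- numeric(n)
  for (ci in names(clens)) {
    sel <- which(contig == ci)
    if (length(sel) == 0) next
    chars <- strsplit(mag$contigs[[ci]], "", fixed = TRUE)[[1]]
    m <- length(sel)
    p1 <- outer(start1[sel], 0:(L - 1L), "+")
    p2 <- outer(start2[sel], 0:(L - 1L), "+")
    R1 <- matrix(chars[p1], m, L); R2 <- matrix(chars[p2], m, L)
    M1 <- R1; M2 <- R2
    ts <- truth_snvs[truth_snvs$contig == ci, , drop = FALSE]
    for (si in seq_len(nrow(ts))) {
      pos <- ts$pos[si]
      c1 <- pos - start1[sel] + 1L; c2 <- pos - start2[sel] + 1L
      in1 <- c1 >= 1L & c1 <= L; in2 <- c2 >= 1L & c2 <= L
      cover <- which(in1 | in2)
      if (length(cover) == 0) next
      carrier <- cover[stats::runif(length(cover)) < ts$frequency[si]]
      if (length(carrier) == 0) next
      k1 <- carrier[in1[carrier]]
      if (length(k1)) M1[cbind(k1, c1[k1])] <- ts$variant_base[si]
      k2 <- carrier[in2[carrier]]
      if (length(k2)) M2[cbind(k2, c2[k2])] <- ts$variant_base[si]
    }
    if (config$error_rate > 0) {
      for (Mn in c("M1", "M2")) {
        M <- get(Mn)
        err <- which(stats::runif(length(M)) < config$error_rate)
        if (length(err)) {
          M[err] <- vapply(M[err], function(b) sample(setdiff(BASES, b), 1L),
                           character(1))
          assign(Mn, M)
        }
      }
    }
    ident[sel] <- (rowSums(M1 == R1) + rowSums(M2 == R2)) / (2 * L)
    seq1[sel] <- apply(M1, 1L, paste, collapse = "")
    seq2[sel] <- apply(M2, 1L, paste, collapse = "")
  }
  data.frame(pair_id = sprintf("%s_p%07d", mag$mag_id, seq_len(n)),
             contig = contig, start1 = start1, start2 = start2,
             insert_size = insert, mapq1 = mapq, mapq2 = mapq,
             pair_identity = ident, seq1 = seq1, seq2 = seq2,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_pairs <- function() {
  data.frame(pair_id = character(0), contig = character(0),
             start1 = integer(0), start2 = integer(0), insert_size = integer(0),
             mapq1 = integer(0), mapq2 = integer(0), pair_identity = numeric(0),
             seq1 = character(0), seq2 = character(0), stringsAsFactors = FALSE)
}

#' Simulate the full two-clade scenario
#'
#' Orchestrates ancestor simulation, insertion of ancestral (vertically
#' inherited) MGEs, divergence into six populations, per-population
#' polymorphism injection, donor-to-recipient recombination tracts, and
#' post-divergence MGE transfer. Read pairs are simulated separately per MAG
#' with [simulate_read_pairs()] (they are the expensive part). The whole
#' scenario is a deterministic function of the config (including its seed).
#'
#' @param config a [sim_config()].
#' @return a list of class `"sim_scenario"`: `config`, `ancestor`, `mags`
#'   (named list), `lineage`, and `truth` (list with `snvs`, `tracts`, `mges`).
#' @export
simulate_scenario <- function(config) {
  validate_config(config)
  anc <- simulate_ancestor(config)   # sets the seed
  anc_specs <- Filter(function(m) identical(m$mode, "ancestral"), config$mges)
  anc_mges <- empty_mge_truth()
  if (length(anc_specs)) {
    ins <- insert_mges(stats::setNames(list(anc), "ancestor"), anc_specs)
    anc <- ins$mags[["ancestor"]]
    anc_mges <- ins$mges
  }
  div <- diverge_populations(anc, config)
  mags <- div$mags
  truth_snvs <- empty_truth_snvs()
  for (id in names(mags)) {
    truth_snvs <- rbind(truth_snvs, inject_polymorphisms(mags[[id]], config)$truth)
  }
  tracts <- data.frame(donor = character(0), recipient = character(0),
                       contig = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  for (pr in config$recomb_pairs) {
    dn <- pr[1]; rc <- pr[2]
    rec <- inject_recombination(
      mags[[dn]], mags[[rc]], config,
      donor_truth = truth_snvs[truth_snvs$mag_id == dn, , drop = FALSE],
      recipient_truth = truth_snvs[truth_snvs$mag_id == rc, , drop = FALSE],
      avoid = anc_mges[c("contig", "start", "end")])
    mags[[rc]] <- rec$recipient
    truth_snvs <- rbind(truth_snvs[truth_snvs$mag_id != rc, , drop = FALSE],
                        rec$truth)
    tracts <- rbind(tracts, rec$tracts)
  }
  # cross-clade transfer of an ancestral element: the recipient's copy is
  # overwritten by the donor's current copy (the element locus is identical
  # across MAGs at this point, substitution-only evolution preserves lengths)
  for (spec in config$mges) {
    if (identical(spec$mode, "ancestral") && !is.null(spec$transfer_donor)) {
      r <- anc_mges[anc_mges$mge_name == spec$name, ][1, ]
      dn <- spec$transfer_donor; rc <- spec$transfer_recipient
      substr(mags[[rc]]$contigs[[r$contig]], r$start, r$end) <-
        substr(mags[[dn]]$contigs[[r$contig]], r$start, r$end)
    }
  }
  # ancestral elements: every diverged MAG inherits the insertion coordinates
  mge_truth <- empty_mge_truth()
  if (nrow(anc_mges) > 0) {
    for (id in names(mags)) {
      for (i in seq_len(nrow(anc_mges))) {
        r <- anc_mges[i, ]
        mge_truth <- rbind(mge_truth, data.frame(
          mag_id = id, mge_name = r$mge_name, contig = r$contig,
          start = r$start, end = r$end, kind = r$kind, truncated = r$truncated,
          sequence = substr(mags[[id]]$contigs[[r$contig]], r$start, r$end),
          stringsAsFactors = FALSE))
      }
    }
  }
  tr_specs <- Filter(function(m) identical(m$mode, "transfer"), config$mges)
  if (length(tr_specs)) {
    ins <- insert_mges(mags, tr_specs, truth_snvs = truth_snvs,
                       tracts = tracts, mge_truth = mge_truth)
    mags <- ins$mags; truth_snvs <- ins$truth_snvs
    tracts <- ins$tracts; mge_truth <- ins$mges
  }
  rownames(truth_snvs) <- NULL; rownames(tracts) <- NULL
  rownames(mge_truth) <- NULL
  structure(list(config = config, ancestor = anc, mags = mags,
                 lineage = div$lineage,
                 truth = list(snvs = truth_snvs, tracts = tracts,
                              mges = mge_truth)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %d MAGs, %s bp each, %d truth SNVs, %d tracts, %d MGE copies\n",
              length(x$mags), format(mag_size(x$mags[[1]]), big.mark = ","),
              nrow(x$truth$snvs), nrow(x$truth$tracts), nrow(x$truth$mges)))
  invisible(x)
}
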