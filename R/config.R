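#' Simulation configuration for the two-clade borehole scenario
#'
#' Builds the configuration object consumed by the synthetic-data generator
#' ([simulate_scenario()] and the individual `simulate_*`/`inject_*` steps).
#' Defaults emulate the study conditions the analysis assumes: six MAG-like
#' populations forming two clades of three, pairwise within-clade ANI of about
#' 99.99% and between-clade ANI of about 84%, per-ORF-bp SNV rates in the range
#' implied by per-MAG burdens of order 10^3-10^4 on a ~3 Mbp genome, a small
#' number of recombination tracts transferred across clades, and a mix of
#' vertically inherited and horizontally transferred mobile genetic elements.
#'
#' @param seed integer seed; together with the config it fully determines all
#'   simulator output.
#' @param n_contigs number of contigs in the ancestral genome.
#' @param contig_lengths integer vector of contig lengths (bp); recycled to
#'   `n_contigs`.
#' @param orf_fraction target fraction of each contig covered by ORFs.
#' @param clade_divergence expected per-site substitution fraction between the
#'   two clade reference genomes (0.16 gives ~84% between-clade identity).
#' @param within_clade_divergence expected per-site substitution fraction
#'   between a population and its clade reference; 5e-5 makes the *pairwise*
#'   identity between two populations of a clade ~99.99%.
#' @param snv_rate expected polymorphic sites per bp of ORF sequence.
#' @param snv_freq_range length-2 numeric, the (min, max) variant frequency
#'   drawn for each polymorphic site; must lie inside (0, 1).
#' @param n_recomb_tracts number of recombination tracts per donor->recipient
#'   pair listed in `recomb_pairs`.
#' @param tract_length_mean,tract_length_sd tract length distribution (bp),
#'   truncated below at 1000 bp.
#' @param recomb_pairs list of length-2 character vectors `c(donor, recipient)`.
#' @param mges list of MGE specifications; each element is a list with fields
#'   `name`, `mode` ("ancestral" = inserted into the ancestor before
#'   divergence, "transfer" = identical copy inserted into `targets` after
#'   divergence), `length` (cargo + repeats, bp), `repeat_length` (inverted
#'   terminal repeat, bp), optional `targets` (character vector of MAG ids) and
#'   optional `truncate` (named numeric: fraction of the element kept for the
#'   named target MAGs, emulating a truncated homolog).
#' @param coverage mean read depth of the simulated read pairs.
#' @param read_length mate length (bp).
#' @param insert_median,insert_sd insert (fragment) size distribution (bp).
#' @param error_rate per-base sequencing error probability (substitutions only).
#' @param mapq_default mapQ assigned to both mates of a pair.
#' @param mapq_zero_fraction fraction of pairs assigned mapQ 0 on both mates so
#'   the mapQ filter has something to remove.
#' @param mag_ids,clades,depth_intervals,abundance_class,completeness per-MAG
#'   labels for the six populations (clade x depth layout of the study design).
#'
#' @return a list of class `"sim_config"`, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 5L,
                       contig_lengths = 20000L,
                       orf_fraction = 0.85,
                       clade_divergence = 0.16,
                       within_clade_divergence = 5e-5,
                       snv_rate = 2e-3,
                       snv_freq_range = c(0.05, 0.35),
                       n_recomb_tracts = 2L,
                       tract_length_mean = 10000,
                       tract_length_sd = 2000,
                       recomb_pairs = list(c("D-65", "S-132")),
                       mges = default_mges(),
                       coverage = 50,
                       read_length = 150L,
                       insert_median = 350,
                       insert_sd = 40,
                       error_rate = 0.001,
                       mapq_default = 30L,
                       mapq_zero_fraction = 0.02,
                       mag_ids = c("S-30", "S-65", "S-132", "D-30", "D-65", "D-132"),
                       clades = c("S", "S", "S", "D", "D", "D"),
                       depth_intervals = c("0-30", "41-65", "108-132",
                                           "0-30", "41-65", "108-132"),
                       abundance_class = c("abundant", "rare", "rare",
                                           "rare", "abundant", "abundant"),
                       completeness = 0.9) {
  cfg <- list(
    seed = as.integer(seed),
    n_contigs = as.integer(n_contigs),
    contig_lengths = as.integer(rep_len(contig_lengths, n_contigs)),
    orf_fraction = orf_fraction,
    clade_divergence = clade_divergence,
    within_clade_divergence = within_clade_divergence,
    snv_rate = snv_rate,
    snv_freq_range = as.numeric(snv_freq_range),
    n_recomb_tracts = as.integer(n_recomb_tracts),
    tract_length_mean = tract_length_mean,
    tract_length_sd = tract_length_sd,
    recomb_pairs = recomb_pairs,
    mges = mges,
    coverage = coverage,
    read_length = as.integer(read_length),
    insert_median = insert_median,
    insert_sd = insert_sd,
    error_rate = error_rate,
    mapq_default = as.integer(mapq_default),
    mapq_zero_fraction = mapq_zero_fraction,
    mag_ids = mag_ids,
    clades = clades,
    depth_intervals = depth_intervals,
    abundance_class = abundance_class,
    completeness = rep_len(completeness, length(mag_ids))
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Default mobile genetic element specifications
#'
#' Three elements emulating the inheritance patterns the analysis must
#' distinguish:
#' * `ISanc1` - inserted into the ancestor and inherited vertically, so its
#'   copies diverge with the genomes (high identity within clades, clade-level
#'   identity between them): the congruent case.
#' * `TnX1` - also ancestrally present, but after divergence the recipient
#'   population's copy is overwritten by the donor's (a cross-clade transfer /
#'   gene-conversion event), making one between-clade pair near-identical
#'   while within-clade pairs involving the recipient drop to clade-level
#'   identity: the incongruent case.
#' * `IStrn1` - an identical copy inserted into three MAGs after divergence,
#'   truncated to 0.61 of its length in one of them (the ratio observed for
#'   the truncated insertion-sequence homolog in the study system, 131/214
#'   residues).
#'
#' @return list of MGE specification lists; see [sim_config()].
#' @export
default_mges <- function() {
  list(
    list(name = "ISanc1", mode = "ancestral", length = 1200L,
         repeat_length = 25L, kind = "insertion_sequence"),
    list(name = "TnX1", mode = "ancestral", length = 1500L,
         repeat_length = 25L, kind = "composite_transposon",
         transfer_donor = "D-65", transfer_recipient = "S-132"),
    list(name = "IStrn1", mode = "transfer", length = 1000L,
         repeat_length = 25L, kind = "insertion_sequence",
         targets = c("D-132", "D-65", "S-132"),
         truncate = c("S-132" = 0.61))
  )
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` object (or bare list with the same fields).
#' @return the config, invisibly; stops with a configuration error otherwise.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg, call. = FALSE)
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be a single integer")
  chk(cfg$n_contigs >= 1, "n_contigs must be positive")
  chk(all(cfg$contig_lengths > 0), "contig lengths must be positive")
  for (f in c("orf_fraction", "clade_divergence", "within_clade_divergence",
              "error_rate", "mapq_zero_fraction")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "must be in [0, 1]"))
  }
  chk(cfg$snv_rate >= 0, "snv_rate must be >= 0")
  chk(length(cfg$snv_freq_range) == 2 &&
        cfg$snv_freq_range[1] > 0 && cfg$snv_freq_range[2] < 1 &&
        cfg$snv_freq_range[1] <= cfg$snv_freq_range[2],
      "snv_freq_range must be inside (0, 1) with min <= max")
  chk(cfg$n_recomb_tracts >= 0, "n_recomb_tracts must be >= 0")
  chk(cfg$coverage >= 0, "coverage must be >= 0")
  chk(cfg$read_length > 0, "read_length must be positive")
  chk(cfg$insert_median >= 2 * cfg$read_length || cfg$coverage == 0,
      "insert_median must be at least twice the read length")
  chk(length(cfg$mag_ids) == length(cfg$clades) &&
        length(cfg$mag_ids) == length(cfg$depth_intervals) &&
        length(cfg$mag_ids) == length(cfg$abundance_class),
      "per-MAG label vectors must have equal length")
  chk(all(cfg$completeness > 0 & cfg$completeness <= 1),
      "completeness must be in (0, 1]")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param cfg a `sim_config` object.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns a
#'   validated `sim_config`.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  # yaml round-trips named numeric vectors (truncate) as lists; restore them
  x$mges <- lapply(x$mges, function(m) {
    if (!is.null(m$truncate)) m$truncate <- unlist(m$truncate)
    m
  })
  x$recomb_pairs <- lapply(x$recomb_pairs, unlist)
  x$contig_lengths <- as.integer(unlist(x$contig_lengths))
  cfg <- x
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}
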