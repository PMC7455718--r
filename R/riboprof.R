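# Mitoribosome-profiling codon-occupancy analysis: A-site assignment with
# length-dependent offsets, per-transcript occupancy normalization, codon
# position filters, and per-codon fold change between two conditions under
# the vertebrate mitochondrial genetic code.

#' The vertebrate mitochondrial genetic code, RNA codons
#'
#' Table from the standard genetic-code registry (NCBI translation
#' table 2 / SGC1): AUA codes Met, UGA codes Trp, and AGA/AGG are stop
#' codons.
#'
#' @return Named character vector: RNA codon -> one-letter amino acid
#'   (`*` for stop).
#' @export
mito_genetic_code <- function() {
  gc <- Biostrings::getGeneticCode("SGC1")
  names(gc) <- chartr("T", "U", names(gc))
  gc
}

#' Build a transcript model
#'
#' @param id transcript id.
#' @param sequence RNA sequence string (A/C/G/U).
#' @param cds_start,cds_end CDS bounds, 1-based inclusive; the CDS
#'   length must be divisible by 3.
#' @return An object of class `transcript_model` with the per-codon
#'   identities precomputed.
#' @export
transcript_model <- function(id, sequence, cds_start, cds_end) {
  sequence <- chartr("T", "U", toupper(sequence))
  stopifnot(cds_start >= 1, cds_end <= nchar(sequence),
            (cds_end - cds_start + 1) %% 3 == 0)
  n_codons <- (cds_end - cds_start + 1) %/% 3
  starts <- cds_start + 3 * (seq_len(n_codons) - 1)
  codons <- substring(sequence, starts, starts + 2)
  structure(list(id = id, sequence = sequence, cds_start = cds_start,
                 cds_end = cds_end, n_codons = n_codons, codons = codons),
            class = "transcript_model")
}

#' A-site offsets by footprint length
#'
#' The distance from the footprint 5' end to the ribosomal A site is 14
#' nt for 23-31-nt footprints and 15 nt for 32-34-nt footprints; other
#' lengths have no defined offset and are discarded from occupancy.
#'
#' @param length footprint length(s) in nt.
#' @return Integer offset(s); `NA` outside 23-34.
#' @export
asite_offset <- function(length) {
  ifelse(length >= 23 & length <= 31, 14L,
         ifelse(length >= 32 & length <= 34, 15L, NA_integer_))
}

#' Map footprints to A-site codon indices
#'
#' The A-site nucleotide is the 5' position plus the length-dependent
#' offset; the codon index is its 0-based codon within the CDS.
#' Footprints with no defined offset or whose A site falls outside the
#' CDS return `NA`.
#'
#' @param pos5 footprint 5' positions (1-based transcript coordinates).
#' @param length footprint lengths (nt).
#' @param tm a [transcript_model()].
#' @return Integer vector of 0-based codon indices (`NA` = discarded).
#' @export
asite_codon <- function(pos5, length, tm) {
  stopifnot(inherits(tm, "transcript_model"))
  if (any(pos5 < 1 | pos5 + length - 1 > nchar(tm$sequence)))
    stop("footprint outside transcript bounds")
  asite <- pos5 + asite_offset(length)
  idx <- (asite - tm$cds_start) %/% 3
  idx[is.na(asite) | asite < tm$cds_start | asite > tm$cds_end] <- NA_integer_
  as.integer(idx)
}

#' Raw A-site counts per codon of one transcript
#'
#' @param footprints data.frame with columns `transcript`, `pos5`,
#'   `length`.
#' @param tm a [transcript_model()].
#' @return Integer vector of length `tm$n_codons` (codon order).
#' @export
codon_counts <- function(footprints, tm) {
  fp <- footprints[footprints$transcript == tm$id, , drop = FALSE]
  idx <- asite_codon(fp$pos5, fp$length, tm)
  tabulate(idx[!is.na(idx)] + 1L, nbins = tm$n_codons)
}

#' Normalized codon occupancy
#'
#' Counts divided by the mean count over all CDS codons of the
#' transcript (zero-count codons included in the denominator), so that
#' mean occupancy per transcript is 1.
#'
#' @param counts integer vector of per-codon counts.
#' @return Numeric occupancies; all-`NA` (flagged via attribute
#'   `undefined`) if the transcript has no reads.
#' @export
codon_occupancy <- function(counts) {
  m <- mean(counts)
  if (m == 0) {
    out <- rep(NA_real_, length(counts))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  counts / m
}

#' Filter codon positions across samples
#'
#' Removes positions whose occupancy is below `min_occ` in two or more
#' samples, and always removes the first and last CDS codon (start and
#' stop).
#'
#' @param occ matrix of occupancies, codons x samples (one transcript).
#' @param min_occ occupancy floor (default 0.05, i.e. 5%).
#' @return Logical keep vector over codon positions.
#' @export
filter_codon_positions <- function(occ, min_occ = 0.05) {
  occ <- as.matrix(occ)
  low <- rowSums(occ < min_occ, na.rm = TRUE)
  keep <- low < 2
  keep[c(1L, nrow(occ))] <- FALSE
  keep
}

#' Per-codon occupancy fold change between two conditions
#'
#' For every kept codon position the fold change is the ratio of the
#' replicate-mean occupancies (condition of interest over control).
#' Positions are grouped by codon identity under the mitochondrial
#' genetic code, and each codon's fold-change distribution is compared
#' against the pooled fold changes of all other codons by a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param transcripts list of [transcript_model()]s.
#' @param samples named list of footprint data.frames: elements
#'   `ko1`, `ko2`, `wt1`, `wt2` (two replicates per condition; more or
#'   fewer replicates are accepted via `ko`/`wt` name prefixes).
#' @param min_occ occupancy floor for [filter_codon_positions()].
#' @return A list with `positions` (per-position table: transcript,
#'   codon index, codon, occupancies, fold change) and `codons`
#'   (per-codon summary: n, median fold change, rank-sum p-value).
#' @export
occupancy_fold_change <- function(transcripts, samples, min_occ = 0.05) {
  ko_names <- grep("^ko", names(samples), value = TRUE)
  wt_names <- grep("^wt", names(samples), value = TRUE)
  stopifnot(length(ko_names) >= 1, length(wt_names) >= 1)
  pos_rows <- list()
  for (tm in transcripts) {
    occ <- sapply(samples, function(fp) codon_occupancy(codon_counts(fp, tm)))
    if (anyNA(occ)) next  # transcript empty in some sample
    keep <- filter_codon_positions(occ, min_occ)
    ko_mean <- rowMeans(occ[, ko_names, drop = FALSE])
    wt_mean <- rowMeans(occ[, wt_names, drop = FALSE])
    ok <- keep & wt_mean > 0
    if (!any(ok)) next
    pos_rows[[tm$id]] <- data.frame(
      transcript = tm$id, codon_index = which(ok) - 1L,
      codon = tm$codons[ok], ko = ko_mean[ok], wt = wt_mean[ok],
      fc = ko_mean[ok] / wt_mean[ok], stringsAsFactors = FALSE)
  }
  positions <- do.call(rbind, pos_rows)
  if (is.null(positions) || nrow(positions) == 0)
    return(list(positions = positions,
                codons = data.frame(codon = character(), n = integer(),
                                    median_fc = numeric(), p = numeric())))
  rownames(positions) <- NULL
  codons <- sort(unique(positions$codon))
  summ <- do.call(rbind, lapply(codons, function(cd) {
    fc_in <- positions$fc[positions$codon == cd]
    fc_out <- positions$fc[positions$codon != cd]
    p <- if (length(fc_out) >= 1 && length(fc_in) >= 1)
      suppressWarnings(stats::wilcox.test(fc_in, fc_out,
                                          alternative = "two.sided")$p.value)
    else NA_real_
    data.frame(codon = cd, n = length(fc_in),
               median_fc = stats::median(fc_in), p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  aa <- mito_genetic_code()
  summ$aa <- unname(aa[summ$codon])
  list(positions = positions, codons = summ)
}
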