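# Pseudouridine detection from CMC-plus / CMC-minus sequencing.
#
# CMC forms an adduct at the N3 of pseudouridine that blocks reverse
# transcription one position 3' of the Psi, so CMC-treated libraries show
# a drop in read pileup at the Psi relative to untreated libraries. The
# Psi score quantifies that drop from the two pileup tracks:
#
#   score(x) = ((rm(x)/rm(x+1) - rp(x)/rp(x+1))
#               - (rm(x+1)/rm(x+2) - rp(x+1)/rp(x+2))) * 100
#
# where rm / rp are the per-position read counts in the CMC-minus and
# CMC-plus samples.

#' Effective 5' end of a read after the 5'-proximal mismatch shift
#'
#' Reverse transcription across a CMC adduct can add non-templated
#' nucleotides; when the leftmost or penultimate read nucleotide
#' mismatches the reference, the 5' end is shifted to the 3' side of
#' the most 3' such mismatch. The shift is applied once, evaluated only
#' within the original first two nucleotides.
#'
#' @param start 5' position(s) of the read(s), 1-based.
#' @param mm0 logical/0-1: mismatch at read offset 0 (leftmost nt)?
#' @param mm1 logical/0-1: mismatch at read offset 1 (penultimate)?
#' @return Adjusted 5' position(s): `start + 2` if offset 1 mismatches,
#'   else `start + 1` if offset 0 mismatches, else `start`.
#' @export
effective_5p <- function(start, mm0 = 0, mm1 = 0) {
  start + ifelse(as.logical(mm1), 2L, ifelse(as.logical(mm0), 1L, 0L))
}

#' Filter aligned reads for Psi-score calculation
#'
#' Keeps properly paired reads that overlap the 3'-CCA of the tRNA by at
#' least one nucleotide and do not overlap the 3' trailer.
#'
#' @param reads data.frame with columns `ref`, `start`, `end` (1-based
#'   inclusive), `mm0`, `mm1`, `paired`.
#' @param annotation data.frame with columns `ref`, `length`,
#'   `cca_start` (first position of CCA) and `trailer_start` (first
#'   position 3' of the mature tRNA; `NA` for none).
#' @return The kept rows of `reads`.
#' @export
filter_reads <- function(reads, annotation) {
  stopifnot(all(c("ref", "start", "end", "paired") %in% names(reads)))
  ann <- annotation[match(reads$ref, annotation$ref), ]
  if (anyNA(ann$ref)) stop("reads reference sequences missing from annotation")
  cca_end <- ann$cca_start + 2L
  keep <- as.logical(reads$paired) &
    reads$end >= ann$cca_start & reads$start <= cca_end &
    (is.na(ann$trailer_start) | reads$end < ann$trailer_start)
  reads[keep, , drop = FALSE]
}

#' Build a pileup track from filtered reads
#'
#' A read contributes one count to every position its
#' [effective 5', 3'] interval covers (spanning coverage from the
#' shifted 5' end).
#'
#' @param reads filtered reads (see [filter_reads()]); `mm0`/`mm1`
#'   columns, if present, are applied through [effective_5p()].
#' @param ref_length reference length.
#' @return Integer vector of per-position counts, length `ref_length`.
#' @export
build_pileup <- function(reads, ref_length) {
  s <- effective_5p(reads$start,
                    if (is.null(reads$mm0)) 0 else reads$mm0,
                    if (is.null(reads$mm1)) 0 else reads$mm1)
  e <- pmin(reads$end, ref_length)
  s <- pmax(s, 1L)
  cov <- integer(ref_length)
  ok <- s <= e
  if (any(ok)) {
    # difference-array coverage accumulation
    d <- integer(ref_length + 1L)
    tab_s <- tabulate(s[ok], nbins = ref_length)
    tab_e <- tabulate(e[ok] + 1L, nbins = ref_length + 1L)
    d[seq_len(ref_length)] <- tab_s
    d <- d - tab_e
    cov <- cumsum(d[seq_len(ref_length)])
  }
  as.integer(cov)
}

#' Psi score at one or more positions
#'
#' Exact evaluation of the drop-off contrast between the CMC-minus and
#' CMC-plus pileups (see the module header). The score is undefined
#' (`NA`) wherever any of the four denominators rm(x+1), rm(x+2),
#' rp(x+1), rp(x+2) is zero; zero counts are never replaced by
#' pseudocounts, which would change the statistic.
#'
#' @param rm integer vector, CMC-minus pileup.
#' @param rp integer vector, CMC-plus pileup (same length).
#' @param x position(s); requires `x + 2 <= length(rm)`.
#' @return Numeric score(s); `NA` where undefined.
#' @examples
#' psi_score(c(100, 100, 100), c(50, 100, 100), 1)   # 50
#' @export
psi_score <- function(rm, rp, x) {
  stopifnot(length(rm) == length(rp))
  if (any(x < 1) || any(x + 2 > length(rm)))
    stop("x out of range: the score needs positions x..x+2")
  den_ok <- rm[x + 1] > 0 & rm[x + 2] > 0 & rp[x + 1] > 0 & rp[x + 2] > 0
  s <- ((rm[x] / rm[x + 1] - rp[x] / rp[x + 1]) -
          (rm[x + 1] / rm[x + 2] - rp[x + 1] / rp[x + 2])) * 100
  ifelse(den_ok, s, NA_real_)
}

#' Psi-score track over a whole reference
#'
#' @inheritParams psi_score
#' @return Numeric vector of length `length(rm)`; positions that cannot
#'   host the score (the last two) are `NA`.
#' @export
psi_score_track <- function(rm, rp) {
  L <- length(rm)
  out <- rep(NA_real_, L)
  if (L >= 3) out[1:(L - 2)] <- psi_score(rm, rp, 1:(L - 2))
  out
}

#' Average per-replicate Psi-score tracks into a final track
#'
#' The final score at a position is the arithmetic mean over replicates
#' and is defined only where the score is defined in every replicate.
#'
#' @param tracks list of per-replicate score vectors (equal length).
#' @return Numeric vector of final scores.
#' @export
finalize_scores <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  m <- do.call(cbind, tracks)
  out <- rowMeans(m)
  out[apply(m, 1, anyNA)] <- NA_real_
  out
}

#' Call Psi sites from a final score track
#'
#' Positions at or above the threshold are called, optionally restricted
#' to reference U positions, excluding positions within 3 nt of the 3'
#' end (the score needs x+2, and 3'-terminal Psi is undetectable by this
#' assay). A minimum-coverage gate requires at least `min_cov` reads at
#' x+2 in both samples (all replicates) so that calls are not made from
#' near-empty denominators.
#'
#' @param final final score vector (from [finalize_scores()] or
#'   [psi_score_track()]).
#' @param threshold calling threshold on the score scale (default 10).
#' @param is_u optional logical vector: is the reference base U?
#' @param pileups optional list of per-replicate `list(rm=, rp=)` used
#'   for the coverage gate.
#' @param min_cov minimum reads at x+2 in both samples (default 20).
#' @return Integer vector of called positions (1-based), sorted by
#'   decreasing score.
#' @export
call_psi_sites <- function(final, threshold = 10, is_u = NULL,
                           pileups = NULL, min_cov = 20) {
  stopifnot(!is.na(threshold))  # +Inf is allowed and calls nothing
  L <- length(final)
  ok <- !is.na(final) & final >= threshold
  ok[seq_len(L) > L - 3L] <- FALSE
  if (!is.null(is_u)) ok <- ok & is_u
  if (!is.null(pileups)) {
    x <- seq_len(L)
    covok <- rep(TRUE, L)
    for (p in pileups) {
      cv <- x + 2 <= L
      cv[cv] <- p$rm[x[cv] + 2] >= min_cov & p$rp[x[cv] + 2] >= min_cov
      covok <- covok & cv
    }
    ok <- ok & covok
  }
  sites <- which(ok)
  sites[order(final[sites], decreasing = TRUE)]
}

#' Full Psi-seq analysis from replicate read tables
#'
#' Convenience wrapper: filters reads, builds CMC-minus/plus pileups per
#' replicate, scores each replicate and averages them.
#'
#' @param replicates list of replicates, each `list(minus=, plus=)`
#'   read data.frames (see [filter_reads()] for columns).
#' @param annotation annotation data.frame (one row per reference).
#' @param ref reference id to analyse.
#' @return A list with `final` (score track), `per_replicate` (score
#'   vectors), `pileups` (per replicate `list(rm, rp)`).
#' @export
psi_seq_analysis <- function(replicates, annotation, ref) {
  L <- annotation$length[match(ref, annotation$ref)]
  pileups <- lapply(replicates, function(rep) {
    fm <- filter_reads(rep$minus[rep$minus$ref == ref, ], annotation)
    fp <- filter_reads(rep$plus[rep$plus$ref == ref, ], annotation)
    list(rm = build_pileup(fm, L), rp = build_pileup(fp, L))
  })
  per_rep <- lapply(pileups, function(p) psi_score_track(p$rm, p$rp))
  list(final = finalize_scores(per_rep), per_replicate = per_rep,
       pileups = pileups)
}
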