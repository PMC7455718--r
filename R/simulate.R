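# Seeded synthetic-data generators for the three analysis stages. Each
# generator is bit-reproducible under a fixed seed and returns the truth
# needed by recovery tests alongside the simulated observations.

#' Simulate an LC-MS peak list from a digest with known site stoichiometry
#'
#' The reference sequence is digested (complete digest, linear
#' 3'-phosphate products) and every zero-missed fragment is expanded
#' into its modification isoforms at the variable sites it covers.
#' Isoform intensities are proportional to the product of per-site
#' frequencies, with optional multiplicative log-normal noise; peaks
#' are emitted at the theoretical negative-mode m/z of each isoform.
#'
#' @param seq reference [mod_seq()] with variable sites at their parent
#'   (unmodified) base.
#' @param site_freqs data.frame with columns `position`, `isoform`
#'   (residue short name whose parent matches the reference base) and
#'   `freq` in [0, 1].
#' @param rule a [cleavage_rule()]; cyclic variants are not emitted.
#' @param charge charge state of the emitted peaks.
#' @param base_intensity total intensity per fragment.
#' @param cv multiplicative intensity coefficient of variation (0 = no
#'   noise).
#' @param seed random seed (fixes the output bit-for-bit).
#' @return A list: `peaks` (data.frame `mz`, `z`, `intensity`),
#'   `truth` (the input `site_freqs`), `isoforms` (per-peak bookkeeping:
#'   fragment span, modified positions carried).
#' @export
simulate_ms_peaks <- function(seq, site_freqs, rule = rnase_rule("A"),
                              charge = 2L, base_intensity = 100,
                              cv = 0, seed = 1L) {
  stopifnot(all(site_freqs$freq >= 0 & site_freqs$freq <= 1))
  set.seed(seed)
  rule$cyclic <- FALSE
  frags <- digest_sequence(seq, rule, max_missed = 0L)
  peaks <- list(); iso <- list()
  for (i in seq_len(nrow(frags))) {
    fr <- frags[i, ]
    sites <- site_freqs[site_freqs$position >= fr$start &
                          site_freqs$position <= fr$end, , drop = FALSE]
    combos <- if (nrow(sites) == 0) list(integer(0)) else
      unlist(lapply(0:nrow(sites), function(k)
        utils::combn(seq_len(nrow(sites)), k, simplify = FALSE)),
        recursive = FALSE)
    for (on in combos) {
      fs <- fragment_seq(seq, fr)
      prob <- 1
      modded <- integer(0)
      for (j in seq_len(nrow(sites))) {
        if (j %in% on) {
          fs$residues[sites$position[j] - fr$start + 1L] <- sites$isoform[j]
          prob <- prob * sites$freq[j]
          modded <- c(modded, sites$position[j])
        } else prob <- prob * (1 - sites$freq[j])
      }
      if (prob == 0) next
      intensity <- base_intensity * prob
      if (cv > 0) intensity <- intensity *
          exp(stats::rnorm(1, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2))))
      peaks[[length(peaks) + 1L]] <- data.frame(
        mz = ion_mz(oligo_neutral_mass(fs), charge), z = charge,
        intensity = intensity)
      iso[[length(iso) + 1L]] <- data.frame(
        start = fr$start, end = fr$end,
        modified_positions = paste(modded, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  list(peaks = do.call(rbind, peaks), truth = site_freqs,
       isoforms = do.call(rbind, iso))
}

#' Simulate CMC-plus / CMC-minus read tables with RT drop-off at Psi
#'
#' Reads start at the 3' end of the tRNA (always overlapping the CCA)
#' and extend 5'-ward. Extension into each next position fails with the
#' baseline drop-off probability in both samples, and additionally with
#' `stop_prob` when the next position is a Psi site in the CMC-plus
#' sample only, leaving the read 5' end immediately 3' of the Psi.
#'
#' @param ref_length tRNA reference length (CCA at the last 3 nt).
#' @param psi_sites integer positions of Psi residues.
#' @param stop_prob CMC-specific termination probability at a Psi site.
#' @param baseline_dropoff per-position baseline termination probability.
#' @param n_reads reads per sample.
#' @param seed random seed.
#' @param ref reference id recorded in the read tables.
#' @return A list with `minus` and `plus` read data.frames (`ref`,
#'   `start`, `end`, `mm0`, `mm1`, `paired`) and `truth` (the Psi
#'   sites).
#' @export
simulate_psiseq_reads <- function(ref_length, psi_sites, stop_prob = 0.4,
                                  baseline_dropoff = 0.005,
                                  n_reads = 50000L, seed = 1L,
                                  ref = "tRNA") {
  stopifnot(stop_prob >= 0, stop_prob <= 1,
            baseline_dropoff >= 0, baseline_dropoff <= 1,
            all(psi_sites >= 1 & psi_sites <= ref_length))
  set.seed(seed)
  L <- ref_length
  five_prime_dist <- function(cmc_plus) {
    # q[k]: probability that extension into position k fails
    q <- rep(baseline_dropoff, L)
    if (cmc_plus && length(psi_sites))
      q[psi_sites] <- 1 - (1 - baseline_dropoff) * (1 - stop_prob)
    # P(5' = m): survive extension into L-1..m, then fail into m-1
    surv <- rev(cumprod(rev(1 - q[seq_len(L - 1)])))  # surv[m] = prod_{j=m}^{L-1}(1-q_j)
    p <- numeric(L)
    p[1] <- surv[1]
    if (L > 1) p[2:L] <- c(surv[2:(L - 1)], 1) * q[1:(L - 1)]
    p
  }
  draw <- function(cmc_plus) {
    p <- five_prime_dist(cmc_plus)
    s <- sample.int(L, n_reads, replace = TRUE, prob = p)
    data.frame(ref = ref, start = s, end = L, mm0 = 0L, mm1 = 0L,
               paired = 1L, stringsAsFactors = FALSE)
  }
  list(minus = draw(FALSE), plus = draw(TRUE), truth = sort(psi_sites))
}

#' Deterministic toy mitochondrial transcriptome
#'
#' A small set of synthetic protein-coding transcripts respecting the
#' vertebrate mitochondrial genetic code: each CDS starts with AUG, ends
#' with UAA, and draws its internal codons uniformly from the sense
#' codons; UTRs are long enough for any 23-34-nt footprint whose A site
#' lies in the CDS.
#'
#' @param n_genes number of transcripts (default 13, the mtDNA-encoded
#'   protein count).
#' @param n_codons CDS codons per transcript (including start and stop).
#' @param utr5,utr3 UTR lengths in nt.
#' @param seed random seed.
#' @return A list of [transcript_model()]s.
#' @export
make_toy_transcriptome <- function(n_genes = 13L, n_codons = 120L,
                                   utr5 = 20L, utr3 = 25L, seed = 101L) {
  set.seed(seed)
  code <- mito_genetic_code()
  sense <- names(code)[code != "*" & names(code) != "AUG"]
  lapply(seq_len(n_genes), function(g) {
    cds <- c("AUG", sample(sense, n_codons - 2L, replace = TRUE), "UAA")
    bases <- c("A", "C", "G", "U")
    seqs <- paste0(paste(sample(bases, utr5, TRUE), collapse = ""),
                   paste(cds, collapse = ""),
                   paste(sample(bases, utr3, TRUE), collapse = ""))
    transcript_model(sprintf("MT-G%02d", g), seqs,
                     cds_start = utr5 + 1L,
                     cds_end = utr5 + 3L * n_codons)
  })
}

#' Simulate mitoribosome footprints with codon-dependent dwell weights
#'
#' A-site codons are drawn with probability proportional to the dwell
#' weight of their codon identity (uniform weight 1 unless overridden);
#' footprint lengths are uniform over 23-34 nt and 5' positions are
#' back-computed through the length-dependent A-site offset.
#'
#' @param transcripts list of [transcript_model()]s.
#' @param dwell named numeric vector of codon dwell weights (> 0);
#'   unnamed codons get weight 1.
#' @param n number of footprints.
#' @param seed random seed.
#' @return A list with `footprints` (data.frame `transcript`, `pos5`,
#'   `length`) and `truth` (the dwell weights used, all codons).
#' @export
simulate_footprints <- function(transcripts, dwell = numeric(), n = 200000L,
                                seed = 1L) {
  stopifnot(all(dwell > 0))
  set.seed(seed)
  pool <- do.call(rbind, lapply(transcripts, function(tm) {
    data.frame(transcript = tm$id, codon_index = seq_len(tm$n_codons) - 1L,
               codon = tm$codons, cds_start = tm$cds_start,
               tlen = nchar(tm$sequence), stringsAsFactors = FALSE)
  }))
  # interior codons only, so every footprint length fits in the UTRs
  pool <- pool[pool$codon_index > 0 & pool$codon_index < (
    stats::ave(pool$codon_index, pool$transcript, FUN = max)), , drop = FALSE]
  w <- rep(1, nrow(pool))
  hit <- pool$codon %in% names(dwell)
  w[hit] <- dwell[pool$codon[hit]]
  if (n == 0L)
    return(list(footprints = data.frame(transcript = character(),
                                        pos5 = integer(), length = integer()),
                truth = dwell))
  pick <- sample.int(nrow(pool), n, replace = TRUE, prob = w)
  len <- sample(23:34, n, replace = TRUE)
  asite <- pool$cds_start[pick] + 3L * pool$codon_index[pick]
  pos5 <- asite - asite_offset(len)
  fp <- data.frame(transcript = pool$transcript[pick], pos5 = pos5,
                   length = len, stringsAsFactors = FALSE)
  ok <- fp$pos5 >= 1 & fp$pos5 + fp$length - 1 <= pool$tlen[pick]
  list(footprints = fp[ok, , drop = FALSE], truth = dwell)
}
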