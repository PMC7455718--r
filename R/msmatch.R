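# Assignment of observed negative-mode peaks to theoretical fragments,
# CID product-ion prediction, modification localization, site-frequency
# quantification from XIC intensities, and charge-series deconvolution.

#' Default library of single modification mass deltas
#'
#' Deltas searched on top of the catalog's fragment masses when a peak
#' does not match an unmodified fragment directly. One delta per
#' fragment, matching the study design of assigning fragments by the
#' difference between observed and calculated m/z.
#'
#' @return A data.frame with columns `name`, `formula`.
#' @export
delta_library <- function() {
  data.frame(
    name = c("methyl", "dimethyl", "cyanoethyl", "isopentenyl",
             "thio", "dihydro", "formyl"),
    formula = c("CH2", "C2H4", "C3H3N", "C5H8", "S-O", "H2", "CO"),
    stringsAsFactors = FALSE)
}

#' Assign observed peaks to theoretical fragments
#'
#' Each peak is compared against every catalog row (at the peak's charge
#' if known, otherwise all charges), both unshifted and shifted by each
#' single delta in the library. Matches within `tol_ppm` are returned,
#' sorted per peak by absolute ppm error then fragment start, so the
#' result is invariant under peak-list permutation. Unmatched peaks are
#' reported with `matched = FALSE`.
#'
#' @param peaks data.frame with columns `mz`, `intensity` and optionally
#'   `z` (NA allowed) and `rt`.
#' @param catalog a [fragment_catalog()].
#' @param tol_ppm matching tolerance in ppm (> 0), default 10.
#' @param deltas a delta library as from [delta_library()], or `NULL`
#'   to match unmodified fragments only.
#' @param mode mass mode used for delta masses (must match the catalog).
#' @return A data.frame with one row per (peak, candidate) match plus
#'   one row (`matched = FALSE`) per unmatched peak: columns `peak`,
#'   `mz`, `z`, `intensity`, `matched`, `start`, `end`, `residues`,
#'   `three_prime`, `delta`, `ppm`.
#' @export
assign_peaks <- function(peaks, catalog, tol_ppm = 10, deltas = delta_library(),
                         mode = c("mono", "average")) {
  mode <- match.arg(mode)
  stopifnot(tol_ppm > 0, all(c("mz", "intensity") %in% names(peaks)))
  if (is.null(peaks$z)) peaks$z <- NA_integer_
  dnames <- c("", if (!is.null(deltas)) deltas$name)
  dmass <- c(0, if (!is.null(deltas))
    vapply(deltas$formula, function(f) formula_mass(parse_formula(f), mode),
           numeric(1)))
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    cand <- if (is.na(p$z)) catalog else catalog[catalog$charge == p$z, ]
    hits <- list()
    for (d in seq_along(dnames)) {
      mz_theo <- ion_mz(cand$neutral_mass + dmass[d], cand$charge)
      ppm <- (p$mz - mz_theo) / mz_theo * 1e6
      sel <- which(abs(ppm) <= tol_ppm)
      if (length(sel))
        hits[[length(hits) + 1L]] <- data.frame(
          peak = i, mz = p$mz, z = cand$charge[sel],
          intensity = p$intensity, matched = TRUE,
          start = cand$start[sel], end = cand$end[sel],
          residues = cand$residues[sel],
          three_prime = cand$three_prime[sel],
          delta = dnames[d], ppm = ppm[sel], stringsAsFactors = FALSE)
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      h <- h[order(abs(h$ppm), h$start), , drop = FALSE]
      out[[i]] <- h
    } else {
      out[[i]] <- data.frame(peak = i, mz = p$mz, z = p$z,
                             intensity = p$intensity, matched = FALSE,
                             start = NA_integer_, end = NA_integer_,
                             residues = NA_character_,
                             three_prime = NA_character_,
                             delta = NA_character_, ppm = NA_real_,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- CID product ions ------------------------------------------------------

#' Predict CID product-ion series for a fragment
#'
#' For an n-mer precursor, each backbone cleavage k = 1..n-1 yields one
#' ion per series. The c ion is the 5' piece with a 3'-phosphate; y is
#' the 3' piece with a 5'-hydroxyl; w is the 3' piece with a
#' 5'-phosphate; a-B is the 5' piece cleaved at the 3' C-O bond with
#' neutral loss of the 3'-terminal nucleobase. c and y satisfy
#' mass(c_k) + mass(y_(n-k)) = M + H2O for every k.
#'
#' @param frag a [mod_seq()] of length >= 2 (the precursor).
#' @param max_charge maximum charge state per ion.
#' @param mode `"mono"` or `"average"`.
#' @return A data.frame with columns `series`, `index` (k), `charge`,
#'   `neutral_mass`, `mz`.
#' @export
cid_product_ions <- function(frag, max_charge = 1L,
                             mode = c("mono", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frag, "mod_seq"))
  n <- length(frag$residues)
  if (n < 2L) stop("CID requires a fragment of length >= 2")
  rows <- list()
  h2o <- formula_mass(formula(H = 2, O = 1), mode)
  for (k in seq_len(n - 1L)) {
    five <- mod_seq(frag$residues[1:k], id = "5p",
                    five_prime = frag$five_prime, three_prime = "p")
    y3 <- mod_seq(frag$residues[(k + 1):n], id = "3p",
                  five_prime = "OH", three_prime = frag$three_prime)
    w3 <- y3; w3$five_prime <- "p"
    c_mass <- oligo_neutral_mass(five, mode)
    y_mass <- oligo_neutral_mass(y3, mode)
    w_mass <- oligo_neutral_mass(w3, mode)
    # a ion: 5' piece without the bridging 3'-O (c - HPO3 - H2O);
    # a-B additionally loses the 3'-terminal nucleobase (with its base
    # modification, if any) as a neutral.
    hpo3 <- formula_mass(formula(H = 1, O = 3, P = 1), mode)
    a_mass <- c_mass - hpo3 - h2o
    res_k <- frag$residues[k]
    base <- residue_parent(res_k)
    base_fm <- .PARENT_BASE[[base]] +
      (residue_formula(res_k) - .PARENT_NUCLEOSIDE[[base]])
    ab_mass <- a_mass - formula_mass(base_fm, mode)
    rows[[length(rows) + 1L]] <- data.frame(
      series = c("c", "y", "w", "a-B"),
      index = c(k, n - k, n - k, k),
      neutral_mass = c(c_mass, y_mass, w_mass, ab_mass),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[rep(seq_len(nrow(tab)), each = max_charge), , drop = FALSE]
  tab$charge <- rep(seq_len(max_charge), nrow(tab) / max_charge)
  tab$mz <- ion_mz(tab$neutral_mass, tab$charge)
  rownames(tab) <- NULL
  tab
}

#' Localize a mass delta within a fragment from CID evidence
#'
#' For each candidate position of the fragment, the full c/y (and
#' optionally w and a-B) ladders are predicted with the delta placed at
#' that position, and scored by the number of observed product ions
#' matched within `tol_ppm`. The best-scoring position is returned;
#' ties (evidence not covering both flanks) are reported as an
#' ambiguous set, with the 5'-most position as the point call.
#'
#' @param frag a [mod_seq()] precursor (unshifted residues).
#' @param delta delta formula string (e.g. `"CH2"`).
#' @param observed data.frame of observed product ions with columns
#'   `mz` and optionally `z` (default 1).
#' @param tol_ppm product-ion tolerance in ppm.
#' @param candidates candidate positions within the fragment; default
#'   all positions.
#' @param series ion series used for scoring; default `c("c", "y")`.
#' @param max_charge product-ion charge states to predict.
#' @param mode mass mode.
#' @return A list with `position` (best, 5'-most on ties), `ambiguous`
#'   (all tied positions), `scores` (matched-ion count per candidate).
#' @export
localize_modification <- function(frag, delta, observed, tol_ppm = 10,
                                  candidates = NULL, series = c("c", "y"),
                                  max_charge = 1L,
                                  mode = c("mono", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frag, "mod_seq"))
  n <- length(frag$residues)
  if (is.null(candidates)) candidates <- seq_len(n)
  if (!length(candidates)) stop("no candidate position for the delta")
  if (length(candidates) == 1L)
    return(list(position = candidates, ambiguous = candidates,
                scores = stats::setNames(NA_real_, candidates)))
  dmass <- formula_mass(parse_formula(delta), mode)
  zobs <- if (is.null(observed$z)) rep(1L, nrow(observed)) else observed$z
  scores <- vapply(candidates, function(pos) {
    ions <- cid_product_ions(frag, max_charge = max_charge, mode = mode)
    ions <- ions[ions$series %in% series, , drop = FALSE]
    # shift every ion whose piece contains the candidate position
    contains <- ifelse(ions$series %in% c("c", "a-B"),
                       ions$index >= pos, ions$index > n - pos)
    ions$mz <- ion_mz(ions$neutral_mass + ifelse(contains, dmass, 0),
                      ions$charge)
    matched <- vapply(seq_len(nrow(observed)), function(i) {
      sel <- ions$charge == zobs[i]
      any(abs((observed$mz[i] - ions$mz[sel]) / ions$mz[sel]) * 1e6 <=
            tol_ppm)
    }, logical(1))
    sum(matched)
  }, numeric(1))
  best <- max(scores)
  tied <- candidates[scores == best]
  list(position = min(tied), ambiguous = tied,
       scores = stats::setNames(scores, candidates))
}

# ---- site frequency --------------------------------------------------------

#' Per-site modification frequency from summed peak intensities
#'
#' The frequency of an isoform at a site is its summed intensity divided
#' by the summed intensity of all isoforms covering the site (the XIC
#' ratio). A pooling map merges chemically interconverted pairs before
#' normalization, e.g. `c(m6A = "m1A")` pools the Dimroth-rearranged m6A
#' signal into m1A.
#'
#' @param assignments data.frame with columns `trna`, `position`,
#'   `isoform`, `intensity`.
#' @param pooling named character vector mapping isoform labels to the
#'   label their intensity is pooled into; default pools m6A into m1A.
#' @return A data.frame `trna`, `position`, `isoform`, `intensity`,
#'   `frequency`; frequencies over each site sum to 1. Sites whose total
#'   intensity is zero get `NA` frequency.
#' @examples
#' x <- data.frame(trna = "Cys", position = 52,
#'                 isoform = c("m1A", "unmodified"), intensity = c(17, 83))
#' site_frequency(x)   # m1A frequency 0.17
#' @export
site_frequency <- function(assignments, pooling = c(m6A = "m1A")) {
  req <- c("trna", "position", "isoform", "intensity")
  stopifnot(all(req %in% names(assignments)))
  a <- assignments
  if (length(pooling)) {
    hit <- a$isoform %in% names(pooling)
    a$isoform[hit] <- pooling[a$isoform[hit]]
  }
  agg <- stats::aggregate(intensity ~ trna + position + isoform, data = a,
                          FUN = sum)
  tot <- stats::aggregate(intensity ~ trna + position, data = agg, FUN = sum)
  names(tot)[3] <- "total"
  out <- merge(agg, tot, by = c("trna", "position"), sort = TRUE)
  out$frequency <- ifelse(out$total > 0, out$intensity / out$total, NA_real_)
  out$total <- NULL
  out[order(out$trna, out$position, -out$intensity), , drop = FALSE]
}

#' Quantify site stoichiometry from a peak list against a reference
#'
#' End-to-end XIC-ratio quantification: the reference sequence is
#' digested (complete digest, linear products), each fragment covering
#' candidate modification sites is expanded into its modification
#' isoform combinations, observed peaks are matched to isoform m/z
#' within `tol_ppm`, and per-site frequencies are computed as summed
#' matched intensity of isoforms carrying the site modification over
#' the summed intensity of all isoforms of fragments covering the site.
#'
#' @param peaks data.frame `mz`, `z`, `intensity`.
#' @param refseq reference [mod_seq()] with candidate sites at their
#'   parent base.
#' @param sites data.frame `position`, `isoform` (candidate residue
#'   short names).
#' @param rule a [cleavage_rule()].
#' @param tol_ppm matching tolerance.
#' @param mode mass mode.
#' @return A data.frame `trna`, `position`, `isoform`, `frequency`.
#' @export
quantify_site_frequencies <- function(peaks, refseq, sites,
                                      rule = rnase_rule("A"), tol_ppm = 10,
                                      mode = c("mono", "average")) {
  mode <- match.arg(mode)
  rule$cyclic <- FALSE
  frags <- digest_sequence(refseq, rule, max_missed = 0L)
  rows <- list()
  for (i in seq_len(nrow(frags))) {
    fr <- frags[i, ]
    ss <- sites[sites$position >= fr$start & sites$position <= fr$end, ,
                drop = FALSE]
    if (nrow(ss) == 0) next
    combos <- unlist(lapply(0:nrow(ss), function(k)
      utils::combn(seq_len(nrow(ss)), k, simplify = FALSE)),
      recursive = FALSE)
    for (on in combos) {
      fs <- fragment_seq(refseq, fr)
      fs$residues[ss$position[on] - fr$start + 1L] <- ss$isoform[on]
      m <- oligo_neutral_mass(fs, mode)
      mz_theo <- ion_mz(m, peaks$z)
      hit <- abs((peaks$mz - mz_theo) / mz_theo) * 1e6 <= tol_ppm
      inten <- sum(peaks$intensity[hit])
      for (j in seq_len(nrow(ss)))
        rows[[length(rows) + 1L]] <- data.frame(
          trna = refseq$id, position = ss$position[j],
          isoform = if (j %in% on) ss$isoform[j] else "unmodified",
          intensity = inten, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(trna = character(), position = integer(),
                      isoform = character(), frequency = numeric()))
  site_frequency(do.call(rbind, rows), pooling = NULL)
}

# ---- whole-molecule deconvolution ------------------------------------------

#' Deconvolute a multiply charged negative-ion series to a neutral mass
#'
#' Each ion contributes M_i = z_i * (m/z)_i + z_i * 1.007276; the result
#' is the intensity-weighted mean and the (unweighted) standard
#' deviation of the per-ion masses. When charges are unknown, the
#' consecutive integer charge assignment (descending with m/z) that
#' minimizes the mass spread is inferred.
#'
#' @param ions data.frame with columns `mz`, `intensity` and optionally
#'   `z` (all-NA allowed).
#' @param z_range candidate charge range searched during inference.
#' @return A list with `mass` (weighted mean), `sd`, `masses` (per ion),
#'   `z` (charges used).
#' @export
deconvolute_neutral_mass <- function(ions, z_range = 1:40) {
  stopifnot(nrow(ions) >= 1, all(c("mz", "intensity") %in% names(ions)))
  if (!is.null(ions$z) && !all(is.na(ions$z))) {
    z <- ions$z
  } else {
    # consecutive charges, increasing as m/z decreases: the highest-m/z
    # ion gets the lowest charge of the run
    ord <- order(ions$mz, decreasing = TRUE)
    n <- nrow(ions)
    best <- NULL
    for (z_lo in z_range) {
      z_assign <- integer(n)
      z_assign[ord] <- z_lo + (seq_len(n) - 1L)
      m <- z_assign * ions$mz + z_assign * PROTON_MASS
      spread <- if (n > 1) stats::sd(m) else 0
      if (is.null(best) || spread < best$spread)
        best <- list(z = z_assign, spread = spread)
    }
    z <- best$z
  }
  masses <- z * ions$mz + z * PROTON_MASS
  list(mass = sum(masses * ions$intensity) / sum(ions$intensity),
       sd = if (length(masses) > 1) stats::sd(masses) else 0,
       masses = masses, z = z)
}
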