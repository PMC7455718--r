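# In-silico RNase digestion of modified RNA sequences.
#
# RNase T1 cleaves 3' of guanosine; RNase A cleaves 3' of pyrimidines.
# Products carry 5'-hydroxyl and 3'-phosphate (or 2',3'-cyclic phosphate)
# groups; the parent's own termini are inherited by the terminal fragments.

#' Define a cleavage rule
#'
#' @param enzyme rule name.
#' @param cleave_after residue short names cleaved 3' of.
#' @param blocked modified residues that resist cleavage (disjoint from
#'   `cleave_after`).
#' @param cyclic also emit 2',3'-cyclic phosphate (>p) variants of each
#'   3'-phosphate fragment?
#' @return An object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(enzyme, cleave_after, blocked = character(),
                          cyclic = TRUE) {
  if (length(intersect(cleave_after, blocked)))
    stop("cleaved and blocked sets must be disjoint")
  structure(list(enzyme = enzyme, cleave_after = cleave_after,
                 blocked = blocked, cyclic = cyclic),
            class = "cleavage_rule")
}

#' Built-in RNase T1 and RNase A rules
#'
#' T1 cleaves 3' of G (queuosine included; base-methylated G assumed
#' resistant). RNase A cleaves 3' of pyrimidines, including their
#' modified forms. Both emit cyclic-phosphate variants by default.
#' Enzyme behaviour on modified residues is configurable via
#' [cleavage_rule()] since it is an assumption, not a measured fact.
#'
#' @param enzyme `"T1"` or `"A"`.
#' @param cyclic emit >p variants?
#' @return A `cleavage_rule`.
#' @export
rnase_rule <- function(enzyme = c("T1", "A"), cyclic = TRUE) {
  enzyme <- match.arg(enzyme)
  if (enzyme == "T1") {
    cleavage_rule("T1", cleave_after = c("G", "Q", "ceQ"),
                  blocked = c("m1G", "m2G", "m22G"), cyclic = cyclic)
  } else {
    cleavage_rule("A",
                  cleave_after = c("C", "U", "Y", "ce1Y", "m5C", "f5C",
                                   "m3C", "m5U", "D", "s2U", "tm5U",
                                   "tm5s2U", "cmnm5U", "cmnm5s2U",
                                   "cetm5U", "cetm5s2U"),
                  cyclic = cyclic)
  }
}

#' Digest a modified sequence in silico
#'
#' Cleavage occurs 3' of every residue in the rule's cleaved set that is
#' not in its blocked set. Internal fragments get 5'-OH and 3'-phosphate;
#' the 5'-terminal fragment inherits the parent 5' chemistry and the
#' 3'-terminal fragment inherits the parent 3' chemistry. When the rule's
#' cyclic flag is set, every 3'-phosphate fragment is also emitted as a
#' 2',3'-cyclic phosphate (>p) variant.
#'
#' @param seq a [mod_seq()].
#' @param rule a [cleavage_rule()].
#' @param max_missed maximum number of missed cleavages (default 0,
#'   a complete digest).
#' @return A data.frame with columns `start`, `end` (1-based inclusive),
#'   `missed`, `five_prime`, `three_prime`, `is_5p_terminal`,
#'   `is_3p_terminal` and `residues` (comma-separated short names).
#' @examples
#' s <- mod_seq(strsplit("AUGCG", "")[[1]], five_prime = "OH")
#' digest_sequence(s, rnase_rule("T1", cyclic = FALSE))
#' @export
digest_sequence <- function(seq, rule, max_missed = 0L) {
  stopifnot(inherits(seq, "mod_seq"), inherits(rule, "cleavage_rule"),
            max_missed >= 0L)
  n <- length(seq$residues)
  if (n == 0L) stop("empty sequence")
  cut_after <- which(seq$residues %in% setdiff(rule$cleave_after,
                                               rule$blocked))
  cut_after <- cut_after[cut_after < n]  # a 3'-terminal site yields no cut
  bounds <- c(0L, cut_after, n)          # fragment k spans bounds[k]+1..bounds[k+1]
  out <- list()
  nfrag <- length(bounds) - 1L
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      is5 <- start == 1L
      is3 <- end == n
      p5 <- if (is5) seq$five_prime else "OH"
      p3 <- if (is3) seq$three_prime else "p"
      out[[length(out) + 1L]] <- data.frame(
        start = start, end = end, missed = m,
        five_prime = p5, three_prime = p3,
        is_5p_terminal = is5, is_3p_terminal = is3,
        residues = paste(seq$residues[start:end], collapse = ","),
        stringsAsFactors = FALSE)
      if (rule$cyclic && p3 == "p") {
        cyc <- out[[length(out)]]
        cyc$three_prime <- "cp"
        out[[length(out) + 1L]] <- cyc
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$three_prime), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "parent_id") <- seq$id
  res
}

#' Materialize one digest fragment as a mod_seq
#'
#' @param seq the parent [mod_seq()].
#' @param frag_row one row of the data.frame from [digest_sequence()].
#' @return A [mod_seq()] with the fragment's terminal chemistry.
#' @export
fragment_seq <- function(seq, frag_row) {
  mod_seq(seq$residues[frag_row$start:frag_row$end],
          id = sprintf("%s:%d-%d%s", seq$id, frag_row$start, frag_row$end,
                       if (frag_row$three_prime == "cp") ">p" else ""),
          five_prime = if (frag_row$five_prime == "p") "p" else "OH",
          three_prime = frag_row$three_prime)
}

#' Theoretical fragment catalog with masses and m/z values
#'
#' Digests a sequence and computes, for every fragment and every charge
#' state 1..`z_max`, the neutral mass and negative-mode m/z. This is the
#' search space for peak assignment.
#'
#' @inheritParams digest_sequence
#' @param z_max maximum charge state (>= 1).
#' @param mode `"mono"` or `"average"` masses.
#' @return A data.frame: fragment columns plus `charge`, `neutral_mass`,
#'   `mz`, ordered by (start, end, charge).
#' @export
fragment_catalog <- function(seq, rule, max_missed = 0L, z_max = 2L,
                             mode = c("mono", "average")) {
  mode <- match.arg(mode)
  stopifnot(z_max >= 1L)
  frags <- digest_sequence(seq, rule, max_missed)
  frags$neutral_mass <- vapply(seq_len(nrow(frags)), function(i)
    oligo_neutral_mass(fragment_seq(seq, frags[i, ]), mode), numeric(1))
  cat <- frags[rep(seq_len(nrow(frags)), each = z_max), , drop = FALSE]
  cat$charge <- rep(seq_len(z_max), nrow(frags))
  cat$mz <- ion_mz(cat$neutral_mass, cat$charge)
  cat <- cat[order(cat$start, cat$end, cat$three_prime, cat$charge), ,
             drop = FALSE]
  rownames(cat) <- NULL
  attr(cat, "parent_id") <- seq$id
  cat
}
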