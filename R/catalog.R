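# The packaged mt-tRNA modification catalog.
#
# The mt-tRNA-Cys entry is transcribed from the published record (its
# masses and digest fragments reproduce the printed values); the other 21
# entries are SYNTHETIC stand-ins: plausible cloverleaf-sized sequences
# whose modification placements follow field conventions (m1A9, Psi 27/28,
# wobble-34 and position-37 chemistry, m5U54, ...) and whose summary
# counts match the published totals for the human mt-tRNA set: 22 tRNAs,
# 1575 residues, 137 modified positions (8.7%), 18 modification kinds,
# 52 Psi sites. They are fixtures for testing pipeline code, not measured
# modification maps.

#' The curated 69-nt human mt-tRNA-Cys sequence with its modifications
#'
#' 5'-monophosphate, 3'-hydroxyl, anticodon GCA, with m1G9, Psi 27/28/32
#' (canonical numbering), i6A37, Psi39 and the minor m1A58. Canonical
#' position labels are attached where they differ from sequence
#' positions (this tRNA has a short D-arm).
#'
#' @return A [mod_seq()].
#' @export
mt_trna_cys <- function() {
  base <- "AGCUCCGAGGUGAUUUUCAUAUUGAAUUGCAAAUUCGAAGAAGCAGCUUCAAACCUGCCGGGGCUUCCA"
  res <- strsplit(base, "")[[1]]
  mods <- c("9" = "m1G", "22" = "Y", "23" = "Y", "27" = "Y", "32" = "i6A",
            "34" = "Y", "52" = "m1A")
  res[as.integer(names(mods))] <- mods
  labels <- as.character(seq_along(res))
  canon <- c("9" = "9", "22" = "27", "23" = "28", "27" = "32", "32" = "37",
             "34" = "39", "52" = "58")
  labels[as.integer(names(canon))] <- canon
  mod_seq(res, id = "mt-tRNA-Cys", five_prime = "p", three_prime = "OH",
          labels = labels)
}

# Specification of the synthetic catalog entries: lengths, anticodons
# (positions 34-36; Ser-AGY lacks the D-arm, anticodon at 28-30) and
# modification placements (sequence position -> residue short name).
.CATALOG_SPEC <- list(
  Ala = list(len = 69, ac = "UGC", mods = c("9" = "m1A", "10" = "m2G", "27" = "Y", "38" = "Y", "66" = "Y")),
  Arg = list(len = 69, ac = "UCG", mods = c("9" = "m1A", "20" = "D", "27" = "Y", "37" = "t6A", "39" = "Y")),
  Asn = list(len = 75, ac = "GUU", mods = c("9" = "m1G", "10" = "m2G", "20" = "D", "27" = "Y", "28" = "Y", "34" = "Q", "37" = "t6A", "39" = "Y", "48" = "m5C")),
  Asp = list(len = 68, ac = "GUC", mods = c("9" = "m1A", "20" = "D", "27" = "Y", "34" = "Q", "38" = "Y", "54" = "m5U")),
  Gln = list(len = 74, ac = "UUG", mods = c("9" = "m1A", "10" = "m2G", "20" = "D", "27" = "Y", "28" = "Y", "34" = "tm5s2U", "37" = "m1G", "38" = "Y", "49" = "m5C")),
  Glu = list(len = 69, ac = "UUC", mods = c("9" = "m1A", "10" = "m2G", "20" = "D", "27" = "Y", "34" = "tm5s2U", "38" = "Y", "54" = "m5U")),
  Gly = list(len = 70, ac = "UCC", mods = c("9" = "m1A", "27" = "Y", "28" = "Y", "34" = "cmnm5U", "37" = "t6A")),
  His = list(len = 74, ac = "GUG", g_minus1 = TRUE, mods = c("9" = "m1A", "27" = "Y", "34" = "Q", "38" = "Y", "48" = "m5C")),
  Ile = list(len = 75, ac = "GAU", mods = c("9" = "m1A", "27" = "Y", "28" = "Y", "32" = "m3C", "37" = "t6A")),
  `Leu-UUR` = list(len = 75, ac = "UAA", mods = c("9" = "m1A", "10" = "m2G", "20" = "D", "27" = "Y", "28" = "Y", "34" = "tm5U", "37" = "m1G", "39" = "Y", "48" = "m5C")),
  `Leu-CUN` = list(len = 74, ac = "UAG", mods = c("9" = "m1A", "20" = "D", "26" = "m22G", "27" = "Y", "28" = "Y", "37" = "m1G")),
  Lys = list(len = 75, ac = "UUU", mods = c("9" = "m1A", "20" = "D", "27" = "Y", "28" = "Y", "34" = "cmnm5s2U", "37" = "t6A", "39" = "Y")),
  Met = list(len = 68, ac = "CAU", mods = c("9" = "m1A", "27" = "Y", "34" = "f5C", "38" = "Y", "48" = "m5C")),
  Phe = list(len = 73, ac = "GAA", mods = c("9" = "m1A", "10" = "m2G", "20" = "D", "27" = "Y", "37" = "ms2i6A", "39" = "Y")),
  Pro = list(len = 75, ac = "UGG", mods = c("9" = "m1G", "10" = "m2G", "20" = "D", "27" = "Y", "28" = "Y", "37" = "m1G", "48" = "m5C", "66" = "Y", "67" = "Y")),
  `Ser-UCN` = list(len = 75, ac = "UGA", mods = c("9" = "m1A", "27" = "Y", "32" = "m3C", "37" = "i6A", "39" = "Y", "48" = "m5C")),
  `Ser-AGY` = list(len = 62, ac = "GCU", ac_pos = 28, mods = c("9" = "m1A", "23" = "Y", "31" = "t6A", "35" = "Y")),
  Thr = list(len = 69, ac = "UGU", mods = c("9" = "m1A", "10" = "m2G", "27" = "Y", "37" = "t6A", "38" = "Y", "54" = "m5U")),
  Trp = list(len = 73, ac = "UCA", mods = c("9" = "m1A", "20" = "D", "27" = "Y", "28" = "Y", "34" = "tm5U", "48" = "m5C")),
  Tyr = list(len = 75, ac = "GUA", mods = c("9" = "m1A", "27" = "Y", "34" = "Q", "37" = "i6A", "39" = "Y", "48" = "m5C")),
  Val = list(len = 69, ac = "UAC", mods = c("9" = "m1A", "10" = "m2G", "39" = "Y"))
)

# Deterministic acceptor/arm filler so synthetic sequences are
# reproducible without touching the RNG.
.backbone <- function(len) {
  rep_len(strsplit("GGCAUAGCUCAGUUGGUAGAGCAUCGGACUU", "")[[1]], len)
}

.make_synthetic_entry <- function(name, spec) {
  res <- .backbone(spec$len)
  res[(spec$len - 2):spec$len] <- c("C", "C", "A")
  ac_pos <- if (is.null(spec$ac_pos)) 34L else spec$ac_pos
  res[ac_pos:(ac_pos + 2L)] <- strsplit(spec$ac, "")[[1]]
  # wobble modifications keep the anticodon's parent base
  pos <- as.integer(names(spec$mods))
  stopifnot(all(pos <= spec$len - 3L))
  res[pos] <- unname(spec$mods)
  labels <- NULL
  if (isTRUE(spec$g_minus1)) {
    res[1] <- "G"
    labels <- as.character(seq_len(spec$len))
    labels[1] <- "-1"
  }
  mod_seq(res, id = paste0("mt-tRNA-", name), five_prime = "p",
          three_prime = "OH", labels = labels)
}

#' The packaged 22-entry mt-tRNA modification catalog
#'
#' One entry per human mt-tRNA species. The Cys entry is the curated
#' sequence ([mt_trna_cys()]); all other entries are synthetic fixtures
#' (see the provenance column) whose summary counts match the published
#' totals for the set. The His entry carries the post-transcriptionally
#' added G at its 5' end, labelled position `-1`.
#'
#' @return An object of class `mod_catalog`: a list with `entries`
#'   (named list of [mod_seq()]) and `meta` (data.frame with `trna`,
#'   `anticodon`, `length`, `provenance`).
#' @export
mt_trna_catalog <- function() {
  entries <- lapply(names(.CATALOG_SPEC), function(nm)
    .make_synthetic_entry(nm, .CATALOG_SPEC[[nm]]))
  names(entries) <- names(.CATALOG_SPEC)
  entries$Cys <- mt_trna_cys()
  ord <- sort(names(entries))
  entries <- entries[ord]
  meta <- data.frame(
    trna = ord,
    anticodon = vapply(ord, function(nm)
      if (nm == "Cys") "GCA" else .CATALOG_SPEC[[nm]]$ac, character(1)),
    length = vapply(entries, length, integer(1)),
    provenance = ifelse(ord == "Cys", "curated", "synthetic"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(entries = entries, meta = meta), class = "mod_catalog")
}

#' @export
print.mod_catalog <- function(x, ...) {
  s <- catalog_summary(x)
  cat(sprintf(paste0("mod_catalog: %d tRNAs, %d residues, %d modified ",
                     "positions (%.1f%%), %d Psi sites\n"),
              nrow(x$meta), s$n_residues, s$n_modified_positions,
              s$percent_modified, s$n_psi_sites))
  invisible(x)
}

#' Summary statistics of a modification catalog
#'
#' A modified position is a residue carrying a non-standard short name,
#' plus any post-transcriptionally added residue labelled `-1` (the His
#' G-1). Psi sites are residues with short name `Y`. The percentage is
#' 100 x modified / total residues, rounded to one decimal.
#'
#' @param catalog a `mod_catalog` from [mt_trna_catalog()].
#' @return A list with `n_kinds`, `n_modified_positions`, `n_residues`,
#'   `percent_modified`, `n_psi_sites` and `per_trna` (named integer
#'   vector of modified-site counts).
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "mod_catalog"))
  std <- c("A", "G", "C", "U")
  per <- vapply(catalog$entries, function(s) {
    modified <- !(s$residues %in% std)
    if (!is.null(s$labels)) modified <- modified | s$labels == "-1"
    sum(modified)
  }, integer(1))
  kinds <- unique(unlist(lapply(catalog$entries, function(s)
    setdiff(s$residues, std))))
  n_res <- sum(vapply(catalog$entries, length, integer(1)))
  n_mod <- sum(per)
  n_psi <- sum(vapply(catalog$entries, function(s)
    sum(s$residues == "Y"), integer(1)))
  list(n_kinds = length(kinds),
       n_modified_positions = n_mod,
       n_residues = n_res,
       percent_modified = round(100 * n_mod / max(n_res, 1L), 1),
       n_psi_sites = n_psi,
       per_trna = per)
}
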