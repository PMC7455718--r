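# Shared I/O: tab-delimited tables with fixed schemas, and modified
# sequences as FASTA (parent letters) plus a sidecar modification TSV.

#' Write a data.frame as a UTF-8 tab-delimited file
#'
#' Header row, no quoting, no row names; the column order of the input
#' is preserved.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-delimited table written by [write_tsv_table()]
#' @param path input path.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read an observed peak list (columns mz, z, intensity, rt)
#'
#' Empty `z` entries mean the charge is unknown and may be inferred
#' downstream.
#'
#' @param path TSV path.
#' @return A data.frame with numeric `mz`, integer `z` (NA allowed),
#'   numeric `intensity`.
#' @export
read_peaks_tsv <- function(path) {
  p <- read_tsv_table(path)
  stopifnot(all(c("mz", "intensity") %in% names(p)))
  if (is.null(p$z)) p$z <- NA_integer_
  p$z <- suppressWarnings(as.integer(p$z))
  stopifnot(all(p$mz > 0), all(p$intensity >= 0))
  p
}

#' Write modified sequences as FASTA plus a modification sidecar TSV
#'
#' The FASTA holds the parent-letter (unmodified) sequences; the sidecar
#' lists one row per modified position: `seq_id`, `position` (1-based),
#' `short_name`.
#'
#' @param seqs list of [mod_seq()].
#' @param fasta_path,mods_path output paths.
#' @export
write_mod_fasta <- function(seqs, fasta_path, mods_path) {
  con <- file(fasta_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  rows <- list()
  for (s in seqs) {
    writeLines(c(paste0(">", s$id),
                 paste(residue_parent(s$residues), collapse = "")), con)
    mod <- which(!(s$residues %in% c("A", "G", "C", "U")))
    if (length(mod))
      rows[[s$id]] <- data.frame(seq_id = s$id, position = mod,
                                 short_name = s$residues[mod],
                                 stringsAsFactors = FALSE)
  }
  write_tsv_table(do.call(rbind, c(rows, list(
    data.frame(seq_id = character(), position = integer(),
               short_name = character())))), mods_path)
  invisible(fasta_path)
}

#' Read modified sequences from FASTA plus a modification sidecar TSV
#'
#' @param fasta_path FASTA of parent-letter sequences.
#' @param mods_path sidecar TSV (`seq_id`, `position`, `short_name`);
#'   `NULL` for none.
#' @param five_prime,three_prime terminal chemistry applied to every
#'   sequence (mature tRNA defaults).
#' @return A named list of [mod_seq()].
#' @export
read_mod_fasta <- function(fasta_path, mods_path = NULL, five_prime = "p",
                           three_prime = "OH") {
  ss <- Biostrings::readBStringSet(fasta_path)
  mods <- if (!is.null(mods_path)) read_tsv_table(mods_path) else NULL
  out <- lapply(seq_along(ss), function(i) {
    id <- names(ss)[i]
    res <- strsplit(chartr("Tt", "Uu", toupper(as.character(ss[[i]]))),
                    "")[[1]]
    if (!is.null(mods)) {
      m <- mods[mods$seq_id == id, , drop = FALSE]
      if (nrow(m)) {
        bad <- residue_parent(m$short_name) != res[m$position]
        if (any(bad))
          stop("modification parent mismatch in ", id, " at position ",
               paste(m$position[bad], collapse = ","))
        res[m$position] <- m$short_name
      }
    }
    mod_seq(res, id = id, five_prime = five_prime,
            three_prime = three_prime)
  })
  names(out) <- names(ss)
  out
}
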