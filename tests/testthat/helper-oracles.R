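# Independent oracles used across the suite. These deliberately do not
# share code paths with the package: masses are summed from their own
# atom tables, digestion is brute-force splitting, and the drop-off
# score is a literal transcription of its defining expression.

# atom-count oracle for oligonucleotide masses
oracle_atoms <- list(
  A = c(C = 10, H = 13, N = 5, O = 4, P = 0, S = 0),
  G = c(C = 10, H = 13, N = 5, O = 5, P = 0, S = 0),
  C = c(C = 9, H = 13, N = 3, O = 5, P = 0, S = 0),
  U = c(C = 9, H = 12, N = 2, O = 6, P = 0, S = 0)
)
oracle_weights <- list(
  mono = c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
           P = 30.973762, S = 31.972071),
  average = c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994,
              P = 30.973762, S = 32.065)
)
# deltas vs parent, duplicated here on purpose
oracle_deltas <- list(
  m1A = c(C = 1, H = 2), m1G = c(C = 1, H = 2), m2G = c(C = 1, H = 2),
  m22G = c(C = 2, H = 4), m3C = c(C = 1, H = 2), m5C = c(C = 1, H = 2),
  m5U = c(C = 1, H = 2), m6A = c(C = 1, H = 2),
  Y = c(), ce1Y = c(C = 3, H = 3, N = 1), D = c(H = 2),
  s2U = c(S = 1, O = -1), i6A = c(C = 5, H = 8),
  ms2i6A = c(C = 6, H = 10, S = 1), t6A = c(C = 5, H = 7, N = 1, O = 4),
  tm5U = c(C = 3, H = 7, N = 1, O = 3, S = 1),
  tm5s2U = c(C = 3, H = 7, N = 1, O = 2, S = 2),
  cmnm5U = c(C = 3, H = 5, N = 1, O = 2),
  cmnm5s2U = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  f5C = c(C = 1, O = 1), Q = c(C = 7, H = 10, O = 2),
  cetm5U = c(C = 6, H = 10, N = 2, O = 3, S = 1),
  cetm5s2U = c(C = 6, H = 10, N = 2, O = 2, S = 2),
  ceQ = c(C = 10, H = 13, N = 1, O = 2)
)
oracle_parent <- c(m1A = "A", m1G = "G", m2G = "G", m22G = "G", m3C = "C",
                   m5C = "C", m5U = "U", m6A = "A", Y = "U", ce1Y = "U",
                   D = "U", s2U = "U", i6A = "A", ms2i6A = "A", t6A = "A",
                   tm5U = "U", tm5s2U = "U", cmnm5U = "U", cmnm5s2U = "U",
                   f5C = "C", Q = "G", cetm5U = "U", cetm5s2U = "U",
                   ceQ = "G", A = "A", G = "G", C = "C", U = "U")

oracle_oligo_mass <- function(residues, p5 = "p", p3 = "OH",
                              mode = "mono") {
  atoms <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  add <- function(a, v) { a[names(v)] <- a[names(v)] + v; a }
  for (r in residues) {
    atoms <- add(atoms, oracle_atoms[[oracle_parent[[r]]]])
    d <- oracle_deltas[[r]]
    if (!is.null(d) && length(d)) atoms <- add(atoms, d)
  }
  n <- length(residues)
  atoms <- add(atoms, c(H = 1 * (n - 1), O = 3 * (n - 1), P = 1 * (n - 1)))
  atoms <- add(atoms, c(H = -2 * (n - 1), O = -1 * (n - 1)))
  if (p5 == "p") atoms <- add(atoms, c(H = 1, O = 3, P = 1))
  if (p3 == "p") atoms <- add(atoms, c(H = 1, O = 3, P = 1))
  if (p3 == "cp") atoms <- add(atoms, c(H = -1, O = 2, P = 1))
  sum(oracle_weights[[mode]][names(atoms)] * atoms)
}

# brute-force digestion oracle: split after every cleavable residue
oracle_digest <- function(residues, cleave_after, blocked = character()) {
  n <- length(residues)
  cuts <- which(residues %in% setdiff(cleave_after, blocked))
  cuts <- cuts[cuts < n]
  bounds <- c(0, cuts, n)
  lapply(seq_len(length(bounds) - 1), function(i)
    (bounds[i] + 1):bounds[i + 1])
}

# literal transcription of the drop-off score expression
oracle_score <- function(rm, rp, x) {
  ((rm[x] / rm[x + 1] - rp[x] / rp[x + 1]) -
     (rm[x + 1] / rm[x + 2] - rp[x + 1] / rp[x + 2])) * 100
}

# random modified sequence over a residue alphabet
random_mod_seq <- function(len, alphabet = c("A", "G", "C", "U"),
                           five_prime = "OH", three_prime = "OH") {
  mod_seq(sample(alphabet, len, replace = TRUE),
          five_prime = five_prime, three_prime = three_prime)
}

# Round-trip quantification fixture: sequences whose RNase A digest has
# exactly one variable methylatable site per informative fragment, with
# distinct fragment m/z so assignment is unambiguous.
make_ms_recovery_fixture <- function(n_sites, seed) {
  set.seed(seed)
  sites_per_seq <- 4L
  n_seq <- ceiling(n_sites / sites_per_seq)
  seqs <- list(); sites <- list()
  made <- 0L
  for (i in seq_len(n_seq)) {
    repeat {
      # blocks of A/G ended by a pyrimidine: each RNase A fragment is
      # A/G run + C or U
      blocks <- lapply(seq_len(sites_per_seq), function(j)
        c("A", sample(c("A", "G"), sample(1:4, 1), replace = TRUE),
          sample(c("C", "U"), 1)))
      res <- unlist(blocks)
      s <- mod_seq(res, id = sprintf("syn%02d", i), five_prime = "OH",
                   three_prime = "OH")
      cat <- fragment_catalog(s, rnase_rule("A", cyclic = FALSE),
                              z_max = 2)
      if (anyDuplicated(round(cat$mz[cat$charge == 2], 3)) == 0) break
    }
    pos <- cumsum(vapply(blocks, length, integer(1)))  # fragment ends
    starts <- c(1L, head(pos, -1) + 1L)
    take <- min(sites_per_seq, n_sites - made)
    site_pos <- vapply(seq_len(take), function(j) {
      cand <- which(res[starts[j]:pos[j]] == "A") + starts[j] - 1L
      if (!length(cand)) NA_integer_ else cand[1]
    }, integer(1))
    ok <- !is.na(site_pos)
    if (any(ok)) {
      sites[[i]] <- data.frame(seq_id = s$id, position = site_pos[ok],
                               isoform = "m1A",
                               freq = round(stats::runif(sum(ok), 0.05,
                                                         0.95), 2))
      made <- made + sum(ok)
    }
    seqs[[s$id]] <- s
    if (made >= n_sites) break
  }
  list(seqs = seqs, sites = do.call(rbind, sites))
}
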