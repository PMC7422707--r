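# Independent oracles used by the property-style tests. Each reimplements
# the quantity under test from first principles, by a different route than
# the package code.

# Brute-force tryptic digestion: find cleavage indices directly, then
# enumerate all runs of <= max_missed + 1 adjacent fragments.
oracle_digest <- function(seq, max_missed) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cuts <- integer(0)
  for (i in seq_len(max(n - 1, 0))) {
    if (res[i] %in% c("K", "R") && res[i + 1] != "P") cuts <- c(cuts, i)
  }
  bounds <- c(0, cuts, n)
  frags <- data.frame(start = head(bounds, -1) + 1, end = bounds[-1])
  out <- list()
  for (i in seq_len(nrow(frags))) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nrow(frags)) break
      out[[length(out) + 1]] <- data.frame(
        start = frags$start[i], end = frags$end[j],
        sequence = substr(seq, frags$start[i], frags$end[j]),
        missed_cleavages = m
      )
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# Atomic-composition peptide mass: count elements per residue, then apply
# atomic masses. Fully independent of the package's residue-mass tables.
AA_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0), A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0), P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0), T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0), N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0), Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0), E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0), R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0), W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)
ATOM_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)
ATOM_AVG <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065)

oracle_mass <- function(seq, type = "monoisotopic") {
  res <- strsplit(seq, "")[[1]]
  comp <- Reduce(`+`, AA_FORMULA[res])
  comp["H"] <- comp["H"] + 2  # terminal water
  comp["O"] <- comp["O"] + 1
  atoms <- if (type == "monoisotopic") ATOM_MONO else ATOM_AVG
  sum(comp * atoms[names(comp)])
}

# Regex motif oracles (perl lookahead handles overlaps).
oracle_motif <- function(seq, third) {
  m <- gregexpr(paste0("S(?=.", third, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

random_peptide <- function(n, alphabet = mepephos:::AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
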