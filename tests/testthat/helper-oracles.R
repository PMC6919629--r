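# Independent reference implementations used only as test oracles.

# Exhaustive window scan for cleavage motifs (no vectorized shortcuts).
oracle_scan_sites <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    if (aa[i] %in% c("K", "R") && aa[i + 1L] %in% c("K", "R"))
      out[[length(out) + 1L]] <- data.frame(kind = "PC", start = i,
                                            end = i + 1L)
  }
  for (i in seq_len(max(n - 3L, 0L))) {
    if (aa[i] == "R" && aa[i + 1L] != "X" &&
        aa[i + 2L] %in% c("K", "R") && aa[i + 3L] == "R")
      out[[length(out) + 1L]] <- data.frame(kind = "FURIN", start = i,
                                            end = i + 3L)
  }
  do.call(rbind, out)
}

# Brute-force global alignment: enumerate every alignment recursively and
# return the maximum score (exponential; use only on short sequences).
oracle_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(x)) return(gap * (length(y) - j + 1L))
    if (j > length(y)) return(gap * (length(x) - i + 1L))
    max(rec(i + 1L, j + 1L) + (if (x[i] == y[j]) match else mismatch),
        rec(i + 1L, j) + gap,
        rec(i, j + 1L) + gap)
  }
  rec(1L, 1L)
}

# Enumerate tryptic peptides by brute force from the cleavage point set.
oracle_digest <- function(sequence, max_missed, suppress_KP = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  if (suppress_KP) cuts <- cuts[aa[cuts + 1L] != "P"]
  bounds <- c(0L, cuts, n)
  peps <- character(0)
  for (i in seq_along(bounds)) {
    for (j in seq_along(bounds)) {
      if (j <= i) next
      if (j - i - 1L > max_missed) next
      peps <- c(peps, paste(aa[(bounds[i] + 1L):bounds[j]], collapse = ""))
    }
  }
  sort(peps)
}

# Random peptide of length n from the 20 canonical residues.
random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random valid distance matrix from points in the plane (generic distances,
# ties almost surely absent).
random_distance_matrix <- function(n_leaves) {
  pts <- matrix(runif(2 * n_leaves), ncol = 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(LETTERS[seq_len(n_leaves)], LETTERS[seq_len(n_leaves)])
  D
}
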