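# Independent longhand oracles, deliberately written with naive loops and no
# shared code with the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column-by-column identity of two equal-length (aligned) sequences:
# matches / columns where neither is a gap; ambiguity never matches.
oracle_identity_aligned <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  n_comp <- 0L; n_match <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") {
      n_comp <- n_comp + 1L
      if (ca[k] == cb[k] && ca[k] %in% AA20) n_match <- n_match + 1L
    }
  }
  if (n_comp == 0L) 0 else n_match / n_comp
}

# Transitive single-linkage clustering at an identity threshold; returns the
# number of clusters (each planted cluster should yield one representative
# under greedy pruning when between-cluster identity is far below threshold).
oracle_identity_clusters <- function(res, threshold) {
  n <- length(res)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && oracle_identity_aligned(res[i], res[j]) > threshold) {
      parent[find(j)] <- find(i)
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Longhand SCA on a small alignment (character matrix), mirroring the
# documented formulas with explicit loops.
oracle_sca <- function(mat, lambda = 1 / nrow(mat), min_sub = 1L) {
  n <- nrow(mat); L <- ncol(mat)
  count_col <- function(col, rows = seq_len(n)) {
    out <- numeric(20)
    for (r in rows) {
      k <- which(AA20 == mat[r, col])
      if (length(k) == 1) out[k] <- out[k] + 1
    }
    out
  }
  pfreq <- function(counts) (counts / sum(counts) + lambda) / (1 + 20 * lambda)
  dir_energy <- matrix(NA_real_, L, L)   # [i, j] = energy of i given dj
  for (j in seq_len(L)) {
    cj <- count_col(j)
    dom <- which.max(cj)
    rows <- which(mat[, j] == AA20[dom])
    if (length(rows) < min_sub) next
    for (i in seq_len(L)) {
      if (i == j) next
      p_full <- pfreq(count_col(i))
      p_sub <- pfreq(count_col(i, rows))
      s <- 0
      for (x in 1:20) s <- s + log(p_sub[x] / p_full[x])^2
      dir_energy[i, j] <- sqrt(s)
    }
  }
  ddg <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    v <- c(dir_energy[i, j], dir_energy[j, i])
    if (!all(is.na(v))) ddg[i, j] <- mean(v, na.rm = TRUE)
  }
  ddg
}

# Longhand per-column conservation energy.
oracle_conservation <- function(column, q, lambda) {
  counts <- numeric(20)
  for (ch in column) {
    k <- which(AA20 == ch)
    if (length(k) == 1) counts[k] <- counts[k] + 1
  }
  p <- (counts / sum(counts) + lambda) / (1 + 20 * lambda)
  s <- 0
  for (x in 1:20) s <- s + log(p[[x]] / q[[x]])^2
  unname(sqrt(s))
}

random_seq <- function(len, gap_rate = 0) {
  ch <- sample(AA20, len, replace = TRUE)
  if (gap_rate > 0) ch[runif(len) < gap_rate] <- "-"
  paste0(ch, collapse = "")
}

# Minimal PDB writer for Calpha-only fixtures (plain text, built at test time).
# Column layout follows the PDB ATOM record; `alt` gives one altloc character
# (or "") per atom.
write_ca_pdb <- function(path, resno, xyz, chain = "A",
                         alt = rep("", length(resno))) {
  alt <- ifelse(nzchar(alt), alt, " ")
  lines <- character(length(resno))
  for (k in seq_along(resno)) {
    lines[k] <- sprintf(
      "ATOM  %5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      k, alt[k], "ALA", chain, resno[k], xyz[k, 1], xyz[k, 2], xyz[k, 3])
  }
  writeLines(c(lines, "END"), path)
  path
}
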