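# Independent brute-force oracles: plain recursive enumeration of all
# pseudoknot-free structures, kept deliberately separate from the
# package's dynamic programmes.

oraclePairEnergy <- function(a, b, sameStrand, allowGU = TRUE,
                             allowGUInter = FALSE) {
  key <- paste(sort(c(a, b)), collapse = "")
  if (key == "CG") return(-3)
  if (key == "AU") return(-2)
  if (key == "GU") {
    if (sameStrand && allowGU) return(-1)
    if (!sameStrand && allowGUInter) return(-1)
  }
  NA_real_
}

# Every nested structure of the given residue/strand vectors, as
# list(pairs = 2-col matrix or NULL, energy =). Exponential; use at
# toy sizes only.
oracleStructures <- function(chars, strand = rep(1L, length(chars)),
                             minHairpin = 3L) {
  ok <- function(i, j) {
    same <- strand[i] == strand[j]
    if (same && j - i <= minHairpin) return(NA_real_)
    oraclePairEnergy(chars[i], chars[j], same)
  }
  rec <- function(i, j) {
    if (i > j) return(list(list(pairs = NULL, energy = 0)))
    out <- rec(i + 1L, j)
    for (k in seq(i + 1L, length.out = max(0L, j - i))) {
      e <- ok(i, k)
      if (is.na(e)) next
      for (inner in rec(i + 1L, k - 1L)) {
        for (outer in rec(k + 1L, j)) {
          out[[length(out) + 1L]] <- list(
            pairs = rbind(inner$pairs, outer$pairs, c(i, k)),
            energy = inner$energy + outer$energy + e)
        }
      }
    }
    out
  }
  rec(1L, length(chars))
}

oracleMFE <- function(seqStr) {
  chars <- strsplit(seqStr, "")[[1]]
  min(vapply(oracleStructures(chars), function(s) s$energy, numeric(1)))
}

# min energy at each count of intermolecular pairs, for a two-strand
# complex (tiny sizes)
oracleProfile <- function(seqA, seqB) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  chars <- c(a, b)
  strand <- rep(1:2, c(length(a), length(b)))
  structs <- oracleStructures(chars, strand)
  rOf <- function(s) {
    if (is.null(s$pairs)) return(0L)
    sum(strand[s$pairs[, 1]] != strand[s$pairs[, 2]])
  }
  r <- vapply(structs, rOf, integer(1))
  e <- vapply(structs, function(s) s$energy, numeric(1))
  tapply(e, r, min)
}

# Boltzmann pairing probabilities by direct enumeration
oraclePairProb <- function(seqA, seqB = NULL, RT = 0.61) {
  a <- strsplit(seqA, "")[[1]]
  chars <- a
  strand <- rep(1L, length(a))
  if (!is.null(seqB)) {
    b <- strsplit(seqB, "")[[1]]
    chars <- c(a, b)
    strand <- c(strand, rep(2L, length(b)))
  }
  structs <- oracleStructures(chars, strand)
  w <- vapply(structs, function(s) exp(-s$energy / RT), numeric(1))
  Z <- sum(w)
  n <- length(chars)
  P <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    prs <- structs[[k]]$pairs
    if (is.null(prs)) next
    for (row in seq_len(nrow(prs))) {
      i <- prs[row, 1]
      j <- prs[row, 2]
      P[i, j] <- P[i, j] + w[k]
      P[j, i] <- P[j, i] + w[k]
    }
  }
  P / Z
}

randomRNA <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
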