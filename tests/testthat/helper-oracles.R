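# Independent oracles used across the suite.  These deliberately share
# no code with the package implementation paths they check.

# quadratic-space affine-gap Smith-Waterman score (gap of length L costs
# open + L * ext)
sw_score_oracle <- function(a, b, mat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
    F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]], E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# grid-search isoelectric point: minimises |net charge| over a 0.001 pH
# grid with an independently written Henderson-Hasselbalch sum
pi_grid_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  nK <- sum(ch == "K"); nR <- sum(ch == "R"); nH <- sum(ch == "H")
  nD <- sum(ch == "D"); nE <- sum(ch == "E"); nC <- sum(ch == "C")
  nY <- sum(ch == "Y")
  grid <- seq(0, 14, by = 0.001)
  charge <- sapply(grid, function(ph) {
    pos <- 1 / (1 + 10^(ph - 7.5)) + nK / (1 + 10^(ph - 10)) +
      nR / (1 + 10^(ph - 12)) + nH / (1 + 10^(ph - 5.98))
    neg <- 1 / (1 + 10^(3.55 - ph)) + nD / (1 + 10^(4.05 - ph)) +
      nE / (1 + 10^(4.45 - ph)) + nC / (1 + 10^(9 - ph)) +
      nY / (1 + 10^(10 - ph))
    pos - neg
  })
  grid[which.min(abs(charge))]
}

# exhaustive longest strictly-monotone chain length over anchor rank
# pairs (both orientations tried), by depth-first enumeration; n <= 12
max_chain_oracle <- function(ra, rb) {
  n <- length(ra)
  best <- 0L
  chase <- function(dir) {
    rec <- function(last_a, last_b, avail, len) {
      best <<- max(best, len)
      for (i in avail) {
        if ((is.na(last_a) || ra[i] > last_a) &&
            (is.na(last_b) || (dir == 1 && rb[i] > last_b) ||
             (dir == -1 && rb[i] < last_b))) {
          rec(ra[i], rb[i], setdiff(avail, i), len + 1L)
        }
      }
    }
    rec(NA, NA, seq_len(n), 0L)
  }
  chase(1); chase(-1)
  best
}

# greedy block decomposition using the exhaustive chain oracle: each
# round remove one maximum-length chain (>= min_block) among unused
# anchors; returns the block sizes
greedy_blocks_oracle <- function(ra, rb, min_block) {
  find_chain <- function(idx, dir) {
    # returns the first maximum-length chain (lexicographic DFS order)
    best_chain <- integer(0)
    rec <- function(last_a, last_b, avail, chain) {
      if (length(chain) > length(best_chain)) best_chain <<- chain
      for (i in avail) {
        if ((is.na(last_a) || ra[i] > last_a) &&
            (is.na(last_b) || (dir == 1 && rb[i] > last_b) ||
             (dir == -1 && rb[i] < last_b))) {
          rec(ra[i], rb[i], setdiff(avail, i), c(chain, i))
        }
      }
    }
    rec(NA, NA, idx, integer(0))
    best_chain
  }
  avail <- seq_along(ra)
  sizes <- integer(0)
  repeat {
    if (length(avail) < min_block) break
    c1 <- find_chain(avail, 1)
    c2 <- find_chain(avail, -1)
    chain <- if (length(c1) >= length(c2)) c1 else c2
    if (length(chain) < min_block) break
    sizes <- c(sizes, length(chain))
    avail <- setdiff(avail, chain)
  }
  sizes
}

# random amino-acid sequence over the 20 standard letters
random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE),
        collapse = "")
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# the substitution matrix the package aligns with (BLOSUM62, neutral X)
test_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0L; m[, "X"] <- 0L
  m
}
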