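# Independent oracles used across the suite. Each recomputes a quantity by
# a different route than the implementation under test.

# --- elemental-composition peptide mass -------------------------------------
# Monoisotopic mass from summed atomic compositions (C, H, N, O, S), fully
# independent of the package's residue-mass table.
.ATOM <- c(H = 1.007825032, C = 12, N = 14.003074005, O = 15.99491462,
           S = 31.972071)

# in-chain residue formulas: C, H, N, O, S
.RES_FORMULA <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)
colnames(.RES_FORMULA) <- c("C", "H", "N", "O", "S")

# modification element deltas, same column order
.MOD_FORMULA <- rbind(
  "carbamidomethyl"      = c(2, 3, 1, 1, 0),
  "oxidation"            = c(0, 0, 0, 1, 0),
  "amidation"            = c(0, 1, 1, -1, 0),    # -OH +NH2
  "acetyl"               = c(2, 2, 0, 1, 0),
  "pyroglutamate-from-Q" = c(0, -3, -1, 0, 0),   # -NH3
  "pyroglutamate-from-E" = c(0, -2, 0, -1, 0),   # -H2O
  "octanoyl"             = c(8, 14, 0, 1, 0),
  "decanoyl"             = c(10, 18, 0, 1, 0)
)

elementalMass <- function(sequence, modNames = character(0)) {
  counts <- colSums(.RES_FORMULA[strsplit(sequence, "")[[1L]], ,
                                 drop = FALSE])
  counts["H"] <- counts["H"] + 2
  counts["O"] <- counts["O"] + 1
  for (m in modNames) counts <- counts + .MOD_FORMULA[m, ]
  sum(counts * .ATOM[names(counts)])
}

# --- flood-fill connected-component labeling --------------------------------
# Slow reference labeling with selectable connectivity.
bruteLabel <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1),
         c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      nextLab <- nextLab + 1L
      queue <- list(c(r, c))
      lab[r, c] <- nextLab
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (o in offs) {
          rr <- p[1L] + o[1L]; cc <- p[2L] + o[2L]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nextLab
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# --- balanced two-way ANOVA by cell means -----------------------------------
# Classical cell-means decomposition for a balanced a x b design with n
# observations per cell.
cellMeansAnova <- function(table) {
  g <- factor(table$group); q <- factor(table$quarter); y <- table$count
  a <- nlevels(g); b <- nlevels(q)
  n <- nrow(table) / (a * b)
  grand <- mean(y)
  gm <- tapply(y, g, mean)
  qm <- tapply(y, q, mean)
  cm <- tapply(y, list(g, q), mean)
  ssG <- n * b * sum((gm - grand)^2)
  ssQ <- n * a * sum((qm - grand)^2)
  ssCells <- n * sum((cm - grand)^2)
  ssI <- ssCells - ssG - ssQ
  ssT <- sum((y - grand)^2)
  ssE <- ssT - ssCells
  dfG <- a - 1; dfQ <- b - 1; dfI <- dfG * dfQ
  dfE <- a * b * (n - 1)
  mse <- ssE / dfE
  f <- c(ssG / dfG, ssQ / dfQ, ssI / dfI) / mse
  list(ss = c(group = ssG, quarter = ssQ, interaction = ssI, error = ssE,
              total = ssT),
       df = c(dfG, dfQ, dfI, dfE),
       F = f,
       p = pf(f, c(dfG, dfQ, dfI), dfE, lower.tail = FALSE))
}

# --- interval stabbing / pair scan ------------------------------------------
stabCoverage <- function(starts, ends, L) {
  vapply(seq_len(L), function(i) sum(starts <= i & ends >= i), 0L)
}

pairScanDibasic <- function(sequence) {
  res <- strsplit(sequence, "")[[1L]]
  out <- integer(0)
  for (i in seq_len(length(res) - 1L)) {
    if (res[i] %in% c("K", "R") && res[i + 1L] %in% c("K", "R"))
      out <- c(out, i)
  }
  out
}

# --- shared fixtures --------------------------------------------------------

# grid of n well-separated cells on a straight-gut image
makeSeparatedSpec <- function(n = 100, seed = 1, imageSide = 512L,
                              noiseSd = 0, radius = 6) {
  cells <- wellSeparatedCells(n, imageShape = c(imageSide, imageSide),
                              radius = radius, seed = seed)
  simImageSpec(cells, imageShape = c(imageSide, imageSide),
               noiseSd = noiseSd, seed = seed)
}

# the merge scene: 6 singletons plus a 2-cell and a 3-cell cluster of equal
# per-cell area
makeClusterSpec <- function(seed = 1, noiseSd = 0) {
  simImageSpec(clusterScene(), noiseSd = noiseSd, seed = seed)
}

detectAll <- detectCells
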