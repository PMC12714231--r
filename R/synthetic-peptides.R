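#' Simulate identified peptides tiling a precursor
#'
#' Draws peptides as true substrings of the precursor, with termini sampled
#' preferentially at cleavage points flanking dibasic (K/R pair) motifs --
#' the prohormone convertase convention -- and at the protein termini.
#' Modifications are sampled from the supported set: carbamidomethyl fixed
#' on Cys, oxidation variable on Met, N-terminal acetylation, N-terminal
#' pyroglutamate on Gln/Glu, and C-terminal amidation.
#'
#' Each emitted peptide records its (start, end) span, so
#' [locatePeptide()] recovers it at that position by construction.
#'
#' @param precursor a [Precursor-class] or a plain amino-acid string.
#' @param nPeptides number of peptides to draw.
#' @param seed integer RNG seed.
#' @param dibasicWeight sampling weight of a cleavage point adjacent to a
#'   dibasic site, relative to weight 1 for an ordinary inter-residue point
#'   (protein termini get weight 5). Dibasic cleavage dominates prohormone
#'   processing, so the default is strongly skewed toward those points.
#' @param lengthRange allowed peptide lengths (inclusive). The lower bound
#'   of 2 admits the excised basic-pair dipeptide itself, a legitimate
#'   processing product in no-enzyme peptidomic searches.
#' @param modProbs named numeric vector of per-opportunity probabilities
#'   for the variable modifications.
#' @return data.frame of peptide hits: precursor_id, sequence, start, end,
#'   mods (\code{"pos|name"} entries joined by \code{";"}, empty when
#'   unmodified). Positions in \code{mods} are within the peptide, 1-based.
#' @examples
#' pre <- precursor("ghrl", "MGSSFLSPSQKPQGKRRSLLDMDDLIEKRQAE")
#' simulatePeptides(pre, 5, seed = 1)
#' @export
simulatePeptides <- function(precursor, nPeptides, seed = 1L,
                             dibasicWeight = 50, lengthRange = c(2L, 30L),
                             modProbs = c(oxidation = 0.3, acetyl = 0.1,
                                          pyroglutamate = 0.5,
                                          amidation = 0.2)) {
  seq <- if (is(precursor, "Precursor")) precursor@sequence else precursor
  id <- if (is(precursor, "Precursor")) precursor@id else "precursor"
  L <- nchar(seq)
  if (L < 10L) stopf("precursor must be at least 10 residues (got %d)", L)
  if (nPeptides == 0L) {
    return(data.frame(precursor_id = character(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      mods = character(0)))
  }
  # cleavage points 0..L between residues; weight points flanking or inside
  # a dibasic pair, and the protein termini
  w <- rep(1, L + 1L)
  sites <- findDibasicSites(seq)
  for (k in seq_len(nrow(sites))) {
    i <- sites$start[k]
    w[c(i - 1L, i, i + 1L) + 1L] <- dibasicWeight
  }
  w[c(1L, L + 1L)] <- pmax(w[c(1L, L + 1L)], 5)
  withSeed(seed, {
    hits <- vector("list", nPeptides)
    for (p in seq_len(nPeptides)) {
      # first terminus from the cleavage-point weights, second from the
      # same weights restricted to spans of allowed length
      repeat {
        b1 <- sample(0:L, 1L, prob = w)
        allowed <- which(abs(0:L - b1) >= lengthRange[1L] &
                           abs(0:L - b1) <= lengthRange[2L])
        if (length(allowed)) break
      }
      b2 <- (0:L)[allowed][sample.int(length(allowed), 1L,
                                      prob = w[allowed])]
      a <- min(b1, b2); z <- max(b1, b2)
      start <- a + 1L; end <- z
      pep <- substring(seq, start, end)
      mods <- character(0)
      cys <- which(strsplit(pep, "")[[1L]] == "C")
      mods <- c(mods, sprintf("%d|carbamidomethyl", cys))
      met <- which(strsplit(pep, "")[[1L]] == "M")
      ox <- met[stats::runif(length(met)) < modProbs[["oxidation"]]]
      mods <- c(mods, sprintf("%d|oxidation", ox))
      first <- substring(pep, 1L, 1L)
      if (first %in% c("Q", "E") &&
          stats::runif(1) < modProbs[["pyroglutamate"]]) {
        mods <- c(mods, sprintf("1|pyroglutamate-from-%s", first))
      } else if (stats::runif(1) < modProbs[["acetyl"]]) {
        mods <- c(mods, "1|acetyl")
      }
      if (stats::runif(1) < modProbs[["amidation"]])
        mods <- c(mods, sprintf("%d|amidation", nchar(pep)))
      hits[[p]] <- data.frame(
        precursor_id = id, sequence = pep, start = start, end = end,
        mods = paste(mods, collapse = ";")
      )
    }
    do.call(rbind, hits)
  })
}
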