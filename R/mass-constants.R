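# Monoisotopic mass constants (Da), derived from CODATA/AME atomic masses
# (H 1.00782503207, C 12 exactly, N 14.0030740048, O 15.9949146196,
# S 31.97207100). Residue masses are in-chain (dehydrated) masses; a free
# peptide adds one water.

.RESIDUE_MASS <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527638,
  V = 99.0684139, T = 101.0476785, C = 103.0091848, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404849, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
)

.WATER_MASS <- 18.0105647

# Unimod-style modification deltas. Pyroglutamate formation is a loss:
# NH3 from Gln, H2O from Glu; amidation swaps the C-terminal OH for NH2.
.MOD_DELTA <- c(
  "carbamidomethyl"      =  57.0214637,
  "oxidation"            =  15.9949146,
  "amidation"            =  -0.9840156,
  "acetyl"               =  42.0105647,
  "pyroglutamate-from-Q" = -17.0265491,
  "pyroglutamate-from-E" = -18.0105647,
  "octanoyl"             = 126.1044651,
  "decanoyl"             = 154.1357652
)

#' Monoisotopic mass constants
#'
#' The residue and modification masses bundled with the package. Residue
#' masses are monoisotopic in-chain masses (Da); modification deltas are
#' keyed by Unimod-style names covering the search parameters of the
#' peptidomic identifications: fixed carbamidomethyl (Cys), variable
#' oxidation (Met), C-terminal amidation, N-terminal acetylation and
#' pyroglutamate (from Gln or Glu), and the octanoyl/decanoyl acylations of
#' the dedicated ghrelin search.
#'
#' @return Named numeric vector.
#' @examples
#' residueMasses()[c("G", "K", "R")]
#' modificationDeltas()["oxidation"]
#' @export
residueMasses <- function() .RESIDUE_MASS

#' @rdname residueMasses
#' @export
modificationDeltas <- function() .MOD_DELTA
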