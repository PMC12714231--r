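#' Specify a synthetic ablation cohort
#'
#' Defaults emulate a typical larval ablation experiment: 15 fish per group
#' and a control mean of 30 cells per quarter (120 per fish) for a single
#' subtype, with mild overdispersion. The \code{effect} argument sets the
#' multiplicative reduction seen in the ablated group; the study-scale
#' effect sizes of interest are in the 0.3-0.5 range (30-50% loss).
#'
#' @param groupMeans numeric matrix (subtypes x 4 quarters) of expected
#'   control-group cells per fish, or a single number recycled to a
#'   one-subtype 1 x 4 matrix.
#' @param effect multiplicative reduction in [0, 1] for the ablated group;
#'   scalar or a matrix shaped like \code{groupMeans}.
#' @param nFishPerGroup fish per group (>= 2).
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson.
#' @param seed integer RNG seed.
#' @param subtypes optional subtype labels (rownames of groupMeans).
#' @return A validated [SimCohortSpec-class].
#' @examples
#' spec <- simCohortSpec(groupMeans = 30, effect = 0.5, seed = 1)
#' head(simulateCounts(spec))
#' @export
simCohortSpec <- function(groupMeans = 30, effect = 0, nFishPerGroup = 15L,
                          dispersion = 0.05, seed = 1L, subtypes = NULL) {
  if (!is.matrix(groupMeans))
    groupMeans <- matrix(groupMeans, nrow = 1L, ncol = 4L)
  if (!is.matrix(effect))
    effect <- matrix(effect, nrow = nrow(groupMeans), ncol = ncol(groupMeans))
  if (is.null(rownames(groupMeans)))
    rownames(groupMeans) <- subtypes %||%
      paste0("subtype", seq_len(nrow(groupMeans)))
  new("SimCohortSpec",
      nFishPerGroup = as.integer(nFishPerGroup), groupMeans = groupMeans,
      effect = effect, dispersion = dispersion, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "SimCohortSpec", function(object) {
  cat("SimCohortSpec:", object@nFishPerGroup, "fish/group,",
      nrow(object@groupMeans), "subtype(s), dispersion",
      object@dispersion, "\n")
  cat("  control means (per quarter):\n")
  print(object@groupMeans)
})

#' Simulate per-fish cell-count tables
#'
#' Draws one count per fish x subtype x quarter. Control-group means are
#' \code{groupMeans}; ablated-group means are \code{groupMeans * (1 -
#' effect)}. Counts are negative-binomial with overdispersion
#' \code{dispersion} (Poisson when it is 0). Output is the long-format
#' count table consumed by the statistics stage.
#'
#' @param spec a [SimCohortSpec-class].
#' @return data.frame with columns fish_id, group (\code{control} /
#'   \code{ablated}), subtype, quarter (1-4), count.
#' @export
setMethod("simulateCounts", "SimCohortSpec", function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    subtypes <- rownames(spec@groupMeans)
    grid <- expand.grid(
      quarter = 1:4, subtype = subtypes,
      fish = seq_len(spec@nFishPerGroup), group = c("control", "ablated"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    mu <- spec@groupMeans[cbind(match(grid$subtype, subtypes), grid$quarter)]
    mu <- ifelse(grid$group == "ablated",
                 mu * (1 - spec@effect[cbind(match(grid$subtype, subtypes),
                                             grid$quarter)]),
                 mu)
    n <- nrow(grid)
    counts <- if (spec@dispersion > 0) {
      stats::rnbinom(n, size = 1 / spec@dispersion, mu = mu)
    } else {
      stats::rpois(n, mu)
    }
    counts[mu == 0] <- 0L
    data.frame(
      fish_id = paste0(substr(grid$group, 1, 1), grid$fish),
      group = grid$group, subtype = grid$subtype,
      quarter = grid$quarter, count = as.integer(counts)
    )
  })
})
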