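#' Trace the last common ancestor of a population
#'
#' Starting from the parents of the final population, the set of unique
#' ancestor indices is followed backwards one step at a time until the
#' first singleton set is reached: the individual in that singleton,
#' one step further back, is the last common ancestor (LCA) and its
#' locus variant is fixed in the population. The backward ancestor-set
#' sequence is not assumed to shrink monotonically. If no singleton is
#' found by step 0, the founding clone (fitness 0) is the de facto
#' common ancestor and `coalesced` is `FALSE`.
#'
#' @param parents Integer matrix with `T` rows and `N` columns; row `t`
#'   holds, for each individual of the population at step `t`, the
#'   index of its parent in the population at step `t - 1`.
#' @param F_archive Optional numeric matrix with `T + 1` rows of
#'   per-step fitness vectors (row `t + 1` is step `t`), used to look
#'   up the LCA fitness.
#' @param t Time-step whose population is traced (default the last row).
#'
#' @return A list with `lca_time` (time-step index of the LCA),
#'   `lca_index`, `lca_fitness` (`NA` without `F_archive`, 0 when not
#'   coalesced) and `coalesced`.
#' @examples
#' r <- run_replicate(chlamy_dfe(), sim_config(N = 50, steps = 30),
#'                    seed = 1, keep_ancestry = TRUE)
#' trace_last_common_ancestor(r$parents, r$F_archive)
#' @export
trace_last_common_ancestor <- function(parents, F_archive = NULL,
                                       t = nrow(parents)) {
  stopifnot(is.matrix(parents), t >= 1, t <= nrow(parents))
  x <- unique(parents[t, ])
  k <- 1L # after k backward steps the set lives in the population at t - k
  while (length(x) > 1L && k < t) {
    x <- unique(parents[t - k, x])
    k <- k + 1L
  }
  if (length(x) == 1L) {
    lca_time <- t - k
    fit <- if (is.null(F_archive)) NA_real_ else F_archive[lca_time + 1L, x]
    list(lca_time = lca_time, lca_index = x, lca_fitness = fit,
         coalesced = TRUE)
  } else {
    list(lca_time = 0L, lca_index = NA_integer_, lca_fitness = 0,
         coalesced = FALSE)
  }
}

#' Outcome flags of a completed replicate
#'
#' A replicate has `retained` the locus when at least one individual of
#' the final population carries it, and has `crossed` the fitness
#' threshold when, in addition, the fitness contribution of the last
#' common ancestor strictly exceeds the threshold.
#'
#' @param replicate A `gb_replicate` object.
#' @param fitness_threshold Threshold (defaults to the replicate's
#'   configured value).
#' @return List with logical `crossed` and `retained`.
#' @export
crossed_and_retained <- function(replicate,
                                 fitness_threshold =
                                   replicate$config$fitness_threshold) {
  retained <- !replicate$extinct && any(replicate$final$L == 1L)
  list(crossed = retained && replicate$lca_fitness > fitness_threshold,
       retained = retained)
}
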