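#' Simulation configuration
#'
#' Collects the population-level parameters of the model. Defaults are
#' the study conditions: populations of `N = 1000` haploid individuals
#' updated for `steps = 1000` mutational time-steps, fitness threshold
#' 0.1 for calling a locus adapted, neutrality cutoff `5e-4`, initial
#' expression at the leaky-expression floor `E0 = 1e-3` with expression
#' bounded in `[1e-3, 1]`, and power-law mutational effects on
#' expression with exponent `alpha = 2.25` above a lower cutoff
#' `delta_E_min = 1e-7`. The cutoff is small enough that a single
#' mutation essentially never saturates expression (the probability
#' that one draw reaches `E_max` is below `2e-9`), so expression
#' evolves through occasional sizeable jumps against a background of
#' negligible perturbations.
#'
#' @param N Population size (>= 1).
#' @param steps Number of mutational time-steps T (>= 1).
#' @param regime `"high"` (many competing variants per step; parents
#'   drawn by multinomial sampling proportional to relative fitness) or
#'   `"low"` (a single variant fixes per step, chosen with probability
#'   proportional to relative fitness).
#' @param d Per-offspring, per-step probability of whole-locus deletion
#'   by structural variation, in `[0, 1]`.
#' @param fitness_threshold Fitness level that the last common ancestor
#'   must exceed for a replicate to count as having adapted.
#' @param neutral_threshold Classification cutoff for neutral mutations.
#' @param E0 Initial expression level of every individual.
#' @param E_min,E_max Expression bounds; updates leaving the interval
#'   are reset to the nearest bound.
#' @param alpha Power-law exponent of `|dE|` (> 1).
#' @param delta_E_min Lower cutoff of `|dE|` (> 0), required for the
#'   power law to be normalisable.
#' @param seed Optional integer seed stored for bookkeeping.
#'
#' @return A `sim_config` object.
#' @examples
#' sim_config(regime = "low", d = 0.005)
#' @export
sim_config <- function(N = 1000, steps = 1000, regime = c("high", "low"),
                       d = 0, fitness_threshold = 0.1,
                       neutral_threshold = 5e-4,
                       E0 = 1e-3, E_min = 1e-3, E_max = 1,
                       alpha = 2.25, delta_E_min = 1e-7, seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(N >= 1, steps >= 1, d >= 0, d <= 1,
            fitness_threshold > 0, neutral_threshold > 0,
            E_min > 0, E_min <= E0, E0 <= E_max,
            alpha > 1, delta_E_min > 0)
  structure(list(N = as.integer(N), steps = as.integer(steps),
                 regime = regime, d = d,
                 fitness_threshold = fitness_threshold,
                 neutral_threshold = neutral_threshold,
                 E0 = E0, E_min = E_min, E_max = E_max,
                 alpha = alpha, delta_E_min = delta_E_min,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: N = %d, T = %d, %s mutation-rate regime, d = %g\n",
    x$N, x$steps, x$regime, x$d))
  cat(sprintf("  fitness threshold %g, E in [%g, %g], alpha = %g\n",
              x$fitness_threshold, x$E_min, x$E_max, x$alpha))
  invisible(x)
}

#' Normalised relative fitness of a population
#'
#' Individuals with locus fitness contribution `F <= -1` are lethal and
#' receive zero weight. Among viable individuals the selection weight is
#' `1 + F - minfit`, where `minfit` is the minimum viable fitness;
#' weights are normalised to sum to one. Because of the shift, even an
#' individual with `F = 0` (e.g. one that has lost the locus) has
#' positive weight whenever `minfit < 0`.
#'
#' @param fitness Numeric vector of locus fitness contributions.
#' @return Probability vector of the same length, summing to 1.
#'   Signals an error of class `gb_extinct` when no individual is
#'   viable.
#' @examples
#' relative_fitness(c(0, 0.5, -2)) # c(0.4, 0.6, 0)
#' @export
relative_fitness <- function(fitness) {
  viable <- fitness > -1
  if (!any(viable))
    stop(structure(class = c("gb_extinct", "error", "condition"),
                   list(message = "population extinct: no viable individuals",
                        call = sys.call())))
  minfit <- min(fitness[viable])
  w <- ifelse(viable, 1 + fitness - minfit, 0)
  w / sum(w)
}

#' Initial population state
#'
#' Every individual starts with the locus present, adaptive value 0
#' (hence fitness contribution 0) and expression at the leaky floor
#' `E0`.
#'
#' @param config A [sim_config()].
#' @return A `population_state` list with fields `F`, `E`, `L`
#'   (locus-presence flags) and time index `t = 0`.
#' @export
initialize_population <- function(config) {
  structure(list(F = numeric(config$N),
                 E = rep(config$E0, config$N),
                 L = rep(1L, config$N),
                 t = 0L),
            class = "population_state")
}

#' Derived adaptive values of a population state
#'
#' @param state A `population_state`.
#' @return Numeric vector `F / E` with `NA` for locus-free individuals.
#' @export
state_adaptive_value <- function(state) {
  ifelse(state$L == 1L, state$F / state$E, NA_real_)
}

# Inverse-CDF categorical draw shared (bit-for-bit) with the C++ core:
# for each uniform u, the smallest index i with cum[i] > u * cum[n].
inverse_cdf_pick <- function(cum, u) {
  findInterval(u * cum[length(cum)], cum) + 1L
}

#' Select parents for the next time-step
#'
#' In the high mutation-rate regime each of the `N` offspring draws its
#' parent independently with probability proportional to relative
#' fitness; in the low regime a single parent is drawn once and all
#' offspring descend from it (one variant fixes per time-step).
#'
#' @param relfit Probability vector from [relative_fitness()].
#' @param regime `"high"` or `"low"`.
#' @param N Number of offspring (defaults to `length(relfit)`).
#' @return Integer vector of `N` parent indices.
#' @export
select_parents <- function(relfit, regime = c("high", "low"),
                           N = length(relfit)) {
  regime <- match.arg(regime)
  cum <- cumsum(relfit)
  if (regime == "low") {
    rep(inverse_cdf_pick(cum, runif(1)), N)
  } else {
    inverse_cdf_pick(cum, runif(N))
  }
}

#' Advance a population by one mutational time-step
#'
#' Reference implementation of the per-step update rule. For each
#' offspring: inherit from the selected parent; if the parent lacks the
#' locus, or a deletion event occurs (probability `d`), the offspring
#' carries no locus (`L = 0`, `F = 0`, `E = 0`) and receives no
#' mutation; otherwise the offspring inherits the parent's fitness plus
#' a DFE draw and the parent's expression plus a power-law expression
#' perturbation, clipped to the expression bounds. Lethal offspring
#' (`F <= -1`) remain in the state but receive zero selection weight at
#' the next step.
#'
#' Random draws occur in a fixed per-offspring order shared with the
#' compiled path used by [run_replicate()], so that looping this
#' function reproduces a compiled replicate bit-for-bit from the same
#' seed.
#'
#' @param state A `population_state`.
#' @param dfe A [dfe_params()] object.
#' @param config A [sim_config()].
#' @param track_expression Draw and apply expression perturbations
#'   (default `TRUE`). When `FALSE` carrier expression stays at `E0`.
#' @param jump_prob,jump_effect Optional rare-jump augmentation of the
#'   DFE (see [draw_fitness_effects()]).
#'
#' @return A `step_outcome` list: the next `population_state`, the
#'   `parents` index vector, and the raw `delta_F` and `delta_E`
#'   applied per offspring (`NA` where the locus was absent or
#'   deleted).
#' @export
advance_step <- function(state, dfe, config, track_expression = TRUE,
                         jump_prob = 0, jump_effect = 0.15) {
  dfe <- as_dfe_params(dfe)
  N <- config$N
  relfit <- relative_fitness(state$F)
  parents <- select_parents(relfit, config$regime, N)
  Fn <- numeric(N); En <- numeric(N); Ln <- integer(N)
  dF <- rep(NA_real_, N); dE <- rep(NA_real_, N)
  for (j in seq_len(N)) {
    i <- parents[j]
    lost <- state$L[i] == 0L
    if (!lost && config$d > 0 && runif(1) < config$d) lost <- TRUE
    if (lost) next
    if (jump_prob > 0 && runif(1) < jump_prob) {
      dF[j] <- jump_effect
    } else if (runif(1) < dfe$f) {
      dF[j] <- rgamma(1, shape = dfe$s, scale = dfe$p / dfe$s)
    } else {
      dF[j] <- -rgamma(1, shape = dfe$s, scale = dfe$n / dfe$s)
    }
    Fn[j] <- state$F[i] + dF[j]
    if (track_expression) {
      mag <- config$delta_E_min *
        (1 - runif(1))^(-1 / (config$alpha - 1))
      dE[j] <- if (runif(1) < 0.5) -mag else mag
      En[j] <- min(config$E_max, max(config$E_min, state$E[i] + dE[j]))
    } else {
      En[j] <- config$E0
    }
    Ln[j] <- 1L
  }
  next_state <- structure(list(F = Fn, E = En, L = Ln, t = state$t + 1L),
                          class = "population_state")
  structure(list(state = next_state, parents = parents,
                 delta_F = dF, delta_E = dE),
            class = "step_outcome")
}

#' Run one replicate population
#'
#' Simulates a full replicate for `config$steps` time-steps using the
#' compiled core, recording per-step population summaries, tracing the
#' last common ancestor of the final population, and classifying the
#' outcome (locus retained; fitness threshold crossed by the fixed
#' variant).
#'
#' @inheritParams advance_step
#' @param seed Optional integer; when supplied, `set.seed(seed)` is
#'   called first so the replicate is fully reproducible.
#' @param keep_ancestry Return the full parent matrix and fitness
#'   archive (memory: `steps * N` integers plus doubles).
#' @param collect_delta_A Record the adaptive-value increment of every
#'   carrier-to-carrier transition (requires `track_expression`).
#'
#' @return A `gb_replicate` list with, among others, `trajectory` (data
#'   frame of per-step mean fitness, sd, mean expression, mean adaptive
#'   value over carriers, carrier count), outcome flags `retained`,
#'   `crossed`, `ever_crossed`, `extinct`, the LCA fields `lca_time`,
#'   `lca_fitness`, `coalesced`, the trajectory summaries
#'   `min_mean_fitness` and `time_of_min`, and the final state.
#' @examples
#' r <- run_replicate(chlamy_dfe(), sim_config(N = 100, steps = 50), seed = 1)
#' r$crossed; r$min_mean_fitness
#' @export
run_replicate <- function(dfe, config, seed = NULL,
                          track_expression = TRUE,
                          keep_ancestry = FALSE,
                          collect_delta_A = FALSE,
                          jump_prob = 0, jump_effect = 0.15) {
  dfe <- as_dfe_params(dfe)
  stopifnot(inherits(config, "sim_config"))
  if (collect_delta_A && !track_expression)
    stop("collect_delta_A requires track_expression = TRUE", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_replicate(
    config$N, config$steps, config$regime == "low", config$d,
    dfe$p, dfe$f, dfe$n, dfe$s, jump_prob, jump_effect,
    config$E0, config$E_min, config$E_max,
    config$alpha, config$delta_E_min, config$fitness_threshold,
    track_expression, keep_ancestry, collect_delta_A)
  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("mean_F", "sd_F", "mean_E", "mean_A", "n_carriers")
  traj <- cbind(t = 0:config$steps, traj)
  out <- list(
    trajectory = traj,
    retained = res$retained,
    crossed = res$crossed,
    ever_crossed = res$ever_crossed,
    extinct = res$extinct,
    coalesced = res$coalesced,
    lca_time = res$lca_time,
    lca_index = res$lca_index,
    lca_fitness = res$lca_fitness,
    steps_run = res$steps_run,
    min_mean_fitness = min(traj$mean_F[seq_len(res$steps_run + 1)]),
    time_of_min = which.min(traj$mean_F[seq_len(res$steps_run + 1)]) - 1L,
    final = list(F = res$final_F, E = res$final_E, L = res$final_L),
    fixed_fitness = res$fixed_fitness,
    delta_A = res$delta_A,
    parents = res$parents,
    F_archive = res$F_archive,
    dfe = dfe, config = config, seed = seed,
    track_expression = track_expression)
  class(out) <- "gb_replicate"
  out
}

#' @export
print.gb_replicate <- function(x, ...) {
  cat(sprintf(
    "Replicate (%s regime, N = %d, T = %d, d = %g): %s\n",
    x$config$regime, x$config$N, x$config$steps, x$config$d,
    if (x$extinct) "extinct"
    else if (x$crossed) "crossed the fitness threshold"
    else if (x$retained) "retained, not crossed"
    else "locus lost"))
  cat(sprintf("  LCA fitness %.4g at t = %d; min mean fitness %.4g at t = %d\n",
              x$lca_fitness, x$lca_time, x$min_mean_fitness, x$time_of_min))
  invisible(x)
}
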