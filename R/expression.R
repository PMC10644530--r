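#' Draw mutational effects on expression level
#'
#' Magnitudes are Pareto distributed with density proportional to
#' `x^-alpha` on `[delta_E_min, Inf)`, sampled by inversion
#' (`x = delta_E_min * (1 - u)^(-1/(alpha - 1))`); the sign is negative
#' with probability 0.5, independent of the magnitude.
#'
#' @param count Number of draws.
#' @param alpha Power-law exponent (> 1; default 2.25).
#' @param delta_E_min Lower cutoff of the magnitude (> 0).
#' @return Numeric vector of signed expression changes.
#' @examples
#' set.seed(1)
#' summary(abs(draw_expression_effects(1000)))
#' @export
draw_expression_effects <- function(count, alpha = 2.25,
                                    delta_E_min = 1e-7) {
  if (alpha <= 1)
    stop("alpha must exceed 1 for the power law to be normalisable",
         call. = FALSE)
  stopifnot(delta_E_min > 0, count >= 0)
  count <- as.integer(count)
  mag <- delta_E_min * (1 - runif(count))^(-1 / (alpha - 1))
  sign <- ifelse(runif(count) < 0.5, -1, 1)
  sign * mag
}

#' Apply an expression change with bounce-back at the bounds
#'
#' @param E_parent Parental expression level(s).
#' @param delta_E Signed expression change(s).
#' @param E_min,E_max Expression bounds; results outside `[E_min,
#'   E_max]` are reset to the nearest bound.
#' @return Updated expression level(s).
#' @examples
#' update_expression(0.001, -0.01) # stays at the leaky floor
#' update_expression(0.9, 0.5)     # capped at maximal expression
#' @export
update_expression <- function(E_parent, delta_E, E_min = 1e-3, E_max = 1) {
  pmin(E_max, pmax(E_min, E_parent + delta_E))
}

#' Adaptive value from fitness and expression
#'
#' The adaptive value `A = F / E` is the maximal fitness contribution
#' of the expression product, realised at maximal expression `E = 1`,
#' so that `F = A * E` exactly. It is undefined for locus-free
#' individuals (`E = 0`).
#'
#' @param fitness Locus fitness contribution(s).
#' @param expression Expression level(s), all > 0.
#' @return Numeric adaptive value(s).
#' @export
adaptive_value <- function(fitness, expression) {
  if (any(expression <= 0))
    stop("adaptive value is undefined for locus-free individuals (E = 0)",
         call. = FALSE)
  fitness / expression
}

#' Pool adaptive-value increments across replicates
#'
#' Concatenates the per-mutation adaptive-value changes
#' `dA = A_child - A_parent` (carrier-to-carrier transitions only)
#' recorded by replicates run with `collect_delta_A = TRUE`.
#'
#' @param replicates A list of `gb_replicate` objects, or a single one.
#' @return Numeric vector of pooled `dA` values.
#' @seealso [pool_delta_A()] to run the replicates and pool in one call.
#' @export
collect_delta_A <- function(replicates) {
  if (inherits(replicates, "gb_replicate")) replicates <- list(replicates)
  pools <- lapply(replicates, function(r) {
    if (is.null(r$delta_A))
      stop("replicate was run without collect_delta_A = TRUE", call. = FALSE)
    r$delta_A
  })
  unlist(pools, use.names = FALSE)
}

#' Run replicates and pool their adaptive-value increments
#'
#' @param dfe A [dfe_params()] object.
#' @param config A [sim_config()].
#' @param n_replicates Number of replicates to pool across.
#' @param seed_base Base seed; per-replicate seeds are derived from it.
#' @return Numeric vector of pooled `dA` values (up to
#'   `n_replicates * N * steps` entries).
#' @export
pool_delta_A <- function(dfe, config, n_replicates = 1, seed_base = 1) {
  reps <- lapply(seq_len(n_replicates), function(k) {
    run_replicate(dfe, config, seed = derive_seed(seed_base, 0, 0, k),
                  track_expression = TRUE, collect_delta_A = TRUE)
  })
  collect_delta_A(reps)
}
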