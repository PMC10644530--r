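#' Two-sided gamma DFE parameters
#'
#' Bundles and validates the four parameters of a two-sided gamma
#' distribution of fitness effects (DFE). A mutation is beneficial with
#' probability `f`; beneficial effects are drawn from a gamma
#' distribution with shape `s` and scale `p/s` (so the branch mean is
#' `p`), deleterious effects are the negative of a gamma draw with shape
#' `s` and scale `n/s` (branch mean magnitude `n`). Smaller `s` gives
#' longer-tailed DFEs.
#'
#' @param p Mean effect of beneficial mutations (fitness units, > 0).
#' @param f Probability that a mutation is beneficial, in `[0, 1]`.
#' @param n Mean absolute effect of deleterious mutations (> 0).
#' @param s Gamma shape parameter (> 0).
#'
#' @return An object of class `dfe_params`.
#' @examples
#' chlamy_dfe() # the parameter set closest to Chlamydomonas reinhardtii
#' dfe_params(p = 0.005, f = 0.5, n = 0.005, s = 0.1)
#' @export
dfe_params <- function(p, f, n, s) {
  stopifnot(is.numeric(p), length(p) == 1, is.finite(p), p > 0,
            is.numeric(f), length(f) == 1, is.finite(f), f >= 0, f <= 1,
            is.numeric(n), length(n) == 1, is.finite(n), n > 0,
            is.numeric(s), length(s) == 1, is.finite(s), s > 0)
  structure(list(p = p, f = f, n = n, s = s), class = "dfe_params")
}

#' @export
print.dfe_params <- function(x, ...) {
  cat(sprintf("Two-sided gamma DFE: p = %g, f = %g, n = %g, s = %g\n",
              x$p, x$f, x$n, x$s))
  invisible(x)
}

#' @rdname dfe_params
#' @export
chlamy_dfe <- function() dfe_params(p = 0.001, f = 0.75, n = 0.01, s = 0.3)

as_dfe_params <- function(x) {
  if (inherits(x, "dfe_params")) return(x)
  x <- as.list(x)
  dfe_params(x$p, x$f, x$n, x$s)
}

#' Draw mutational fitness effects from a DFE
#'
#' Samples independent signed fitness effects from the two-sided gamma
#' DFE. Optionally augments the DFE with a rare fixed-size beneficial
#' jump: with probability `jump_prob` the gamma draw is replaced by the
#' constant `jump_effect`.
#'
#' @param params A [dfe_params()] object.
#' @param count Number of draws.
#' @param jump_prob Probability of the rare large-effect jump (default 0).
#' @param jump_effect Fitness effect of the jump.
#'
#' @return Numeric vector of `count` signed fitness effects. Uses the R
#'   random number generator; seed with [set.seed()].
#' @examples
#' set.seed(1)
#' summary(draw_fitness_effects(chlamy_dfe(), 1000))
#' @export
draw_fitness_effects <- function(params, count, jump_prob = 0,
                                 jump_effect = 0.15) {
  params <- as_dfe_params(params)
  stopifnot(count >= 0, jump_prob >= 0, jump_prob <= 1)
  count <- as.integer(count)
  if (count == 0) return(numeric(0))
  beneficial <- runif(count) < params$f
  out <- numeric(count)
  nb <- sum(beneficial)
  out[beneficial] <- rgamma(nb, shape = params$s, scale = params$p / params$s)
  out[!beneficial] <- -rgamma(count - nb, shape = params$s,
                              scale = params$n / params$s)
  if (jump_prob > 0) {
    jump <- runif(count) < jump_prob
    out[jump] <- jump_effect
  }
  out
}

#' Classify mutational effects as positive, neutral or negative
#'
#' Effects at least `neutral_threshold` in magnitude are classified as
#' positive or negative according to sign (boundaries inclusive);
#' everything in between is effectively neutral, i.e. invisible to
#' selection at the population sizes considered here.
#'
#' @param effects Numeric vector of signed fitness effects.
#' @param neutral_threshold Positive classification cutoff
#'   (default `5e-4`).
#'
#' @return An `effect_classification` list with counts `n_positive`,
#'   `n_neutral`, `n_negative` and the mean absolute magnitudes of the
#'   positive and negative classes (`NA` for empty classes).
#' @examples
#' classify_effects(c(4e-4, 5e-4, -5e-4))
#' @export
classify_effects <- function(effects, neutral_threshold = 5e-4) {
  stopifnot(neutral_threshold > 0)
  pos <- effects >= neutral_threshold
  neg <- effects <= -neutral_threshold
  structure(list(
    n_positive = sum(pos),
    n_neutral = length(effects) - sum(pos) - sum(neg),
    n_negative = sum(neg),
    mean_abs_positive = if (any(pos)) mean(effects[pos]) else NA_real_,
    mean_abs_negative = if (any(neg)) mean(-effects[neg]) else NA_real_,
    n_total = length(effects),
    neutral_threshold = neutral_threshold
  ), class = "effect_classification")
}

# E[X | X >= cutoff] for a gamma with mean m and shape s (scale m/s),
# via the identity E[X 1{X >= c}] = m * P(Gamma(s + 1, m/s) >= c)
truncated_gamma_mean <- function(m, s, cutoff) {
  tail <- pgamma(cutoff, shape = s, scale = m / s, lower.tail = FALSE)
  ifelse(tail > 0,
         m * pgamma(cutoff, shape = s + 1, scale = m / s,
                    lower.tail = FALSE) / tail,
         NA_real_)
}

#' Closed-form classification fractions of a DFE
#'
#' Exact counterpart of [classify_effects()] applied to infinitely many
#' draws: tail probabilities of the two gamma branches give the class
#' fractions, and truncated gamma means give the mean magnitudes of the
#' classified (non-neutral) classes. Everything reduces to regularized
#' incomplete gamma functions.
#'
#' @param params A [dfe_params()] object.
#' @param neutral_threshold Non-negative classification cutoff.
#'
#' @return Named list with `frac_positive`, `frac_neutral`,
#'   `frac_negative`, `mean_abs_positive`, `mean_abs_negative`.
#' @examples
#' analytic_fractions(chlamy_dfe())
#' @export
analytic_fractions <- function(params, neutral_threshold = 5e-4) {
  params <- as_dfe_params(params)
  stopifnot(neutral_threshold >= 0)
  c0 <- neutral_threshold
  frac_pos <- params$f *
    pgamma(c0, shape = params$s, scale = params$p / params$s,
           lower.tail = FALSE)
  frac_neg <- (1 - params$f) *
    pgamma(c0, shape = params$s, scale = params$n / params$s,
           lower.tail = FALSE)
  list(frac_positive = frac_pos,
       frac_neutral = 1 - frac_pos - frac_neg,
       frac_negative = frac_neg,
       mean_abs_positive = truncated_gamma_mean(params$p, params$s, c0),
       mean_abs_negative = truncated_gamma_mean(params$n, params$s, c0))
}

#' The surveyed grid of DFE parameter sets
#'
#' Enumerates the Cartesian product of DFE parameter values surveyed in
#' the study: `p` in \{0.001, 0.003, 0.005\}, `f` in \{0.25, 0.5,
#' 0.75\}, `n` in \{0.001, 0.005, 0.01\} and `s` in \{0.1, 0.3, 0.6,
#' 0.9\} for populations of size 1000 (108 sets), with `s` restricted
#' to \{0.3, 0.6, 0.9\} for populations of size 100 (81 sets). Rows are
#' ordered lexicographically in (p, f, n, s) so that per-index results
#' are reproducible.
#'
#' @param population_size Either 1000 or 100.
#'
#' @return A `dfe_grid` data frame with columns `p`, `f`, `n`, `s` and
#'   attributes `deletion_probs` (the surveyed values of the locus
#'   deletion probability, `c(0, 0.005, 0.01, 0.05)`) and
#'   `population_size`.
#' @examples
#' nrow(dfe_grid(1000)) # 108
#' nrow(dfe_grid(100))  # 81
#' @export
dfe_grid <- function(population_size = 1000) {
  if (!population_size %in% c(100, 1000))
    stop("population_size must be 100 or 1000", call. = FALSE)
  s_vals <- if (population_size == 1000) c(0.1, 0.3, 0.6, 0.9)
            else c(0.3, 0.6, 0.9)
  g <- expand.grid(s = s_vals, n = c(0.001, 0.005, 0.01),
                   f = c(0.25, 0.5, 0.75), p = c(0.001, 0.003, 0.005),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("p", "f", "n", "s")]
  rownames(g) <- NULL
  structure(g,
            deletion_probs = c(0, 0.005, 0.01, 0.05),
            population_size = population_size,
            class = c("dfe_grid", "data.frame"))
}

#' Classification census over a grid of DFEs
#'
#' Computes, for every DFE in a grid, the fractions of positive,
#' neutral and negative effect mutations and the mean magnitudes of the
#' two classified classes, either exactly (`method = "analytic"`, the
#' default, using incomplete gamma closed forms) or by Monte Carlo
#' (`method = "monte-carlo"`, drawing `draws` mutations per DFE, the
#' procedure used to produce the published census). The two agree to
#' within binomial sampling error; ties between the two branches (DFEs
#' with `p == n`) are broken at random by the Monte-Carlo route but are
#' exact ties analytically.
#'
#' @param grid A [dfe_grid()] or data frame with columns `p`, `f`, `n`,
#'   `s`.
#' @param neutral_threshold Classification cutoff (default `5e-4`).
#' @param method `"analytic"` or `"monte-carlo"`.
#' @param draws Number of Monte-Carlo draws per DFE.
#'
#' @return A data frame with one row per DFE: the parameters, class
#'   fractions, class mean magnitudes, and logical class flags
#'   `neutral_majority` (neutral fraction strictly exceeds both other
#'   fractions), `negative_more_numerous`, `negative_larger` (strict
#'   comparisons of fraction and mean magnitude), plus the two joint
#'   flags `stringent` (neutral majority and negative both larger and
#'   more numerous) and `permissive` (neutral minority and negative
#'   both smaller and less numerous).
#' @seealso [census_summary()] for the aggregate counts.
#' @examples
#' census <- dfe_census(dfe_grid(1000))
#' census_summary(census)
#' @export
dfe_census <- function(grid, neutral_threshold = 5e-4,
                       method = c("analytic", "monte-carlo"),
                       draws = 1e6) {
  method <- match.arg(method)
  grid <- as.data.frame(grid)[, c("p", "f", "n", "s")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    prm <- dfe_params(grid$p[i], grid$f[i], grid$n[i], grid$s[i])
    if (method == "analytic") {
      analytic_fractions(prm, neutral_threshold)
    } else {
      cl <- cpp_classify_draws(prm$p, prm$f, prm$n, prm$s, draws,
                               neutral_threshold)
      list(frac_positive = cl$n_positive / draws,
           frac_neutral = cl$n_neutral / draws,
           frac_negative = cl$n_negative / draws,
           mean_abs_positive = cl$mean_abs_positive,
           mean_abs_negative = cl$mean_abs_negative)
    }
  })
  out <- cbind(grid, do.call(rbind, lapply(rows, as.data.frame)))
  out$neutral_majority <- out$frac_neutral > out$frac_positive &
    out$frac_neutral > out$frac_negative
  out$negative_more_numerous <- out$frac_negative > out$frac_positive
  out$negative_larger <- out$mean_abs_negative > out$mean_abs_positive
  out$stringent <- out$neutral_majority & out$negative_more_numerous &
    out$negative_larger
  out$permissive <- out$frac_neutral < out$frac_positive &
    out$frac_neutral < out$frac_negative &
    out$frac_negative < out$frac_positive &
    out$mean_abs_negative < out$mean_abs_positive
  attr(out, "method") <- method
  attr(out, "neutral_threshold") <- neutral_threshold
  out
}

#' Aggregate counts of DFE classes in a census
#'
#' @param census Output of [dfe_census()].
#' @return Named list of counts and percentages over the censused DFEs.
#' @export
census_summary <- function(census) {
  n <- nrow(census)
  list(
    n_dfe = n,
    n_neutral_majority = sum(census$neutral_majority),
    pct_neutral_majority = 100 * mean(census$neutral_majority),
    n_negative_more_numerous = sum(census$negative_more_numerous),
    pct_negative_more_numerous = 100 * mean(census$negative_more_numerous),
    n_negative_larger = sum(census$negative_larger),
    pct_negative_larger = 100 * mean(census$negative_larger),
    n_stringent = sum(census$stringent),
    n_permissive = sum(census$permissive)
  )
}
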