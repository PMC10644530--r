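# Ensembles, parameter sweeps and the derived statistics behind the
# headline results: conducivity, locus loss/retention classes,
# trajectory summaries, correlation structure, and the shape of the
# distribution of mutational effects on adaptive value.

# Deterministic seed splitting: partial sweeps replay the same
# per-replicate seeds as full sweeps. All arithmetic stays exact in
# doubles (products < 2^53) and results stay below 2^31.
derive_seed <- function(seed_base, i = 0, j = 0, k = 0) {
  h <- as.numeric(seed_base) %% 2147483647
  for (x in c(i, j, k)) {
    h <- (h * 69069 + x + 1) %% 2147483647
  }
  as.integer(h + 1)
}

#' Run an ensemble of replicate populations
#'
#' Runs `n_replicates` independent replicates of one DFE under one
#' configuration, with per-replicate seeds derived deterministically
#' from `seed_base`, and tabulates per-replicate outcomes.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates (default 100, the study's
#'   ensemble size).
#' @param seed_base Base seed for deterministic per-replicate seeds.
#' @param d_index,grid_index Indices mixed into the derived seeds so
#'   that ensembles embedded in a sweep are reproducible in isolation.
#' @param keep_replicates Also return the list of `gb_replicate`
#'   objects (memory-heavy; default `FALSE`).
#' @param early_stop Stop running replicates once both binary outcomes
#'   of the ensemble are decided: whether at least half of
#'   `n_replicates` replicates cross (the conducive call) and whether
#'   more than half ever cross. The decisions are exact — identical to
#'   running all `n_replicates` with the same seeds — because once
#'   `ceiling(n/2)` crossings (or enough failures) are observed the
#'   classification cannot flip; the fractions reported then rest on
#'   the completed prefix of replicates. Default `FALSE`.
#'
#' @return A `gb_ensemble` data frame with one row per replicate:
#'   outcome flags (`crossed`, `retained`, `ever_crossed`, `extinct`),
#'   LCA fields, trajectory summaries (`min_mean_fitness`,
#'   `time_of_min`), final carrier count, and — when expression is
#'   tracked — the Pearson correlations of the mean-fitness trajectory
#'   with the mean-expression and mean-adaptive-value trajectories
#'   (`cor_F_E`, `cor_F_A`). Attributes: `dfe`, `config`,
#'   `mean_trajectory` (per-step mean over replicates of the
#'   population-mean fitness), and optionally `replicates`.
#' @examples
#' e <- run_ensemble(chlamy_dfe(), sim_config(N = 100, steps = 100),
#'                   n_replicates = 5, seed_base = 1)
#' conducivity(e)
#' @export
run_ensemble <- function(dfe, config, n_replicates = 100, seed_base = 1,
                         track_expression = FALSE,
                         collect_delta_A = FALSE,
                         keep_replicates = FALSE,
                         early_stop = FALSE,
                         jump_prob = 0, jump_effect = 0.15,
                         grid_index = 0, d_index = 0) {
  dfe <- as_dfe_params(dfe)
  stopifnot(n_replicates >= 1)
  need_cross <- ceiling(n_replicates / 2)        # conducive when reached
  need_ever <- floor(n_replicates / 2) + 1L      # ">half ever cross"
  n_crossed <- n_ever <- 0L
  reps <- vector("list", n_replicates)
  traj_sum <- numeric(config$steps + 1)
  rows <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    r <- run_replicate(dfe, config,
                       seed = derive_seed(seed_base, grid_index, d_index, k),
                       track_expression = track_expression,
                       collect_delta_A = collect_delta_A,
                       jump_prob = jump_prob, jump_effect = jump_effect)
    traj_sum <- traj_sum + r$trajectory$mean_F
    dc <- if (track_expression) trajectory_driver_correlations(r)
          else list(cor_F_E = NA_real_, cor_F_A = NA_real_)
    rows[[k]] <- data.frame(
      replicate = k, seed = r$seed,
      crossed = r$crossed, retained = r$retained,
      ever_crossed = r$ever_crossed, extinct = r$extinct,
      coalesced = r$coalesced,
      lca_time = r$lca_time, lca_fitness = r$lca_fitness,
      min_mean_fitness = r$min_mean_fitness,
      time_of_min = r$time_of_min,
      final_carriers = sum(r$final$L),
      cor_F_E = dc$cor_F_E, cor_F_A = dc$cor_F_A)
    if (keep_replicates || collect_delta_A) reps[[k]] <- r
    if (early_stop) {
      n_crossed <- n_crossed + r$crossed
      n_ever <- n_ever + r$ever_crossed
      remaining <- n_replicates - k
      cross_decided <- n_crossed >= need_cross ||
        n_crossed + remaining < need_cross
      ever_decided <- n_ever >= need_ever ||
        n_ever + remaining < need_ever
      if (cross_decided && ever_decided) break
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  attr(out, "dfe") <- dfe
  attr(out, "config") <- config
  attr(out, "seed_base") <- seed_base
  attr(out, "mean_trajectory") <- traj_sum / nrow(out)
  attr(out, "n_target") <- n_replicates
  if (collect_delta_A)
    attr(out, "delta_A") <- collect_delta_A(reps[!vapply(reps, is.null,
                                                         logical(1))])
  if (keep_replicates) attr(out, "replicates") <- reps
  class(out) <- c("gb_ensemble", "data.frame")
  out
}

#' Conducivity of a replicate ensemble
#'
#' The conducivity of a parameter set is the fraction of replicate
#' populations in which the locus is retained and the fitness of the
#' last common ancestor of the final population exceeds the fitness
#' threshold. A parameter set is conducive when its conducivity is at
#' least `conducive_at` (0.5: at least half the replicates crossed).
#'
#' @param results A `gb_ensemble` data frame, or a logical vector of
#'   per-replicate crossing flags.
#' @param conducive_at Threshold on the fraction.
#' @return List with `conducivity` (fraction crossed) and logical
#'   `conducive`.
#' @export
conducivity <- function(results, conducive_at = 0.5) {
  crossed <- if (is.data.frame(results)) results$crossed else results
  frac <- mean(crossed)
  list(conducivity = frac, conducive = frac >= conducive_at)
}

#' Minimum of a mean-fitness trajectory
#'
#' @param replicate A `gb_replicate`, or a numeric trajectory of
#'   population-mean fitness (time starting at 0).
#' @return List with `min_mean_fitness` and `time_of_min` (argmin in
#'   time-steps; ties broken by the earliest step).
#' @export
trajectory_summary <- function(replicate) {
  traj <- if (inherits(replicate, "gb_replicate"))
    replicate$trajectory$mean_F else as.numeric(replicate)
  list(min_mean_fitness = min(traj),
       time_of_min = which.min(traj) - 1L)
}

#' Correlation of fitness with expression and adaptive-value trajectories
#'
#' Pearson correlations, over time-steps, of the population-mean
#' fitness trajectory with the carrier-mean expression and
#' adaptive-value trajectories. A positive correlation with adaptive
#' value (expression) indicates that fitness change is driven by
#' functionality (expression). Steps with no carriers are dropped;
#' constant trajectories give `NA`.
#'
#' @param replicate A `gb_replicate` run with `track_expression = TRUE`.
#' @return List with `cor_F_E` and `cor_F_A`.
#' @export
trajectory_driver_correlations <- function(replicate) {
  tr <- replicate$trajectory
  ok <- !is.na(tr$mean_E)
  safe_cor <- function(x, y) {
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  list(cor_F_E = safe_cor(tr$mean_F, tr$mean_E),
       cor_F_A = safe_cor(tr$mean_F, tr$mean_A))
}

#' Sweep replicate ensembles over a grid of DFEs
#'
#' Runs one ensemble per (DFE, deletion probability) combination and
#' aggregates per-parameter-set outcomes. Seeds derive from
#' `(seed_base, grid row, d index, replicate)`, so any sub-grid of a
#' sweep reproduces the corresponding rows of the full sweep.
#'
#' @param grid A [dfe_grid()] or data frame with columns `p,f,n,s`.
#' @param config A [sim_config()]; its `d` is ignored in favour of `d`.
#' @param n_replicates Replicates per parameter set.
#' @param d Vector of locus-deletion probabilities to sweep.
#' @param seed_base Base seed.
#' @param time_of_min_method `"replicate_mean"` (mean over replicates
#'   of the per-replicate argmin; default) or `"ensemble_argmin"`
#'   (argmin of the replicate-averaged trajectory).
#' @param early_stop Per parameter set, stop its ensemble as soon as
#'   the conducive and crossed classifications are decided (see
#'   [run_ensemble()]); the reported `conducive` flags and the counts
#'   built on them are identical to the full run, while the continuous
#'   columns then rest on the completed replicate prefix (`n_run`
#'   records how many replicates each row used). Default `FALSE`.
#' @param verbose Print one progress line per parameter set.
#'
#' @return A `gb_sweep` data frame with one row per (DFE, d):
#'   parameters, `conducivity` and logical `conducive` (LCA definition,
#'   threshold 0.5), `cross_fraction` (fraction of replicates whose
#'   fixed lineage ever exceeded the threshold), `loss_fraction`
#'   (fraction not retaining the locus), `extinct_fraction`,
#'   `mean_min_fitness`, `mean_time_of_min` and `n_replicates`.
#' @export
run_sweep <- function(grid, config, n_replicates = 20, d = 0,
                      seed_base = 1,
                      time_of_min_method = c("replicate_mean",
                                             "ensemble_argmin"),
                      early_stop = FALSE,
                      verbose = FALSE) {
  time_of_min_method <- match.arg(time_of_min_method)
  grid <- as.data.frame(grid)[, c("p", "f", "n", "s")]
  rows <- list()
  for (di in seq_along(d)) {
    cfg <- config
    cfg$d <- d[di]
    for (gi in seq_len(nrow(grid))) {
      dfe <- dfe_params(grid$p[gi], grid$f[gi], grid$n[gi], grid$s[gi])
      ens <- run_ensemble(dfe, cfg, n_replicates = n_replicates,
                          seed_base = seed_base, early_stop = early_stop,
                          grid_index = gi, d_index = di)
      tom <- if (time_of_min_method == "replicate_mean")
        mean(ens$time_of_min)
      else which.min(attr(ens, "mean_trajectory")) - 1
      cond <- conducivity(ens)
      rows[[length(rows) + 1L]] <- data.frame(
        p = dfe$p, f = dfe$f, n = dfe$n, s = dfe$s, d = cfg$d,
        conducivity = cond$conducivity, conducive = cond$conducive,
        cross_fraction = mean(ens$ever_crossed),
        loss_fraction = mean(!ens$retained),
        extinct_fraction = mean(ens$extinct),
        mean_min_fitness = mean(ens$min_mean_fitness),
        mean_time_of_min = tom,
        n_replicates = n_replicates,
        n_run = nrow(ens))
      if (verbose)
        message(sprintf(
          "d = %g, DFE %d/%d (p=%g f=%g n=%g s=%g): conducivity %.2f",
          cfg$d, gi, nrow(grid), dfe$p, dfe$f, dfe$n, dfe$s,
          cond$conducivity))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "seed_base") <- seed_base
  class(out) <- c("gb_sweep", "data.frame")
  out
}

#' Classify sweep rows by adaptation and locus retention
#'
#' Parameter sets where more than `cross_cutoff` of replicates crossed
#' the fitness threshold at some point are split into those that kept
#' the locus and those that subsequently lost it from more than
#' `loss_cutoff` of the replicate populations (adaptive proto-genes
#' that are nevertheless lost); the remainder never crossed.
#'
#' @param sweep A `gb_sweep` data frame.
#' @param loss_cutoff Loss fraction above which a crossed set counts as
#'   lost (default 0.95).
#' @param cross_cutoff Crossing fraction that defines "crossed"
#'   (default 0.5, strict).
#' @return The sweep with an added factor column `class` with levels
#'   `"retained-conducive"`, `"crossed-then-lost"`, `"not-crossed"`.
#' @export
loss_classification <- function(sweep, loss_cutoff = 0.95,
                                cross_cutoff = 0.5) {
  crossed <- sweep$cross_fraction > cross_cutoff
  lost <- sweep$loss_fraction > loss_cutoff
  cls <- ifelse(!crossed, "not-crossed",
                ifelse(lost, "crossed-then-lost", "retained-conducive"))
  sweep$class <- factor(cls, levels = c("retained-conducive",
                                        "crossed-then-lost",
                                        "not-crossed"))
  sweep
}

safe_cor_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = sum(ok)))
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Correlations between sweep outcomes and DFE census features
#'
#' Pearson correlations (with two-sided p-values from the t transform)
#' between per-DFE conducivity and the analytic class fractions, the
#' conducivity of the stringent-DFE subset (negative mutations both
#' more numerous and larger) against its negative fraction, and
#' between the per-DFE mean minimum fitness and mean time of minimum.
#' P-values are reported raw, without multiplicity correction.
#'
#' @param sweep A `gb_sweep` restricted to one deletion probability.
#' @param census Output of [dfe_census()] on the same grid (rows are
#'   merged on `p, f, n, s`).
#' @param crossed_only_min_time Also compute the min-fitness/time
#'   correlation restricted to conducive parameter sets.
#' @return Data frame with columns `pair`, `r`, `p_value`, `n`.
#' @export
sweep_correlations <- function(sweep, census,
                               crossed_only_min_time = TRUE) {
  m <- merge(as.data.frame(sweep), as.data.frame(census),
             by = c("p", "f", "n", "s"), sort = FALSE)
  pairs <- list(
    `conducivity~frac_negative` =
      safe_cor_test(m$conducivity, m$frac_negative),
    `conducivity~frac_positive` =
      safe_cor_test(m$conducivity, m$frac_positive),
    `conducivity~frac_neutral` =
      safe_cor_test(m$conducivity, m$frac_neutral),
    `stringent_conducivity~frac_negative` = {
      st <- m$negative_more_numerous & m$negative_larger
      safe_cor_test(m$conducivity[st], m$frac_negative[st])
    },
    `min_fitness~time_of_min` =
      safe_cor_test(m$mean_min_fitness, m$mean_time_of_min))
  if (crossed_only_min_time) {
    cc <- m$conducive
    pairs$`min_fitness~time_of_min|conducive` <-
      safe_cor_test(m$mean_min_fitness[cc], m$mean_time_of_min[cc])
  }
  data.frame(pair = names(pairs),
             r = vapply(pairs, `[[`, numeric(1), "r"),
             p_value = vapply(pairs, `[[`, numeric(1), "p_value"),
             n = vapply(pairs, `[[`, numeric(1), "n"),
             row.names = NULL)
}

#' Tail-shape model selection for adaptive-value increments
#'
#' Fits an exponential and a power-law (Pareto) model to the upper half
#' of the beneficial branch of the `dA` distribution by maximum
#' likelihood and selects the better model by log-likelihood on the
#' same sample. The Pareto exponent MLE is
#' `1 + m / sum(log(x / xmin))`; the (shifted) exponential rate MLE is
#' `1 / (mean(x) - xmin)`. The threshold `xmin` is a fixed quantile of
#' the fitted branch (default: the median, i.e. the upper half is
#' fitted), which makes the family contest robust both to the
#' sub-resolution bulk of near-zero increments and to over-fitting a
#' narrow tail window.
#'
#' The beneficial branch is fitted by default because the exponential
#' scale of the increments tracks the mean beneficial effect `p`;
#' pooling the two signed branches of a DFE with `p != n` superimposes
#' two different gamma scales and manufactures a spurious multi-scale
#' power-law region.
#'
#' @param delta_a Numeric vector of adaptive-value increments (pooled
#'   across individuals, steps and replicates).
#' @param side Which branch to fit: `"positive"` (default),
#'   `"negative"` (magnitudes of the deleterious branch) or
#'   `"absolute"` (both pooled).
#' @param tail_prob Quantile of the branch used as the fitting
#'   threshold (default 0.5).
#' @param n_min Minimum number of branch values required (default
#'   1000); below it the fit is declined.
#' @return A `gb_tailfit` list: `law` (`"exponential"` or
#'   `"power-law"`), `xmin`, `exponent` (Pareto alpha), `rate`
#'   (exponential), per-model log-likelihoods, tail size `n_tail`, and
#'   `declined`.
#' @export
fit_delta_a_shape <- function(delta_a,
                              side = c("positive", "negative", "absolute"),
                              tail_prob = 0.5, n_min = 1000) {
  side <- match.arg(side)
  x <- switch(side,
              positive = delta_a[delta_a > 0],
              negative = -delta_a[delta_a < 0],
              absolute = abs(delta_a))
  x <- x[is.finite(x) & x > 0]
  if (length(x) < n_min)
    return(structure(list(declined = TRUE, n = length(x), side = side),
                     class = "gb_tailfit"))
  xmin <- quantile(x, tail_prob, names = FALSE)
  tail <- x[x >= xmin]
  m <- length(tail)
  slog <- sum(log(tail / xmin))
  alpha <- 1 + m / slog
  ll_power <- m * log((alpha - 1) / xmin) - alpha * slog
  rate <- 1 / (mean(tail) - xmin)
  ll_exp <- m * log(rate) - rate * sum(tail - xmin)
  structure(list(
    law = if (ll_exp >= ll_power) "exponential" else "power-law",
    side = side, xmin = xmin, exponent = alpha, rate = rate,
    loglik_power = ll_power, loglik_exp = ll_exp,
    n_tail = m, n = length(x), declined = FALSE),
    class = "gb_tailfit")
}

#' @export
print.gb_tailfit <- function(x, ...) {
  if (isTRUE(x$declined)) {
    cat("Tail fit declined: too few samples (", x$n, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "%s branch of dA above %.3g (n = %d): %s preferred\n",
    x$side, x$xmin, x$n_tail, x$law))
  cat(sprintf(
    "  power-law exponent %.3f (logLik %.1f) vs exponential rate %.3g (logLik %.1f)\n",
    x$exponent, x$loglik_power, x$rate, x$loglik_exp))
  invisible(x)
}

#' Adaptation under a rare large-effect jump scenario
#'
#' Runs the high mutation-rate regime with an otherwise non-conducive
#' DFE (`p = 0.001, f = 0.25, n = 0.005, s = 0.1`) augmented by an atom
#' of extremely rare (probability `1e-4`), large beneficial mutations
#' (`dF = 0.15`) that replace the gamma draw, and reports the
#' conducivity: even vanishingly rare large-effect beneficial mutations
#' suffice for adaptation in this regime.
#'
#' @param config A [sim_config()] with `regime = "high"`.
#' @param n_replicates Ensemble size.
#' @param seed_base Base seed.
#' @param jump_prob,jump_effect Jump atom parameters.
#' @param dfe Baseline DFE (defaults to the non-conducive set above).
#' @return List with `conducivity`, `conducive` and the ensemble.
#' @export
rare_jump_scenario <- function(config, n_replicates = 100, seed_base = 1,
                               jump_prob = 1e-4, jump_effect = 0.15,
                               dfe = dfe_params(p = 0.001, f = 0.25,
                                                n = 0.005, s = 0.1)) {
  stopifnot(config$regime == "high")
  ens <- run_ensemble(dfe, config, n_replicates = n_replicates,
                      seed_base = seed_base,
                      jump_prob = jump_prob, jump_effect = jump_effect)
  c(conducivity(ens), list(ensemble = ens))
}
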