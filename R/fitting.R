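#' Split per-condition duration arrays into train/test summaries
#'
#' For every reafference condition, half of the bout-duration and half of
#' the interbout-duration observations (rounding the extra element into the
#' training half) are drawn at random; per-condition means of each half
#' form the 36-value training and test summaries used by
#' [fit_controller()].
#'
#' @param ds a data frame with columns `condition`, `metric`
#'   (`"bout"`/`"interbout"`) and `value_ms` — one row per observed
#'   duration.
#' @param seed integer seed for the random split.
#' @return list of two data frames (`train`, `test`) with columns
#'   `condition`, `metric`, `mean_ms`.
#' @export
split_durations <- function(ds, seed = NULL) {
  need <- c("condition", "metric", "value_ms")
  if (!all(need %in% names(ds))) stop("`ds` must have columns ",
                                      paste(need, collapse = ", "))
  groups <- split(ds$value_ms, list(ds$metric, ds$condition), drop = TRUE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every condition/metric array needs at least 2 observations")
  with_seed(seed, {
    key <- do.call(rbind, strsplit(names(groups), "\\.", perl = FALSE))
    tr <- te <- numeric(length(groups))
    for (i in seq_along(groups)) {
      v <- groups[[i]]
      n_train <- ceiling(length(v) / 2)
      pick <- sample.int(length(v), n_train)
      tr[i] <- mean(v[pick])
      te[i] <- mean(v[-pick])
    }
    list(train = data.frame(condition = key[, 2], metric = key[, 1],
                            mean_ms = tr, stringsAsFactors = FALSE),
         test = data.frame(condition = key[, 2], metric = key[, 1],
                           mean_ms = te, stringsAsFactors = FALSE))
  })
}

#' Normalized mean absolute error between duration summaries
#'
#' The fitting objective: the mean over the 36 summary entries (18 bout
#' means + 18 interbout means) of the absolute model-target difference
#' normalized by the target. Entries for which the model produced no output
#' (no third bout in the test trial) contribute a fixed pessimistic penalty
#' so the objective stays finite for degenerate parameter sets.
#'
#' @param model_summary,target_summary numeric vectors of equal length and
#'   ordering (model entries may be `NA`).
#' @param penalty value contributed by missing model entries.
#' @return the error (dimensionless).
#' @examples
#' duration_mae(c(110, 220), c(100, 200))  # 0.1
#' @export
duration_mae <- function(model_summary, target_summary, penalty = 2) {
  if (length(model_summary) != length(target_summary))
    stop("summaries must have equal length")
  if (any(!is.finite(target_summary) | target_summary == 0))
    stop("target summary entries must be non-zero finite (cannot normalize)")
  err <- abs(model_summary - target_summary) / target_summary
  err[is.na(model_summary)] <- penalty
  mean(err)
}

#' Default parameter bounds for fitting
#'
#' Time constants span 0.05-20 s (searched on a log scale), weights
#' 0.001-10, the threshold 0.01-1: wide enough to cover
#' physiological-scale dynamics while keeping the unit-clipped sensory
#' drive meaningful.
#'
#' @return an 8 x 2 matrix of lower/upper bounds, rows named by parameter.
#' @export
default_bounds <- function() {
  b <- rbind(omega_f = c(0.001, 10), omega_r = c(0.001, 10),
             tau_s = c(0.05, 20), thr = c(0.01, 1),
             omega_s = c(0.001, 10), omega_m = c(0.001, 10),
             tau_m = c(0.05, 20), omega_i = c(0.001, 10))
  colnames(b) <- c("lower", "upper")
  b
}

#' Fit the controller to a duration summary with a genetic algorithm
#'
#' Minimizes the normalized mean absolute error ([duration_mae()]) between
#' the model's 36-value duration table (second-bout and second-interbout
#' durations across the 18 unique reafference conditions, from the short
#' model test trial) and a target summary. The optimizer is a standard
#' generational GA: tournament selection, uniform crossover, per-gene
#' Gaussian mutation and elitism; time constants are searched in log space.
#' The objective, not the optimizer, is normative — any derivative-free
#' method reaching the same error would do.
#'
#' @param target a data frame with columns `condition`, `metric`,
#'   `mean_ms` covering the 18 conditions x 2 metrics (as produced by
#'   [split_durations()] or from [model_duration_table()] output).
#' @param test optional second summary used only to report a held-out
#'   error.
#' @param bounds parameter bounds, see [default_bounds()].
#' @param control list overriding GA settings: `pop_size` (64),
#'   `generations` (200), `tournament_k` (3), `crossover_p` (0.5),
#'   `mutation_p` (0.2), `mutation_sd` (0.1, in fractions of the bound
#'   range), `elite` (2), `penalty` (2).
#' @param dt simulation step (s).
#' @param seed integer seed; the fit is reproducible given the seed.
#' @return an object of class `controller_fit`: fitted `params`,
#'   `train_error`, `test_error`, per-generation best-error `history`,
#'   the aligned `target`, and the call settings.
#' @export
fit_controller <- function(target, test = NULL, bounds = default_bounds(),
                           control = list(), dt = 0.005, seed = NULL) {
  ctl <- modifyList(list(pop_size = 64L, generations = 200L,
                         tournament_k = 3L, crossover_p = 0.5,
                         mutation_p = 0.2, mutation_sd = 0.1, elite = 2L,
                         penalty = 2), control)
  if (!is.matrix(bounds) || nrow(bounds) != 8L ||
      any(bounds[, 2] <= bounds[, 1]) || any(bounds[, 1] <= 0))
    stop("`bounds` must be an 8 x 2 matrix of positive lower < upper bounds")
  conds <- enumerate_conditions(dt)
  tvec <- align_summary(target, conds)
  tevec <- if (!is.null(test)) align_summary(test, conds)
  cond_mat <- encode_conditions(conds, dt)
  seg <- round(0.075 / dt)
  log_scale <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  lo <- ifelse(log_scale, log(bounds[, 1]), bounds[, 1])
  hi <- ifelse(log_scale, log(bounds[, 2]), bounds[, 2])

  decode <- function(g) {
    v <- ifelse(log_scale, exp(g), g)
    controller_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8])
  }
  evaluate <- function(g) {
    tbl <- model_trial_table_cpp(as_param_vector(decode(g)), cond_mat, dt,
                                 0.3, 9.7, 10, seg)
    duration_mae(as.numeric(tbl), tvec, ctl$penalty)
  }

  with_seed(seed, {
    np <- ctl$pop_size
    pop <- t(replicate(np, runif(8, lo, hi)))
    fit <- apply(pop, 1, evaluate)
    history <- numeric(ctl$generations)
    for (gen in seq_len(ctl$generations)) {
      ord <- order(fit)
      newpop <- pop[ord[seq_len(ctl$elite)], , drop = FALSE]
      while (nrow(newpop) < np) {
        pick <- function() {
          cand <- sample.int(np, ctl$tournament_k)
          cand[which.min(fit[cand])]
        }
        pa <- pop[pick(), ]; pb <- pop[pick(), ]
        cross <- runif(8) < ctl$crossover_p
        child <- ifelse(cross, pb, pa)
        mut <- runif(8) < ctl$mutation_p
        child[mut] <- child[mut] +
          rnorm(sum(mut), 0, ctl$mutation_sd * (hi - lo)[mut])
        newpop <- rbind(newpop, pmin(pmax(child, lo), hi))
      }
      pop <- newpop
      fit <- apply(pop, 1, evaluate)
      history[gen] <- min(fit)
    }
    history <- cummin(c(min(fit), history))[-1]
    best <- pop[which.min(fit), ]
    params <- decode(best)
    model <- model_trial_table_cpp(as_param_vector(params), cond_mat, dt,
                                   0.3, 9.7, 10, seg)
    structure(list(
      params = params,
      train_error = duration_mae(as.numeric(model), tvec, ctl$penalty),
      test_error = if (!is.null(tevec))
        duration_mae(as.numeric(model), tevec, ctl$penalty),
      history = history, seed = seed, control = ctl, dt = dt,
      target = data.frame(condition = rep(condition_labels(conds), 2),
                          metric = rep(c("bout", "interbout"),
                                       each = length(conds)),
                          target_ms = tvec,
                          model_ms = as.numeric(model))),
      class = "controller_fit")
  })
}

# Order a condition/metric/mean_ms data frame into the 36-vector layout
# used internally: 18 bout means then 18 interbout means, in enumeration
# order.
align_summary <- function(summary, conds) {
  labs <- condition_labels(conds)
  out <- numeric(2 * length(labs))
  for (m in c("bout", "interbout")) {
    sel <- summary[summary$metric == m, ]
    idx <- match(labs, sel$condition)
    if (any(is.na(idx)))
      stop("summary is missing conditions for metric ", m, ": ",
           paste(labs[is.na(idx)], collapse = ", "))
    off <- if (m == "bout") 0L else length(labs)
    out[off + seq_along(labs)] <- sel$mean_ms[idx]
  }
  out
}

#' @export
print.controller_fit <- function(x, ...) {
  cat("<controller fit>\n")
  cat(sprintf("  train MAE: %.4f", x$train_error))
  if (!is.null(x$test_error)) cat(sprintf("  test MAE: %.4f", x$test_error))
  cat(sprintf("  (%d generations)\n", length(x$history)))
  invisible(x)
}

#' @export
coef.controller_fit <- function(object, ...) {
  p <- unclass(object$params)
  p[seq_len(8)]
}

#' @export
summary.controller_fit <- function(object, ...) {
  checks <- acute_ordering_checks(predict(object))
  out <- list(fit = object, checks = checks)
  class(out) <- "summary.controller_fit"
  out
}

#' @export
print.summary.controller_fit <- function(x, ...) {
  print(x$fit)
  cat("  parameters:\n")
  print(round(coef(x$fit), 4))
  cat("  qualitative acute-reaction checks:",
      sum(x$checks, na.rm = TRUE), "of", length(x$checks), "pass\n")
  invisible(x)
}

#' @export
predict.controller_fit <- function(object, conditions = NULL, ...) {
  model_duration_table(object$params, conditions, object$dt)
}

#' @export
simulate.controller_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_controller(object$params, ..., dt = object$dt)
}

#' @export
plot.controller_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(seq_along(x$history), x$history, type = "l", log = "y",
       xlab = "generation", ylab = "best MAE", main = "GA convergence")
  lim <- range(c(x$target$target_ms, x$target$model_ms), na.rm = TRUE)
  plot(x$target$target_ms, x$target$model_ms, xlim = lim, ylim = lim,
       pch = ifelse(x$target$metric == "bout", 19, 1),
       xlab = "target duration (ms)", ylab = "model duration (ms)",
       main = "model vs target")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit a `controller_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(list(params = as.list(coef(fit)),
                            train_error = fit$train_error,
                            test_error = fit$test_error,
                            history = fit$history, seed = fit$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
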