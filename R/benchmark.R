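#' Enumerate a benchmark run manifest
#'
#' Deterministically enumerates every pose record of a benchmark
#' configuration (systems x antibody-modeling tools x models per tool x
#' docking engines x poses per engine) and reports the expected totals: the
#' overall pose count and the count per free-antibody conformational
#' ensemble per docking tool (one tool's models across all systems on one
#' engine).
#'
#' @param systems character vector of system ids (or an integer count).
#' @param tools character vector of antibody-modeling tool tags.
#' @param models_per_tool antibody models per tool per system.
#' @param engines character vector of docking-engine tags.
#' @param poses_per_engine docked poses retained per engine.
#' @param expand also return the full record table (default `TRUE`).
#' @return list of class `run_manifest`: `total`,
#'   `per_ensemble_per_engine`, the dimension sizes, and `records` when
#'   expanded.
#' @export
enumerate_manifest <- function(systems, tools = "tool", models_per_tool = 1,
                               engines = "engine", poses_per_engine = 1,
                               expand = TRUE) {
  if (is.numeric(systems) && length(systems) == 1)
    systems <- sprintf("system%03d", seq_len(systems))
  dims <- c(systems = length(systems), tools = length(tools),
            models_per_tool = models_per_tool,
            engines = length(engines), poses_per_engine = poses_per_engine)
  if (any(dims < 1))
    stop("config error: zero-size dimension(s): ",
         paste(names(dims)[dims < 1], collapse = ", "))
  total <- prod(dims)
  per_ensemble <- length(systems) * models_per_tool * poses_per_engine
  records <- NULL
  if (expand) {
    records <- expand.grid(pose = seq_len(poses_per_engine),
                           model = seq_len(models_per_tool),
                           engine = engines, tool = tools, system = systems,
                           stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
    records <- records[, c("system", "tool", "model", "engine", "pose")]
    stopifnot(nrow(records) == total)
  }
  structure(list(total = total, per_ensemble_per_engine = per_ensemble,
                 dims = dims, records = records),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", x$total, "pose records (",
      x$per_ensemble_per_engine, "per ensemble per engine )\n")
  invisible(x)
}

#' Naive (random) model selection
#'
#' Uniform random subset of an ensemble without replacement, reproducible
#' by seed.
#'
#' @param model_ids candidate ids.
#' @param k number of models to select.
#' @param seed RNG seed.
#' @return character/integer vector of selected ids.
#' @export
naive_selection <- function(model_ids, k, seed = NULL) {
  if (k < 1 || k > length(model_ids))
    stop("size error: k must lie in [1, ", length(model_ids), "]")
  if (!is.null(seed)) set.seed(seed)
  model_ids[sample.int(length(model_ids), k)]
}

#' Confidence-guided model filtering
#'
#' Rejects antibody models whose certainty falls below a threshold. Systems
#' left without any surviving model are excluded; the number of systems
#' remaining and the mean CDR-H3 length of the survivors are reported, and
#' results falling below a minimum representation of the system set are
#' flagged for suppression in plots/outputs.
#'
#' @param models data.frame with columns `system`, `model_id`, `certainty`
#'   and optionally `h3_length`.
#' @param threshold certainty threshold; models with `certainty <
#'   threshold` are rejected.
#' @param min_representation minimum retained fraction of systems for the
#'   data point to be reported (default 0.05).
#' @return list: `retained` (filtered data.frame), `systems_remaining`,
#'   `mean_h3_length` (NA without an `h3_length` column), `suppressed`.
#' @export
certainty_filter <- function(models, threshold,
                             min_representation = 0.05) {
  stopifnot(all(c("system", "model_id", "certainty") %in% names(models)))
  keep <- models$certainty >= threshold
  retained <- models[keep, , drop = FALSE]
  n_sys <- length(unique(models$system))
  remaining <- length(unique(retained$system))
  mean_h3 <- if ("h3_length" %in% names(models) && nrow(retained))
    mean(retained$h3_length) else NA_real_
  list(retained = retained, systems_remaining = remaining,
       mean_h3_length = mean_h3,
       suppressed = remaining < min_representation * n_sys)
}

#' Top-N success rate
#'
#' A system succeeds when any of its top-`n` ranked poses reaches the DockQ
#' threshold; the rate is the fraction of successful systems. Systems
#' listed in `systems` but absent from the pose table count as failures
#' (with a warning).
#'
#' @param poses data.frame with columns `system`, `rank`, `dockq`.
#' @param n depth of the ranked list considered.
#' @param dockq_threshold success threshold (0.23 epitope mapping, 0.49
#'   antibody design).
#' @param systems optional full system list.
#' @return list of class `success_table`: `rate`, `per_system` (named
#'   logical), `n`, `dockq_threshold`.
#' @export
topn_success <- function(poses, n = 5, dockq_threshold = 0.23,
                         systems = NULL) {
  stopifnot(all(c("system", "rank", "dockq") %in% names(poses)))
  if (is.null(systems)) systems <- unique(poses$system)
  top <- poses[poses$rank <= n, , drop = FALSE]
  hit <- tapply(top$dockq >= dockq_threshold, top$system, any)
  per_system <- stats::setNames(rep(FALSE, length(systems)), systems)
  per_system[names(hit)] <- as.logical(hit)
  empty <- setdiff(systems, unique(poses$system))
  if (length(empty))
    warning("system(s) without poses counted as failures: ",
            paste(empty, collapse = ", "))
  structure(list(rate = mean(per_system), per_system = per_system,
                 n = n, dockq_threshold = dockq_threshold),
            class = "success_table")
}

#' Pool ranked pose lists across engines
#'
#' Union of per-engine composite rankings re-sorted by the global composite
#' order (total descending, then `z_iptm`, then `pose_id`); duplicated pose
#' ids are kept once.
#'
#' @param rankings list of `composite_ranking` data.frames whose composite
#'   scores were standardized per engine.
#' @return combined `composite_ranking`.
#' @export
pool_engines <- function(rankings) {
  all <- do.call(rbind, lapply(rankings, as.data.frame))
  all <- all[order(-all$total, -all$z_iptm, all$pose_id), , drop = FALSE]
  all <- all[!duplicated(all$pose_id), , drop = FALSE]
  all$rank <- seq_len(nrow(all))
  rownames(all) <- NULL
  structure(all, class = c("composite_ranking", "data.frame"))
}

#' Bootstrap a success rate
#'
#' Resamples the success indicators with replacement (unit: the antibody
#' models, or systems) and recomputes the rate per iteration, reporting the
#' bootstrap mean and a percentile interval.
#'
#' @param success logical (or 0/1) vector of per-unit success indicators.
#' @param iterations bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @param conf interval coverage (default 0.95, i.e. the 2.5--97.5
#'   percentile interval).
#' @return list: `rate` (point estimate), `boot_mean`, `lower`, `upper`,
#'   `iterations`.
#' @export
bootstrap_success <- function(success, iterations = 200, seed = NULL,
                              conf = 0.95) {
  success <- as.logical(success)
  if (length(success) < 2)
    stop("bootstrap requires at least 2 units")
  if (!is.null(seed)) set.seed(seed)
  n <- length(success)
  rates <- vapply(seq_len(iterations), function(i)
    mean(success[sample.int(n, n, replace = TRUE)]), numeric(1))
  qs <- stats::quantile(rates, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(rate = mean(success), boot_mean = mean(rates),
       lower = qs[1], upper = qs[2], iterations = iterations)
}

#' Success rate as a function of the certainty threshold
#'
#' Sweeps a certainty threshold over a model table carrying per-model
#' success indicators: at each threshold, models below it are rejected via
#' [certainty_filter()], systems without survivors leave the denominator,
#' and the success rate is the fraction of remaining systems with at least
#' one successful surviving model. This is the confidence-guided selection
#' curve; points whose retained system fraction falls below
#' `min_representation` are flagged `suppressed`.
#'
#' @param models data.frame with `system`, `model_id`, `certainty`,
#'   `success` (logical) and optionally `h3_length`.
#' @param thresholds numeric vector of certainty thresholds.
#' @param min_representation minimum retained system fraction.
#' @return data.frame: `threshold`, `systems_remaining`, `mean_h3_length`,
#'   `success_rate` (NA when no system remains), `suppressed`.
#' @export
threshold_sweep <- function(models, thresholds,
                            min_representation = 0.05) {
  stopifnot("success" %in% names(models))
  rows <- lapply(thresholds, function(th) {
    flt <- certainty_filter(models, th, min_representation)
    rate <- if (nrow(flt$retained))
      mean(tapply(flt$retained$success, flt$retained$system, any))
    else NA_real_
    data.frame(threshold = th, systems_remaining = flt$systems_remaining,
               mean_h3_length = flt$mean_h3_length, success_rate = rate,
               suppressed = flt$suppressed)
  })
  do.call(rbind, rows)
}

#' Significance star codes
#'
#' @param p numeric vector of p-values.
#' @return `"***"` for p < .001, `"**"` for p < .01, `"*"` for p < .05,
#'   `""` otherwise.
#' @export
star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Success/failure discriminant statistics for interface properties
#'
#' For each property column, compares the mean over successfully predicted
#' complexes with the mean over failures: the standardized difference is
#' the Cohen's-d style pooled-sd difference `(mean_success - mean_failure)
#' / sd_pooled`, and the p-value comes from a Welch two-sample t-test.
#' Positive differences indicate higher success when the property is high.
#'
#' @param panel data.frame of per-system property values (numeric columns).
#' @param success logical vector, one entry per row of `panel` (for pooled
#'   multi-tool analyses, the union of successes across tools).
#' @return data.frame: `property`, `mean_success`, `mean_failure`,
#'   `std_difference`, `p_value`, `stars`, `n_success`, `n_failure`.
#'   Properties with fewer than 2 systems in either group are skipped with
#'   a warning.
#' @export
discriminant_stats <- function(panel, success) {
  success <- as.logical(success)
  stopifnot(length(success) == nrow(panel))
  num <- names(panel)[vapply(panel, is.numeric, TRUE)]
  rows <- lapply(num, function(prop) {
    xs <- panel[[prop]][success]
    xf <- panel[[prop]][!success]
    xs <- xs[is.finite(xs)]; xf <- xf[is.finite(xf)]
    if (length(xs) < 2 || length(xf) < 2) {
      warning("skipping '", prop, "': fewer than 2 systems in a group")
      return(NULL)
    }
    n1 <- length(xs); n2 <- length(xf)
    sp <- sqrt(((n1 - 1) * stats::var(xs) + (n2 - 1) * stats::var(xf)) /
                 (n1 + n2 - 2))
    d <- if (sp > 0) (mean(xs) - mean(xf)) / sp else 0
    p <- stats::t.test(xs, xf, var.equal = FALSE)$p.value
    data.frame(property = prop, mean_success = mean(xs),
               mean_failure = mean(xf), std_difference = d, p_value = p,
               stars = star_code(p), n_success = n1, n_failure = n2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
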