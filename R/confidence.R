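#' Z-standardize values against a population
#'
#' Standardization throughout the package uses the population convention:
#' the standard deviation divides by n, not n - 1, matching the use of the
#' arithmetic mean and standard deviation of the full model population.
#'
#' @param values numeric vector to standardize.
#' @param population numeric vector defining mean and sd; defaults to
#'   `values` itself.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return `(values - mean(population)) / sd(population)`.
#' @export
zscore <- function(values, population = values,
                   sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(population) < 2)
    stop("degenerate population: need at least 2 values")
  mu <- mean(population)
  s <- if (sd_type == "population")
    sqrt(mean((population - mu)^2)) else stats::sd(population)
  if (!is.finite(s) || s <= 0)
    stop("degenerate population: zero standard deviation")
  (values - mu) / s
}

#' Model certainty from predicted errors
#'
#' Converts tool-reported predicted errors (or B-factor-style confidences)
#' into a standardized certainty: errors are z-scored against the pooled
#' population of all models of the same tool across all systems and the sign
#' is flipped, so a smaller predicted error gives a larger certainty.
#' Populations from different tools must never be pooled; use
#' [certainty_by_tool()] for multi-tool tables.
#'
#' @param predicted_errors numeric vector, one value per model.
#' @param population pooled errors for the same tool; defaults to
#'   `predicted_errors`.
#' @param population_id tag naming the standardization population.
#' @return data.frame of class `certainty_table` with columns `model`,
#'   `predicted_error`, `certainty`, `population_id`.
#' @export
model_certainty <- function(predicted_errors, population = predicted_errors,
                            population_id = "population") {
  z <- zscore(predicted_errors, population)
  nm <- names(predicted_errors)
  if (is.null(nm)) nm <- as.character(seq_along(predicted_errors))
  structure(data.frame(model = nm, predicted_error = predicted_errors,
                       certainty = -z, population_id = population_id,
                       row.names = NULL),
            class = c("certainty_table", "data.frame"))
}

#' Certainty for a multi-tool model table
#'
#' @param models data.frame with columns `tool`, `model_id`,
#'   `predicted_error` (and any others, carried through).
#' @return `models` with a `certainty` column, standardized separately per
#'   tool over the pooled per-tool population.
#' @export
certainty_by_tool <- function(models) {
  if (!all(c("tool", "model_id", "predicted_error") %in% names(models)))
    stop("population error: models must carry tool, model_id, predicted_error")
  out <- do.call(rbind, lapply(split(models, models$tool), function(g) {
    g$certainty <- -zscore(g$predicted_error)
    g
  }))
  rownames(out) <- NULL
  out
}

#' Construct a per-pose confidence bundle
#'
#' Holds the confidence evidence attached to one docked pose: per-residue
#' pLDDT, scalar pTM, the aligned-error probability tensor over distance
#' bins (from which ipTM is derived), the residue-to-chain-group partition
#' and the physics docking score.
#'
#' @param plddt numeric vector in \[0, 100\], one value per residue.
#' @param ptm scalar in \[0, 1\].
#' @param pae_probs array `n x n x k` of probabilities over error bins;
#'   every `(i, j)` slice must sum to 1 (tolerance 1e-6).
#' @param bin_centers error-bin centers in Angstrom, length `k`.
#' @param chain_partition character vector length `n` assigning each residue
#'   to a chain group (e.g. `"antibody"` / `"antigen"`).
#' @param phys_score docking-engine score in engine-native units.
#' @param engine engine tag: `"propose"`, `"zdock"` or `"other"`.
#' @param pose_id identifier.
#' @return object of class `confidence_bundle`.
#' @export
confidence_bundle <- function(plddt, ptm, pae_probs, bin_centers,
                              chain_partition, phys_score,
                              engine = c("other", "propose", "zdock"),
                              pose_id = "pose") {
  engine <- match.arg(engine)
  n <- length(plddt)
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT outside [0, 100]")
  if (ptm < 0 || ptm > 1) stop("pTM outside [0, 1]")
  d <- dim(pae_probs)
  if (length(d) != 3 || d[1] != n || d[2] != n || d[3] != length(bin_centers))
    stop("pae_probs must be n x n x k with k = length(bin_centers)")
  sums <- apply(pae_probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("pae_probs slices do not sum to 1")
  if (length(chain_partition) != n)
    stop("chain_partition length must match plddt")
  if (!is.finite(phys_score)) stop("phys_score must be finite")
  structure(list(plddt = plddt, ptm = ptm, pae_probs = pae_probs,
                 bin_centers = bin_centers,
                 chain_partition = chain_partition,
                 phys_score = phys_score, engine = engine,
                 pose_id = pose_id),
            class = "confidence_bundle")
}

# TM-score distance normalization; clamped at 1 A (also covers N <= 15,
# where the cube-root argument goes negative)
.d0 <- function(n_res) {
  if (n_res <= 15) return(1.0)
  max(1.24 * (n_res - 15)^(1 / 3) - 1.8, 1.0)
}

#' pTM / ipTM from aligned-confidence probabilities
#'
#' Computes the expected TM-style score from the binned aligned-error
#' probability tensor: for each residue i the mean over selected partners j
#' of `sum_k p[i,j,k] / (1 + (bin_k / d0(N))^2)`, returning the maximum over
#' i. With `pair_mask = "interchain"` only cross-chain-group pairs enter the
#' mean, which yields the interface score ipTM; with `"all"` the full pTM.
#' `d0` is the usual TM-score normalization `1.24 (N - 15)^(1/3) - 1.8`
#' clamped at 1, with N the number of residues in scope (full complex).
#'
#' @param bundle a [confidence_bundle()].
#' @param pair_mask `"all"` or `"interchain"`.
#' @return scalar in \[0, 1\].
#' @export
ptm_from_probs <- function(bundle, pair_mask = c("all", "interchain")) {
  pair_mask <- match.arg(pair_mask)
  n <- length(bundle$plddt)
  k <- length(bundle$bin_centers)
  d0 <- .d0(n)
  f <- 1 / (1 + (bundle$bin_centers / d0)^2)
  # per-pair expected TM term: collapse the bin axis
  tm <- matrix(matrix(bundle$pae_probs, n * n, k) %*% f, n, n)
  mask <- if (pair_mask == "all") matrix(TRUE, n, n)
          else outer(bundle$chain_partition, bundle$chain_partition, `!=`)
  if (!any(mask)) stop("empty pair mask")
  per_i <- rowSums(tm * mask) / pmax(rowSums(mask), 1)
  max(per_i[rowSums(mask) > 0])
}

#' Equal-weight composite score for one pose
#'
#' The composite rescoring total is the unweighted sum of the four
#' standardized components: z(pLDDT) + z(pTM) + z(ipTM) + z(phys). All
#' terms are weighted equally; no renormalization is applied.
#'
#' @param z_plddt,z_ptm,z_iptm,z_phys standardized components.
#' @param pose_id identifier.
#' @return one-row data.frame of class `composite_score` with the four
#'   components and their `total`.
#' @export
composite_score <- function(z_plddt, z_ptm, z_iptm, z_phys,
                            pose_id = "pose") {
  comp <- c(z_plddt = z_plddt, z_ptm = z_ptm, z_iptm = z_iptm,
            z_phys = z_phys)
  if (length(comp) != 4 || any(!is.finite(comp)))
    stop("incomplete evidence: all four components must be finite scalars")
  structure(data.frame(pose_id = pose_id, z_plddt = z_plddt, z_ptm = z_ptm,
                       z_iptm = z_iptm, z_phys = z_phys,
                       total = sum(comp), row.names = NULL),
            class = c("composite_score", "data.frame"))
}

# z-score that tolerates a zero-spread metric (all poses identical on that
# metric carry no ranking information: contribute 0)
.safe_z <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

# default orientation of engine-native physics scores
.ENGINE_HIGHER_BETTER <- c(propose = FALSE, zdock = TRUE, other = TRUE)

#' Rescore and re-rank docking poses with the composite
#'
#' Extracts the four raw metrics from each pose's confidence bundle (mean
#' pLDDT, pTM, ipTM derived from the aligned-error probabilities, physics
#' score), standardizes each across the pose population, and ranks poses by
#' descending composite total. Physics scores are first oriented so that a
#' more favorable score maps to a more positive z (per-engine
#' higher-/lower-is-better flag), and are standardized per engine by
#' default. Ties are broken by descending `z_iptm`, then by `pose_id`.
#'
#' @param bundles list of [confidence_bundle()] objects (>= 2).
#' @param phys_scope `"per_engine"` (default) or `"pooled"`; pooling mixed
#'   engines must be requested explicitly.
#' @param higher_better optional named logical vector overriding the
#'   per-engine score orientation.
#' @return data.frame of class `composite_ranking`, one row per pose in rank
#'   order: `rank`, `pose_id`, `engine`, raw metrics, z-components, `total`.
#' @export
rescore_poses <- function(bundles, phys_scope = c("per_engine", "pooled"),
                          higher_better = NULL) {
  phys_scope <- match.arg(phys_scope)
  if (length(bundles) < 2)
    stop("rescoring needs a population of at least 2 poses")
  hb <- .ENGINE_HIGHER_BETTER
  if (!is.null(higher_better)) hb[names(higher_better)] <- higher_better
  raw <- data.frame(
    pose_id = vapply(bundles, function(b) b$pose_id, ""),
    engine = vapply(bundles, function(b) b$engine, ""),
    plddt = vapply(bundles, function(b) mean(b$plddt), 0),
    ptm = vapply(bundles, function(b) b$ptm, 0),
    iptm = vapply(bundles, function(b) ptm_from_probs(b, "interchain"), 0),
    phys = vapply(bundles, function(b) b$phys_score, 0))
  if (phys_scope == "per_engine" && length(unique(raw$engine)) > 1) {
    eng_n <- table(raw$engine)
    if (any(eng_n < 2))
      stop("population error: engine(s) with a single pose cannot be ",
           "standardized per engine: ",
           paste(names(eng_n)[eng_n < 2], collapse = ", "))
  }
  oriented <- ifelse(hb[raw$engine], raw$phys, -raw$phys)
  z_phys <- numeric(nrow(raw))
  if (phys_scope == "per_engine") {
    for (e in unique(raw$engine)) {
      i <- raw$engine == e
      z_phys[i] <- .safe_z(oriented[i])
    }
  } else {
    z_phys <- .safe_z(oriented)
  }
  out <- cbind(raw,
               z_plddt = .safe_z(raw$plddt), z_ptm = .safe_z(raw$ptm),
               z_iptm = .safe_z(raw$iptm), z_phys = z_phys)
  out$total <- out$z_plddt + out$z_ptm + out$z_iptm + out$z_phys
  out <- out[order(-out$total, -out$z_iptm, out$pose_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out[, c("rank", "pose_id", "engine", "plddt", "ptm", "iptm",
                    "phys", "z_plddt", "z_ptm", "z_iptm", "z_phys",
                    "total")],
            class = c("composite_ranking", "data.frame"))
}

# default AlphaFold-style PAE bins: 0.5 A wide, centers 0.25 .. 31.75
.DEFAULT_PAE_BINS <- seq(0.25, 31.75, by = 0.5)

#' Read a confidence JSON file
#'
#' Accepts the JSON dialect emitted by structure-prediction tools: fields
#' `plddt` (array), `ptm` (scalar), `chain_partition` (array of chain-group
#' tags) and either `pae_probs` + `bin_centers` (full probability bins,
#' nested row-major) or `pae` (a point-estimate matrix, treated as a delta
#' distribution on the nearest default bin).
#'
#' @param path JSON file.
#' @param phys_score,engine,pose_id metadata not carried by the JSON.
#' @return a [confidence_bundle()].
#' @export
read_confidence_json <- function(path, phys_score = 0, engine = "other",
                                 pose_id = sub("\\.[^.]*$", "",
                                               basename(path))) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(j$plddt)
  if (!is.null(j$pae_probs)) {
    bins <- j$bin_centers
    probs <- if (is.array(j$pae_probs) && length(dim(j$pae_probs)) == 3)
      j$pae_probs
    else aperm(array(unlist(j$pae_probs), dim = c(length(bins), n, n)),
               c(3, 2, 1))
  } else if (!is.null(j$pae)) {
    pae <- matrix(unlist(j$pae), n, n, byrow = TRUE)
    bins <- .DEFAULT_PAE_BINS
    probs <- array(0, c(n, n, length(bins)))
    idx <- matrix(vapply(as.vector(pae),
                         function(v) which.min(abs(bins - v)), 1L), n, n)
    probs[cbind(as.vector(row(pae)), as.vector(col(pae)),
                as.vector(idx))] <- 1
  } else stop("confidence JSON carries neither pae_probs nor pae")
  confidence_bundle(j$plddt, j$ptm, probs, bins, j$chain_partition,
                    phys_score, engine, pose_id)
}

#' Read physics docking scores from TSV
#'
#' @param path TSV with columns `pose_id`, `engine`, `score`.
#' @return data.frame.
#' @export
read_phys_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pose_id", "engine", "score") %in% names(df)))
    stop("scores TSV must have columns pose_id, engine, score")
  df
}

#' Write a composite ranking
#'
#' @param ranking a `composite_ranking`.
#' @param path output path; format by extension (`.json` else TSV).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(ranking, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
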