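# Sloan neutral community model: hands as pooled source, private inanimate
# surfaces as sink. Occurrence of each ASV in the sink is predicted from its
# source abundance via the upper tail of a beta distribution governed by the
# migration parameter m; deviations beyond Wilson confidence bands indicate
# selection by the sink (above) or source (below) environment.

#' Pooled source abundance profile
#'
#' Pools the source (hand) samples into a single profile. The default
#' `"mean"` mode averages relative abundances with equal weight per sample,
#' which is robust to sequencing-depth variation; `"pooled_counts"` sums raw
#' counts across source samples before normalizing, weighting samples by
#' depth. Either way the result is renormalized over the analyzed ASV set.
#'
#' @param a an `abundance_table` (mode `"mean"`) or a [count_table()]
#'   (mode `"pooled_counts"`).
#' @param source_samples sample ids forming the source pool.
#' @param asv_set ASVs to retain (default: all columns).
#' @param mode `"mean"` or `"pooled_counts"`.
#' @return Named numeric vector P summing to 1 over `asv_set`.
#' @export
pooled_source_profile <- function(a, source_samples, asv_set = NULL,
                                  mode = c("mean", "pooled_counts")) {
  mode <- match.arg(mode)
  vals <- if (inherits(a, "count_table")) a$counts else a$values
  if (is.null(asv_set)) asv_set <- colnames(vals)
  if (length(source_samples) == 0) stop("empty source sample set")
  missing <- setdiff(source_samples, rownames(vals))
  if (length(missing) > 0)
    stop("source samples absent: ", paste(missing, collapse = ", "))
  sub <- vals[source_samples, asv_set, drop = FALSE]
  P <- if (mode == "pooled_counts") {
    colSums(sub)
  } else {
    if (inherits(a, "count_table"))
      sub <- sub / rowSums(vals[source_samples, , drop = FALSE])
    colMeans(sub)
  }
  if (sum(P) == 0) stop("source profile is all zero over the ASV set")
  P / sum(P)
}

#' Observed occurrence of ASVs across sink samples
#'
#' Per ASV, the fraction of sink samples in which the ASV is detected
#' (relative abundance strictly greater than zero).
#'
#' @param a an `abundance_table`.
#' @param sink_samples sample ids of the sink community.
#' @param asv_set ASVs to report (default: all).
#' @return Named numeric vector of occurrences in \[0, 1\].
#' @export
observed_occurrence <- function(a, sink_samples,
                                asv_set = colnames(a$values)) {
  if (length(sink_samples) == 0) stop("empty sink sample set")
  colMeans(a$values[sink_samples, asv_set, drop = FALSE] > 0)
}

#' Expected occurrence under the neutral model
#'
#' Probability that an ASV with source relative abundance `P_i` exceeds the
#' detection threshold 1/N in a sink community of size N with migration
#' parameter m: the upper tail of Beta(N*P_i*m, N*(1-P_i)*m) at 1/N.
#' Degenerate cases: P_i = 0 gives 0, P_i = 1 gives 1.
#'
#' @param P_i source relative abundance(s) in \[0, 1\] (vectorized).
#' @param N sink community size (> 1).
#' @param m migration parameter in (0, 1\].
#' @return Expected occurrence(s) in \[0, 1\].
#' @export
expected_occurrence <- function(P_i, N, m) {
  if (N <= 1) stop("N must exceed 1")
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  if (any(P_i < 0 | P_i > 1)) stop("P_i must lie in [0, 1]")
  out <- numeric(length(P_i))
  pos <- P_i > 0 & P_i < 1
  out[P_i == 1] <- 1
  out[pos] <- stats::pbeta(1 / N, N * P_i[pos] * m, N * (1 - P_i[pos]) * m,
                           lower.tail = FALSE)
  out
}

#' Fit the neutral community model
#'
#' Estimates the migration parameter m by maximizing the binomial
#' log-likelihood of per-ASV detection counts across sink samples,
#' sum over ASVs of k*log(occ_exp) + (n - k)*log(1 - occ_exp), with a
#' bounded scalar search on (1e-6, 1). The community size N defaults to the
#' mean read depth of the sink samples (`n_mode = "reads"`); the literal
#' per-sample ASV richness is available as `n_mode = "richness"`. Wilson
#' score bands around the expected occurrence at the fitted m classify each
#' ASV as above (occ_obs > upper bound), below (occ_obs < lower bound) or
#' neutral.
#'
#' @param counts a [count_table()] (counts are needed for N and detection).
#' @param source_samples,sink_samples sample id vectors; samples owned by
#'   the root carrier should be excluded by the caller (see
#'   [ncm_sample_sets()]).
#' @param asv_set ASVs to fit, e.g. `top_taxa()` at ASV level; default all
#'   ASVs detected in source or sink.
#' @param P optional known source profile (named by ASV); when supplied,
#'   `source_samples` may be empty and the pooled source step is skipped
#'   (used e.g. when fitting against a known simulated source).
#' @param level confidence level of the Wilson bands (default 0.95).
#' @param n_mode `"reads"` (N = mean sink read depth) or `"richness"`
#'   (N = mean number of ASVs per sink sample).
#' @param N optional known community size, overriding `n_mode` (e.g. the
#'   true N of a simulated community).
#' @return An object of class `ncm_fit`: `m`, `N`, `n_sink_samples`,
#'   `fit_quality` (generalized R-squared of occ_obs against occ_exp),
#'   `loglik`, and `asv` — a data.frame with per-ASV `P`, `occ_obs`,
#'   `occ_exp`, `ci_lo`, `ci_hi`, `label`.
#' @export
fit_ncm <- function(counts, source_samples = character(), sink_samples,
                    asv_set = NULL, level = 0.95,
                    n_mode = c("reads", "richness"), P = NULL, N = NULL) {
  n_mode <- match.arg(n_mode)
  stopifnot(inherits(counts, "count_table"))
  a <- suppressWarnings(relative_abundance(counts))
  source_samples <- intersect(source_samples, rownames(a$values))
  sink_samples <- intersect(sink_samples, rownames(a$values))
  if (is.null(P) && length(source_samples) == 0)
    stop("empty source sample set")
  if (length(sink_samples) < 5) stop("need at least 5 sink samples")
  if (is.null(asv_set)) {
    asv_set <- if (!is.null(P)) names(P) else {
      det <- colSums(counts$counts[c(source_samples, sink_samples), ,
                                   drop = FALSE]) > 0
      colnames(counts$counts)[det]
    }
  }
  if (is.null(P)) {
    P <- pooled_source_profile(a, source_samples, asv_set)
  } else {
    if (is.null(names(P))) stop("P must be named by ASV id")
    P <- P[asv_set]
    P <- P / sum(P)
  }
  occ_obs <- observed_occurrence(a, sink_samples, asv_set)
  n <- length(sink_samples)
  k <- round(occ_obs * n)
  if (is.null(N)) {
    N <- if (n_mode == "reads") {
      mean(rowSums(counts$counts[sink_samples, , drop = FALSE]))
    } else {
      mean(rowSums(counts$counts[sink_samples, , drop = FALSE] > 0))
    }
  }
  if (N <= 1) stop("degenerate community size N")

  eps <- 1e-12
  negll <- function(m) {
    pe <- pmin(pmax(expected_occurrence(P, N, m), eps), 1 - eps)
    -sum(k * log(pe) + (n - k) * log(1 - pe))
  }
  opt <- stats::optimize(negll, interval = c(1e-6, 1), tol = 1e-8)
  # guard against a flat likelihood: the optimum must beat a coarse grid
  grid <- exp(seq(log(1e-6), log(1), length.out = 25))
  gvals <- vapply(grid, negll, numeric(1))
  if (min(gvals) < opt$objective - 1e-6) {
    opt <- stats::optimize(negll,
                           interval = range(grid[pmax(1, which.min(gvals) - 1)],
                                            grid[pmin(length(grid),
                                                      which.min(gvals) + 1)]),
                           tol = 1e-8)
  }
  if (!is.finite(opt$objective))
    stop("neutral-model fit failed to converge; likelihood grid: ",
         paste(sprintf("m=%.2g:%.4g", grid, gvals), collapse = " "))
  m_hat <- opt$minimum
  # on a likelihood plateau (e.g. fully saturated occurrence) report the
  # boundary value rather than an arbitrary interior point
  if (negll(1) <= opt$objective + 1e-9) m_hat <- 1
  occ_exp <- expected_occurrence(P, N, m_hat)
  ci <- wilson_interval(occ_exp, n, level)
  label <- ifelse(occ_obs > ci[, "hi"], "above",
                  ifelse(occ_obs < ci[, "lo"], "below", "neutral"))
  ss_res <- sum((occ_obs - occ_exp)^2)
  ss_tot <- sum((occ_obs - mean(occ_obs))^2)
  fit_quality <- 1 - ss_res / ss_tot
  structure(list(
    m = m_hat, N = N, n_sink_samples = n, level = level,
    loglik = -opt$objective, fit_quality = fit_quality,
    asv = data.frame(asv_id = asv_set, P = as.numeric(P),
                     occ_obs = as.numeric(occ_obs),
                     occ_exp = as.numeric(occ_exp),
                     ci_lo = as.numeric(ci[, "lo"]),
                     ci_hi = as.numeric(ci[, "hi"]),
                     label = label, stringsAsFactors = FALSE,
                     row.names = NULL)),
    class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("ncm_fit: m =", signif(x$m, 4), " N =", round(x$N),
      " sinks =", x$n_sink_samples,
      " R2 =", round(x$fit_quality, 3), "\n")
  print(table(x$asv$label))
  invisible(x)
}

#' Source/sink sample sets for the neutral model
#'
#' Convenience selector: post-experiment hand samples form the source and
#' post-experiment private inanimate surfaces the sink, both excluding
#' samples owned by the root carrier.
#'
#' @param meta sample metadata (from a [count_table()]).
#' @param carrier owner id of the root carrier to exclude (NULL keeps all).
#' @param sink_types surface types forming the sink community.
#' @return List with `source` and `sink` sample id vectors.
#' @export
ncm_sample_sets <- function(meta, carrier = NULL,
                            sink_types = PRIVATE_INANIMATE_TYPES) {
  post <- meta[meta$timepoint == "post", , drop = FALSE]
  if (!is.null(carrier)) post <- post[post$owner != carrier, , drop = FALSE]
  list(source = post$sample_id[post$surface_type == "hand"],
       sink = post$sample_id[post$surface_type %in% sink_types])
}

#' Summarize a neutrality partition
#'
#' Counts and fractions per label, the per-label ASV lists, and — when a
#' second fit is supplied — the fraction of shared ASVs with identical
#' labels across the two fits (partition consistency between experiments).
#'
#' @param fit an `ncm_fit`.
#' @param fit2 optional second `ncm_fit` to compare against.
#' @return List with `counts`, `fractions`, `members`, and (with `fit2`)
#'   `consistency` and `consistent_asvs`.
#' @export
partition_neutrality <- function(fit, fit2 = NULL) {
  lab <- factor(fit$asv$label, levels = c("above", "neutral", "below"))
  out <- list(counts = table(lab),
              fractions = prop.table(table(lab)),
              members = split(fit$asv$asv_id, lab))
  if (!is.null(fit2)) {
    shared <- intersect(fit$asv$asv_id, fit2$asv$asv_id)
    l1 <- fit$asv$label[match(shared, fit$asv$asv_id)]
    l2 <- fit2$asv$label[match(shared, fit2$asv$asv_id)]
    out$consistency <- mean(l1 == l2)
    out$consistent_asvs <- shared[l1 == l2]
  }
  out
}

#' Bootstrap neutrality labels by sink subsampling
#'
#' Repeatedly subsamples a fraction `f` of the sink samples without
#' replacement, refits m, and relabels every ASV; reports the fraction of
#' replicates assigning each label per ASV.
#'
#' @inheritParams fit_ncm
#' @param f subsample fraction (default 0.9).
#' @param R number of replicates (default 1000).
#' @param seed optional integer seed.
#' @param P optional known source profile, passed through to [fit_ncm()].
#' @return A data.frame (class `bootstrap_result`) with per-ASV columns
#'   `frac_above`, `frac_neutral`, `frac_below` (rows sum to 1).
#' @export
bootstrap_neutrality <- function(counts, source_samples, sink_samples,
                                 asv_set = NULL, f = 0.9, R = 1000,
                                 level = 0.95, seed = NULL, P = NULL) {
  stopifnot(f > 0, f <= 1, R >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_sub <- floor(f * length(sink_samples))
  if (n_sub < 5) stop("subsample would contain fewer than 5 sink samples")
  full <- fit_ncm(counts, source_samples, sink_samples, asv_set, level,
                  P = P)
  asv_ids <- full$asv$asv_id
  tally <- matrix(0, length(asv_ids), 3,
                  dimnames = list(asv_ids, c("above", "neutral", "below")))
  for (r in seq_len(R)) {
    sub <- sample(sink_samples, n_sub)
    fit_r <- fit_ncm(counts, source_samples, sub, asv_ids, level, P = P)
    lab <- fit_r$asv$label[match(asv_ids, fit_r$asv$asv_id)]
    for (l in c("above", "neutral", "below"))
      tally[, l] <- tally[, l] + (lab == l)
  }
  out <- as.data.frame(tally / R)
  names(out) <- paste0("frac_", names(out))
  out <- cbind(data.frame(asv_id = asv_ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  class(out) <- c("bootstrap_result", "data.frame")
  out
}
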