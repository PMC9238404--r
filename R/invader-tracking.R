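# Headline analyses: invader quantification, carrier rank analysis,
# proximity-effect statistics, eigencentrality correlation, and the
# hand-homogenization test.

#' Invader relative abundance per sample
#'
#' Sums the relative abundances of the invader ASVs in every sample.
#'
#' @param a an `abundance_table` at ASV level.
#' @param tax a [taxonomy_map()] flagging the invader ASVs.
#' @return Named numeric vector (per sample) in \[0, 1\].
#' @export
invader_abundance <- function(a, tax) {
  inv <- intersect(invader_asvs(tax), colnames(a$values))
  if (length(invader_asvs(tax)) == 0) stop("empty invader ASV set")
  if (length(inv) == 0)
    return(stats::setNames(numeric(nrow(a$values)), rownames(a$values)))
  rowSums(a$values[, inv, drop = FALSE])
}

#' Rank participants by invader contamination of their surfaces
#'
#' For each participant, the invader abundances over their owned sampled
#' surfaces are sorted in decreasing order (the rank curve) and summarized
#' by their mean, with a display band of +/- 0.2 standard deviation.
#' Participants are ordered by mean abundance; the top entries are the most
#' probable root carriers. Public surfaces are excluded.
#'
#' @param prof named invader abundance vector (from [invader_abundance()]).
#' @param meta sample metadata covering the names of `prof`.
#' @return List with `ranking` (data.frame participant, mean_abundance,
#'   sd_abundance, band, n_surfaces; ordered, ties broken by id) and
#'   `curves` (per-participant sorted abundance vectors).
#' @export
rank_participants <- function(prof, meta) {
  meta <- meta[match(names(prof), meta$sample_id), , drop = FALSE]
  keep <- meta$timepoint == "post" & meta$owner != "public"
  prof <- prof[keep]
  meta <- meta[keep, , drop = FALSE]
  if (length(prof) == 0) stop("no post-experiment owned surfaces in profile")
  curves <- lapply(split(prof, meta$owner),
                   function(x) sort(x, decreasing = TRUE))
  no_surface <- setdiff(unique(meta$owner), names(curves))
  if (length(no_surface) > 0)
    warning("participants without sequenced surfaces omitted: ",
            paste(no_surface, collapse = ", "))
  mu <- vapply(curves, mean, numeric(1))
  sdv <- vapply(curves, function(x) if (length(x) > 1) stats::sd(x) else 0,
                numeric(1))
  ranking <- data.frame(participant = names(curves),
                        mean_abundance = as.numeric(mu),
                        sd_abundance = as.numeric(sdv),
                        band = 0.2 * as.numeric(sdv),
                        n_surfaces = vapply(curves, length, integer(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  ranking <- ranking[order(-ranking$mean_abundance, ranking$participant), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  if (length(unique(ranking$mean_abundance)) < nrow(ranking))
    ranking$tied <- duplicated(ranking$mean_abundance) |
      duplicated(ranking$mean_abundance, fromLast = TRUE)
  list(ranking = ranking, curves = curves)
}

#' Proximity effect of the carrier on surface contamination
#'
#' Tests whether invader contamination on private inanimate surfaces
#' declines with geodesic distance from the carrier's hands. Surfaces are
#' bucketed at distance 1, 2, and >= 3 (unreachable included); a
#' Kruskal-Wallis omnibus test is followed by pairwise Dunn tests with
#' Benjamini-Hochberg adjustment. Carrier-owned surfaces are excluded.
#'
#' @param prof named invader abundance vector.
#' @param dist distance map from [geodesic_from()] (named by surface id).
#' @param meta sample metadata with `surface_id` linking samples to network
#'   vertices.
#' @param carrier owner id of the root carrier.
#' @return List with `buckets` (per-bucket n, mean, quartiles), `kruskal`,
#'   and `dunn` (pairwise data.frame).
#' @export
proximity_effect <- function(prof, dist, meta, carrier) {
  meta <- meta[match(names(prof), meta$sample_id), , drop = FALSE]
  keep <- meta$timepoint == "post" &
    meta$surface_type %in% PRIVATE_INANIMATE_TYPES &
    meta$owner != carrier & meta$owner != "public"
  prof <- prof[keep]
  meta <- meta[keep, , drop = FALSE]
  d <- dist[meta$surface_id]
  bucket <- bucket_distances(d)
  ok <- !is.na(bucket)
  prof <- prof[ok]; bucket <- droplevels(bucket[ok])
  if (nlevels(bucket) < 2)
    stop("fewer than 2 non-empty distance buckets")
  test <- dunn_test(prof, bucket)
  qs <- t(vapply(split(prof, bucket), stats::quantile, numeric(5),
                 probs = c(0, 0.25, 0.5, 0.75, 1)))
  buckets <- data.frame(bucket = levels(bucket),
                        n = as.integer(table(bucket)),
                        mean = as.numeric(tapply(prof, bucket, mean)),
                        q25 = qs[, 2], median = qs[, 3], q75 = qs[, 4],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(buckets = buckets, kruskal = test$kruskal, dunn = test$pairs)
}

#' Correlation of invader contamination with surface eigencentrality
#'
#' Spearman correlation between invader abundance and touch-network
#' eigencentrality over private inanimate surfaces, excluding (i) surfaces
#' owned by the carrier, (ii) surfaces the carrier touched more than
#' `max_carrier_touches` times, and (iii) untouched surfaces (no network
#' edge).
#'
#' @param prof named invader abundance vector.
#' @param centrality named eigencentrality vector (from
#'   [eigencentrality()]).
#' @param meta sample metadata with `surface_id`.
#' @param net the `touch_network` (for carrier touch counts and degree).
#' @param carrier owner id of the root carrier.
#' @param max_carrier_touches exclusion threshold (default 5).
#' @return List with `rho`, `p`, `n`, and the retained `surface_id`s. `rho`
#'   is NA when centrality is constant over the retained surfaces.
#' @export
eigencentrality_correlation <- function(prof, centrality, meta, net, carrier,
                                        max_carrier_touches = 5) {
  meta <- meta[match(names(prof), meta$sample_id), , drop = FALSE]
  keep <- meta$timepoint == "post" &
    meta$surface_type %in% PRIVATE_INANIMATE_TYPES &
    meta$owner != carrier & meta$owner != "public"
  prof <- prof[keep]
  meta <- meta[keep, , drop = FALSE]
  carrier_hand <- paste(carrier, "hand", sep = "_")
  ec <- net$counts
  carrier_touches <- stats::setNames(numeric(nrow(meta)), meta$surface_id)
  hit <- ec$surface_u == carrier_hand | ec$surface_v == carrier_hand
  other <- ifelse(ec$surface_u[hit] == carrier_hand,
                  ec$surface_v[hit], ec$surface_u[hit])
  carrier_touches[other[other %in% names(carrier_touches)]] <-
    ec$count[hit][other %in% names(carrier_touches)]
  deg <- igraph::degree(net$graph)
  touched <- meta$surface_id %in% names(deg) & deg[meta$surface_id] > 0
  keep2 <- touched & carrier_touches[meta$surface_id] <= max_carrier_touches
  prof <- prof[keep2]
  ids <- meta$surface_id[keep2]
  if (length(prof) < 3) stop("fewer than 3 surfaces remain after exclusions")
  res <- spearman_test(prof, centrality[ids])
  list(rho = res$rho, p = res$p, n = res$n, surface_id = ids)
}

#' Hand-to-hand dissimilarity vector
#'
#' Bray-Curtis dissimilarities between all hand pairs at one timepoint,
#' with invader ASVs removed and rows renormalized beforehand. Names encode
#' the participant pair as "Pi|Pj" so pre/post vectors can be matched.
#'
#' @param counts a [count_table()].
#' @param tax a [taxonomy_map()] (invader ASVs are dropped).
#' @param timepoint `"pre"` or `"post"`.
#' @return Named numeric vector of pairwise dissimilarities.
#' @export
hand_dissimilarity <- function(counts, tax, timepoint) {
  meta <- counts$meta
  sel <- meta$sample_id[meta$surface_type == "hand" &
                          meta$timepoint == timepoint]
  if (length(sel) < 2) stop("need at least 2 hand samples")
  keep_taxa <- setdiff(colnames(counts$counts), invader_asvs(tax))
  sub <- counts$counts[sel, keep_taxa, drop = FALSE]
  a <- suppressWarnings(relative_abundance(sub))
  owners <- meta$owner[match(rownames(a$values), meta$sample_id)]
  d <- bray_curtis(a)
  n <- nrow(d)
  pairs <- utils::combn(n, 2)
  out <- d[t(pairs)]
  o1 <- pmin(owners[pairs[1, ]], owners[pairs[2, ]])
  o2 <- pmax(owners[pairs[1, ]], owners[pairs[2, ]])
  stats::setNames(out, paste(o1, o2, sep = "|"))
}

#' Paired test of microbiota homogenization
#'
#' Compares matched pre/post dissimilarity vectors (same participant pairs)
#' with the Wilcoxon signed-rank test. Homogenization means the post
#' dissimilarities are systematically smaller than the pre ones.
#'
#' @param pre_dis,post_dis named dissimilarity vectors over identical pair
#'   sets (see [hand_dissimilarity()]).
#' @return List with `statistic`, `p_value`, `direction`
#'   (`"homogenized"` if the post median is below the pre median,
#'   `"diversified"` if above, `"none"`), `median_pre`, `median_post`, `n`.
#' @export
homogenization_test <- function(pre_dis, post_dis) {
  if (is.null(names(pre_dis)) || is.null(names(post_dis)))
    stop("dissimilarity vectors must be named by participant pair")
  if (!setequal(names(pre_dis), names(post_dis)))
    stop("pre and post pair sets do not match")
  post_dis <- post_dis[names(pre_dis)]
  if (all(pre_dis == post_dis)) {
    return(list(statistic = NA_real_, p_value = 1, direction = "none",
                median_pre = stats::median(pre_dis),
                median_post = stats::median(post_dis),
                n = length(pre_dis)))
  }
  wt <- stats::wilcox.test(pre_dis, post_dis, paired = TRUE, exact = FALSE)
  mpre <- stats::median(pre_dis); mpost <- stats::median(post_dis)
  direction <- if (mpost < mpre) "homogenized"
               else if (mpost > mpre) "diversified" else "none"
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = direction, median_pre = mpre, median_post = mpost,
       n = length(pre_dis))
}
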