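# Core data model: sample x ASV count tables with per-sample metadata,
# taxonomy maps, and relative-abundance tables.

#' Recognized surface types
#'
#' Controlled vocabulary for the `surface_type` metadata field. Hands, faces
#' and phones are personal surfaces sampled both before and after an
#' experiment; the remaining types are inanimate surfaces sampled at the end.
#' Unknown values are coerced to `"other_public"` on read.
#'
#' @export
SURFACE_TYPES <- c(
  "hand", "face", "phone", "mouse", "keyboard", "cup", "desk",
  "chair_arm", "chair_seatback", "door_handle", "door_button",
  "dispenser_button", "printer_screen", "other_public"
)

#' Private inanimate surface types
#'
#' The surface types treated as privately owned inanimate surfaces (the sink
#' community of the neutral model and the target of the proximity analysis).
#'
#' @export
PRIVATE_INANIMATE_TYPES <- c(
  "phone", "mouse", "keyboard", "cup", "desk", "chair_arm", "chair_seatback"
)

REQUIRED_META_COLS <- c("sample_id", "experiment_id", "surface_type",
                        "owner", "timepoint")

#' Construct a count table
#'
#' Bundles a sample x taxon matrix of sequence counts with per-sample
#' metadata. This is the raw observational unit of the package: rows are
#' surface swab samples, columns are amplicon sequence variants (ASVs).
#'
#' @param counts integer matrix, samples in rows, taxa in columns; both
#'   dimensions must be named.
#' @param meta data.frame with one row per sample and at least the columns
#'   `sample_id`, `experiment_id`, `surface_type`, `owner`, `timepoint`.
#'   A `surface_id` column (the touch-network vertex the sample was swabbed
#'   from) and an `is_carrier_owned` flag are carried through when present.
#' @return An object of class `count_table` with elements `counts` and `meta`.
#' @export
count_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have sample rownames and taxon colnames")
  if (any(counts < 0)) stop("negative count in table")
  if (any(counts != round(counts))) stop("non-integer count in table")
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_META_COLS, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  absent <- setdiff(rownames(counts), meta$sample_id)
  if (length(absent) > 0)
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata")
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id
  unknown <- !(meta$surface_type %in% SURFACE_TYPES)
  if (any(unknown)) {
    warning("unknown surface_type value(s) mapped to other_public: ",
            paste(unique(meta$surface_type[unknown]), collapse = ", "))
    meta$surface_type[unknown] <- "other_public"
  }
  if (!"is_carrier_owned" %in% names(meta))
    meta$is_carrier_owned <- FALSE
  structure(list(counts = counts, meta = meta), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  timepoints:", paste(names(table(x$meta$timepoint)),
                             table(x$meta$timepoint), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count table and its sample metadata from TSV files
#'
#' Counts are stored as a tab-separated table with samples in rows (first
#' column holds sample ids) and taxa in columns; metadata is a second TSV
#' keyed by `sample_id`.
#'
#' @param path path to the counts TSV.
#' @param meta_path path to the metadata TSV.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, meta_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(raw[[1]])
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- samples
  if (any(is.na(counts))) stop("missing value in count table")
  if (any(counts < 0)) stop("negative count in table")
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  count_table(counts, meta)
}

#' Write a count table to TSV files
#'
#' Inverse of [read_count_table()]: round-trips are bit-identical for
#' integer tables.
#'
#' @param t a [count_table()].
#' @param path path for the counts TSV.
#' @param meta_path path for the metadata TSV.
#' @export
write_count_table <- function(t, path, meta_path) {
  df <- data.frame(sample_id = rownames(t$counts), t$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(t$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(t)
}

#' Construct a taxonomy map
#'
#' Maps ASV ids to genus/species assignments and flags the invader ASVs.
#' ASVs without a genus assignment carry the string `"unassigned"`.
#'
#' @param asv_id character vector of ASV ids.
#' @param genus,species character vectors parallel to `asv_id`.
#' @param invader logical vector flagging the invader ASVs.
#' @return A data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(asv_id, genus, species, invader) {
  stopifnot(length(asv_id) == length(genus),
            length(asv_id) == length(species),
            length(asv_id) == length(invader))
  if (anyDuplicated(asv_id)) stop("duplicated asv_id in taxonomy")
  structure(
    data.frame(asv_id = as.character(asv_id), genus = as.character(genus),
               species = as.character(species), invader = as.logical(invader),
               stringsAsFactors = FALSE),
    class = c("taxonomy_map", "data.frame"))
}

#' Read / write a taxonomy map (TSV with columns asv_id, genus, species,
#' invader)
#'
#' @param path path to the taxonomy TSV.
#' @return A [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  taxonomy_map(df$asv_id, df$genus, df$species, as.logical(df$invader))
}

#' @rdname read_taxonomy
#' @param tax a [taxonomy_map()].
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tax)
}

#' Invader ASV ids of a taxonomy map
#' @param tax a [taxonomy_map()].
#' @export
invader_asvs <- function(tax) tax$asv_id[tax$invader]

#' Row-normalize a count table to relative abundances
#'
#' Each retained sample row sums to one. Samples with zero total counts are
#' dropped with a warning, mirroring the exclusion of low-biomass swabs that
#' cannot be sequenced.
#'
#' @param t a [count_table()], or a numeric matrix with named rows/columns.
#' @return An `abundance_table`: list with a `values` matrix (rows sum to 1)
#'   and the (possibly subset) `meta`.
#' @export
relative_abundance <- function(t) {
  if (inherits(t, "count_table")) {
    m <- t$counts
    meta <- t$meta
  } else {
    m <- as.matrix(t)
    meta <- NULL
  }
  rs <- rowSums(m)
  if (all(rs == 0)) stop("empty table: all sample rows sum to zero")
  if (any(rs == 0)) {
    warning("dropping ", sum(rs == 0), " zero-sum sample(s): ",
            paste(rownames(m)[rs == 0], collapse = ", "))
    m <- m[rs > 0, , drop = FALSE]
    if (!is.null(meta)) meta <- meta[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  abundance_table(m / rs, meta)
}

#' Construct an abundance table
#'
#' @param values numeric matrix of relative abundances; rows must sum to 1.
#' @param meta optional sample metadata (as in [count_table()]).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, meta = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("negative relative abundance")
  bad <- abs(rowSums(values) - 1) > 1e-9
  if (any(bad))
    stop("abundance rows must sum to 1: ",
         paste(rownames(values)[bad], collapse = ", "))
  structure(list(values = values, meta = meta), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values),
      "taxa\n")
  invisible(x)
}

#' Pool an ASV-level abundance table to genus level
#'
#' ASVs unassigned at the genus level are removed and ASVs assigned to the
#' same genus are pooled by summation. The invader ASVs are pooled into a
#' single species-level column (named after the invader species) that is kept
#' separate from any native genus, so that networks can be built including
#' the invader as its own taxon. Rows are re-normalized after the removal of
#' unassigned ASVs.
#'
#' @param a an `abundance_table` at ASV level.
#' @param tax a [taxonomy_map()] covering the taxa of `a`.
#' @return An `abundance_table` whose columns are genera (plus the invader
#'   species column when invader ASVs are present).
#' @export
collapse_to_genus <- function(a, tax) {
  vals <- a$values
  idx <- match(colnames(vals), tax$asv_id)
  if (any(is.na(idx)))
    stop("taxa absent from taxonomy: ",
         paste(colnames(vals)[is.na(idx)], collapse = ", "))
  genus <- tax$genus[idx]
  invader <- tax$invader[idx]
  # invader ASVs form one species-level group regardless of genus assignment
  inv_name <- if (any(invader)) {
    sp <- unique(tax$species[idx][invader])
    sp <- sp[sp != "unassigned"]
    if (length(sp) > 0) sp[1] else "invader"
  } else NULL
  group <- ifelse(invader, inv_name, genus)
  keep <- invader | genus != "unassigned"
  if (!any(keep)) stop("no genera: all ASVs unassigned at the genus level")
  vals <- vals[, keep, drop = FALSE]
  group <- group[keep]
  pooled <- t(rowsum(t(vals), group = group))
  rs <- rowSums(pooled)
  if (any(rs == 0)) {
    warning("dropping ", sum(rs == 0),
            " sample(s) with no genus-assigned reads")
    pooled <- pooled[rs > 0, , drop = FALSE]
    if (!is.null(a$meta)) a$meta <- a$meta[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  abundance_table(pooled / rs, a$meta)
}

#' Most abundant taxa of an abundance table
#'
#' Returns the `k` taxa with the highest mean relative abundance across
#' samples, ties broken lexicographically by taxon id. When `include` names
#' a taxon (typically the invader) that did not make the top `k`, it is
#' appended, since the invader networks are built over the most abundant
#' genera plus the invader species.
#'
#' @param a an `abundance_table`.
#' @param k number of taxa to keep.
#' @param include optional taxon id appended if absent from the top `k`.
#' @return Character vector of taxon ids, highest mean abundance first.
#' @export
top_taxa <- function(a, k, include = NULL) {
  stopifnot(k >= 1)
  means <- colMeans(a$values)
  ids <- colnames(a$values)
  ord <- order(-means, ids)
  if (k > length(ids)) {
    warning("k exceeds number of taxa; returning all ", length(ids), " taxa")
    k <- length(ids)
  }
  out <- ids[ord][seq_len(k)]
  if (!is.null(include) && include %in% ids && !(include %in% out))
    out <- c(out, include)
  out
}
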