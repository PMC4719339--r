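#' Transcriptome-wide Pearson correlation with a clinical covariate
#'
#' Computes, for every probe, the Pearson correlation between its log2
#' expression profile and a per-sample numeric covariate (typically a
#' disease-activity index). Probes with zero variance across samples get an
#' undefined (`NA`) coefficient and are excluded from downstream selection.
#'
#' @param expr numeric matrix, probes x samples, with probe rownames and
#'   sample colnames (see [read_expression_tsv()]).
#' @param covariate named numeric vector; names must cover the matrix's
#'   sample ids (order is reconciled internally).
#' @return data.frame with columns `probe_id`, `r`, `n`.
#' @export
correlate_probes <- function(expr, covariate) {
  validate_expression(expr)
  if (ncol(expr) < 3L) {
    stop("need at least 3 samples to correlate", call. = FALSE)
  }
  if (is.null(names(covariate))) {
    if (length(covariate) != ncol(expr)) {
      stop("unnamed covariate must have one value per sample", call. = FALSE)
    }
    names(covariate) <- colnames(expr)
  }
  missing_ids <- setdiff(colnames(expr), names(covariate))
  if (length(missing_ids)) {
    stop("covariate missing for sample(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  y <- covariate[colnames(expr)]
  if (any(!is.finite(y))) stop("non-finite covariate values", call. = FALSE)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy == 0) stop("covariate is constant: correlation undefined",
                     call. = FALSE)
  xc <- expr - rowMeans(expr)
  ssx <- rowSums(xc^2)
  r <- as.vector(xc %*% yc) / sqrt(ssx * ssy)
  r[ssx == 0] <- NA_real_
  data.frame(probe_id = rownames(expr), r = r, n = ncol(expr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select probes above a correlation threshold
#'
#' Filters a [correlate_probes()] table at an r cutoff. `positive` mode keeps
#' probes with r at or above the threshold (the screen's default reading:
#' transcripts over-expressed with activity); `absolute` mode uses |r|.
#' The comparison is inclusive (>=) by default, with a strict (>) flag.
#' Probes with undefined r are never selected.
#'
#' @param correlations data.frame from [correlate_probes()].
#' @param threshold r cutoff in (0, 1); default 0.5.
#' @param direction `"positive"` or `"absolute"`.
#' @param inclusive logical; if `FALSE` the comparison is strict (>).
#' @return character vector of probe ids, ordered by descending r then
#'   probe id. An empty selection is legal and warns.
#' @export
select_probes <- function(correlations, threshold = 0.5,
                          direction = c("positive", "absolute"),
                          inclusive = TRUE) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single value in (0, 1)", call. = FALSE)
  }
  r <- correlations$r
  stat <- if (direction == "absolute") abs(r) else r
  keep <- if (inclusive) stat >= threshold else stat > threshold
  keep[is.na(keep)] <- FALSE
  sel <- correlations[keep, , drop = FALSE]
  sel <- sel[order(-sel$r, sel$probe_id), , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no probe met the |r| threshold of ", threshold, call. = FALSE)
  }
  sel$probe_id
}

#' Venn-region counts for 2 or 3 probe sets
#'
#' Partitions the union of the given sets into exclusive Venn regions and
#' counts each region's members. Region names join the participating set
#' names with `&`; counts over all regions sum to the union size.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return list with `regions` (named integer vector of exclusive region
#'   counts) and `union_size`.
#' @export
overlap_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stop("overlap_sets needs a list of 2 or 3 sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  keys <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  all_keys <- unlist(lapply(seq_along(sets), function(k) {
    combn(names(sets), k, FUN = paste, collapse = "&")
  }))
  counts <- stats::setNames(integer(length(all_keys)), all_keys)
  tab <- table(keys)
  counts[names(tab)] <- as.integer(tab)
  list(regions = counts, union_size = length(universe))
}

#' Jaccard similarity between two sets
#'
#' @param a,b character vectors.
#' @return |intersection| / |union| (0 when both are empty).
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
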