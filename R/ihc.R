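#' Segment an immunostained field into stain and nuclei surfaces
#'
#' Classifies each pixel of an RGB field by fixed channel-difference scores:
#' brown immunostain pixels have a red-minus-blue excess of at least
#' `stain_thr` with luminance at most `lum_max` (excludes pale background);
#' blue (hematoxylin) nuclei pixels have a blue-minus-red excess of at least
#' `nuclei_thr`. The stain test is applied first, so the two masks are
#' disjoint by construction. Thresholds default to the synthetic-field
#' palette and are exposed for real images.
#'
#' @param image numeric array H x W x 3, either 8-bit (0--255) or
#'   unit-scaled (0--1, as returned by `png::readPNG`).
#' @param stain_thr,nuclei_thr channel-difference thresholds (8-bit units).
#' @param lum_max luminance upper bound for stain pixels (8-bit units).
#' @param min_nuclei_px minimum nuclei surface for a field to be usable.
#' @return one-row data.frame: `S`, `N`, `ratio` (`NA` when N = 0),
#'   `usable`.
#' @export
segment_field <- function(image, stain_thr = 50, nuclei_thr = 50,
                          lum_max = 200, min_nuclei_px = 50) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    stop("field image must be an RGB array (H x W x 3)", call. = FALSE)
  }
  img <- image
  if (max(img) <= 1) img <- img * 255
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  stain <- (r - b >= stain_thr) & (lum <= lum_max)
  nuclei <- (b - r >= nuclei_thr) & !stain
  s <- sum(stain); n <- sum(nuclei)
  data.frame(S = s, N = n,
             ratio = if (n > 0) s / n else NA_real_,
             usable = n >= min_nuclei_px)
}

#' Aggregate field quantifications into a slide-level S/N ratio
#'
#' Averages the stain-to-nuclei surface ratio over usable fields (equal
#' weight per field). A slide with fewer than `min_fields` usable fields is
#' discarded rather than quantified — discard is a status, not an error.
#'
#' @param fields data.frame of field quantifications (rows from
#'   [segment_field()]; columns `S`, `N`, `ratio`, `usable`).
#' @param min_fields minimum usable fields for quantification (default 3).
#' @return list with `mean_ratio` (`NA` when discarded), `n_usable`,
#'   `status` (`"quantified"` or `"discarded"`).
#' @export
quantify_slide <- function(fields, min_fields = 3) {
  if (NROW(fields) < 1L) stop("need at least one field", call. = FALSE)
  ok <- fields$usable & !is.na(fields$ratio)
  if (sum(ok) >= min_fields) {
    list(mean_ratio = mean(fields$ratio[ok]), n_usable = sum(ok),
         status = "quantified")
  } else {
    list(mean_ratio = NA_real_, n_usable = sum(ok), status = "discarded")
  }
}

#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' U counts pairs where an x observation exceeds a y observation, with ties
#' counted 1/2. For pooled sample sizes up to `exact_max` the two-sided
#' p-value is exact: every assignment of the pooled values to the two groups
#' is enumerated and p is the fraction of assignments whose U deviates from
#' the null mean n1*n2/2 at least as much as the observed U (identical
#' multisets therefore give p = 1). Larger samples use the tie-corrected
#' normal approximation with continuity correction; a fully tied pooled
#' sample (zero null variance) gives p = 1 by convention.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exact_max pooled size at or below which enumeration is used
#'   (default 12).
#' @return list with `statistic` (U), `p_value`, `method`, `group_ns`.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) stop("non-finite observations", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(u - mu)
    devs <- apply(idx, 2L, function(i) {
      abs(u_stat(pooled[i], pooled[-i]) - mu)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    pooled <- c(x, y)
    nn <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = u, p_value = p, method = method, group_ns = c(n1, n2))
}

#' Kruskal-Wallis rank test across three or more groups
#'
#' Tie-corrected H statistic with a chi-square p-value on g - 1 degrees of
#' freedom (delegated to [stats::kruskal.test()]). A fully tied sample, for
#' which the tie correction leaves H undefined, returns p = 1 by convention.
#'
#' @param groups list of >= 3 non-empty numeric vectors.
#' @return list with `statistic` (H), `p_value`, `df`, `group_ns`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("kruskal_wallis needs >= 3 groups; use mann_whitney for 2",
         call. = FALSE)
  }
  ns <- lengths(groups)
  if (any(ns < 1L)) stop("every group must be non-empty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (sum(ns) < 5L) stop("need total n >= 5", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(statistic = NA_real_, p_value = 1,
                df = length(groups) - 1L, group_ns = ns))
  }
  fac <- factor(rep(seq_along(groups), ns))
  kt <- stats::kruskal.test(values, fac)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), group_ns = ns)
}

#' Quantify a manifest of stained fields slide by slide
#'
#' Reads each field image listed in a manifest, segments it, aggregates
#' fields per slide and returns per-slide quantifications alongside group
#' labels, ready for [mann_whitney()] / [kruskal_wallis()].
#'
#' @param manifest data.frame with columns `slide_id`, `field_id`, `path`
#'   and optionally `group`.
#' @param min_fields,min_nuclei_px see [quantify_slide()], [segment_field()].
#' @param ... further arguments passed to [segment_field()].
#' @return data.frame: `slide_id`, `group` (NA when absent), `S_total`,
#'   `N_total`, `n_usable`, `mean_ratio`, `status`.
#' @export
quantify_manifest <- function(manifest, min_fields = 3, min_nuclei_px = 50,
                              ...) {
  need <- c("slide_id", "field_id", "path")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  slides <- split(manifest, manifest$slide_id)
  rows <- lapply(slides, function(mf) {
    quants <- do.call(rbind, lapply(mf$path, function(p) {
      segment_field(png::readPNG(p), min_nuclei_px = min_nuclei_px, ...)
    }))
    sq <- quantify_slide(quants, min_fields = min_fields)
    data.frame(
      slide_id = mf$slide_id[1L],
      group = if ("group" %in% names(mf)) mf$group[1L] else NA_character_,
      S_total = sum(quants$S), N_total = sum(quants$N),
      n_usable = sq$n_usable, mean_ratio = sq$mean_ratio,
      status = sq$status, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
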