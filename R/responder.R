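#' Baseline good-versus-poor responder differential-expression screen
#'
#' Probe-wise two-sample Student t test (pooled variance by default, Welch
#' behind a flag) comparing baseline expression between poor and good
#' responders, with no multiple-testing correction gating the result — a
#' Benjamini-Hochberg FDR column is emitted for information only. A probe
#' "passes" when its uncorrected p-value is below `alpha` *and* it is
#' over-expressed in poor responders by at least `fc_cut`-fold
#' (log2fc >= log2(fc_cut); strict > with `strict = TRUE`). The screen is
#' one-directional by design: it looks for transcripts over-expressed in
#' poor responders.
#'
#' @param expr probes x samples log2 matrix.
#' @param groups named character vector of labels `good` / `poor` covering
#'   all samples (extra names ignored).
#' @param alpha uncorrected significance level (default 0.05).
#' @param fc_cut fold-change cutoff on the natural scale (default 1.5).
#' @param welch use Welch's unequal-variance t instead of pooled Student t.
#' @param strict use a strict (>) fold-change comparison.
#' @return data.frame: `probe_id`, `t_stat`, `p_value`, `fdr`, `log2fc`
#'   (mean poor minus mean good), `passes`.
#' @export
de_screen <- function(expr, groups, alpha = 0.05, fc_cut = 1.5,
                      welch = FALSE, strict = FALSE) {
  validate_expression(expr)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(expr)) {
      stop("unnamed groups must have one label per sample", call. = FALSE)
    }
    names(groups) <- colnames(expr)
  }
  miss <- setdiff(colnames(expr), names(groups))
  if (length(miss)) {
    stop("group label missing for sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  g <- groups[colnames(expr)]
  bad <- setdiff(unique(g), c("good", "poor"))
  if (length(bad)) {
    stop("group labels must be 'good'/'poor'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  xp <- expr[, g == "poor", drop = FALSE]
  xg <- expr[, g == "good", drop = FALSE]
  n1 <- ncol(xp); n0 <- ncol(xg)
  if (n1 < 2L || n0 < 2L) {
    stop("each responder group needs >= 2 samples (poor: ", n1,
         ", good: ", n0, ")", call. = FALSE)
  }
  m1 <- rowMeans(xp); m0 <- rowMeans(xg)
  v1 <- rowSums((xp - m1)^2) / (n1 - 1L)
  v0 <- rowSums((xg - m0)^2) / (n0 - 1L)
  diff <- m1 - m0
  if (welch) {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v0^2 / (n0^2 * (n0 - 1L)))
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep(n1 + n0 - 2L, length(diff))
  }
  tval <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(tval), df)
  # degenerate probes: no variance and no mean difference => no evidence
  flat <- se2 == 0 & diff == 0
  tval[flat] <- 0
  p[flat] <- 1
  p <- pmax(p, .Machine$double.xmin)
  cut <- log2(fc_cut)
  over <- if (strict) diff > cut else diff >= cut
  data.frame(
    probe_id = rownames(expr),
    t_stat = tval,
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    log2fc = diff,
    passes = p < alpha & over,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Hypergeometric overrepresentation of a query list in a reference set
#'
#' Tests whether a query gene list overlaps a reference set more than
#' expected when drawing `n` genes at random from a universe of `N` genes
#' containing `K` reference genes: `p_hyper` is the upper hypergeometric
#' tail P(X >= k). The odds ratio comes from the 2x2 membership table, with
#' a Haldane 0.5 correction applied to every cell when any cell is zero.
#'
#' @param query,reference,universe character vectors; `query` and
#'   `reference` must be subsets of `universe`.
#' @return list with `k`, `K`, `n`, `N`, `p_hyper`, `odds_ratio`.
#' @export
overrepresentation_test <- function(query, reference, universe) {
  query <- unique(query); reference <- unique(reference)
  universe <- unique(universe)
  out_q <- setdiff(query, universe)
  if (length(out_q)) {
    stop("query members outside the universe: ",
         paste(utils::head(out_q, 5), collapse = ", "), call. = FALSE)
  }
  out_r <- setdiff(reference, universe)
  if (length(out_r)) {
    stop("reference members outside the universe: ",
         paste(utils::head(out_r, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe); K <- length(reference); n <- length(query)
  k <- length(intersect(query, reference))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
  if (min(a, b, cc, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(k = k, K = K, n = n, N = N,
       p_hyper = p, odds_ratio = (a * d) / (b * cc))
}
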