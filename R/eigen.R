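#' Construct a two-condition perturbation experiment
#'
#' Bundles an expression matrix with per-sample condition labels, an optional
#' control-to-perturbed pairing, and an inversion flag. The inversion flag
#' is used for receptor-blockade designs (e.g. anti-IL6R therapy): a negative
#' drug effect on a transcript, sign-flipped, reads as a positive effect of
#' the blocked cytokine.
#'
#' @param expr probes x samples log2 matrix.
#' @param condition named character vector (`control` / `perturbed`) covering
#'   every sample.
#' @param pairing optional data.frame with columns `control`, `perturbed`
#'   forming a bijection between the two condition groups.
#' @param invert logical; flip fold-change signs for interpretation.
#' @return object of class `perturbation_experiment`.
#' @export
perturbation_experiment <- function(expr, condition, pairing = NULL,
                                    invert = FALSE) {
  validate_expression(expr)
  if (is.null(names(condition))) {
    if (length(condition) != ncol(expr)) {
      stop("unnamed condition must have one label per sample", call. = FALSE)
    }
    names(condition) <- colnames(expr)
  }
  miss <- setdiff(colnames(expr), names(condition))
  if (length(miss)) {
    stop("condition missing for sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  condition <- condition[colnames(expr)]
  bad <- setdiff(unique(condition), c("control", "perturbed"))
  if (length(bad)) {
    stop("condition labels must be 'control'/'perturbed'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(c("control", "perturbed") %in% condition)) {
    stop("both conditions must be present", call. = FALSE)
  }
  if (!is.null(pairing)) {
    ctrl <- names(condition)[condition == "control"]
    pert <- names(condition)[condition == "perturbed"]
    if (!setequal(pairing$control, ctrl) || !setequal(pairing$perturbed, pert) ||
        anyDuplicated(pairing$control) || anyDuplicated(pairing$perturbed)) {
      stop("pairing must be a bijection between control and perturbed samples",
           call. = FALSE)
    }
  }
  structure(list(expr = expr, condition = condition, pairing = pairing,
                 invert = isTRUE(invert)),
            class = "perturbation_experiment")
}

#' Percent variance explained by the first principal component
#'
#' The gene-set eigenvalue statistic: the percentage of total variation in a
#' (sub)matrix of expression data, across an experiment's samples, that is
#' carried by the first principal component. Gene rows are mean-centred;
#' genes are *not* unit-scaled, so the amplitude structure of the set is
#' retained and only the share of variance is summarised. Computed from the
#' eigendecomposition of the sample-by-sample cross-product of the centred
#' matrix; eigenvalues below a 1e-12 relative floor are treated as exact
#' zeros, so rank-1 data returns exactly 100.
#'
#' @param x numeric matrix, genes x samples (>= 1 gene, >= 2 samples).
#' @return scalar in (0, 100].
#' @export
eigenvalue_pct <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (nrow(x) < 1L) stop("need >= 1 gene", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite expression values", call. = FALSE)
  xc <- x - rowMeans(x)
  total <- sum(xc^2)
  if (total <= 0) {
    stop("zero total variance: eigenvalue statistic undefined", call. = FALSE)
  }
  ev <- eigen(crossprod(xc), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev[ev < total * 1e-12] <- 0
  100 * ev[1L] / sum(ev)
}

#' Per-gene interpreted log2 fold changes of an experiment
#'
#' Mean perturbed-minus-control log2 fold change per gene; with a pairing,
#' the mean of within-pair differences (identical in expectation, smaller
#' variance). The experiment's `invert` flag flips the sign for
#' interpretation.
#'
#' @param exp a [perturbation_experiment()].
#' @param probes optional character vector restricting the computation.
#' @return named numeric vector of interpreted log2 fold changes.
#' @export
log2_fold_changes <- function(exp, probes = NULL) {
  stopifnot(inherits(exp, "perturbation_experiment"))
  x <- exp$expr
  if (!is.null(probes)) x <- x[probes, , drop = FALSE]
  if (is.null(exp$pairing)) {
    fc <- rowMeans(x[, exp$condition == "perturbed", drop = FALSE]) -
      rowMeans(x[, exp$condition == "control", drop = FALSE])
  } else {
    d <- x[, exp$pairing$perturbed, drop = FALSE] -
      x[, exp$pairing$control, drop = FALSE]
    fc <- rowMeans(d)
  }
  if (exp$invert) fc <- -fc
  fc
}

#' Summarise a gene set's behaviour in a perturbation experiment
#'
#' Computes the set's eigenvalue (% variance on PC1, both conditions pooled),
#' the absolute Pearson correlation between PC1 sample scores and the 0/1
#' condition indicator, the fractions of set genes whose interpreted log2
#' fold change exceeds +/- log2(`fc_threshold`), and the mean interpreted
#' log2 fold change. Set members absent from the matrix are reported and
#' excluded; an empty intersection is an error.
#'
#' @param set character vector of probe ids.
#' @param exp a [perturbation_experiment()].
#' @param fc_threshold fold-change cutoff on the natural scale (default 1.5).
#' @return object of class `enrichment_summary`: list with
#'   `eigenvalue_pct`, `pc1_condition_assoc`, `frac_up`, `frac_down`,
#'   `mean_log2fc`, `n_used`, `absent`.
#' @export
perturbation_profile <- function(set, exp, fc_threshold = 1.5) {
  stopifnot(inherits(exp, "perturbation_experiment"))
  set <- unique(set)
  present <- intersect(set, rownames(exp$expr))
  if (length(present) == 0L) {
    stop("gene set has no member in the expression matrix", call. = FALSE)
  }
  absent <- setdiff(set, present)
  sub <- exp$expr[present, , drop = FALSE]
  fc <- log2_fold_changes(exp, present)
  cut <- log2(fc_threshold)
  eig <- eigenvalue_pct(sub)
  xc <- sub - rowMeans(sub)
  sv <- svd(xc, nu = 0, nv = 1)
  scores <- xc_pc1_scores(sv)
  ind <- as.numeric(exp$condition == "perturbed")
  assoc <- if (stats::sd(scores) == 0 || stats::sd(ind) == 0) NA_real_ else
    abs(stats::cor(scores, ind))
  structure(list(
    eigenvalue_pct = eig,
    pc1_condition_assoc = assoc,
    frac_up = mean(fc >= cut),
    frac_down = mean(fc <= -cut),
    mean_log2fc = mean(fc),
    n_used = length(present),
    absent = absent
  ), class = "enrichment_summary")
}

xc_pc1_scores <- function(sv) as.vector(sv$v[, 1L] * sv$d[1L])

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf(
    "enrichment summary: eigenvalue %.1f%% (PC1~condition |r| = %s)\n",
    x$eigenvalue_pct,
    ifelse(is.na(x$pc1_condition_assoc), "NA",
           sprintf("%.2f", x$pc1_condition_assoc))))
  cat(sprintf("  genes used %d (absent %d); mean log2FC %+.3f; up %.0f%%, down %.0f%%\n",
              x$n_used, length(x$absent), x$mean_log2fc,
              100 * x$frac_up, 100 * x$frac_down))
  if (!is.null(x$perm_p)) cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  invisible(x)
}

#' Size-matched permutation null for the eigenvalue statistic
#'
#' Draws `n_perm` random gene sets of the same size from all probes of the
#' experiment's matrix and recomputes the eigenvalue statistic for each,
#' giving an add-one-smoothed permutation p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)`. This null is an extension:
#' it quantifies how unusual the set's PC1 coherence is relative to random
#' sets of equal size.
#'
#' @inheritParams perturbation_profile
#' @param n_perm number of random sets (>= 100).
#' @param seed integer seed for the draws.
#' @return list with `perm_p`, `observed`, `null` (the null eigenvalues).
#' @export
eigen_permutation_test <- function(set, exp, n_perm = 999, seed = 1) {
  stopifnot(inherits(exp, "perturbation_experiment"))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  universe <- rownames(exp$expr)
  set <- unique(intersect(set, universe))
  m <- length(set)
  if (m == 0L) stop("gene set has no member in the matrix", call. = FALSE)
  if (m > length(universe)) {
    stop("set larger than the probe universe", call. = FALSE)
  }
  observed <- eigenvalue_pct(exp$expr[set, , drop = FALSE])
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(universe), m)
      eigenvalue_pct(exp$expr[idx, , drop = FALSE])
    }, numeric(1))
  })
  # small epsilon: row order must not matter, so numerically tied null
  # draws (e.g. the degenerate whole-universe set) count as >= observed
  list(perm_p = (1 + sum(null >= observed - 1e-9)) / (n_perm + 1),
       observed = observed, null = null)
}

#' Genes induced by a perturbation
#'
#' Probes whose interpreted log2 fold change is at least
#' log2(`fc_threshold`); with the default threshold this is the reference
#' "cytokine-induced genes" list used by the responder enrichment analysis.
#'
#' @inheritParams perturbation_profile
#' @return character vector of probe ids (possibly empty).
#' @export
induced_set <- function(exp, fc_threshold = 1.5) {
  fc <- log2_fold_changes(exp)
  names(fc)[fc >= log2(fc_threshold)]
}

#' Evaluate with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
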