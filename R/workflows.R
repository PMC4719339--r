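#' Build a perturbation experiment from files
#'
#' @param expr_path expression TSV path.
#' @param design_path design CSV path (`sample_id`, `condition`, optional
#'   `pair_id`).
#' @param invert logical inversion flag (receptor-blockade convention).
#' @return a [perturbation_experiment()].
#' @export
experiment_from_files <- function(expr_path, design_path, invert = FALSE) {
  expr <- read_expression_tsv(expr_path)
  design <- read_design_csv(design_path)
  condition <- stats::setNames(design$condition, design$sample_id)
  pairing <- NULL
  if ("pair_id" %in% names(design) && !all(is.na(design$pair_id))) {
    ctrl <- design[design$condition == "control", ]
    pert <- design[design$condition == "perturbed", ]
    pert <- pert[match(ctrl$pair_id, pert$pair_id), ]
    if (any(is.na(pert$sample_id))) {
      stop("pair_id does not pair every control with a perturbed sample",
           call. = FALSE)
    }
    pairing <- data.frame(control = ctrl$sample_id,
                          perturbed = pert$sample_id,
                          stringsAsFactors = FALSE)
  }
  perturbation_experiment(expr, condition, pairing, invert)
}

default_covariates <- c("das28_crp", "sdai", "cdai")

#' Disease-activity workflow: scores, correlation screens, overlap,
#' perturbation enrichment
#'
#' Runs the activity arm of the pipeline: compute the disease-activity score
#' panel for the baseline visit, correlate every probe with each index,
#' select probes at the r threshold, count the Venn overlap of the
#' selections, then profile the DAS28-CRP selection (and any gene sets in
#' `config$sets_gmt`) in each configured perturbation experiment, including
#' the size-matched permutation null. All outputs plus a run manifest are
#' written to `config$out_dir`.
#'
#' @param config list (or path to a JSON file) with elements:
#'   `expr` (cohort expression TSV), `clinical` (clinical CSV; the
#'   `baseline` visit is used), `perturbations` (named list, each with
#'   `expr`, `design`, `invert`), optional `sets_gmt`, `covariates`
#'   (default DAS28-CRP/SDAI/CDAI), `threshold` (default 0.5), `direction`
#'   (default `"positive"`), `fc_threshold` (default 1.5), `n_perm`
#'   (default 999), `seed` (default 1), `out_dir`.
#' @return invisibly, a list with the score table, per-index selections,
#'   overlap counts and per-perturbation enrichment summaries.
#' @export
run_activity_workflow <- function(config) {
  config <- normalize_config(config)
  need <- c("expr", "clinical", "perturbations", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("activity workflow config lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  covariates <- config$covariates %||% default_covariates
  threshold <- config$threshold %||% 0.5
  direction <- config$direction %||% "positive"
  fc_threshold <- config$fc_threshold %||% 1.5
  n_perm <- config$n_perm %||% 999
  seed <- config$seed %||% 1
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  expr <- read_expression_tsv(config$expr)
  clinical <- read_clinical_csv(config$clinical)
  base <- score_panel(clinical[clinical$visit == "baseline", ])
  if (nrow(base) == 0L) stop("no baseline visit rows found", call. = FALSE)
  write_clinical_csv(base, file.path(out, "scores_baseline.csv"))
  message("scored ", nrow(base), " baseline visits")

  selections <- list()
  for (cov in covariates) {
    y <- stats::setNames(base[[cov]], base$patient_id)
    cors <- correlate_probes(expr, y)
    utils::write.table(cors, file.path(out, paste0("correlations_", cov,
                                                   ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    selections[[cov]] <- suppressWarnings(
      select_probes(cors, threshold = threshold, direction = direction))
    message("screen ", cov, ": ", length(selections[[cov]]), " of ",
            nrow(cors), " probes selected at r >= ", threshold)
  }
  write_gmt(selections, file.path(out, "selected_probes.gmt"))
  ov <- overlap_sets(selections)
  jsonlite::write_json(list(regions = as.list(ov$regions),
                            union_size = ov$union_size),
                       file.path(out, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)

  sets <- list(das28_selected = selections[[covariates[1L]]])
  if (!is.null(config$sets_gmt)) sets <- c(sets, read_gmt(config$sets_gmt))

  enrichment <- list()
  for (pname in names(config$perturbations)) {
    pc <- config$perturbations[[pname]]
    exp_obj <- experiment_from_files(pc$expr, pc$design,
                                     invert = isTRUE(pc$invert))
    per_exp <- list()
    fcs <- log2_fold_changes(exp_obj)
    utils::write.table(
      data.frame(probe_id = names(fcs), log2fc = fcs, row.names = NULL),
      file.path(out, paste0("log2fc_", pname, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (sname in names(sets)) {
      members <- intersect(sets[[sname]], rownames(exp_obj$expr))
      if (length(members) == 0L) next
      prof <- perturbation_profile(members, exp_obj,
                                   fc_threshold = fc_threshold)
      perm <- eigen_permutation_test(members, exp_obj, n_perm = n_perm,
                                     seed = seed)
      prof$perm_p <- perm$perm_p
      per_exp[[sname]] <- unclass(prof)[c("eigenvalue_pct",
                                          "pc1_condition_assoc", "frac_up",
                                          "frac_down", "mean_log2fc",
                                          "n_used", "perm_p")]
    }
    enrichment[[pname]] <- per_exp
    message("enrichment in ", pname, ": ", length(per_exp), " sets profiled")
  }
  jsonlite::write_json(enrichment, file.path(out, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  plot_perturbation_radar(enrichment, file.path(out, "radar.png"))

  outputs <- setdiff(list.files(out, full.names = TRUE),
                     file.path(out, "run_manifest.json"))
  write_run_manifest(config, c(config$expr, config$clinical, outputs),
                     file.path(out, "run_manifest.json"), seed = seed)
  invisible(list(scores = base, selections = selections, overlap = ov,
                 enrichment = enrichment))
}

#' Responder workflow: differential expression and enrichment in induced
#' genes
#'
#' Runs the responder arm: derive good/poor labels from the clinical table's
#' baseline and 6-month DAS28-CRP via the EULAR matrix (good responders vs
#' no-response patients; moderate responders are excluded, matching the
#' good-versus-poor contrast) unless a `groups` CSV is supplied; screen
#' baseline expression for transcripts over-expressed in poor responders;
#' build the cytokine-induced reference set from the stimulation experiment;
#' and test the pass-list's overrepresentation in it over the universe of
#' probes shared by both matrices.
#'
#' @param config list (or JSON path) with `expr`, `clinical` (or `groups`, a
#'   CSV with `patient_id`, `group`), `stimulation` (list: `expr`, `design`,
#'   optional `invert`), optional `alpha` (0.05), `fc_cut` (1.5),
#'   `fc_threshold` (1.5), `out_dir`.
#' @return invisibly, a list with the DE table, the induced set and the
#'   overrepresentation test.
#' @export
run_responder_workflow <- function(config) {
  config <- normalize_config(config)
  need <- c("expr", "stimulation", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("responder workflow config lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$clinical) && is.null(config$groups)) {
    stop("responder workflow needs 'clinical' or 'groups'", call. = FALSE)
  }
  alpha <- config$alpha %||% 0.05
  fc_cut <- config$fc_cut %||% 1.5
  fc_threshold <- config$fc_threshold %||% 1.5
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  expr <- read_expression_tsv(config$expr)
  if (!is.null(config$groups)) {
    gdf <- utils::read.csv(config$groups, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "group") %in% names(gdf))) {
      stop("groups CSV needs columns patient_id, group", call. = FALSE)
    }
    groups <- stats::setNames(gdf$group, gdf$patient_id)
  } else {
    clinical <- read_clinical_csv(config$clinical)
    base <- score_panel(clinical[clinical$visit == "baseline", ])
    m6 <- score_panel(clinical[clinical$visit == "m6", ])
    m6 <- m6[match(base$patient_id, m6$patient_id), ]
    if (any(is.na(m6$patient_id))) {
      stop("every baseline patient needs a 6-month visit", call. = FALSE)
    }
    cat_ <- eular_response(base$das28_crp, m6$das28_crp)
    groups <- stats::setNames(
      ifelse(cat_ == "good", "good", ifelse(cat_ == "none", "poor", NA)),
      base$patient_id)
    groups <- groups[!is.na(groups)]
    message("EULAR labels: ", sum(groups == "good"), " good, ",
            sum(groups == "poor"), " poor (moderate excluded: ",
            sum(cat_ == "moderate"), ")")
  }
  expr_used <- expr[, colnames(expr) %in% names(groups), drop = FALSE]
  de <- de_screen(expr_used, groups, alpha = alpha, fc_cut = fc_cut)
  utils::write.table(de, file.path(out, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pass <- de$probe_id[de$passes]
  message("DE screen: ", length(pass), " of ", nrow(de),
          " probes over-expressed in poor responders")

  sc <- config$stimulation
  stim <- experiment_from_files(sc$expr, sc$design,
                                invert = isTRUE(sc$invert))
  induced <- induced_set(stim, fc_threshold = fc_threshold)
  universe <- intersect(rownames(expr), rownames(stim$expr))
  ot <- overrepresentation_test(intersect(pass, universe),
                                intersect(induced, universe), universe)
  jsonlite::write_json(ot, file.path(out, "overrepresentation.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("overlap %d/%d pass-list probes in %d induced (universe %d): p = %.3g",
                  ot$k, ot$n, ot$K, ot$N, ot$p_hyper))
  write_gmt(list(de_pass = if (length(pass)) pass else "none",
                 induced = if (length(induced)) induced else "none"),
            file.path(out, "responder_sets.gmt"))

  outputs <- setdiff(list.files(out, full.names = TRUE),
                     file.path(out, "run_manifest.json"))
  write_run_manifest(config, c(config$expr, outputs),
                     file.path(out, "run_manifest.json"),
                     seed = config$seed %||% NULL)
  invisible(list(de = de, pass = pass, induced = induced, overlap = ot))
}

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON path",
                             call. = FALSE)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Radar-style summary of perturbation responses
#'
#' One polygon per gene set; one axis per perturbation experiment; the
#' radius on each axis is the fraction of set genes whose interpreted fold
#' change exceeds the cutoff (`frac_up`).
#'
#' @param enrichment nested list as produced by [run_activity_workflow()]:
#'   `enrichment[[experiment]][[set]]$frac_up`.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
plot_perturbation_radar <- function(enrichment, path) {
  exps <- names(enrichment)
  sets <- unique(unlist(lapply(enrichment, names)))
  if (length(exps) < 1L || length(sets) < 1L) return(invisible(path))
  k <- length(exps)
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)] + pi / 2
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Fraction of set genes induced, per experiment")
  for (rr in c(0.25, 0.5, 0.75, 1)) {
    graphics::polygon(rr * cos(c(ang, ang[1L])), rr * sin(c(ang, ang[1L])),
                      border = "grey80")
  }
  graphics::text(1.18 * cos(ang), 1.18 * sin(ang), exps, cex = 0.9)
  cols <- grDevices::hcl.colors(max(3L, length(sets)), "Dark 3")
  for (i in seq_along(sets)) {
    rad <- vapply(exps, function(e) {
      v <- enrichment[[e]][[sets[i]]]$frac_up
      if (is.null(v)) 0 else v
    }, numeric(1))
    rad <- c(rad, rad[1L])
    graphics::polygon(rad * cos(c(ang, ang[1L])), rad * sin(c(ang, ang[1L])),
                      border = cols[i], lwd = 2)
  }
  graphics::legend("bottomleft", legend = sets, col = cols[seq_along(sets)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(path)
}

#' Dot plot of slide-level S/N ratios by group with median bars
#'
#' @param slide_quants data.frame with `group` and `mean_ratio` (or `ratio`)
#'   columns.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
plot_slide_ratios <- function(slide_quants, path) {
  val <- slide_quants$mean_ratio %||% slide_quants$ratio
  if (is.null(val)) val <- slide_quants$ratio
  keep <- !is.na(val)
  val <- val[keep]
  grp <- factor(slide_quants$group[keep])
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  xi <- as.integer(grp)
  graphics::plot(jitter(xi, amount = 0.08), val, pch = 19,
                 col = "grey30", xaxt = "n", xlab = "",
                 ylab = "S/N ratio", xlim = c(0.5, nlevels(grp) + 0.5))
  graphics::axis(1, at = seq_len(nlevels(grp)), labels = levels(grp))
  meds <- tapply(val, grp, stats::median)
  graphics::segments(seq_len(nlevels(grp)) - 0.2, meds,
                     seq_len(nlevels(grp)) + 0.2, meds, lwd = 3, col = "red3")
  invisible(path)
}
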