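#' Simulation parameters for the synthetic study generator
#'
#' Defines the study conditions the generator emulates: a cohort of biopsied
#' patients whose synovial transcriptome contains expression modules driven
#' by a latent disease-activity variable, paired pre/post-treatment biopsies
#' in which an IL6-receptor blocker suppresses the IL6-dependent module,
#' short cytokine-stimulation cultures in which TNF-alpha induces the TNF
#' module, and responder labels tied to baseline TNF-module expression.
#'
#' @param n_patients cohort size (default 60).
#' @param n_probes probes on the array (default 2000).
#' @param module_sizes named integer vector with entries `tnf_module`,
#'   `il6_module`, `shared_module`, `background`; must sum to at most
#'   `n_probes` (any remainder is background).
#' @param activity_effect slope linking the latent activity (in SD units) to
#'   module-gene expression, log2 units per SD (default 0.8).
#' @param noise_sd residual expression SD, log2 units (default 1).
#' @param treatment_effect log2 suppression applied to IL6/shared module
#'   genes in post-treatment biopsies (default 1).
#' @param stimulation_effect log2 induction of TNF-module genes in
#'   stimulated cultures (default 1).
#' @param responder_shift baseline log2 elevation of TNF-module genes in
#'   poor responders (default 1).
#' @param seed integer random seed.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 60, n_probes = 2000,
                              module_sizes = c(tnf_module = 100,
                                               il6_module = 100,
                                               shared_module = 50,
                                               background = 1750),
                              activity_effect = 0.8, noise_sd = 1,
                              treatment_effect = 1, stimulation_effect = 1,
                              responder_shift = 1, seed = 1) {
  stopifnot(n_patients > 0, n_probes > 0, noise_sd > 0)
  need <- c("tnf_module", "il6_module", "shared_module", "background")
  miss <- setdiff(need, names(module_sizes))
  if (length(miss)) {
    stop("module_sizes lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  module_sizes <- module_sizes[need]
  if (any(module_sizes < 0)) stop("module sizes must be >= 0", call. = FALSE)
  if (sum(module_sizes) > n_probes) {
    stop("module sizes (", sum(module_sizes), ") exceed n_probes (",
         n_probes, ")", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), n_probes = as.integer(n_probes),
    module_sizes = module_sizes, activity_effect = activity_effect,
    noise_sd = noise_sd, treatment_effect = treatment_effect,
    stimulation_effect = stimulation_effect,
    responder_shift = responder_shift, seed = as.integer(seed)
  ), class = "simulation_params")
}

# deterministic probe/module layout shared by cohort and perturbation
# generators: probes are assigned to modules in fixed blocks so the same
# probe ids mean the same module in every emitted matrix
probe_modules <- function(params) {
  sizes <- params$module_sizes
  extra <- params$n_probes - sum(sizes)
  labels <- rep(c(names(sizes), "background"),
                times = c(sizes, extra))
  ids <- sprintf("probe_%05d", seq_len(params$n_probes))
  stats::setNames(labels, ids)
}

# components of a clinical visit from a latent activity vector; monotone
# transforms with clipped Gaussian noise keep the link simple and bounded
clinical_from_activity <- function(a, patient_ids, visit) {
  n <- length(a)
  tjc <- pmin(28, pmax(0, round(10 + 6 * a + stats::rnorm(n, 0, 2))))
  sjc <- pmin(28, pmax(0, round(8 + 5 * a + stats::rnorm(n, 0, 2))))
  crp <- exp(log(9) + 0.8 * a + stats::rnorm(n, 0, 0.3))
  pga <- pmin(10, pmax(0, 4.5 + 1.5 * a + stats::rnorm(n, 0, 0.8)))
  ega <- pmin(10, pmax(0, 4.5 + 1.4 * a + stats::rnorm(n, 0, 0.8)))
  data.frame(patient_id = patient_ids, visit = visit,
             tjc28 = tjc, sjc28 = sjc, crp_mg_l = crp,
             pga_cm = pga, ega_cm = ega, stringsAsFactors = FALSE)
}

#' Simulate a baseline biopsy cohort with clinical follow-up
#'
#' Draws a latent disease activity a ~ N(0, 1) per patient and generates
#' (i) a baseline log2 expression matrix in which genes of the TNF, IL6 and
#' shared modules follow `baseline + activity_effect * a + noise`, while
#' background genes carry noise only; (ii) baseline clinical components
#' generated monotonically from the same latent a; (iii) responder labels
#' from a latent responder propensity correlated (rho = 0.6) with a — the
#' top 20 percent are poor responders and additionally receive
#' `responder_shift` on TNF-module genes at baseline; and (iv) 6-month
#' clinical components generated from a reduced activity, calibrated so that
#' good responders improve their DAS28 by well over 1.2 and poor responders
#' by under 0.6 in expectation.
#'
#' @param params a [simulation_params()] object.
#' @return object of class `cohort_bundle`: list with `expression`
#'   (probes x patients), `clinical_baseline`, `clinical_6mo` (data.frames)
#'   and `truth` (list: `modules`, `activity`, `response`).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  modules <- probe_modules(params)
  with_seed(params$seed, {
    n <- params$n_patients
    p <- params$n_probes
    pid <- sprintf("P%03d", seq_len(n))

    a <- stats::rnorm(n)
    propensity <- 0.6 * a + 0.8 * stats::rnorm(n)
    poor <- propensity > stats::qnorm(0.8)
    response <- stats::setNames(ifelse(poor, "poor", "good"), pid)

    baseline_level <- stats::runif(p, 4, 12)
    noise <- matrix(stats::rnorm(p * n, 0, params$noise_sd), p, n)
    linked <- modules %in% c("tnf_module", "il6_module", "shared_module")
    x <- baseline_level + noise
    x[linked, ] <- x[linked, ] + params$activity_effect *
      matrix(a, sum(linked), n, byrow = TRUE)
    tnf <- modules == "tnf_module"
    x[tnf, poor] <- x[tnf, poor] + params$responder_shift
    dimnames(x) <- list(names(modules), pid)

    clin0 <- clinical_from_activity(a, pid, "baseline")
    a6 <- a - ifelse(poor, 0.25, 1.9)
    clin6 <- clinical_from_activity(a6, pid, "m6")

    structure(list(
      expression = x,
      clinical_baseline = clin0,
      clinical_6mo = clin6,
      truth = list(modules = modules,
                   activity = stats::setNames(a, pid),
                   response = response)
    ), class = "cohort_bundle")
  })
}

#' Simulate a two-condition perturbation experiment
#'
#' Two designs are supported. `"stimulation"`: paired stimulated versus
#' unstimulated cell cultures in which TNF-module genes are induced by
#' `stimulation_effect` log2 units (default 3 pairs, matching small culture
#' experiments). `"paired_treatment"`: paired pre/post-treatment biopsies in
#' which IL6-module and shared-module genes are suppressed by
#' `treatment_effect` log2 units (default 12 pairs); the returned
#' experiment carries `invert = TRUE`, the receptor-blockade convention
#' under which drug-suppressed genes read as cytokine-induced. A per-pair,
#' per-gene random intercept (donor or patient effect) makes the pairing
#' informative. Residual noise defaults to the design's natural scale:
#' short-term cell cultures are far less variable than human biopsies, so
#' the stimulation design uses SD 0.3 (donor effect SD 0.2) while the
#' paired-treatment design uses the cohort's `noise_sd` (patient effect
#' SD 0.5). All random draws happen before the deterministic effect shift
#' is applied, so a fixed seed yields common random numbers across effect
#' sizes.
#'
#' @param params a [simulation_params()] object.
#' @param design `"stimulation"` or `"paired_treatment"`.
#' @param n_pairs number of sample pairs (default 3 for stimulation, 12 for
#'   paired treatment; must be >= 3).
#' @param noise_sd residual SD override (log2 units, >= 0; 0 gives the
#'   noiseless forcing useful for exact checks).
#' @param pair_sd per-pair random-intercept SD override.
#' @return a [perturbation_experiment()] with a `truth` attribute (list:
#'   `modules`, `targeted`).
#' @export
simulate_perturbation <- function(params,
                                  design = c("stimulation",
                                             "paired_treatment"),
                                  n_pairs = NULL, noise_sd = NULL,
                                  pair_sd = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  design <- match.arg(design)
  if (is.null(n_pairs)) n_pairs <- if (design == "stimulation") 3L else 12L
  if (n_pairs < 3L) stop("need n_pairs >= 3", call. = FALSE)
  if (is.null(noise_sd)) {
    noise_sd <- if (design == "stimulation") 0.3 else params$noise_sd
  }
  if (is.null(pair_sd)) {
    pair_sd <- if (design == "stimulation") 0.2 else 0.5
  }
  if (noise_sd < 0 || pair_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  modules <- probe_modules(params)
  p <- params$n_probes
  if (design == "stimulation") {
    targeted <- names(modules)[modules == "tnf_module"]
    effect <- params$stimulation_effect
    invert <- FALSE
    ctrl_ids <- sprintf("unstim_%02d", seq_len(n_pairs))
    pert_ids <- sprintf("stim_%02d", seq_len(n_pairs))
  } else {
    targeted <- names(modules)[modules %in% c("il6_module", "shared_module")]
    effect <- -params$treatment_effect
    invert <- TRUE
    ctrl_ids <- sprintf("pre_%02d", seq_len(n_pairs))
    pert_ids <- sprintf("post_%02d", seq_len(n_pairs))
  }
  exp_obj <- with_seed(params$seed + 1000L, {
    baseline_level <- stats::runif(p, 4, 12)
    pair_fx <- matrix(stats::rnorm(p * n_pairs), p, n_pairs) * pair_sd
    noise_c <- matrix(stats::rnorm(p * n_pairs), p, n_pairs) * noise_sd
    noise_p <- matrix(stats::rnorm(p * n_pairs), p, n_pairs) * noise_sd
    xc <- baseline_level + pair_fx + noise_c
    xp <- baseline_level + pair_fx + noise_p
    xp[names(modules) %in% targeted, ] <-
      xp[names(modules) %in% targeted, ] + effect
    x <- cbind(xc, xp)
    dimnames(x) <- list(names(modules), c(ctrl_ids, pert_ids))
    condition <- stats::setNames(rep(c("control", "perturbed"),
                                     each = n_pairs), colnames(x))
    perturbation_experiment(
      x, condition,
      pairing = data.frame(control = ctrl_ids, perturbed = pert_ids,
                           stringsAsFactors = FALSE),
      invert = invert
    )
  })
  attr(exp_obj, "truth") <- list(modules = modules, targeted = targeted)
  exp_obj
}

#' Simulate stained histology fields with known surface areas
#'
#' Paints `n_fields` RGB fields on a pale background with brown immunostain
#' regions totalling exactly `stain_area_px` pixels and blue nuclei regions
#' totalling exactly `nuclei_area_px` pixels (stain in the left half of the
#' canvas, nuclei in the right half, each as a contiguous wrapped band at a
#' seeded random offset, so the regions are disjoint and the totals exact).
#' Optional palette jitter perturbs each pixel channel uniformly by up to
#' `jitter` x 255 levels, emulating staining variability.
#'
#' @param n_fields number of fields.
#' @param stain_area_px,nuclei_area_px target surfaces in pixels; each must
#'   fit in half the canvas.
#' @param seed integer seed.
#' @param width,height canvas size in pixels (default 512 x 512).
#' @param jitter per-channel uniform jitter fraction (default 0 = exact
#'   palette).
#' @return list of fields; each field is a list with `image`
#'   (H x W x 3 array, 0--255), `stain_mask`, `nuclei_mask` (logical
#'   matrices) and `truth` (list `S`, `N`, `ratio`).
#' @export
simulate_slide_fields <- function(n_fields, stain_area_px, nuclei_area_px,
                                  seed = 1, width = 512, height = 512,
                                  jitter = 0) {
  half <- (width %/% 2) * height
  if (stain_area_px > half || nuclei_area_px > half) {
    stop("requested area exceeds half-canvas capacity of ", half,
         " px", call. = FALSE)
  }
  if (stain_area_px < 0 || nuclei_area_px < 0) {
    stop("areas must be >= 0", call. = FALSE)
  }
  stain_col <- c(150, 90, 40)
  nuclei_col <- c(60, 70, 150)
  bg_col <- c(235, 230, 225)
  left_cols <- seq_len(width %/% 2)
  right_cols <- setdiff(seq_len(width), left_cols)
  with_seed(seed, {
    lapply(seq_len(n_fields), function(f) {
      img <- array(rep(bg_col, each = height * width),
                   dim = c(height, width, 3))
      band_mask <- function(cols, area) {
        m <- matrix(FALSE, height, width)
        if (area > 0) {
          lin <- as.vector(outer(seq_len(height), (cols - 1L) * height, "+"))
          off <- sample.int(length(lin), 1L)
          pick <- lin[((off + seq_len(area) - 2L) %% length(lin)) + 1L]
          m[pick] <- TRUE
        }
        m
      }
      stain_mask <- band_mask(left_cols, stain_area_px)
      nuclei_mask <- band_mask(right_cols, nuclei_area_px)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[stain_mask] <- stain_col[ch]
        plane[nuclei_mask] <- nuclei_col[ch]
        img[, , ch] <- plane
      }
      if (jitter > 0) {
        img <- img + array(stats::runif(length(img), -1, 1) * jitter * 255,
                           dim = dim(img))
        img <- round(pmin(pmax(img, 0), 255))
      }
      list(image = img, stain_mask = stain_mask, nuclei_mask = nuclei_mask,
           truth = list(S = stain_area_px, N = nuclei_area_px,
                        ratio = if (nuclei_area_px > 0)
                          stain_area_px / nuclei_area_px else 0))
    })
  })
}

#' Simulate slide-level S/N ratios for two responder groups
#'
#' Ground-truth stain surfaces are drawn log-normally with the poor group's
#' mean shifted by `shift` relative to the good group's (nuclei surfaces are
#' drawn with the same spread and no shift), giving per-slide S/N ratios for
#' power studies of the nonparametric group comparison.
#'
#' @param n_good,n_poor slides per group (default 12 each).
#' @param mean_ratio geometric mean S/N ratio of the good group (default 2).
#' @param shift multiplicative stain shift for the poor group (default 1.5).
#' @param sdlog log-scale SD of the per-slide ratios (default 0.3).
#' @param seed integer seed.
#' @return data.frame: `slide_id`, `group`, `ratio`.
#' @export
simulate_slide_ratios <- function(n_good = 12, n_poor = 12, mean_ratio = 2,
                                  shift = 1.5, sdlog = 0.3, seed = 1) {
  with_seed(seed, {
    good <- stats::rlnorm(n_good, log(mean_ratio), sdlog)
    poor <- stats::rlnorm(n_poor, log(mean_ratio * shift), sdlog)
    data.frame(
      slide_id = sprintf("S%03d", seq_len(n_good + n_poor)),
      group = rep(c("good", "poor"), c(n_good, n_poor)),
      ratio = c(good, poor), stringsAsFactors = FALSE
    )
  })
}

#' Write a simulated cohort and perturbation experiments to disk
#'
#' Emits the full set of pipeline inputs for a simulated study: expression
#' TSVs, clinical CSV (both visits stacked), design CSVs, a GMT of the
#' planted modules and a JSON ground-truth sidecar.
#'
#' @param params a [simulation_params()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector of the files written.
#' @export
write_simulated_study <- function(params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_cohort(params)
  stim <- simulate_perturbation(params, "stimulation")
  trt <- simulate_perturbation(params, "paired_treatment")
  fp <- function(x) file.path(out_dir, x)

  write_expression_tsv(bundle$expression, fp("cohort_expression.tsv"))
  write_clinical_csv(rbind(bundle$clinical_baseline, bundle$clinical_6mo),
                     fp("clinical.csv"))
  for (nm in c("stimulation", "paired_treatment")) {
    exp_obj <- if (nm == "stimulation") stim else trt
    write_expression_tsv(exp_obj$expr, fp(paste0(nm, "_expression.tsv")))
    pair_id <- stats::setNames(
      rep(seq_len(nrow(exp_obj$pairing)), 2L),
      c(exp_obj$pairing$control, exp_obj$pairing$perturbed))
    design <- data.frame(sample_id = names(exp_obj$condition),
                         condition = unname(exp_obj$condition),
                         pair_id = pair_id[names(exp_obj$condition)],
                         stringsAsFactors = FALSE)
    write_design_csv(design, fp(paste0(nm, "_design.csv")))
  }
  mods <- split(names(bundle$truth$modules), bundle$truth$modules)
  write_gmt(mods[c("tnf_module", "il6_module", "shared_module")],
            fp("planted_modules.gmt"))
  jsonlite::write_json(
    list(activity = as.list(bundle$truth$activity),
         response = as.list(bundle$truth$response),
         invert = list(stimulation = FALSE, paired_treatment = TRUE)),
    fp("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(
    cohort_expression = fp("cohort_expression.tsv"),
    clinical = fp("clinical.csv"),
    stimulation_expression = fp("stimulation_expression.tsv"),
    stimulation_design = fp("stimulation_design.csv"),
    paired_treatment_expression = fp("paired_treatment_expression.tsv"),
    paired_treatment_design = fp("paired_treatment_design.csv"),
    modules_gmt = fp("planted_modules.gmt"),
    ground_truth = fp("ground_truth.json")
  )
  invisible(files)
}
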