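make_exp <- function(effect = 1, noise = 0.3, n_pairs = 3, seed = 21,
                     invert = FALSE, n_genes = 40, module = 1:10) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * 2 * n_pairs, 0, noise), n_genes, 2 * n_pairs)
  x[module, (n_pairs + 1):(2 * n_pairs)] <-
    x[module, (n_pairs + 1):(2 * n_pairs)] + effect
  dimnames(x) <- list(sprintf("g%02d", 1:n_genes),
                      c(sprintf("c%02d", 1:n_pairs),
                        sprintf("t%02d", 1:n_pairs)))
  perturbation_experiment(
    x, setNames(rep(c("control", "perturbed"), each = n_pairs), colnames(x)),
    pairing = data.frame(control = sprintf("c%02d", 1:n_pairs),
                         perturbed = sprintf("t%02d", 1:n_pairs)),
    invert = invert)
}

test_that("eigenvalue_pct is exact on degenerate structures", {
  # a single gene carries all its variance on one component
  one <- toy_expr(c(1, 2, 3, 7), "g1", paste0("s", 1:4))
  expect_identical(eigenvalue_pct(one), 100)
  # proportional rows are rank-1 after centring
  two <- toy_expr(c(1, 2, 3, 4, 2, 4, 6, 8), c("g1", "g2"), paste0("s", 1:4))
  two["g1", ] <- 1:4; two["g2", ] <- 2 * (1:4) + 5
  expect_equal(eigenvalue_pct(two), 100)
  flat <- toy_expr(rep(3, 8), c("g1", "g2"), paste0("s", 1:4))
  expect_error(eigenvalue_pct(flat), "zero total variance")
  expect_error(eigenvalue_pct(one[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("eigenvalue_pct matches independent decomposition routes", {
  x <- toy_expr(0, c("g1", "g2", "g3"), paste0("s", 1:4))
  x["g1", ] <- c(1, 2, 3, 4)
  x["g2", ] <- c(2, 1, 4, 3)
  x["g3", ] <- c(0, 0, 1, 1)
  expect_equal(eigenvalue_pct(x), eigen_oracle_gene_space(x),
               tolerance = 1e-9)
  expect_equal(eigenvalue_pct(x), eigen_oracle_svd(x), tolerance = 1e-9)
  # random matrices, both routes, genes on either side of sample count
  set.seed(33)
  for (i in 1:20) {
    ng <- sample(2:200, 1); ns <- sample(3:20, 1)
    m <- matrix(rnorm(ng * ns), ng, ns,
                dimnames = list(paste0("g", seq_len(ng)),
                                paste0("s", seq_len(ns))))
    expect_equal(eigenvalue_pct(m), eigen_oracle_svd(m), tolerance = 1e-9)
    expect_equal(eigenvalue_pct(m), eigen_oracle_gene_space(m),
                 tolerance = 1e-9)
  }
})

test_that("eigenvalue_pct is invariant to gene order and row shifts, and noise dilutes it", {
  exp1 <- make_exp(effect = 2)
  mod <- sprintf("g%02d", 1:10)
  sub <- exp1$expr[mod, ]
  expect_equal(eigenvalue_pct(sub[sample(nrow(sub)), ]),
               eigenvalue_pct(sub), tolerance = 1e-9)
  shifted <- sub; shifted[3, ] <- shifted[3, ] + 7
  expect_equal(eigenvalue_pct(shifted), eigenvalue_pct(sub),
               tolerance = 1e-9)
  # appending pure-noise genes to a coherent set never increases the share
  bigger <- exp1$expr[sprintf("g%02d", 1:30), ]
  expect_lt(eigenvalue_pct(bigger), eigenvalue_pct(sub))
})

test_that("perturbation_profile summarises forced effects exactly", {
  expn <- make_exp(effect = 1, noise = 0)
  mod <- sprintf("g%02d", 1:10)
  prof <- perturbation_profile(mod, expn)
  expect_equal(prof$frac_up, 1)
  expect_equal(prof$frac_down, 0)
  expect_equal(prof$mean_log2fc, 1, tolerance = 1e-12)
  # inversion exactly negates the interpreted profile
  expi <- make_exp(effect = 1, noise = 0, invert = TRUE)
  profi <- perturbation_profile(mod, expi)
  expect_equal(profi$frac_down, 1)
  expect_equal(profi$mean_log2fc, -1, tolerance = 1e-12)
  expect_equal(profi$frac_up, prof$frac_down)
})

test_that("fold changes equal a brute-force paired oracle on noisy data", {
  expn <- make_exp(effect = 0.7, noise = 0.5, seed = 77)
  fc <- log2_fold_changes(expn)
  oracle <- sapply(rownames(expn$expr), function(g) {
    d <- expn$expr[g, expn$pairing$perturbed] -
      expn$expr[g, expn$pairing$control]
    mean(d)
  })
  expect_equal(fc, oracle, tolerance = 1e-12)
  # unpaired route: group-mean difference oracle
  exp_unpaired <- perturbation_experiment(expn$expr, expn$condition)
  fc2 <- log2_fold_changes(exp_unpaired)
  oracle2 <- rowMeans(expn$expr[, expn$condition == "perturbed"]) -
    rowMeans(expn$expr[, expn$condition == "control"])
  expect_equal(fc2, oracle2, tolerance = 1e-12)
})

test_that("profile reports and excludes absent set members, rejects empty sets", {
  expn <- make_exp()
  prof <- perturbation_profile(c("g01", "g02", "nope"), expn)
  expect_equal(prof$n_used, 2)
  expect_equal(prof$absent, "nope")
  expect_error(perturbation_profile(c("zz1", "zz2"), expn), "no member")
})

test_that("permutation null is degenerate for the whole universe and seeded", {
  expn <- make_exp()
  all_genes <- rownames(expn$expr)
  res <- eigen_permutation_test(all_genes, expn, n_perm = 100, seed = 3)
  expect_equal(res$perm_p, 1)
  res1 <- eigen_permutation_test(sprintf("g%02d", 1:10), expn,
                                 n_perm = 100, seed = 5)
  res2 <- eigen_permutation_test(sprintf("g%02d", 1:10), expn,
                                 n_perm = 100, seed = 5)
  expect_identical(res1$null, res2$null)
  expect_error(eigen_permutation_test(all_genes, expn, n_perm = 50), ">= 100")
})

test_that("a planted coherent module is detected and background sets are not", {
  p <- simulation_params()
  st <- simulate_perturbation(p, "stimulation")
  truth <- attr(st, "truth")
  tnf <- names(truth$modules)[truth$modules == "tnf_module"]
  res <- eigen_permutation_test(tnf, st, n_perm = 999, seed = 13)
  expect_lte(res$perm_p, 0.01)
  bg <- names(truth$modules)[truth$modules == "background"]
  set.seed(99)
  rand_set <- sample(bg, 100)
  res_bg <- eigen_permutation_test(rand_set, st, n_perm = 999, seed = 13)
  expect_gt(res_bg$perm_p, 0.05)
})

test_that("induced_set applies the fold-change cutoff as specified", {
  expn <- make_exp(effect = 1, noise = 0)     # 2-fold > 1.5
  expect_setequal(induced_set(expn), sprintf("g%02d", 1:10))
  exp_small <- make_exp(effect = 0.4, noise = 0)  # ~1.32-fold < 1.5
  expect_length(induced_set(exp_small), 0)
  # noisy membership equals an oracle filter on recomputed fold changes
  expn2 <- make_exp(effect = 0.8, noise = 0.4, seed = 55)
  fc <- sapply(rownames(expn2$expr), function(g) {
    mean(expn2$expr[g, expn2$pairing$perturbed] -
           expn2$expr[g, expn2$pairing$control])
  })
  expect_setequal(induced_set(expn2), names(fc)[fc >= log2(1.5)])
})

test_that("experiment construction validates labels and pairing", {
  x <- toy_expr(rnorm(12), c("g1", "g2"), paste0("s", 1:6))
  cond <- setNames(rep(c("control", "perturbed"), each = 3), colnames(x))
  expect_s3_class(perturbation_experiment(x, cond),
                  "perturbation_experiment")
  expect_error(perturbation_experiment(x, setNames(rep("control", 6),
                                                   colnames(x))),
               "both conditions")
  bad <- cond; bad[1] <- "stimulated"
  expect_error(perturbation_experiment(x, bad), "stimulated")
  expect_error(perturbation_experiment(
    x, cond, pairing = data.frame(control = c("s1", "s1", "s3"),
                                  perturbed = c("s4", "s5", "s6"))),
    "bijection")
})
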