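# Structural-equation GWAS: lambda estimation, direct effects, path
# enumeration, and the direct/indirect/total decomposition.

rice_dag <- function() {
  trait_network(c("PSA", "RB", "WU", "WUE"),
                data.frame(from = c("PSA", "PSA", "RB"),
                           to = c("WU", "WUE", "WUE")))
}

test_that("parentless traits get empty lambda rows; missing traits error", {
  fx <- make_assoc_fixture(40, 30, 2, seed = 1)
  net <- trait_network(c("tr1", "tr2"), data.frame(from = "tr1", to = "tr2"))
  lam <- estimate_lambda(fx$pheno, net, fx$grm, fx$comp)
  expect_equal(unname(lam$lambda["tr1", ]), c(0, 0))
  expect_true(lam$lambda["tr2", "tr1"] != 0)
  expect_equal(lam$ordering, c("tr1", "tr2"))

  ph <- fx$pheno; ph$tr2 <- NULL
  expect_error(estimate_lambda(ph, net, fx$grm, fx$comp), "not in phenotypes")
})

test_that("with an empty DAG and diagonal components, SEM direct equals MTM", {
  fx <- make_assoc_fixture(25, 15, 3, seed = 2, rho_g = 0, rho_e = 0)
  net <- trait_network(paste0("tr", 1:3))
  w <- fx$g$dosages[, 5]
  sem <- sem_snp_direct_effects(w, fx$pheno, net, fx$grm, fx$comp)
  mtm <- gls_snp_effect(w, fx$pheno, fx$grm, fx$comp)
  expect_equal(sem$effects, mtm$effects, tolerance = 1e-8)
  expect_equal(sem$std_errors, mtm$std_errors, tolerance = 1e-8)
})

test_that("direct effects match a dense per-equation GLS oracle", {
  fx <- make_assoc_fixture(20, 12, 3, seed = 3)
  net <- trait_network(paste0("tr", 1:3),
                       data.frame(from = c("tr1", "tr2"),
                                  to = c("tr3", "tr3")))
  w <- fx$g$dosages[, 2]
  sem <- sem_snp_direct_effects(w, fx$pheno, net, fx$grm, fx$comp)
  Y <- fx$Y[, c("tr1", "tr2", "tr3")]
  oracle <- dense_sem_direct(w, Y, fx$grm$matrix,
                             fx$comp$sigma_g["tr3", "tr3"],
                             fx$comp$sigma_e["tr3", "tr3"],
                             parent_cols = c("tr1", "tr2"))
  expect_equal(unname(sem$effects["tr3"]), oracle$effect, tolerance = 1e-8)
  expect_equal(unname(sem$std_errors["tr3"]), oracle$se, tolerance = 1e-8)
})

test_that("a QTL on an upstream trait shows no direct effect downstream", {
  set.seed(4)
  sc <- sim_scenario(341, 600, trait_names = c("P", "C"),
                     lambda_true = matrix(c(0, 0.8, 0, 0), 2, 2,
                                          dimnames = list(c("P", "C"),
                                                          c("P", "C"))),
    h2_true = c(0.5, 0.5), seed = 4)
  g <- simulate_genotypes(sc)
  sim <- simulate_traits(g, sc)
  W <- center_markers(impute_mean(g))
  # spike a SNP outside the genotyped panel into the parent only, so the
  # polygenic background is uncorrelated with it beyond O(1/sqrt(n))
  w <- rbinom(341, 2, 0.3); w <- w - mean(w)
  s_true <- 0.6
  sim$pheno$P <- sim$pheno$P + s_true * w
  sim$pheno$C <- sim$pheno$C + 0.8 * s_true * w   # via lambda
  grm <- compute_grm(W)
  comp <- cov_components(diag(c(0.5, 0.5)), diag(c(0.7, 0.7)), c("P", "C"))
  net <- trait_network(c("P", "C"), data.frame(from = "P", to = "C"))
  sem <- sem_snp_direct_effects(w, sim$pheno, net, grm, comp)
  mtm <- gls_snp_effect(w, sim$pheno, grm, comp)
  expect_lt(abs(sem$effects["C"]), 0.25)   # ~0 within 3 SE; total is 0.48
  expect_lt(abs(unname(mtm$effects["C"]) - 0.8 * s_true), 0.2)
  expect_lt(abs(unname(sem$effects["P"]) - s_true), 0.15)
})

test_that("path enumeration is exhaustive, ordered and validated", {
  net <- rice_dag()
  expect_equal(enumerate_paths(net, "PSA", "WUE"), list(c("PSA", "WUE")))
  expect_equal(length(enumerate_paths(net, "PSA", "WU")), 1)
  expect_equal(length(enumerate_paths(net, "RB", "WU")), 0)
  expect_error(enumerate_paths(net, "PSA", "XX"), "unknown trait")

  chain <- trait_network(c("A", "B", "C"),
                         data.frame(from = c("A", "B", "A"),
                                    to = c("B", "C", "C")))
  expect_equal(enumerate_paths(chain, "A", "C"),
               list(c("A", "B", "C"), c("A", "C")))

  # incoming-path counts on the four-trait DAG
  count_in <- function(net, tr) {
    sum(vapply(setdiff(net$nodes, tr),
               function(s) length(enumerate_paths(net, s, tr)), 0L))
  }
  expect_equal(count_in(net, "PSA"), 0)
  expect_equal(count_in(net, "RB"), 0)
  expect_equal(count_in(net, "WU"), 1)
  expect_equal(count_in(net, "WUE"), 2)
})

test_that("decomposition reproduces the four-trait closed form", {
  net <- rice_dag()
  L <- matrix(0, 4, 4, dimnames = list(net$nodes, net$nodes))
  L["WU", "PSA"] <- 0.761
  L["WUE", "PSA"] <- 0.963
  L["WUE", "RB"] <- 0.045
  direct <- c(PSA = 0.3, RB = -0.1, WU = 0.2, WUE = 0.05)
  dec <- decompose_effects(direct, L, net)
  expect_equal(dec$effects$PSA$total, 0.3)            # parentless: total = direct
  expect_equal(dec$effects$RB$total, -0.1)
  expect_equal(dec$effects$WU$total, 0.2 + 0.761 * 0.3)
  expect_equal(dec$effects$WUE$total, 0.05 + 0.963 * 0.3 + 0.045 * (-0.1))

  # the reported direct/indirect pair on water use sums to the total
  s_psa <- -0.268 / 0.761
  direct2 <- c(PSA = s_psa, RB = 0, WU = -0.272, WUE = 0)
  dec2 <- decompose_effects(direct2, L, net)
  expect_equal(dec2$effects$WU$direct, -0.272)
  expect_equal(dec2$effects$WU$indirect[["PSA->WU"]], -0.268)
  expect_equal(dec2$effects$WU$total, -0.272 + -0.268)
})

test_that("path-sum totals equal the matrix-inverse reduced form", {
  for (s in 1:40) {
    dl <- random_dag_lambda(5, seed = s)
    direct <- setNames(rnorm(5), dl$net$nodes)
    dec <- decompose_effects(direct, dl$lambda, dl$net)
    totals <- vapply(dl$net$nodes, function(tr) dec$effects[[tr]]$total, 0)
    ref <- solve(diag(5) - dl$lambda, direct[dl$net$nodes])
    expect_lt(max(abs(totals - ref)), 1e-12)
    # exact additivity
    for (tr in dl$net$nodes) {
      e <- dec$effects[[tr]]
      expect_identical(e$total, e$direct + sum(unlist(e$indirect), 0))
    }
  }
  # all-zero lambda: totals collapse to direct effects
  net0 <- trait_network(c("a", "b"))
  dec0 <- decompose_effects(c(a = 1, b = 2), matrix(0, 2, 2), net0)
  expect_equal(dec0$effects$a$total, 1)
  expect_equal(dec0$effects$b$total, 2)
})

test_that("run_sem_gwas decomposes per SNP and matches MTM for parentless traits", {
  fx <- make_assoc_fixture(60, 80, 3, seed = 7)
  net <- trait_network(paste0("tr", 1:3),
                       data.frame(from = c("tr1", "tr1"),
                                  to = c("tr2", "tr3")))
  mtm <- run_mtm_gwas(fx$g, fx$pheno, fx$grm, fx$comp)
  top <- rank_top_snps(mtm, "tr1", 20)
  sem <- run_sem_gwas(fx$g, fx$pheno, net, fx$grm, fx$comp,
                      snp_subset = top$snp_id, mtm = mtm)
  expect_equal(nrow(sem), 20)
  expect_equal(sem$snp_id, top$snp_id)
  # parentless trait: total == direct for every SNP
  expect_equal(sem$total_tr1, sem$direct_tr1)
  # additivity for children
  expect_equal(sem$total_tr2,
               sem$direct_tr2 + sem[["indirect_tr1->tr2"]], tolerance = 1e-12)
  expect_true(all(c("mtm_total_tr1", "mtm_total_tr2") %in% names(sem)))
  expect_error(run_sem_gwas(fx$g, fx$pheno, net, fx$grm, fx$comp,
                            snp_subset = "nope"), "unknown snp_id")
})

test_that("SEM totals track MTM effects on recursive synthetic data", {
  set.seed(8)
  sc <- sim_scenario(341, 800, trait_names = c("P", "C"),
                     lambda_true = matrix(c(0, 0.7, 0, 0), 2, 2,
                                          dimnames = list(c("P", "C"),
                                                          c("P", "C"))),
                     h2_true = c(0.6, 0.6), seed = 8)
  g <- simulate_genotypes(sc)
  sim <- simulate_traits(g, sc)
  grm <- compute_grm(center_markers(impute_mean(g)))
  fit <- fit_mt_gblup(sim$pheno, grm, mcmc_config(400, 1600, 2, seed = 9))
  net <- trait_network(c("P", "C"), data.frame(from = "P", to = "C"))
  mtm <- run_mtm_gwas(g, sim$pheno, grm, fit$components)
  sem <- run_sem_gwas(g, sim$pheno, net, grm, fit$components, mtm = mtm)
  expect_gt(cor(sem$total_P, mtm$effect_P), 0.95)
  expect_gt(cor(sem$total_C, mtm$effect_C), 0.95)
})
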