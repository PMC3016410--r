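test_that("beta matches hand-computed second moments", {
  expect_equal(beta(c(-1, 1), c(-1, 1)), 0)
  expect_equal(beta(c(-2, 2), c(-1, 1)), -1.5)
  expect_equal(beta(c(0, 0), c(-1, 1)), 0.5)   # concentration -> positive
  expect_error(beta(numeric(0), 1), "empty")
  expect_error(beta(c(1, NA), 1), "non-finite")
})

test_that("beta is antisymmetric and order-invariant", {
  withr::with_seed(1, {
    for (i in 1:20) {
      s <- rnorm(50, sd = runif(1, 0.5, 2))
      b <- rnorm(80, sd = runif(1, 0.5, 2))
      expect_equal(beta(s, b), -beta(b, s))
      expect_equal(beta(sample(s), sample(b)), beta(s, b))
    }
  })
})

test_that("torque-formulation oracle agrees with the moment formula", {
  expect_equal(beta_torque_oracle(c(-1, 1), c(-1, 1)), 0)
  expect_equal(beta_torque_oracle(c(-2, 2), c(-1, 1), n_grid = 2e5), -1.5,
               tolerance = 1e-3)
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- rnorm(40, sd = 2); b <- rnorm(60)
      expect_equal(beta_torque_oracle(s, b, n_grid = 2e5), beta(s, b),
                   tolerance = 1e-3)
    }
  })
})

bimod_world <- function(n_genes = 120, n_targets = 15, seed = 5,
                        loading = 0.8) {
  withr::with_seed(seed, {
    n_samp <- 16
    f <- rnorm(n_samp)
    genes <- sprintf("g%03d", seq_len(n_genes))
    vals <- matrix(rnorm(n_genes * n_samp), n_genes,
                   dimnames = list(genes, paste0("s", seq_len(n_samp))))
    petal <- genes[1:4]
    targets <- genes[10 + seq_len(n_targets)]
    for (g in petal) vals[g, ] <- loading * f + sqrt(1 - loading^2) * rnorm(n_samp)
    sg <- rep(c(1, -1), length.out = n_targets)
    for (j in seq_along(targets)) {
      vals[targets[j], ] <- sg[j] * loading * f +
        sqrt(1 - loading^2) * rnorm(n_samp)
    }
    grp <- rep(c("WT", "MT"), each = n_samp / 2)
    mt <- grp == "MT"
    for (g in petal) vals[g, mt] <- vals[g, mt] + 1.5
    expr <- expression_bundle(vals, grp)
    list(expr = expr, petal = petal, targets = targets,
         cm = pearson_map(expr), act = activity(expr))
  })
}

test_that("permutation test flags a planted coexpressed target set", {
  w <- bimod_world()
  res <- permutation_test(w$petal, w$targets, w$act, w$cm,
                          n_perm = 500, seed = 11)
  expect_lt(res$p, 0.05)
  expect_lt(res$beta, 0)
  expect_length(res$null, 500)
  # p consistent with the stored null by the stated formula
  expect_equal(res$p, sum(res$null < res$beta) / res$n_perm)
})

test_that("permutation test honors determinism, zero activity, and guards", {
  w <- bimod_world()
  r1 <- permutation_test(w$petal, w$targets, w$act, w$cm,
                         n_perm = 300, seed = 21)
  r2 <- permutation_test(w$petal, w$targets, w$act, w$cm,
                         n_perm = 300, seed = 21)
  expect_identical(r1$beta, r2$beta)
  expect_identical(r1$p, r2$p)
  # all-zero activity gives beta exactly 0
  act0 <- w$act; act0$alpha[] <- 0
  r0 <- permutation_test(w$petal, w$targets, act0, w$cm,
                         n_perm = 200, seed = 2)
  expect_equal(r0$beta, 0)
  expect_error(permutation_test(w$petal, w$cm$genes, w$act, w$cm,
                                n_perm = 100, seed = 1), "smaller")
  expect_error(permutation_test(w$petal, "nope", w$act, w$cm,
                                n_perm = 100, seed = 1), "not in gene universe")
})

test_that("smoothed and two-sided variants behave as documented", {
  w <- bimod_world()
  raw <- permutation_test(w$petal, w$targets, w$act, w$cm,
                          n_perm = 200, seed = 3)
  sm <- permutation_test(w$petal, w$targets, w$act, w$cm,
                         n_perm = 200, seed = 3, smoothed = TRUE)
  expect_equal(sm$p, (1 + sum(sm$null < sm$beta)) / 201)
  expect_gt(sm$p, 0)
  ts <- permutation_test(w$petal, w$targets, w$act, w$cm,
                         n_perm = 200, seed = 3, two_sided = TRUE)
  expect_equal(ts$p, sum(-abs(ts$null) < -abs(ts$beta)) / 200)
  expect_identical(raw$beta, ts$beta)
})

test_that("rank_petals orders by p with beta and name tie-breaks", {
  w <- bimod_world()
  # blossom with one real petal and one noise petal
  mk_petal <- function(cand, nodes) {
    structure(list(candidate = cand,
                   graph = interaction_network(data.frame(
                     from = nodes[-length(nodes)], to = nodes[-1])),
                   paths = data.frame()), class = "petal")
  }
  noise <- w$cm$genes[100:103]
  bl <- structure(list(driver = w$petal[1],
                       petals = list(planted = mk_petal("planted", w$petal),
                                     decoy = mk_petal("decoy", noise))),
                  class = "blossom")
  rk <- rank_petals(bl, w$targets, w$act, w$cm, n_perm = 300, seed = 17)
  expect_equal(nrow(rk), 2L)
  expect_equal(rk$candidate[1], "planted")
  expect_true(all(diff(rk$p) >= 0))
  expect_true(all(c("beta", "p", "p_bh") %in% names(rk)))
  rk2 <- rank_petals(bl, w$targets, w$act, w$cm, n_perm = 300, seed = 17)
  expect_identical(rk, rk2)
  expect_error(rank_petals(structure(list(driver = "x", petals = list()),
                                     class = "blossom"),
                           w$targets, w$act, w$cm), "no petals")
})
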