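test_that("composite probabilities evaluate the product formula", {
  p <- c(A = 1, B = 0, C = 0)
  expect_equal(composite_specific(p, "A", c("B", "C")), 1.0)
  p2 <- c(A = 0.9, B = 0.3)
  expect_equal(composite_specific(p2, "A", "B"), 0.9 * 0.7)
  # empty set1 is an empty product
  expect_equal(composite_specific(c(B = 0.2), character(0), "B"), 0.8)
  expect_error(composite_specific(p2, "A", "A"), "disjoint")
  expect_error(composite_specific(c(A = 1.2, B = 0.1), "A", "B"), "\\[0, 1\\]")

  expect_equal(composite_any(c(0.5, 0.5), 1:2), 0.75)
  expect_equal(composite_any(c(a = 1, b = 0.1), c("a", "b")), 1)
  expect_equal(composite_any(c(a = 0, b = 0), c("a", "b")), 0)
  expect_error(composite_any(c(a = 0.5), character(0)), "nonempty")
})

test_that("arrangement probabilities sum to one over all partitions", {
  set.seed(4)
  for (C in 2:4) {
    p <- setNames(runif(C), paste0("ct", seq_len(C)))
    total <- 0
    for (mask in 0:(2^C - 1)) {
      in1 <- names(p)[bitwAnd(mask, 2^(seq_len(C) - 1)) > 0]
      total <- total + composite_specific(p, in1, setdiff(names(p), in1))
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("composite probability is monotone in the zero set", {
  p <- c(a = 0.9, b = 0.6, c = 0.4, d = 0.8)
  p1 <- composite_specific(p, "a", "b")
  p2 <- composite_specific(p, "a", c("b", "c"))
  p3 <- composite_specific(p, "a", c("b", "c", "d"))
  expect_true(p1 >= p2 && p2 >= p3)
  # lowering a sign probability in set2 raises its (1-p) factor
  q <- p; q["c"] <- 0.1
  expect_gt(composite_specific(q, "a", c("b", "c")), p2)
})

test_that("posterior means match the conjugate closed form", {
  set.seed(10)
  C <- 4
  U <- crossprod(matrix(rnorm(C * C), C)) / C + diag(C) * 0.05
  prior <- structure(list(U = list(shared = U),
                          weights = c(shared = 1),
                          scales = 1, loglik = 0, iterations = 1),
                     class = "prior_mixture")
  for (i in 1:25) {
    se <- runif(C, 0.05, 0.5)
    b <- rnorm(C, 0, 0.5)
    pan <- structure(list(beta = matrix(b, 1, C,
                                        dimnames = list("g", paste0("ct", 1:C))),
                          se = matrix(se, 1, C,
                                      dimnames = list("g", paste0("ct", 1:C))),
                          missing = matrix(FALSE, 1, C)),
                     class = "effect_panel")
    post <- posterior_panel(pan, prior)
    S <- diag(se^2)
    mu <- solve(solve(U) + solve(S)) %*% solve(S) %*% b
    expect_equal(unname(post$mean[1, ]), drop(mu), tolerance = 1e-8)
  }
})

test_that("a point-mass-at-zero prior forces lfsr to one", {
  C <- 3
  prior <- structure(list(U = list(null = matrix(0, C, C)),
                          weights = c(null = 1),
                          scales = 1, loglik = 0, iterations = 1),
                     class = "prior_mixture")
  pan <- structure(list(beta = matrix(c(1, -2, 0.5), 1, C,
                                      dimnames = list("g", paste0("ct", 1:C))),
                        se = matrix(0.1, 1, C,
                                    dimnames = list("g", paste0("ct", 1:C))),
                        missing = matrix(FALSE, 1, C)),
                   class = "effect_panel")
  post <- posterior_panel(pan, prior)
  expect_equal(unname(post$mean[1, ]), rep(0, C))
  expect_equal(unname(post$lfsr[1, ]), rep(1, C))
  expect_equal(unname(post$p_sign[1, ]), rep(0, C))
})

test_that("a diagonal zero-centered prior shrinks every entry toward zero", {
  prior <- structure(list(U = list(iid = diag(3) * 0.04),
                          weights = c(iid = 1),
                          scales = 0.2, loglik = 0, iterations = 1),
                     class = "prior_mixture")
  set.seed(2)
  B <- matrix(rnorm(30, 0, 0.3), 10, 3, dimnames = list(paste0("g", 1:10),
                                                        paste0("ct", 1:3)))
  S <- matrix(runif(30, 0.05, 0.3), 10, 3, dimnames = dimnames(B))
  pan <- structure(list(beta = B, se = S, missing = S >= 1e6),
                   class = "effect_panel")
  post <- posterior_panel(pan, prior)
  expect_true(all(abs(post$mean) <= abs(B)))
  expect_true(all(post$lfsr >= 0 & post$lfsr <= 0.5 + 1e-12))
})

test_that("the EM recovers a dominant null component on null data", {
  set.seed(2)
  C <- 5; n <- 5000
  nm <- list(paste0("g", 1:n), paste0("CT", 1:C))
  B <- matrix(rnorm(n * C, 0, 0.1), n, C, dimnames = nm)
  S <- matrix(0.1, n, C, dimnames = nm)
  pan <- structure(list(beta = B, se = S, missing = S >= 1e6),
                   class = "effect_panel")
  pr <- fit_prior(pan)
  expect_gt(pr$weights[["null"]], 0.95)
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(pr$loglik) > -1e-8))
})

test_that("the EM recovers a planted singleton sharing pattern", {
  set.seed(3)
  C <- 5; n <- 3000
  nm <- list(paste0("g", 1:n), paste0("CT", 1:C))
  B <- matrix(0, n, C, dimnames = nm)
  B[, 2] <- rnorm(n, 0, 0.5)
  B <- B + matrix(rnorm(n * C, 0, 0.1), n, C)
  S <- matrix(0.1, n, C, dimnames = nm)
  pan <- structure(list(beta = B, se = S, missing = S >= 1e6),
                   class = "effect_panel")
  pr <- fit_prior(pan)
  w_singleton2 <- sum(pr$weights[grep("^singleton_2_", names(pr$weights))])
  expect_gt(w_singleton2, 0.5)
  expect_gt(w_singleton2, sum(pr$weights[grep("^equal_", names(pr$weights))]))
  expect_error(fit_prior(pan, components = list(bad = matrix(c(1, 2, 2, 1,
    rep(0, 21)), 5, 5))), "positive semidefinite")
})

test_that("missing entries borrow nothing under a singleton-only prior", {
  C <- 3
  comp <- list(s1 = diag(c(1, 0, 0)), s2 = diag(c(0, 1, 0)),
               s3 = diag(c(0, 0, 1)))
  prior <- structure(list(U = c(list(null = matrix(0, C, C)),
                                lapply(comp, function(u) 0.25 * u)),
                          weights = setNames(rep(0.25, 4),
                                             c("null", names(comp))),
                          scales = 0.5, loglik = 0, iterations = 1),
                     class = "prior_mixture")
  pan <- structure(list(beta = matrix(c(0.8, 0, 0), 1, C,
                                      dimnames = list("g", paste0("ct", 1:C))),
                        se = matrix(c(0.1, 1e6, 1e6), 1, C,
                                    dimnames = list("g", paste0("ct", 1:C))),
                        missing = matrix(c(FALSE, TRUE, TRUE), 1, C)),
                   class = "effect_panel")
  post <- posterior_panel(pan, prior)
  expect_lt(abs(post$mean[1, 2]), 1e-4)
  expect_lt(abs(post$mean[1, 3]), 1e-4)
  expect_gt(abs(post$mean[1, 1]), 0.5)
})

test_that("the effect panel encodes untested entries with the SE sentinel", {
  fx <- fx_sim()
  eg <- egene_calling(fx$cis)
  pan <- effect_panel(fx$cis, genes = unique(eg$gene[eg$egene]))
  expect_identical(dim(pan$beta), dim(pan$se))
  expect_true(all(pan$beta[pan$missing] == 0))
  expect_true(all(pan$se[pan$missing] == 1e6))
  # the chosen variant is the overall smallest-p variant of the gene
  g1 <- rownames(pan$beta)[1]
  sub <- fx$cis[fx$cis$gene == g1, ]
  expect_identical(unname(pan$variant[g1]), sub$variant[which.min(sub$p)])
})

test_that("scanning a single cell type reduces to the sign probability", {
  P <- matrix(c(0.9, 0.2), 2, 1, dimnames = list(c("g1", "g2"), "CT1"))
  sc <- specificity_scan(P)
  expect_equal(sc$probability, c(0.9, 0.2))
  expect_identical(sc$specific, c(TRUE, FALSE))
})

test_that("group arrangements use the at-least-one probability", {
  P <- matrix(c(0.6, 0.7, 0.05), 1, 3,
              dimnames = list("g", c("IN_A", "IN_B", "EX")))
  sc <- specificity_scan(P, groups = list(IN = c("IN_A", "IN_B")))
  probs <- attr(sc, "probabilities")
  expect_equal(probs["g", "IN"], (1 - 0.4 * 0.3) * (1 - 0.05))
  expect_identical(sc$arrangement, "IN")
})
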