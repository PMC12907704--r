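make_two_group_fit <- function(values, groups) {
  m <- matrix(values, nrow = 1,
              dimnames = list("cg1", paste0("s", seq_along(values))))
  fit_group_means(m, group_design(colnames(m), groups))
}

test_that("fit_group_means recovers group means and pooled variance", {
  fit <- make_two_group_fit(c(1, 3, 5, 7), c("a", "a", "b", "b"))
  expect_equal(unname(fit$coef["cg1", ]), c(2, 6))
  expect_equal(unname(fit$sigma2["cg1"]), 2)   # (1+1+1+1)/2
  expect_equal(fit$df_resid, 2)

  flat <- make_two_group_fit(rep(4.2, 5), c("a", "a", "b", "b", "b"))
  expect_equal(unname(flat$coef["cg1", ]), c(4.2, 4.2))
  expect_equal(unname(flat$sigma2["cg1"]), 0)
})

test_that("fit_group_means matches an ordinary least-squares oracle", {
  set.seed(21)
  groups <- rep(c("g1", "g2", "g3"), times = c(4, 5, 3))
  m <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("cg", 1:20), paste0("s", 1:12)))
  fit <- fit_group_means(m, group_design(colnames(m), groups))
  for (i in 1:20) {
    ols <- lm(m[i, ] ~ 0 + factor(groups))
    expect_equal(unname(fit$coef[i, ]), unname(coef(ols)), tolerance = 1e-10)
    expect_equal(unname(fit$sigma2[i]), summary(ols)$sigma^2, tolerance = 1e-10)
  }
})

test_that("fit_group_means rejects degenerate designs", {
  m <- tiny_beta(4, 3)
  expect_error(fit_group_means(m, group_design(colnames(m), c("a", "b", "c"))),
               "degrees of freedom")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(fit_group_means(m_na, group_design(colnames(m), c("a", "a", "b"))),
               "complete")
})

test_that("estimate_prior recovers a known scaled chi-square hierarchy", {
  set.seed(31)
  d0 <- 4; s0 <- 1; df <- 4; n <- 50000
  sigma2_true <- d0 * s0 / rchisq(n, d0)          # inverse-chi-square prior
  s2 <- sigma2_true * rchisq(n, df) / df           # sampling layer
  fake <- structure(list(sigma2 = s2, df_resid = df), class = "probe_fit")
  prior <- estimate_prior(fake)
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.05)
})

test_that("estimate_prior handles zero log-variance spread", {
  fake <- structure(list(sigma2 = c(cg1 = 1, cg2 = 1), df_resid = 3),
                    class = "probe_fit")
  prior <- estimate_prior(fake)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, 1)

  degenerate <- structure(list(sigma2 = c(0, 0), df_resid = 3), class = "probe_fit")
  expect_error(estimate_prior(degenerate), "degenerate")
})

test_that("estimate_prior agrees with limma's F-distribution fit", {
  set.seed(32)
  s2 <- (2 * 0.5 / rchisq(2000, 2)) * rchisq(2000, 5) / 5
  fake <- structure(list(sigma2 = s2, df_resid = 5), class = "probe_fit")
  prior <- estimate_prior(fake)
  ref <- limma::fitFDist(s2, df1 = 5)
  expect_equal(prior$d0, ref$df2, tolerance = 1e-6)
  expect_equal(prior$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated t with zero prior df equals the ordinary linear-model t", {
  set.seed(41)
  groups <- rep(c("g1", "g2", "g3"), times = c(5, 5, 4))
  m <- matrix(rnorm(20 * 14), 20, 14,
              dimnames = list(paste0("cg", 1:20), paste0("s", 1:14)))
  design <- group_design(colnames(m), groups)
  fit <- fit_group_means(m, design)
  res <- moderated_contrast(fit, list(d0 = 0, s0_sq = 1),
                            c(g1 = 1, g2 = -1, g3 = 0))
  for (i in 1:20) {
    g <- factor(groups)
    ols <- lm(m[i, ] ~ 0 + g)
    cvec <- c(1, -1, 0)
    est <- sum(cvec * coef(ols))
    se <- sqrt(drop(t(cvec) %*% vcov(ols) %*% cvec))
    t_ols <- est / se
    p_ols <- 2 * pt(-abs(t_ols), df = ols$df.residual)
    expect_equal(res$t[i], t_ols, tolerance = 1e-8)
    expect_equal(res$P.Value[i], p_ols, tolerance = 1e-8)
  }
})

test_that("moderated contrast handles degenerate inputs and the d0 = Inf limit", {
  fit <- make_two_group_fit(c(1, 3, 5, 7), c("a", "a", "b", "b"))
  prior <- list(d0 = 2, s0_sq = 1)
  zero <- moderated_contrast(fit, prior, c(a = 0, b = 0))
  expect_equal(zero$logFC, 0)
  expect_equal(zero$P.Value, 1)

  flat <- make_two_group_fit(rep(2, 4), c("a", "a", "b", "b"))
  res <- moderated_contrast(flat, list(d0 = 0, s0_sq = 1), c(a = 1, b = -1))
  expect_equal(res$t, 0)
  expect_equal(res$P.Value, 1)

  inf <- moderated_contrast(fit, list(d0 = Inf, s0_sq = 4), c(a = 1, b = -1))
  # posterior variance pinned at s0_sq: t = logFC / sqrt(4 * (1/2 + 1/2)), normal p
  expect_equal(inf$t, -4 / sqrt(4 * 1))
  expect_equal(inf$P.Value, 2 * pnorm(-2))

  expect_error(moderated_contrast(fit, prior, c(1, -1, 0)), "contrast length")
})

test_that("full moderated pipeline matches limma on random data", {
  set.seed(51)
  groups <- rep(c("tumor_tissue", "normal_tissue", "normal_plasma"),
                times = c(6, 6, 7))
  m <- matrix(rnorm(300 * 19, sd = rep(sqrt(0.2 + rexp(300)), 19)), 300, 19,
              dimnames = list(paste0("cg", 1:300), paste0("s", 1:19)))
  design <- group_design(colnames(m), groups)
  fit <- fit_group_means(m, design)
  prior <- estimate_prior(fit)
  res <- moderated_contrast(fit, prior,
                            c(tumor_tissue = 1, normal_tissue = -1, normal_plasma = 0))

  lfit <- limma::lmFit(m, design$design)
  cm <- limma::makeContrasts(tumor_tissue - normal_tissue, levels = design$design)
  lfit2 <- limma::eBayes(limma::contrasts.fit(lfit, cm))
  tab <- limma::topTable(lfit2, number = Inf, adjust.method = "fdr", sort.by = "none")
  expect_equal(res$logFC, tab$logFC, tolerance = 1e-8)
  expect_equal(res$t, tab$t, tolerance = 1e-6)
  expect_equal(res$P.Value, tab$P.Value, tolerance = 1e-6)
  expect_equal(res$adj.P.Val, tab$adj.P.Val, tolerance = 1e-6)
})

test_that("bh_adjust matches a brute-force step-up oracle", {
  # hand case: 0.01*4/1, 0.02*4/2, 0.03*4/3, 0.04*4/4 -> cummin from the top = 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)

  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(61)
  p <- runif(1000)
  expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  # monotone in p-rank and bounded
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("select_tumor_specific applies the two-contrast rule, ranking and cap", {
  mk <- function(ids, lfc, adj) {
    structure(data.frame(probe_id = ids, logFC = lfc, t = 1,
                         P.Value = adj, adj.P.Val = adj,
                         stringsAsFactors = FALSE),
              class = c("dmp_result", "data.frame"))
  }
  ids <- paste0("cg", 1:6)
  tumor <- mk(ids,
              lfc = c(0.5, 0.3, 0.25, 0.1, -0.6, 0.4),
              adj = c(0.005, 0.001, 0.005, 0.001, 0.001, 0.5))
  tissue <- mk(ids,
               lfc = c(0.0, 0.3, 0.005, 0.0, 0.0, 0.0),
               adj = c(0.5, 0.001, 0.001, 0.5, 0.5, 0.5))
  # cg1: tumor-sig, tissue non-sig -> in; cg2: tissue-specific -> out
  # cg3: tissue adj sig but |lfc| < 0.01 -> in (OR rule); cg4: weak tumor lfc -> out
  # cg5: strong negative lfc -> in; cg6: tumor adj >= 0.01 -> out
  sel <- select_tumor_specific(tumor, tissue)
  expect_identical(sel, c("cg5", "cg1", "cg3"))  # ranked by |logFC| desc

  expect_identical(select_tumor_specific(tumor, tissue, top_n = 2),
                   c("cg5", "cg1"))
  expect_warning(out <- select_tumor_specific(mk(ids, 0, 1), tissue), "no probe")
  expect_identical(out, character(0))

  # ranking cap on a large passing set: largest |logFC| kept, ties stable
  ids2 <- sprintf("cg%04d", 1:700)
  big_t <- mk(ids2, lfc = seq(2, 0.3, length.out = 700), adj = 0.001)
  big_s <- mk(ids2, lfc = 0, adj = 1)
  sel2 <- select_tumor_specific(big_t, big_s)
  expect_length(sel2, 500)
  expect_identical(sel2, ids2[1:500])
})

test_that("select_tumor_specific output always satisfies the filter clauses", {
  set.seed(71)
  tg <- make_tissue_groups(fixture_spec(n_probes = 400, n_dmp = 80,
                                        n_tissue_dmp = 30, n_tumor_tissue = 15,
                                        n_normal_tissue = 15, n_plasma = 15,
                                        seed = 5))
  m <- beta_to_m(tg$beta)
  fit <- fit_group_means(m, tg$design)
  prior <- estimate_prior(fit)
  tumor <- moderated_contrast(fit, prior, c(tumor_tissue = 1, normal_tissue = -1,
                                            normal_plasma = 0))
  tissue <- moderated_contrast(fit, prior, c(tumor_tissue = 0, normal_tissue = 1,
                                             normal_plasma = -1))
  sel <- select_tumor_specific(tumor, tissue)
  expect_true(length(sel) > 0)
  tu <- tumor[match(sel, tumor$probe_id), ]
  ti <- tissue[match(sel, tissue$probe_id), ]
  expect_true(all(tu$adj.P.Val < 0.01 & abs(tu$logFC) > 0.2))
  expect_true(all(ti$adj.P.Val >= 0.05 | abs(ti$logFC) < 0.01))
  expect_true(all(diff(abs(tu$logFC)) <= 0))
})
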