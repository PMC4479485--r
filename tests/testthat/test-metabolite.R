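test_that("median normalization rescales each sample row to median 1", {
  m <- metabolite_matrix(
    c("s1", "s2"), c("WT", "OE"),
    data.frame(a = c(1, 10), b = c(2, 20), c = c(3, 30))
  )
  norm <- median_normalize(m)
  expect_equal(unlist(norm[1, c("a", "b", "c")], use.names = FALSE), c(0.5, 1, 1.5))
  # two rows differing by a constant factor give identical output rows
  expect_equal(
    unlist(norm[2, c("a", "b", "c")], use.names = FALSE),
    unlist(norm[1, c("a", "b", "c")], use.names = FALSE)
  )
  # already median-1 row is a fixed point
  again <- median_normalize(norm)
  expect_equal(again$a, norm$a)

  zero <- raw_metab(data.frame(a = c(0, 1), b = c(0, 2), c = c(0, 3)))
  expect_error(median_normalize(zero), "zero median")
})

test_that("log10 transform is elementwise and names the offending cell", {
  m <- metabolite_matrix(
    c("s1", "s2"), c("WT", "OE"),
    data.frame(a = c(1, 100), b = c(10, 1000))
  )
  lg <- log10_transform(m)
  expect_equal(lg$a, c(0, 2))
  expect_equal(lg$b, c(1, 3))

  bad <- raw_metab(data.frame(a = c(1, 2), b = c(0, 3)))
  expect_error(log10_transform(bad), "s1.*b|b.*s1")
})

test_that("Pareto scaling centers and divides by the root of the sd", {
  m <- raw_metab(data.frame(a = c(1, 2, 3)), group = c("WT", "WT", "OE"))
  sc <- pareto_scale(m)
  expect_equal(sc$a, c(-1, 0, 1)) # sd 1, sqrt(1) = 1

  const <- raw_metab(data.frame(a = c(1, 2, 3), b = c(5, 5, 5)),
    group = c("WT", "WT", "OE")
  )
  expect_warning(sc2 <- pareto_scale(const), "constant")
  expect_equal(sc2$b, c(0, 0, 0))

  # property: post mean 0, post variance = pre sd
  set.seed(14)
  for (i in 1:10) {
    vals <- matrix(rlnorm(8 * 6, 3, 1), 8, 6)
    colnames(vals) <- paste0("m", 1:6)
    mm <- raw_metab(vals)
    out <- pareto_scale(mm)
    pre_sd <- apply(vals, 2, sd)
    for (j in 1:6) {
      col <- out[[paste0("m", j)]]
      expect_lt(abs(mean(col)), 1e-9)
      expect_equal(stats::var(col), unname(pre_sd[j]), tolerance = 1e-9)
    }
  }
})

test_that("the scaling chain order is normalize, log10, Pareto and not commutative", {
  sim <- simulate_metabolites(n_metabolites = 20, n_per_group = 4, seed = 6)
  m <- sim$metabolites
  chain <- scale_metabolites(m)
  manual <- pareto_scale(log10_transform(median_normalize(m)))
  expect_equal(
    as.data.frame(chain[, -(1:2)]),
    as.data.frame(manual[, -(1:2)])
  )
  expect_equal(attr(chain, "stage"), "pareto")
  # permuting the first two steps changes the output
  permuted <- pareto_scale(median_normalize(log10_transform(m)))
  expect_false(isTRUE(all.equal(
    as.data.frame(chain[, -(1:2)]),
    as.data.frame(permuted[, -(1:2)])
  )))
})

test_that("volcano selection requires both the p and the fold-change criterion", {
  # identical groups: nothing selected
  set.seed(31)
  vals <- matrix(rlnorm(10, 4, 0.5), 2, 5)
  vals <- rbind(vals, vals) # OE rows are exact copies of the WT rows
  colnames(vals) <- paste0("m", 1:5)
  same <- raw_metab(vals, group = c("WT", "WT", "OE", "OE"))
  v0 <- volcano_select(scale_metabolites(same))
  expect_false(any(v0$selected))

  # a clean mean shift below the fold-change cutoff: significant p, not selected
  set.seed(8)
  base <- rnorm(12, 0, 0.01)
  shifted <- 10^c(base[1:6], base[7:12] + log10(1.2))
  mm <- raw_metab(
    data.frame(m1 = shifted, m2 = rlnorm(12, 2, 0.2)),
    group = rep(c("WT", "OE"), each = 6)
  )
  v1 <- volcano_select(pareto_scale(log10_transform(mm)))
  row <- v1[v1$metabolite == "m1", ]
  expect_lt(row$p, 0.05)
  expect_lt(abs(row$log2fc), 1)
  expect_false(row$selected)

  expect_error(
    volcano_select(pareto_scale(log10_transform(raw_metab(
      data.frame(m1 = c(1, 2, 3), m2 = c(4, 5, 7)),
      group = c("WT", "OE", "OE")
    )))),
    ">= 2 samples"
  )
})

test_that("both truly shifted metabolites are recovered on the pinned fixture", {
  sim <- simulate_metabolites(
    n_metabolites = 125, n_per_group = 6, n_shifted = 2,
    shift = 0.6, seed = 3
  )
  v <- volcano_select(scale_metabolites(sim$metabolites))
  truth <- sim$truth$shifted_metabolites$metabolite
  expect_true(all(truth %in% v$metabolite[v$selected]))
  # false positives bounded: at most binomial 99.9% bound at alpha = 0.05
  fp <- sum(v$selected & !(v$metabolite %in% truth))
  expect_lte(fp, qbinom(0.999, 123, 0.05))
})
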