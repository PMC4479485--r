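test_that("rpkm matches direct arithmetic and handles zeros", {
  cases <- list(
    list(count = 1000, len = 1000L, total = 1e6, expected = 1000),
    list(count = 0, len = 1234L, total = 5e5, expected = 0),
    list(count = 50, len = 2500L, total = 5e6, expected = 4) # 50 / (2.5 * 5)
  )
  for (cs in cases) {
    ct <- count_table("g1", cs$len, data.frame(s1 = cs$count),
      library_totals = c(s1 = cs$total)
    )
    expect_equal(rpkm(ct)$s1, cs$expected)
  }
})

test_that("rpkm is invariant to scaling counts and totals by the same factor", {
  ct1 <- count_table(c("g1", "g2"), c(800L, 1500L),
    data.frame(s1 = c(7L, 31L)),
    library_totals = c(s1 = 2e5)
  )
  ct2 <- count_table(c("g1", "g2"), c(800L, 1500L),
    data.frame(s1 = c(70L, 310L)),
    library_totals = c(s1 = 2e6)
  )
  expect_equal(rpkm(ct1)$s1, rpkm(ct2)$s1)
})

test_that("quantile normalization equalizes column distributions", {
  ex <- structure(
    tibble::tibble(gene_id = c("g1", "g2"), a = c(1, 3), b = c(2, 4)),
    class = c("ucp_expr", class(tibble::tibble()))
  )
  qn <- quantile_normalize(ex)
  expect_equal(qn$a, c(1.5, 3.5))
  expect_equal(qn$b, c(1.5, 3.5))

  # identical columns are a fixed point
  same <- structure(
    tibble::tibble(gene_id = paste0("g", 1:4), a = c(5, 1, 3, 2), b = c(5, 1, 3, 2)),
    class = c("ucp_expr", class(tibble::tibble()))
  )
  qn2 <- quantile_normalize(same)
  expect_equal(qn2$a, same$a)
  expect_equal(qn2$b, same$b)

  # property: all columns share sorted values; within-column ranks preserved
  set.seed(42)
  for (i in 1:10) {
    m <- matrix(rexp(60), 20, 3)
    ex3 <- structure(
      dplyr::bind_cols(
        tibble::tibble(gene_id = paste0("g", 1:20)),
        tibble::as_tibble(as.data.frame(m))
      ),
      class = c("ucp_expr", class(tibble::tibble()))
    )
    qn3 <- quantile_normalize(ex3)
    sorted <- sapply(c("V1", "V2", "V3"), function(s) sort(qn3[[s]]))
    expect_equal(sorted[, 1], sorted[, 2])
    expect_equal(sorted[, 2], sorted[, 3])
    for (s in c("V1", "V2", "V3")) {
      expect_equal(order(qn3[[s]]), order(ex3[[s]]))
    }
  }

  single <- structure(
    tibble::tibble(gene_id = "g1", a = 1),
    class = c("ucp_expr", class(tibble::tibble()))
  )
  expect_error(quantile_normalize(single), ">= 2 samples")
})

test_that("Kal's Z-test matches the pooled two-proportion statistic", {
  # equal proportions
  res <- kal_z_test(10, 1000, 20, 2000)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  # fixed worked case against the independent oracle
  res2 <- kal_z_test(30, 1e4, 10, 1e4)
  expect_equal(res2$z, oracle_pooled_z(30, 1e4, 10, 1e4), tolerance = 1e-10)
  expect_equal(res2$z, 3.166, tolerance = 1e-3)

  # antisymmetry under swapping the libraries
  swapped <- kal_z_test(10, 1e4, 30, 1e4)
  expect_equal(swapped$z, -res2$z)
  expect_equal(swapped$p, res2$p)

  # 1,000 random draws agree with the oracle to 1e-10
  set.seed(1)
  for (i in 1:1000) {
    N1 <- sample(1e3:1e6, 1)
    N2 <- sample(1e3:1e6, 1)
    x1 <- rpois(1, runif(1, 0.5, 500))
    x2 <- rpois(1, runif(1, 0.5, 500))
    if (x1 + x2 == 0) next
    got <- kal_z_test(x1, N1, x2, N2)
    expect_equal(got$z, oracle_pooled_z(x1, N1, x2, N2), tolerance = 1e-10)
  }

  expect_error(kal_z_test(0, 100, 0, 200), "undefined")
  expect_error(kal_z_test(1, 0, 2, 100), "positive")
})

test_that("DEG calling applies both cutoffs on the right scales", {
  # three genes: strong true shift, shift failing p, flat
  ct <- count_table(
    gene_id = c("gA", "gB", "gC", "gD"),
    length = rep(1000L, 4),
    counts = data.frame(
      WT = c(100L, 2L, 500L, 0L),
      OE1 = c(420L, 9L, 505L, 0L)
    ),
    library_totals = c(WT = 1e5, OE1 = 1e5)
  )
  expr <- rpkm(ct)
  res <- call_degs(ct, expr, oe = "OE1", wt = "WT")

  # calls obey the DEGResult invariants
  up <- res[res$call == "up", ]
  down <- res[res$call == "down", ]
  expect_true(all(up$log2fc >= 1 & up$p <= 0.001))
  expect_true(all(down$log2fc <= -1 & down$p <= 0.001))

  expect_equal(res$call[res$gene_id == "gA"], "up")
  # gB: >2-fold but too few reads for p<=0.001
  expect_gt(res$p[res$gene_id == "gB"], 0.001)
  expect_equal(res$call[res$gene_id == "gB"], "none")
  expect_equal(res$call[res$gene_id == "gC"], "none")
  # zero in both samples: excluded from testing
  expect_false("gD" %in% res$gene_id)

  expect_error(call_degs(ct, expr, oe = "OE9", wt = "WT"), "OE9")
})

test_that("spiked genes are recovered with correct direction on the pinned fixture", {
  sim <- simulate_counts(
    n_genes = 2000, library_size = 5e5, de_fraction = 0.05,
    de_log2fc = 3, seed = 7
  )
  qn <- quantile_normalize(rpkm(sim$counts))
  d1 <- call_degs(sim$counts, qn, "OE1", "WT")
  d2 <- call_degs(sim$counts, qn, "OE2", "WT")
  common <- intersect_degs(d1, d2)
  truth <- sim$truth$de_genes
  strong <- truth[abs(truth$log2fc) >= 3 & truth$baseline_mean >= 50, ]
  hits <- common[common$gene_id %in% strong$gene_id, ]
  expect_gte(nrow(hits) / nrow(strong), 0.8)
  # direction always correct for recovered strong genes
  joined <- merge(hits, strong, by = "gene_id")
  expect_true(all(ifelse(joined$log2fc > 0, "up", "down") == joined$direction))
})

test_that("the intersection rule keeps only same-direction calls", {
  uni <- paste0("g", 1:6)
  a <- fake_deg(uni, c("up", "up", "down", "up", "down", "none"), uni)
  b <- fake_deg(uni, c("up", "none", "down", "down", "down", "none"), uni)
  common <- intersect_degs(a, b)
  expect_setequal(common$gene_id[common$direction == "up"], "g1")
  expect_setequal(common$gene_id[common$direction == "down"], c("g3", "g5"))
  # g4: opposite directions -> excluded from both sets
  expect_false("g4" %in% common$gene_id)

  c_ <- fake_deg(paste0("h", 1:6), rep("none", 6), paste0("h", 1:6))
  expect_error(intersect_degs(a, c_), "universe")
})
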