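test_that("EC fold changes aggregate gene log2 ratios by unweighted mean", {
  expr <- structure(
    tibble::tibble(
      gene_id = c("g1", "g2", "g3", "g4"),
      OE = c(8, 4, 16, 5),
      WT = c(2, 2, 2, 5)
    ),
    class = c("ucp_expr", class(tibble::tibble()))
  )
  ann <- annotation_table(
    c("g1", "g2", "g3", "g4", "g5"),
    replicate(5, character(), simplify = FALSE),
    list("1.1.1.1", "2.2.2.2", "2.2.2.2", "3.3.3.3", "4.4.4.4")
  )
  expect_warning(efc <- ec_fold_changes(expr, ann, "OE", "WT"), "4\\.4\\.4\\.4")
  expect_equal(efc$log2fc[efc$ec == "1.1.1.1"], 2) # log2(8/2)
  expect_equal(efc$log2fc[efc$ec == "2.2.2.2"], 2) # mean(1, 3)
  expect_equal(efc$log2fc[efc$ec == "3.3.3.3"], 0) # ExpA == ExpB
  expect_false("4.4.4.4" %in% efc$ec)
})

test_that("pathway retention requires min_ec fold-change-bearing ECs", {
  efc <- fake_ecfc(sprintf("1.1.1.%d", 1:5), rnorm(5))
  pw <- pathway_map(
    c("P4", "P5", "P7"),
    c("four mapped", "five mapped", "seven ECs three mapped"),
    list(
      sprintf("1.1.1.%d", 1:4),
      sprintf("1.1.1.%d", 1:5),
      c(sprintf("1.1.1.%d", 1:3), sprintf("9.9.9.%d", 1:4))
    )
  )
  kept <- filter_pathways(pw, efc, min_ec = 5)
  expect_equal(kept$pathway_id, "P5") # boundary inclusive; 4 and 3 mapped drop
})

test_that("pathway Z matches the exhaustive subset null on a tiny pool", {
  fc <- c(2.0, 1.8, 2.2, 1.9, 2.1, -0.3, 0.1, -0.2)
  ecs <- sprintf("1.2.3.%d", 1:8)
  efc <- fake_ecfc(ecs, fc)
  pw <- pathway_map(
    c("HOT", "BULK"),
    c("shifted five", "the rest plus overlap"),
    list(ecs[1:5], ecs[3:8]) # pool = union = all 8 ECs
  )
  kept <- filter_pathways(pw, efc)
  scores <- pathway_z(kept, efc, n_sets = "exhaustive")
  hot <- scores[scores$pathway_id == "HOT", ]

  # independent enumeration of all C(8,5) = 56 subset means
  null_means <- apply(combn(8, 5), 2, function(ix) mean(fc[ix]))
  expect_length(null_means, 56)
  z_want <- (mean(fc[1:5]) - mean(null_means)) / sd(null_means)
  expect_equal(hot$z, z_want, tolerance = 1e-12)
  expect_equal(hot$p, 2 * pnorm(-abs(z_want)), tolerance = 1e-12)

  # Monte-Carlo convergence toward the exhaustive null
  mc <- pathway_z(kept, efc, n_sets = 10000, seed = 4)
  expect_equal(mc$z[mc$pathway_id == "HOT"], z_want, tolerance = 0.1)
})

test_that("degenerate pools and undersized pools are handled as specified", {
  ecs <- sprintf("1.1.1.%d", 1:8)
  const <- fake_ecfc(ecs, rep(1.5, 8))
  pw <- pathway_map(c("A", "B"), c("a", "b"), list(ecs[1:5], ecs[2:8]))
  kept <- filter_pathways(pw, const)
  sc <- pathway_z(kept, const, n_sets = 50, seed = 1)
  expect_equal(sc$z, c(0, 0))
  expect_equal(sc$p, c(1, 1))

  # pool not larger than k -> error
  solo <- pathway_map("A", "a", list(ecs[1:5]))
  efc5 <- fake_ecfc(ecs[1:5], rnorm(5))
  expect_error(pathway_z(filter_pathways(solo, efc5), efc5, seed = 1), "pool")
})

test_that("pathway scores are deterministic and sign-equivariant", {
  set.seed(33)
  ecs <- sprintf("2.7.1.%d", 1:20)
  fc <- rnorm(20)
  efc <- fake_ecfc(ecs, fc)
  pw <- pathway_map(
    c("P1", "P2", "P3"), c("a", "b", "c"),
    list(ecs[1:6], ecs[7:13], ecs[c(1, 5, 14:20)])
  )
  kept <- filter_pathways(pw, efc)
  s1 <- pathway_z(kept, efc, n_sets = 200, seed = 99)
  s2 <- pathway_z(kept, efc, n_sets = 200, seed = 99)
  expect_identical(s1, s2)

  neg <- fake_ecfc(ecs, -fc)
  s3 <- pathway_z(filter_pathways(pw, neg), neg, n_sets = 200, seed = 99)
  expect_equal(s3$z, -s1$z, tolerance = 1e-12)
  expect_equal(classify_pathways(s3)$up, classify_pathways(s1)$down)
  expect_equal(classify_pathways(s3)$down, classify_pathways(s1)$up)
})

test_that("classification follows p < alpha and the sign of Z", {
  sc <- tibble::tibble(
    pathway_id = c("up1", "down1", "weak"),
    z = c(2.1, -3.2, 1.0),
    p = c(0.03, 0.001, 0.3)
  )
  cls <- classify_pathways(sc, alpha = 0.05)
  expect_equal(cls$up, "up1")
  expect_equal(cls$down, "down1")
})

test_that("the spiked pathway from the simulator is flagged up", {
  sim <- simulate_counts(n_genes = 1500, library_size = 3e5, de_log2fc = 3, seed = 7)
  ann <- simulate_annotations(sim$counts, sim$truth, seed = 8)
  qn <- quantile_normalize(rpkm(sim$counts))
  efc <- ec_fold_changes(qn, ann$annotation, "OE1", "WT")
  kept <- filter_pathways(ann$pathways, efc)
  sc <- pathway_z(kept, efc, n_sets = 1000, seed = 9)
  spiked <- sc[sc$pathway_id == ann$truth$spiked_pathway, ]
  expect_gt(spiked$z, 0)
  expect_lt(spiked$p, 0.05)
  expect_equal(spiked$direction, "up")
})
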