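# Family aggregation, relative abundance, Bray-Curtis, PCoA and PERMANOVA.

test_that("rank aggregation sums related ASVs and conserves sample totals", {
  ct <- tiny_count_table()
  fam <- aggregate_to_rank(ct, "family")
  expect_identical(sort(colnames(fam$counts)), c("FamA", "FamB"))
  # s1 counts (3, 4, 0, 5): FamA = 3 + 4, FamB = 0 + 5
  expect_identical(unname(fam$counts["s1", c("FamA", "FamB")]), c(7, 5))
  expect_equal(rowSums(fam$counts), rowSums(ct$counts))
  expect_error(aggregate_to_rank(ct, "genus"), "not present")
})

test_that("aggregation conserves totals on random tables at every rank", {
  set.seed(31)
  for (rep in 1:5) {
    n_asv <- sample(5:20, 1)
    counts <- matrix(rpois(6 * n_asv, 8), nrow = 6,
                     dimnames = list(paste0("s", 1:6), paste0("a", 1:n_asv)))
    taxonomy <- data.frame(asv_id = paste0("a", 1:n_asv),
                           domain = "D",
                           phylum = sample(c("P1", "P2"), n_asv, TRUE),
                           class = "C", order = "O",
                           family = sample(c("F1", "F2", "F3"), n_asv, TRUE))
    meta <- data.frame(sample_id = paste0("s", 1:6), bay = "control",
                       season = "summer", depth_cm = 1, site = "x")
    ct <- count_table(counts, taxonomy, meta)
    for (rank in c("phylum", "family"))
      expect_equal(rowSums(aggregate_to_rank(ct, rank)$counts), rowSums(counts))
  }
})

test_that("relative abundance normalises per sample and pools beyond top_k", {
  ct <- tiny_count_table()
  fam <- aggregate_to_rank(ct, "family")
  ra <- relative_abundance(fam)
  expect_equal(unname(rowSums(ra)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(ra["s1", c("FamA", "FamB")]), c(7, 5) / 12)
  # counts (3, 1) normalise to (0.75, 0.25)
  m <- matrix(c(3, 1), 1, dimnames = list("s", c("a1", "a2")))
  ct2 <- count_table(m, data.frame(asv_id = c("a1", "a2"), family = c("X", "Y")),
                     data.frame(sample_id = "s"))
  expect_equal(unname(relative_abundance(ct2)["s", ]), c(0.75, 0.25))
  # pooling keeps per-sample sums at 1 and labels the remainder
  set.seed(4)
  big <- matrix(rpois(4 * 20, 6), 4,
                dimnames = list(paste0("s", 1:4), paste0("f", sprintf("%02d", 1:20))))
  ct3 <- count_table(big, data.frame(asv_id = colnames(big),
                                     family = colnames(big)),
                     data.frame(sample_id = rownames(big)))
  ra3 <- relative_abundance(ct3, top_k = 5)
  expect_identical(ncol(ra3), 6L)
  expect_true("Other_Families" %in% colnames(ra3))
  expect_equal(unname(rowSums(ra3)), rep(1, 4), tolerance = 1e-12)
  # zero-total samples are named in the error
  bad <- big; bad["s2", ] <- 0
  ct4 <- count_table(bad, data.frame(asv_id = colnames(bad), family = colnames(bad)),
                     data.frame(sample_id = rownames(bad)))
  expect_error(relative_abundance(ct4), "s2")
})

test_that("top_k selection breaks mean-abundance ties lexicographically", {
  m <- matrix(c(5, 5, 2), 1, dimnames = list("s", c("zeta", "alpha", "mid")))
  ct <- count_table(m, data.frame(asv_id = colnames(m), family = colnames(m)),
                    data.frame(sample_id = "s"))
  ra <- relative_abundance(ct, top_k = 1)
  expect_identical(colnames(ra)[1], "alpha")
})

test_that("Bray-Curtis matches hand arithmetic and its defining bounds", {
  m <- rbind(x = c(2, 1, 0), y = c(1, 1, 1), z = c(2, 1, 0),
             w = c(0, 0, 5))
  colnames(m) <- paste0("t", 1:3)
  d <- as.matrix(bray_curtis(m, relative = FALSE))
  expect_equal(d["x", "y"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["x", "z"], 0)          # identical samples
  expect_equal(d["x", "w"], 1)          # disjoint support
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("relative-abundance Bray-Curtis ignores proportional rescaling", {
  set.seed(12)
  m <- matrix(rpois(5 * 8, 10) + 1, 5,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
  m2 <- m * c(1, 10, 3, 7, 2)  # wildly different library sizes, same profile
  expect_equal(as.matrix(bray_curtis(m)), as.matrix(bray_curtis(m2)),
               tolerance = 1e-12)
})

test_that("Bray-Curtis agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  m <- matrix(rpois(8 * 12, 5), 8,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:12)))
  m[m < 2] <- 0
  expect_equal(as.matrix(bray_curtis(m, relative = FALSE)),
               as.matrix(vegan::vegdist(m, "bray")), tolerance = 1e-12)
})

test_that("PCoA embeds two points symmetrically and reproduces Euclidean input", {
  d2 <- stats::as.dist(matrix(c(0, 1, 1, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  ord <- pcoa(d2)
  expect_equal(sort(unname(ord$points[, 1])), c(-0.5, 0.5), tolerance = 1e-12)
  set.seed(23)
  X <- matrix(rnorm(7 * 4), 7)
  d <- stats::dist(X)
  ord2 <- pcoa(d)
  expect_lt(max(abs(stats::dist(ord2$points) - d)), 1e-9)
  # spectral identity: eigenvalues sum to the trace of the centred matrix
  expect_equal(sum(ord2$eigenvalues), ord2$trace, tolerance = 1e-9)
  expect_error(pcoa(stats::as.dist(matrix(0, 1, 1))), "at least 2")
})

test_that("PCoA coordinates match classical scaling from cmdscale", {
  set.seed(29)
  m <- matrix(rpois(6 * 10, 6), 6,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  d <- bray_curtis(m)
  ord <- pcoa(d)
  ref <- stats::cmdscale(d, k = 2, eig = TRUE)
  # axes defined up to sign
  for (k in 1:2)
    expect_equal(abs(unname(ord$points[, k])), abs(unname(ref$points[, k])),
                 tolerance = 1e-8)
  expect_equal(ord$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-8)
})

test_that("PERMANOVA partitions match vegan::adonis2 term by term", {
  skip_if_not_installed("vegan")
  set.seed(5)
  Y <- matrix(rpois(12 * 8, 20), 12,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:8)))
  meta <- data.frame(bay = rep(c("control", "heated"), each = 6),
                     depth = rep(c(1, 5, 10), 4))
  d <- bray_curtis(Y)
  ours <- permanova(d, ~ bay * depth, meta, permutations = 999, seed = 7)
  ref <- vegan::adonis2(d ~ bay * depth, data = meta, by = "terms",
                        permutations = 999)
  expect_equal(ours$sum_sq[1:3], ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(ours$pseudo_f[1:3], ref$F[1:3], tolerance = 1e-9)
  expect_equal(ours$df[1:4], ref$Df[1:4])
  # p-values agree up to independent permutation noise
  expect_lt(max(abs(ours$p_value[1:3] - ref$`Pr(>F)`[1:3])), 0.05)
})

test_that("PERMANOVA sums of squares decompose and p respects its floor", {
  set.seed(41)
  Y <- matrix(rexp(10 * 6), 10,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:6)))
  meta <- data.frame(g = rep(c("a", "b"), 5), z = rnorm(10))
  res <- permanova(bray_curtis(Y), ~ g + z, meta, permutations = 99, seed = 2)
  terms_ss <- res$sum_sq[res$term %in% c("g", "z", "Residual")]
  expect_equal(sum(terms_ss), res$sum_sq[res$term == "Total"],
               tolerance = 1e-10)
  expect_equal(sum(res$r_squared[res$term != "Total"]), 1, tolerance = 1e-10)
  expect_true(all(res$p_value >= 1 / 100, na.rm = TRUE))
  # reproducible under seed
  res2 <- permanova(bray_curtis(Y), ~ g + z, meta, permutations = 99, seed = 2)
  expect_identical(res$p_value, res2$p_value)
})

test_that("PERMANOVA rejects rank-deficient designs naming the aliased terms", {
  set.seed(43)
  Y <- matrix(rexp(8 * 5), 8,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  meta <- data.frame(g = rep(c("a", "b"), 4))
  meta$g2 <- meta$g  # perfectly aliased copy
  expect_error(permanova(bray_curtis(Y), ~ g + g2, meta, permutations = 99),
               "aliased")
})

test_that("stronger group separation raises F and lowers p", {
  set.seed(47)
  base <- matrix(rpois(10 * 6, 20), 10,
                 dimnames = list(paste0("s", 1:10), paste0("t", 1:6)))
  meta <- data.frame(g = rep(c("a", "b"), each = 5))
  shifted <- base
  shifted[meta$g == "b", 1] <- shifted[meta$g == "b", 1] + 200
  r0 <- permanova(bray_curtis(base), ~ g, meta, permutations = 199, seed = 3)
  r1 <- permanova(bray_curtis(shifted), ~ g, meta, permutations = 199, seed = 3)
  expect_gt(r1$pseudo_f[1], r0$pseudo_f[1])
  expect_lte(r1$p_value[1], r0$p_value[1])
})

test_that("PERMANOVA power against a planted bay effect grows with effect size", {
  samples <- data.frame(bay = rep(c("control", "heated"), each = 6),
                        season = "summer", depth_cm = rep(c(1, 8, 15, 22, 5, 12), 2))
  fams <- c("ANME-1", "TCS64", "UBA233", "Nitrosopumilaceae")
  power_at <- function(effect) {
    mean(vapply(1:20, function(r) {
      sc <- community_scenario(families = fams,
                               base_log_abundance = c(0, 1, 1, 0.5),
                               depth_slope = rep(0, 4),
                               bay_effect = c(effect, 0, 0, 0),
                               dirichlet_concentration = 40,
                               library_size = 2000, seed = 5000 + r)
      ct <- generate_count_table(sc, samples)
      permanova(bray_curtis(ct), ~ bay, ct$metadata,
                permutations = 99, seed = r)$p_value[1] <= 0.05
    }, logical(1)))
  }
  pow <- vapply(c(0.2, 1.0, 2.5), power_at, numeric(1))
  expect_true(all(diff(pow) >= 0))
  expect_gt(pow[3], pow[1])
})
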