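test_that("relative abundance divides by sample totals", {
  otu <- tiny_otu_table(rbind(c(2, 2), c(1, 3)))
  ra <- relative_abundance(otu)
  expect_equal(ra$OTU_1, c(0.5, 0.25))
  expect_equal(ra$OTU_2, c(0.5, 0.75))

  set.seed(8)
  big <- tiny_otu_table(matrix(rpois(200, 5) + 1, nrow = 10))
  expect_equal(unname(rowSums(relative_abundance(big)[-1])), rep(1, 10),
               tolerance = 1e-12)

  single <- tiny_otu_table(matrix(c(5L, 9L), ncol = 1))
  expect_equal(relative_abundance(single)$OTU_1, c(1, 1))
})

test_that("OTU richness counts present taxa and ignores zero columns", {
  otu <- tiny_otu_table(rbind(c(3, 0, 1), c(2, 5, 0)))
  expect_equal(otu_richness(otu)$richness, c(2L, 2L))

  with_zero <- tiny_otu_table(cbind(rbind(c(3, 0, 1), c(2, 5, 0)), 0L))
  expect_equal(otu_richness(with_zero)$richness, c(2L, 2L))

  full <- tiny_otu_table(matrix(1L, 2, 50))
  expect_equal(otu_richness(full)$richness, c(50L, 50L))
})

test_that("richness agrees with vegan on a simulated table", {
  skip_if_not_installed("vegan")
  sim <- simulate_dataset(seed = 5)
  m <- as.matrix(sim$otu_fungi[-1])
  expect_equal(otu_richness(sim$otu_fungi)$richness,
               unname(vegan::specnumber(m)))
})

test_that("each rarity rule branch classifies its forced profile", {
  # one OTU per branch, profiles in percent across two samples:
  # AAT 2/2, ART 0.005/0.005, CRAT 0.005/2, CRT 0.005/0.5, MT 0.05/0.05,
  # CAT 0.5/2; a filler column absorbs the remainder.
  p <- rbind(
    c(AAT = 0.02, ART = 5e-5, CRAT = 5e-5, CRT = 5e-5, MT = 5e-4, CAT = 0.005),
    c(AAT = 0.02, ART = 5e-5, CRAT = 0.02, CRT = 0.005, MT = 5e-4, CAT = 0.02)
  )
  depth <- 1e6
  counts <- cbind(round(p * depth), FILL = depth - rowSums(round(p * depth)))
  otu <- tiny_otu_table(counts, otu_ids = colnames(counts))
  cls <- classify_rarity(relative_abundance(otu))
  got <- setNames(as.character(cls$per_otu$category), cls$per_otu$otu_id)
  expect_identical(got[["AAT"]], "AAT")
  expect_identical(got[["ART"]], "ART")
  expect_identical(got[["CRAT"]], "CRAT")
  expect_identical(got[["CRT"]], "CRT")
  expect_identical(got[["MT"]], "MT")
  expect_identical(got[["CAT"]], "CAT")
  expect_identical(got[["FILL"]], "AAT")
})

test_that("classification partitions OTUs and fractions sum to 100", {
  set.seed(21)
  counts <- matrix(rnbinom(20 * 1000, mu = 30, size = 0.2), nrow = 20)
  counts[, 1] <- counts[, 1] + 5000  # guarantee positive sample totals
  otu <- tiny_otu_table(counts)
  cls <- classify_rarity(relative_abundance(otu))
  expect_equal(nrow(cls$per_otu), 1000)
  expect_false(anyNA(cls$per_otu$category))
  expect_equal(sum(cls$summary$otu_fraction_pct), 100, tolerance = 1e-9)
  expect_equal(sum(cls$summary$abundance_fraction_pct), 100,
               tolerance = 1e-9)
  # agreement with the literal predicate oracle
  expect_identical(as.character(cls$per_otu$category),
                   oracle_classify(cls$per_otu$min_ra, cls$per_otu$max_ra))
})

test_that("raising the abundant threshold only moves OTUs toward rarer classes", {
  set.seed(31)
  counts <- matrix(rnbinom(10 * 500, mu = 40, size = 0.3) + 1, nrow = 10)
  ra <- relative_abundance(tiny_otu_table(counts))
  lo <- classify_rarity(ra, abundant_threshold = 0.01)
  hi <- classify_rarity(ra, abundant_threshold = 0.05)
  abundant_side <- c("AAT", "CAT", "CRAT")
  was <- as.character(lo$per_otu$category)
  now <- as.character(hi$per_otu$category)
  left_abundant <- was %in% abundant_side & !(now %in% abundant_side)
  entered_abundant <- !(was %in% abundant_side) & now %in% abundant_side
  expect_false(any(entered_abundant))
  expect_true(all(now[left_abundant] %in% c("MT", "CRT", "ART")))
})

test_that("classification is invariant to per-sample count scaling", {
  set.seed(41)
  counts <- matrix(rpois(5 * 200, 10) + 1, nrow = 5)
  otu1 <- tiny_otu_table(counts)
  scaled <- counts
  scaled[2, ] <- scaled[2, ] * 13L
  otu2 <- tiny_otu_table(scaled)
  c1 <- classify_rarity(relative_abundance(otu1))
  c2 <- classify_rarity(relative_abundance(otu2))
  expect_identical(as.character(c1$per_otu$category),
                   as.character(c2$per_otu$category))
})

test_that("rarity thresholds must be ordered", {
  ra <- relative_abundance(tiny_otu_table(matrix(1L, 2, 4)))
  expect_error(classify_rarity(ra, abundant_threshold = 1e-4,
                               rare_threshold = 0.01),
               "rare_threshold < abundant_threshold")
})

test_that("guild aggregation sums to one and handles unknown map entries", {
  otu <- tiny_otu_table(rbind(c(60, 40), c(30, 70)),
                        otu_ids = c("OTU_1", "OTU_2"))
  gm <- tibble::tibble(otu_id = c("OTU_1", "OTU_2"),
                       guild = c("saprotroph", "pathotroph"))
  g <- guild_relative_abundance(otu, gm)
  g1 <- g[g$sample_id == "s1", ]
  expect_equal(g1$rel_abundance[g1$guild == "saprotroph"], 0.6)
  expect_equal(g1$rel_abundance[g1$guild == "pathotroph"], 0.4)
  totals <- tapply(g$rel_abundance, g$sample_id, sum)
  expect_equal(as.vector(totals), c(1, 1))

  # unmapped OTUs -> unassigned
  g2 <- guild_relative_abundance(otu, gm[1, ])
  s1 <- g2[g2$sample_id == "s1", ]
  expect_equal(s1$rel_abundance[s1$guild == "unassigned"], 0.4)

  # map entry for an absent OTU: warning, identical output
  gm3 <- dplyr::bind_rows(gm, tibble::tibble(otu_id = "OTU_999",
                                             guild = "symbiotroph"))
  expect_warning(g3 <- guild_relative_abundance(otu, gm3), "OTU_999")
  expect_equal(g3$rel_abundance, g$rel_abundance)
})
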