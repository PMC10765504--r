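test_that("prevalence filter applies the strict less-than-four rule", {
  m <- toy_counts(cbind(
    a = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),   # 3 of 10 samples
    b = c(2, 5, 1, 9, 0, 0, 0, 0, 0, 0),   # exactly 4
    c = rep(0, 10),                          # absent
    d = rep(1, 10)))
  out <- filter_low_prevalence(m, min_samples = 4)
  expect_setequal(colnames(out), c("b", "d"))
})

test_that("rarefaction hits the exact depth, drops shallow samples, and is seeded", {
  set.seed(1)
  m <- toy_counts(rbind(rmultinom(1, 12000, rep(1, 20))[, 1],
                        rmultinom(1, 9000, rep(1, 20))[, 1],
                        rmultinom(1, 30000, rep(1, 20))[, 1]))
  expect_message(r1 <- rarefy_counts(m, depth = 10000, seed = 5), "dropping 1")
  expect_equal(unname(rowSums(r1)), c(10000, 10000))
  expect_false("s2" %in% rownames(r1))
  r2 <- suppressMessages(rarefy_counts(m, depth = 10000, seed = 5))
  expect_identical(r1, r2)
  r3 <- suppressMessages(rarefy_counts(m, depth = 10000, seed = 6))
  expect_false(identical(r1, r3))
  # never increases any count
  expect_true(all(r1 <= m[rownames(r1), ]))
  expect_error(rarefy_counts(m, depth = 0), ">= 1")
})

test_that("rarefaction preserves expected proportions", {
  m <- toy_counts(matrix(c(10000, 6000, 4000), 1))
  p_in <- c(0.5, 0.3, 0.2)
  draws <- sapply(1:200, function(s)
    rarefy_counts(m, depth = 10000, seed = s)[1, ] / 10000)
  means <- rowMeans(draws)
  se <- apply(draws, 1, stats::sd) / sqrt(200)
  expect_true(all(abs(means - p_in) <= 2 * se + 1e-12))
})

test_that("diversity indices match closed forms and a brute-force oracle", {
  uniform <- toy_counts(matrix(25, 1, 4))
  d <- diversity_indices(uniform)
  expect_equal(d$shannon, log(4))
  expect_equal(d$simpson, 0.75)

  single <- toy_counts(matrix(c(100, 0, 0), 1))
  d1 <- diversity_indices(single)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$simpson, 0)

  v <- c(13, 2, 41, 0, 7, 99)
  dv <- diversity_indices(toy_counts(matrix(v, 1)))
  p <- v[v > 0] / sum(v)
  expect_equal(dv$shannon, -sum(p * log(p)))
  expect_equal(dv$simpson, 1 - sum(p^2))

  # uniform composition maximizes both
  set.seed(2)
  rnd <- diversity_indices(toy_counts(matrix(sample(1:50, 4), 1)))
  expect_lte(rnd$shannon, d$shannon)
  expect_lte(rnd$simpson, d$simpson)
})

test_that("taxonomic aggregation pools rare groups and normalizes per sample", {
  counts <- toy_counts(rbind(c(60, 40, 0), c(30, 69, 1)),
                       asvs = c("a1", "a2", "a3"))
  tax <- tibble::tibble(
    asv = c("a1", "a2", "a3"),
    lineage = c("Bacteria;p;c;o;F1;g", "Bacteria;p;c;o;F2;g",
                "Bacteria;p;c;o;F3;g"))
  agg <- aggregate_taxa(counts, tax, rank = "family", other_threshold = 0.01)
  s1 <- dplyr::filter(agg, sample_id == "s1")
  expect_equal(s1$fraction[s1$group == "F1"], 0.6)
  expect_equal(s1$fraction[s1$group == "F2"], 0.4)
  # F3 is 0.5% of the experiment-wide total -> pooled
  expect_true("other" %in% agg$group)
  expect_false("F3" %in% agg$group)
  sums <- tapply(agg$fraction, agg$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(aggregate_taxa(counts, tax, rank = "species"), "one of")
})

test_that("per-sample fractions sum to one on random tables", {
  set.seed(8)
  counts <- toy_counts(matrix(rpois(60, 30), nrow = 5))
  tax <- tibble::tibble(
    asv = colnames(counts),
    lineage = paste0("B;p;c;o;F", sample(1:4, 12, TRUE), ";g"))
  agg <- aggregate_taxa(counts, tax, other_threshold = 0.05)
  sums <- tapply(agg$fraction, agg$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("copy-number adjustment reproduces the 75% -> 25% worked example", {
  fr <- tibble::tibble(taxon = c("Chlorobiales", "rest"),
                       fraction_pct = c(75, 25))
  cm <- tibble::tibble(taxon = "Chlorobiales", copies = 3)
  adj <- copy_number_adjust(fr, cm, renormalize = FALSE)
  expect_equal(adj$adjusted_pct[adj$taxon == "Chlorobiales"], 25)
  expect_equal(adj$adjusted_pct[adj$taxon == "rest"], 25)

  # renormalized variant rescales to 100: 25 / (25 + 25) = 50%
  adj2 <- copy_number_adjust(fr, cm, renormalize = TRUE)
  expect_equal(adj2$adjusted_pct[adj2$taxon == "Chlorobiales"], 50)
  expect_equal(sum(adj2$adjusted_pct), 100)

  # all-ones copy map is the identity
  id <- copy_number_adjust(fr, tibble::tibble(taxon = "x", copies = 1))
  expect_equal(id$adjusted_pct, id$fraction_pct)
  expect_error(copy_number_adjust(fr, tibble::tibble(taxon = "a", copies = 0.5)),
               ">= 1")
})
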