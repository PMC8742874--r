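# Nearest-distance statistics and the uniform-in-exons placement null.

test_that("nearest_distance follows the half-open gap convention", {
  a <- make_hit("chr1", 100, 106)
  b <- make_hit("chr1", 200, 206)
  expect_equal(nearest_distance(a, b)$distance, 94)
  # overlap and book-ended are distance 0
  expect_equal(nearest_distance(a, make_hit("chr1", 103, 109))$distance, 0)
  expect_equal(nearest_distance(a, make_hit("chr1", 106, 112))$distance, 0)
  # no B on the A sequence: dropped and counted
  d <- nearest_distance(make_hit("chr1", 0, 6), make_hit("chr2", 0, 6))
  expect_equal(nrow(d), 0L)
  expect_equal(attr(d, "n_dropped"), 1L)
})

test_that("the gap is symmetric in its arguments", {
  withr::with_seed(71, {
    for (i in 1:50) {
      s1 <- sample(0:500, 1); s2 <- sample(0:500, 1)
      x <- make_hit("c", s1, s1 + sample(1:20, 1))
      y <- make_hit("c", s2, s2 + sample(1:20, 1))
      expect_equal(nearest_distance(x, y)$distance,
                   nearest_distance(y, x)$distance)
    }
  })
})

test_that("nearest_distance equals the all-pairs brute force", {
  withr::with_seed(72, {
    for (rep in 1:30) {
      n_a <- sample(1:80, 1); n_b <- sample(1:80, 1)
      chrs <- c("c1", "c2")
      a <- make_hit(sample(chrs, n_a, TRUE),
                    s <- sample(0:5000, n_a, TRUE), s + 6)
      b <- make_hit(sample(chrs, n_b, TRUE),
                    s2 <- sample(0:5000, n_b, TRUE), s2 + 6)
      got <- nearest_distance(a, b)
      want <- oracle_nearest(a, b)
      expect_equal(got$distance, want[!is.na(want)])
      expect_equal(attr(got, "n_dropped"), sum(is.na(want)))
    }
  })
})

one_exon_annotation <- function(L) {
  gene_annotation(
    tibble::tibble(gene_id = "g1", seq_id = "chr1", start = 0L, end = L,
                   strand = "+"),
    tibble::tibble(transcript_id = "t1", gene_id = "g1", seq_id = "chr1",
                   start = 0L, end = L, strand = "+"),
    tibble::tibble(transcript_id = "t1", gene_id = "g1", seq_id = "chr1",
                   start = 0L, end = L, strand = "+", type = "exon"))
}

test_that("single-exon null matches the enumerated uniform expectation", {
  # one A interval in the middle of one exon, one B placed uniformly: the
  # exact expected distance is the average of the gap over every possible
  # B start (enumeration oracle, computed here)
  L <- 2000L; LB <- 6L
  ann <- one_exon_annotation(L)
  a <- make_hit("chr1", 997, 1003)
  starts <- 0:(L - LB)
  exact <- mean(pmax(0, pmax(starts - a$end, a$start - (starts + LB))))
  n_sims <- 400
  nl <- simulate_null(ann, a, n_b = 1, motif_len_b = LB, n_sims = n_sims,
                      seed = 5)
  mc_mean <- mean(nl$distances$distance)
  mc_se <- stats::sd(nl$distances$distance) / sqrt(n_sims)
  expect_lt(abs(mc_mean - exact), 3 * mc_se)
})

test_that("the null is bit-reproducible under a fixed seed", {
  ann <- one_exon_annotation(5000L)
  a <- make_hit("chr1", c(100, 2000), c(106, 2006))
  n1 <- simulate_null(ann, a, n_b = 10, motif_len_b = 6, n_sims = 5, seed = 9)
  n2 <- simulate_null(ann, a, n_b = 10, motif_len_b = 6, n_sims = 5, seed = 9)
  expect_identical(n1$distances, n2$distances)
  expect_identical(n1$medians, n2$medians)
})

test_that("simulated intervals always fit inside exons", {
  # a single exon [1000, 1200) and A at [0, 6): containment of every
  # simulated B start in [1000, 1194] forces every distance into
  # [994, 1188]
  ann <- gene_annotation(
    tibble::tibble(gene_id = "g1", seq_id = "chr1", start = 0L, end = 1200L,
                   strand = "+"),
    tibble::tibble(transcript_id = "t1", gene_id = "g1", seq_id = "chr1",
                   start = 0L, end = 1200L, strand = "+"),
    tibble::tibble(transcript_id = "t1", gene_id = "g1", seq_id = "chr1",
                   start = 1000L, end = 1200L, strand = "+", type = "exon"))
  a <- make_hit("chr1", 0, 6)
  nl <- simulate_null(ann, a, n_b = 1, motif_len_b = 6, n_sims = 200,
                      seed = 4)
  expect_true(all(nl$distances$distance >= 994))
  expect_true(all(nl$distances$distance <= 1188))
  # a motif longer than every exon is an error
  expect_error(simulate_null(ann, a, n_b = 1, motif_len_b = 500, n_sims = 1),
               "exon")
})

test_that("compare_to_null reports medians, empirical p and densities", {
  ann <- one_exon_annotation(20000L)
  withr::with_seed(74, {
    s <- sort(sample(0:19900, 40))
    a <- make_hit("chr1", s, s + 6)
    # observed B placed adjacent to every A: observed median 0
    b <- make_hit("chr1", s + 7, s + 13)
    obs <- nearest_distance(a, b)
    expect_equal(median(obs$distance), 1)
    nl <- simulate_null(ann, a, n_b = nrow(b), motif_len_b = 6,
                        n_sims = 50, seed = 2)
    cmp <- compare_to_null(obs, nl)
    expect_lt(cmp$empirical_p, 1 / 50 + 1e-12)
    expect_match(cmp$p_label, "<")
    expect_gt(cmp$null_median_mean, 20)
    expect_setequal(unique(cmp$density$group), c("observed", "null"))
    expect_s3_class(autoplot(cmp), "ggplot")
  })
})

test_that("compare_to_null refuses mismatched A sets", {
  ann <- one_exon_annotation(5000L)
  a <- make_hit("chr1", c(10, 100), c(16, 106))
  obs <- nearest_distance(a, make_hit("chr1", 300, 306))
  nl <- simulate_null(ann, a[1, ], n_b = 5, motif_len_b = 6, n_sims = 3,
                      seed = 1)
  expect_error(compare_to_null(obs, nl), "mismatch")
})

test_that("an observed draw from the null law has a non-extreme percentile", {
  ann <- one_exon_annotation(30000L)
  withr::with_seed(75, {
    s <- sample(0:29900, 50)
    a <- make_hit("chr1", s, s + 6)
    obs_b <- simulate_null(ann, a, n_b = 50, motif_len_b = 6, n_sims = 1)
    obs <- structure(
      dplyr::mutate(a, distance = obs_b$distances$distance),
      n_dropped = 0L, n_a_total = nrow(a), scope = "genome_wide",
      class = c("distance_set", class(a)))
    nl <- simulate_null(ann, a, n_b = 50, motif_len_b = 6, n_sims = 50)
    cmp <- compare_to_null(obs, nl)
    expect_gte(cmp$empirical_p, 0)
    expect_lte(cmp$empirical_p, 1)
  })
})
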