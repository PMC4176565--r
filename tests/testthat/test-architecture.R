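# Oriented window extraction, aggregates, k-means classes and timing
# composition.

test_that("window extraction is anchored at the ACS midpoint and oriented", {
  ramp <- coverage_track(list(chr1 = as.numeric(1:3000)), TRUE)
  plus_org <- one_origin(acs_start = 1495L, acs_end = 1506L, strand = "+")
  w <- extract_origin_window(ramp, plus_org, halfwidth = 100L)
  expect_length(w, 201L)
  expect_true(all(diff(w) > 0))
  expect_equal(w[101], 1501)                    # value at the ACS midpoint

  minus_org <- one_origin(acs_start = 1495L, acs_end = 1506L, strand = "-")
  w2 <- extract_origin_window(ramp, minus_org, halfwidth = 100L)
  expect_equal(w2, rev(w))

  near_end <- one_origin(acs_start = 295L, acs_end = 306L)
  expect_warning(w3 <- extract_origin_window(ramp, near_end, halfwidth = 600L),
                 "excluded")
  expect_null(w3)
})

test_that("orientation invariance: reverse-complementing the genome flips nothing", {
  sim <- fx_sim()
  prof <- fx_cov_g1()
  m <- origin_profile_matrix(prof, sim$origins, halfwidth = 300L)
  # mirrored genome: reverse every chromosome and flip strands/coordinates
  lens <- chrom_lengths(sim$genome)
  prof_r <- coverage_track(lapply(prof$values, rev), TRUE)
  org_r <- sim$origins
  org_r$acs_start <- lens[org_r$chrom] - sim$origins$acs_end
  org_r$acs_end <- lens[org_r$chrom] - sim$origins$acs_start
  org_r$acs_strand <- ifelse(sim$origins$acs_strand == "+", "-", "+")
  m_r <- origin_profile_matrix(prof_r, org_r, halfwidth = 300L)
  common <- intersect(rownames(m), rownames(m_r))
  expect_gt(length(common), 0)
  expect_equal(m_r[common, ], m[common, ])
})

test_that("aggregate_profile is an exact column mean", {
  m <- rbind(a = rep(0, 11), b = rep(2, 11))
  colnames(m) <- as.character(-5:5)
  expect_equal(unname(aggregate_profile(m)), rep(1, 11))
  expect_equal(aggregate_profile(m, "a"), m["a", ])
  set.seed(13)
  r <- matrix(rnorm(60), nrow = 6,
              dimnames = list(paste0("o", 1:6), as.character(-4:5)))
  expect_equal(aggregate_profile(r), apply(r, 2, sum) / 6, tolerance = 1e-12)
  expect_error(aggregate_profile(r, character(0)), "empty")
})

test_that("two planted templates with small noise are perfectly separated", {
  set.seed(17)
  t1 <- sin(seq(0, 6 * pi, length.out = 101))
  t2 <- cos(seq(0, 6 * pi, length.out = 101)) + 2
  m <- rbind(t(replicate(20, t1 + rnorm(101, 0, 0.05))),
             t(replicate(20, t2 + rnorm(101, 0, 0.05))))
  rownames(m) <- paste0("o", 1:40)
  colnames(m) <- as.character(-50:50)
  truth <- rep(1:2, each = 20)
  widths <- stats::setNames(c(rep(190, 20), rep(130, 20)), rownames(m))
  cl <- cluster_origin_profiles(m, widths, k = 2, restarts = 5, seed = 3)
  ari <- mclust::adjustedRandIndex(cl$assignment$class_id, truth)
  expect_equal(ari, 1.0)
  expect_equal(cl$class_mean_ndr_width, c(190, 130))  # ordered by width
})

test_that("identical rows collapse to one populated class with a warning", {
  m <- matrix(1, nrow = 8, ncol = 21,
              dimnames = list(paste0("o", 1:8), as.character(-10:10)))
  w <- stats::setNames(rep(150, 8), rownames(m))
  expect_warning(cl <- cluster_origin_profiles(m, w, k = 2, seed = 1),
                 "collapsing")
  expect_equal(cl$k, 1L)
  expect_error(cluster_origin_profiles(m[1:3, ], w[1:3], k = 5, seed = 1),
               "fewer origin rows")
})

test_that("clustering is deterministic for a fixed seed", {
  set.seed(2)
  m <- matrix(rnorm(50 * 41), nrow = 50,
              dimnames = list(paste0("o", 1:50), as.character(-20:20)))
  w <- stats::setNames(runif(50, 100, 200), rownames(m))
  a <- cluster_origin_profiles(m, w, k = 4, restarts = 6, seed = 11)
  b <- cluster_origin_profiles(m, w, k = 4, restarts = 6, seed = 11)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$centroids, b$centroids)
})

test_that("timing composition fractions sum to one per group", {
  asg <- tibble::tibble(name = paste0("o", 1:10),
                        class_id = c(1, 1, 1, 2, 2, 1, 2, 2, 2, 2))
  org <- tibble::tibble(name = paste0("o", 1:10),
                        timing = rep(c("early", "late"), each = 5))
  comp <- class_timing_composition(asg, org)
  sums <- tapply(comp$fraction, comp$timing, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  # all-early-in-class-1 degenerate case
  asg2 <- tibble::tibble(name = paste0("o", 1:4), class_id = rep(1L, 4))
  org2 <- tibble::tibble(name = paste0("o", 1:4), timing = rep("early", 4))
  comp2 <- class_timing_composition(asg2, org2)
  expect_equal(comp2$fraction[comp2$class_id == 1], 1)
  expect_error(class_timing_composition(
    asg2, tibble::tibble(name = paste0("o", 1:4), timing = "unknown")),
    "timing")
})

test_that("tidy and glance summarize a classification", {
  set.seed(2)
  m <- matrix(rnorm(30 * 21), nrow = 30,
              dimnames = list(paste0("o", 1:30), as.character(-10:10)))
  w <- stats::setNames(runif(30, 100, 200), rownames(m))
  cl <- cluster_origin_profiles(m, w, k = 3, seed = 5)
  td <- generics::tidy(cl)
  expect_named(td, c("name", "class_id", "class_size"))
  expect_equal(nrow(td), 30L)
  gl <- generics::glance(cl)
  expect_equal(gl$k, 3L)
  expect_equal(gl$n, 30L)
})
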