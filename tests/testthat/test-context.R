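# IGR construction, category rules, origin placement and enrichment.

mk_genes <- function(starts, ends, strands, chrom = "chr1") {
  tibble::tibble(gene_id = paste0("g", seq_along(starts)), chrom = chrom,
                 start = starts, end = ends, strand = strands)
}

test_that("category is a pure function of the flanking strands", {
  g <- mk_genes(c(0, 200, 400, 600, 800),
                c(100, 300, 500, 700, 900),
                c("+", "+", "-", "+", "-"))
  igrs <- build_igrs(g)
  expect_equal(nrow(igrs), 4L)                     # 5 genes -> 4 IGRs
  expect_equal(igrs$category,
               c("tandem",      # (+,+)
                 "convergent",  # (+,-)
                 "divergent",   # (-,+)
                 "convergent")) # (+,-)
  gg <- mk_genes(c(0, 200), c(100, 300), c("-", "-"))
  expect_equal(build_igrs(gg)$category, "tandem")  # (-,-) also tandem
})

test_that("strand-flip covariance: divergent and convergent swap", {
  set.seed(41)
  g <- mk_genes(seq(0, 3800, by = 200), seq(100, 3900, by = 200),
                sample(c("+", "-"), 20, replace = TRUE))
  a <- build_igrs(g)
  g2 <- g
  g2$strand <- ifelse(g$strand == "+", "-", "+")
  b <- build_igrs(g2)
  map <- c(tandem = "tandem", divergent = "convergent", convergent = "divergent")
  expect_equal(b$category, unname(map[a$category]))
})

test_that("overlapping genes merge and terminal gaps are excluded", {
  g <- mk_genes(c(0, 50, 300), c(100, 150, 400), c("+", "-", "+"))
  expect_message(igrs <- build_igrs(g), "merged")
  expect_equal(nrow(igrs), 1L)
  expect_equal(igrs$start, 150L)
  expect_equal(igrs$left_strand, "-")   # strand of the rightmost-reaching gene
  expect_warning(build_igrs(mk_genes(0, 100, "+")), "fewer than 2")
})

test_that("expected frequencies are the analytic 50/25/25 and sum to 1", {
  e <- expected_category_frequencies()
  expect_identical(unname(e), c(0.5, 0.25, 0.25))
  expect_identical(names(e), c("tandem", "divergent", "convergent"))
  expect_equal(sum(e), 1)
})

test_that("random-strand genomes reproduce 50/25/25 within the 99% CI", {
  set.seed(1234)
  n <- 10000L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  g <- mk_genes(seq(0, by = 200L, length.out = n),
                seq(100L, by = 200L, length.out = n), strands)
  igrs <- build_igrs(g)
  obs <- table(factor(igrs$category, c("tandem", "divergent", "convergent")))
  m <- nrow(igrs)
  for (cat in names(obs)) {
    p0 <- expected_category_frequencies()[[cat]]
    half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / m)
    expect_lt(abs(obs[[cat]] / m - p0), half + 1e-12)
  }
})

test_that("origins map to containing IGRs with half-open boundaries", {
  g <- mk_genes(c(0, 200, 500), c(100, 300, 600), c("+", "-", "+"))
  igrs <- build_igrs(g)                 # [100,200) convergent, [300,500) divergent
  org <- dplyr::bind_rows(
    one_origin(acs_start = 145L, acs_end = 156L, name = "inIGR"),
    one_origin(acs_start = 245L, acs_end = 256L, name = "inGene"),
    one_origin(acs_start = 95L, acs_end = 106L, name = "atStart"))  # mid = 100
  cats <- origin_igr_category(org, igrs)
  expect_equal(cats$category[cats$name == "inIGR"], "convergent")
  expect_equal(cats$category[cats$name == "inGene"], "intragenic")
  expect_equal(cats$category[cats$name == "atStart"], "convergent")
})

test_that("enrichment fractions sum to 1 and ratios are observed/expected", {
  cats <- tibble::tibble(name = paste0("o", 1:8),
                         category = c(rep("convergent", 6), "tandem", "intragenic"))
  enr <- category_enrichment(cats)
  expect_equal(sum(enr$observed), 1)
  conv <- enr[enr$category == "convergent", ]
  expect_equal(conv$observed, 6 / 7)
  expect_equal(conv$ratio, (6 / 7) / 0.25)
  all_conv <- tibble::tibble(name = "x", category = "convergent")
  expect_equal(category_enrichment(all_conv)$ratio[3], 4)
  expect_error(category_enrichment(tibble::tibble(name = "x", category = "intragenic")),
               "no origin")
})

test_that("uniformly placed origins over random IGRs give ratios near 1", {
  set.seed(77)
  sim <- fx_sim()
  igrs <- build_igrs(sim$genes)
  # place synthetic origins in every IGR and check the composition tracks the
  # IGR pool itself
  mids <- (igrs$start + igrs$end) %/% 2L
  org <- tibble::tibble(name = paste0("u", seq_len(nrow(igrs))),
                        chrom = igrs$chrom, acs_start = mids,
                        acs_end = mids + 11L, acs_strand = "+",
                        timing = "unknown")
  enr <- category_enrichment(origin_igr_category(org, igrs))
  pool <- as.numeric(table(factor(igrs$category,
                                  c("tandem", "divergent", "convergent")))) / nrow(igrs)
  expect_equal(enr$observed, pool, tolerance = 1e-9)
  expect_true(all(abs(enr$ratio - 1) < 0.35))
  # goodness-of-fit test runs and returns an htest
  expect_s3_class(category_gof_test(origin_igr_category(org, igrs)), "htest")
})
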