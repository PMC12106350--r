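test_that("triploid collapse keeps the two smallest distinct alleles", {
  tab <- toy_table(list(list(L1 = c(100L, 104L, 108L),
                             L2 = c(200L, 202L))), min_loci = 1L)
  out <- collapse_triploid(tab)
  expect_equal(out$individuals$genotype[[1]]$L1, c(100L, 104L))
  expect_equal(out$individuals$genotype[[1]]$L2, c(200L, 202L))
  expect_equal(attr(out, "n_discarded"), 1L)
  expect_false(out$individuals$triploid[1])

  big <- collapse_triploid(tab, rule = "largest_two")
  expect_equal(big$individuals$genotype[[1]]$L1, c(104L, 108L))

  # diploid-only record: untouched, nothing discarded
  tab2 <- toy_table(list(list(L1 = c(100L, 104L))), min_loci = 1L)
  out2 <- collapse_triploid(tab2)
  expect_equal(attr(out2, "n_discarded"), 0L)
  expect_equal(out2$individuals$genotype, tab2$individuals$genotype)

  # all eight loci triploid: eight discards reported
  g8 <- stats::setNames(lapply(1:8, function(i) {
    as.integer(c(100 * i, 100 * i + 2, 100 * i + 4))
  }), paste0("L", 1:8))
  out8 <- collapse_triploid(toy_table(list(g8)))
  expect_equal(attr(out8, "n_discarded"), 8L)
})

test_that("allele frequencies count calls over the chosen pool", {
  tab <- toy_table(list(list(L1 = c(1L, 1L)), list(L1 = c(1L, 2L))),
                   min_loci = 1L)
  f <- estimate_allele_frequencies(tab)
  expect_equal(unname(f$L1), c(0.75, 0.25))
  expect_equal(names(f$L1), c("1", "2"))

  # one worker per colony: first by id order in each colony
  gs <- list(list(L1 = c(1L, 1L)), list(L1 = c(2L, 2L)),
             list(L1 = c(3L, 3L)), list(L1 = c(4L, 4L)))
  ind <- data.frame(individual_id = c("b", "a", "d", "c"),
                    colony_id = c("c1", "c1", "c2", "c2"),
                    caste = "worker", ovary_status = "unknown",
                    stringsAsFactors = FALSE)
  ind$genotype <- gs
  tab2 <- genotype_table(ind, locus_panel("L1"), min_loci = 1L)
  f2 <- estimate_allele_frequencies(tab2,
                                    pool = "one_worker_per_colony")
  expect_equal(attr(f2, "n_individuals"), 2L)
  # ids a (colony c1, allele 2) and c (colony c2, allele 4) are kept
  expect_equal(unname(f2$L1[c("2", "4")]), c(0.5, 0.5))
  expect_identical(f2, estimate_allele_frequencies(
    tab2, pool = "one_worker_per_colony"))
  expect_error(estimate_allele_frequencies(
    toy_table(list(list(L1 = c(1L, 1L))), min_loci = 1L),
    pool = "queens_only"), "empty")
})

test_that("an identical heterozygous pair at equifrequent alleles has r = 1", {
  f <- list(L1 = stats::setNames(rep(0.25, 4),
                                 c("100", "102", "104", "106")))
  x <- list(L1 = c(100L, 102L))
  expect_equal(qg_relatedness(x, x, f), 1)
})

test_that("relatedness is symmetric and matches the direct oracle", {
  set.seed(314)
  freqs <- lapply(stats::setNames(1:8, paste0("L", 1:8)), function(i) {
    g <- stats::rgamma(6, 1)
    stats::setNames(g / sum(g), as.character(100 * i + 2 * (0:5)))
  })
  for (i in 1:80) {
    x <- rand_genos(freqs, 1)[[1]]
    y <- rand_genos(freqs, 1)[[1]]
    if (i %% 3 == 0) x[sample(names(x), 2)] <- NULL  # missing loci
    r_xy <- qg_relatedness(x, y, freqs)
    expect_identical(r_xy, qg_relatedness(y, x, freqs))
    expect_equal(r_xy, qg_oracle(x, y, freqs), tolerance = 1e-12)
  }
})

test_that("an all-modal-homozygote comparison is undefined, not zero", {
  f <- list(L1 = c("100" = 1))
  x <- list(L1 = c(100L, 100L))
  expect_true(is.na(qg_relatedness(x, x, f)))
})

test_that("group means hit the pedigree anchors", {
  cfg <- sim_config(seed = 1)
  set.seed(1)
  freqs <- sample_allele_frequencies(cfg)
  panel <- locus_panel(names(freqs),
                       lapply(freqs, function(p) as.integer(names(p))))
  for (case in list(list(rel = "full_sisters", want = 0.75),
                    list(rel = "mother_daughter", want = 0.5),
                    list(rel = "unrelated", want = 0))) {
    prs <- simulate_related_pairs(freqs, 1500, case$rel)
    # frequencies from the analyzed sample itself, as field studies do
    fh <- estimate_allele_frequencies(
      toy_table(unlist(prs, recursive = FALSE), min_loci = 1L,
                panel = panel))
    est <- qg_mean_relatedness(prs, fh)
    expect_lt(abs(est$r - case$want), 4 * est$se + 0.01)
  }
})

test_that("queen pair tables enumerate within-colony pairs by category", {
  g <- function(a) list(L1 = c(a, a))
  q <- data.frame(colony_id = c("c1", "c1", "c1", "c2"),
                  queen_id = c("q1", "q2", "q3", "q4"),
                  type = c("1", "2a", "3", "3"),
                  virtual = c(TRUE, FALSE, FALSE, FALSE),
                  stringsAsFactors = FALSE)
  q$genotype <- list(g(2L), g(4L), g(6L), g(8L))
  f <- list(L1 = stats::setNames(rep(0.25, 4),
                                 c("2", "4", "6", "8")))
  pairs <- pairwise_queen_relatedness(q, f)
  expect_equal(nrow(pairs), 3L)  # c2 has a single queen: no pairs
  expect_setequal(pairs$category, c("1-2", "1-3", "2-3"))
  # order inside the label is canonical
  p2 <- q
  p2$type <- c("3", "2a", "1", "3")
  pairs2 <- pairwise_queen_relatedness(p2, f)
  expect_setequal(pairs2$category, c("1-2", "1-3", "2-3"))
  # 2a/2b split is preserved on request
  pairs3 <- pairwise_queen_relatedness(q, f, split_2a2b = TRUE)
  expect_setequal(pairs3$category, c("1-2a", "1-3", "2a-3"))
})

test_that("mixed sister/stranger pools give a two-mode r distribution", {
  cfg <- sim_config(seed = 2)
  set.seed(2)
  freqs <- sample_allele_frequencies(cfg)
  sis <- simulate_related_pairs(freqs, 120, "full_sisters")
  str <- simulate_related_pairs(freqs, 120, "unrelated")
  r <- vapply(c(sis, str), function(p) {
    qg_relatedness(p[[1]], p[[2]], freqs)
  }, numeric(1))
  lo <- mean(r < 0.25)
  hi <- mean(r > 0.5)
  mid <- mean(r >= 0.25 & r <= 0.5)
  expect_gt(lo, 0.25)
  expect_gt(hi, 0.25)
  expect_lt(mid, lo)
  expect_lt(mid, hi)
})
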