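test_that("a header-only CSV yields an empty table and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("colony,individual,caste,ovary_status,locus,allele1,allele2",
             f)
  tab <- read_genotype_table(f)
  expect_s3_class(tab, "genotype_table")
  expect_equal(nrow(tab$individuals), 0L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(tab, out)
  tab2 <- read_genotype_table(out)
  expect_equal(nrow(tab2$individuals), 0L)
})

test_that("toy and simulated tables round-trip exactly through CSV", {
  g1 <- list(L1 = c(100L, 104L), L2 = c(200L, 200L))
  g2 <- list(L1 = c(100L, 100L))  # L2 missing entirely
  tab <- toy_table(list(g1, g2), caste = c("worker", "queen"),
                   ovary = c("unknown", "developed"), min_loci = 1L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(tab, f)
  tab2 <- read_genotype_table(f, min_loci = 1L)
  expect_equal(tab2$individuals$individual_id,
               tab$individuals$individual_id)
  expect_equal(tab2$individuals$genotype, tab$individuals$genotype)
  expect_equal(tab2$individuals$caste, tab$individuals$caste)

  # property: simulator output round-trips, missingness and all
  for (seed in 1:3) {
    ds <- generate_dataset(sim_config(n_colonies = 2, seed = seed,
                                      prob_triploid_brood = 0.5))
    ff <- withr::local_tempfile(fileext = ".csv")
    write_genotype_table(ds$table, ff)
    back <- read_genotype_table(ff)
    expect_equal(back$individuals$genotype,
                 ds$table$individuals$genotype)
    expect_equal(back$individuals$mito_haplotype,
                 ds$table$individuals$mito_haplotype)
    expect_equal(back$individuals$triploid,
                 ds$table$individuals$triploid)
  }
})

test_that("three allele calls at one locus flag the individual triploid", {
  g <- list(L1 = c(100L, 104L, 108L), L2 = c(200L, 202L))
  tab <- toy_table(list(g), min_loci = 1L)
  expect_true(tab$individuals$triploid[1])
  tab2 <- toy_table(list(list(L1 = c(100L, 104L))), min_loci = 1L)
  expect_false(tab2$individuals$triploid[1])
})

test_that("the seven-locus completeness rule flags, not drops", {
  loci <- paste0("L", 1:8)
  full <- stats::setNames(lapply(1:8, function(i) c(10L * i, 10L * i)),
                          loci)
  sparse <- full[1:5]
  tab <- toy_table(list(full, sparse), panel = locus_panel(loci))
  expect_equal(tab$individuals$low_coverage, c(FALSE, TRUE))
  expect_equal(nrow(tab$individuals), 2L)
})

test_that("malformed input is rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("colony,individual,caste,ovary_status,locus,allele1,allele2",
               "c1,i1,worker,unknown,L1,100,104",
               "c1,i1,worker,unknown,L1,100,106"), f)
  expect_error(read_genotype_table(f), "line 3")

  writeLines(c("colony,individual,caste,ovary_status,locus,allele1,allele2",
               "c1,i1,soldier,unknown,L1,100,104"), f)
  expect_error(read_genotype_table(f), "caste")

  writeLines(c("colony,individual,caste,ovary_status,locus,allele1,allele2",
               "c1,i1,worker,sometimes,L1,100,104"), f)
  expect_error(read_genotype_table(f), "ovary_status")

  writeLines(c("colony,individual,caste,ovary_status,locus,allele1,allele2",
               "c1,i1,worker,unknown,L1,10x,104"), f)
  expect_error(read_genotype_table(f), "line 2")
})

test_that("GenePop export writes one Pop block per colony", {
  g <- list(L1 = c(100L, 104L), L2 = c(200L, 200L))
  tab <- toy_table(list(g), min_loci = 1L)
  f <- withr::local_tempfile(fileext = ".gen")
  export_genepop(tab, f)
  lines <- readLines(f)
  expect_equal(lines[2:3], c("L1", "L2"))
  expect_equal(sum(lines == "Pop"), 1L)
  gl <- lines[length(lines)]
  expect_match(gl, "100104 200200$")
})

test_that("one-worker-per-colony export emits one line per colony", {
  gs <- lapply(1:6, function(i) {
    list(L1 = sort(c(100L, 100L + 2L * i)))
  })
  ind <- data.frame(
    individual_id = paste0("i", 1:6),
    colony_id = rep(c("cA", "cB", "cC"), each = 2),
    caste = rep(c("worker", "worker", "queen"), 2),
    ovary_status = "unknown", stringsAsFactors = FALSE)
  ind$genotype <- gs
  tab <- genotype_table(ind, locus_panel("L1"), min_loci = 1L)
  f <- withr::local_tempfile(fileext = ".gen")
  export_genepop(tab, f, one_worker_per_colony = TRUE)
  lines <- readLines(f)
  geno_lines <- grep(",", lines, fixed = TRUE, value = TRUE)
  expect_equal(length(geno_lines), 3L)
})

test_that("GenePop export refuses triploid individuals", {
  tab <- toy_table(list(list(L1 = c(100L, 102L, 104L))), min_loci = 1L)
  f <- withr::local_tempfile(fileext = ".gen")
  expect_error(export_genepop(tab, f), "triploid")
  expect_silent(export_genepop(collapse_triploid(tab), f))
})
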