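test_that("per-locus parental solutions match brute-force enumeration", {
  # the two-member textbook case a/b, a/c
  par <- infer_parents(list(list(L1 = c(1L, 2L)),
                            list(L1 = c(1L, 3L))))
  expect_true(par$compatible)
  got <- apply(par$loci$L1$mother_pairs, 1, paste, collapse = "/")
  want <- brute_mother_pairs(list(c(1L, 2L), c(1L, 3L)))
  expect_setequal(sort(got), want)

  # randomized property over small allele pools and member counts
  set.seed(42)
  for (rep in 1:60) {
    k <- sample(2:4, 1)
    pairs <- lapply(seq_len(sample(2:4, 1)), function(i) {
      sort(sample.int(k, 2, replace = TRUE))
    })
    par <- infer_parents(lapply(pairs, function(p) list(L1 = p)))
    expect_equal(par$compatible, brute_locus_compatible(pairs))
    expect_equal(par$compatible,
                 verify_sibship(lapply(pairs, function(p)
                   list(L1 = p))))
    if (par$compatible) {
      got <- sort(apply(par$loci$L1$mother_pairs, 1, paste,
                        collapse = "/"))
      expect_equal(got, brute_mother_pairs(pairs))
    }
  }
})

test_that("identical homozygotes force the canonical solution", {
  par <- infer_parents(rep(list(list(L1 = c(5L, 5L))), 3))
  expect_true(par$loci$L1$unique_mother)
  expect_equal(unname(par$loci$L1$mother_pairs[1, ]), c(5, 5))
  expect_equal(unique(par$loci$L1$solutions$father), 5)
})

test_that("disjoint genotypes cannot form one sibship", {
  par <- infer_parents(list(list(L1 = c(1L, 2L)),
                            list(L1 = c(3L, 4L))))
  expect_false(par$compatible)
  expect_equal(nrow(par$loci$L1$mother_pairs), 0L)
  expect_false(verify_sibship(list(list(L1 = c(1L, 2L)),
                                   list(L1 = c(3L, 4L)))))
})

test_that("forced minimal partitions", {
  # eight simulated full sisters: minimum one sibship
  cfg <- sim_config(n_colonies = 1, prob_queen_turnover = 0,
                    prob_multiple_breeders = 0,
                    prob_unrelated_adoptee = 0, seed = 21)
  ds <- generate_dataset(cfg)
  w <- ds$table$individuals[ds$table$individuals$caste == "worker", ]
  part <- min_sibship_partition(stats::setNames(w$genotype,
                                                w$individual_id))
  expect_equal(part$min_count, 1L)
  expect_false(part$ambiguous)

  # a single offspring is trivially one sibship
  p1 <- min_sibship_partition(list(a = list(L1 = c(1L, 2L))))
  expect_equal(p1$min_count, 1L)

  # two engineered families whose fathers differ at shared loci
  e <- engineered_turnover_colony()
  ind <- e$table$individuals
  w8 <- ind[ind$caste == "worker", ]
  part2 <- min_sibship_partition(stats::setNames(w8$genotype,
                                                 w8$individual_id))
  expect_equal(part2$min_count, 2L)
  expect_length(part2$partitions, 1L)
  expect_equal(partition_key(part2$partitions[[1]]),
               partition_key(list(paste0("e1_w", 1:4),
                                  paste0("e1_w", 5:8))))
})

test_that("branch and bound equals exhaustive and unpruned enumeration", {
  set.seed(77)
  cfgs <- list(
    sim_config(n_colonies = 1, seed = 1),
    sim_config(n_colonies = 1, prob_queen_turnover = 1,
               prob_multiple_breeders = 1, seed = 2),
    sim_config(n_colonies = 1, allele_counts = c(A = 3L, B = 4L),
               seed = 3))
  for (rep in 1:25) {
    cfg <- cfgs[[sample.int(3, 1)]]
    freqs <- sample_allele_frequencies(cfg)
    sim <- simulate_colony(cfg, freqs, "t")
    genos <- sim$individuals$genotype
    names(genos) <- sim$individuals$individual_id
    n <- sample(2:7, 1)
    genos <- genos[sample(seq_along(genos), min(n, length(genos)))]
    genos <- lapply(genos, function(g) {
      g[vapply(g, length, integer(1)) <= 2L]
    })
    bb <- min_sibship_partition(genos)
    ex <- min_sibship_partition(genos, method = "exhaustive")
    expect_equal(bb$min_count, ex$min_count)
    expect_equal(partition_set_keys(bb$partitions),
                 partition_set_keys(ex$partitions))
    if (length(genos) <= 5) {
      pure <- pure_min_partitions(genos)
      expect_equal(bb$min_count, pure$min_count)
      expect_equal(partition_set_keys(bb$partitions),
                   partition_set_keys(pure$partitions))
    }
  }
})

test_that("reliability rule emits only large, uniquely solved sibships", {
  e <- engineered_turnover_colony()
  ind <- e$table$individuals
  genos <- stats::setNames(ind$genotype, ind$individual_id)
  sibs <- list(
    build_sibship(paste0("e1_w", 1:4), genos[paste0("e1_w", 1:4)]),
    build_sibship(c("e1_w5", "e1_w6"), genos[c("e1_w5", "e1_w6")]),
    build_sibship("e1_g", genos["e1_g"]))
  rel <- apply_reliability_rule(sibs)
  expect_equal(length(rel$mothers), 1L)
  expect_equal(rel$extra_queen_count, 2L)
  expect_equal(rel$mothers[[1]]$genotype, e$founder)

  # identical heterozygotes leave the mother ambiguous: not emitted
  amb <- build_sibship(paste0("x", 1:4),
                       rep(list(list(L1 = c(1L, 2L))), 4))
  expect_false(amb$unique_solution)
  rel2 <- apply_reliability_rule(list(amb))
  expect_length(rel2$mothers, 0L)
  expect_equal(rel2$extra_queen_count, 1L)
  rel3 <- apply_reliability_rule(list(amb), require_unique = FALSE)
  expect_length(rel3$mothers, 1L)
})

test_that("sibship members decompose over the inferred parents", {
  # soundness audit on simulated colonies: every reported sibship is
  # verified by the independent brute-force checker
  ds <- generate_dataset(sim_config(n_colonies = 3, seed = 31))
  freqs <- estimate_allele_frequencies(ds$table)
  recons <- reconstruct_colonies(ds$table, freqs = freqs)
  for (r in recons) {
    for (s in r$sibships) {
      ind <- subset_colony(ds$table, r$colony_id)$individuals
      genos <- stats::setNames(ind$genotype, ind$individual_id)
      genos <- lapply(genos[s$members], function(g) {
        g[vapply(g, length, integer(1)) <= 2L]
      })
      expect_true(verify_sibship(genos))
    }
  }
})

test_that("queen matching distinguishes mothers, relatives, strangers", {
  e <- engineered_turnover_colony()
  freqs <- e$freqs
  recon <- reconstruct_colony(e$table, "e1", freqs = freqs)
  qm <- recon$queen_match
  expect_equal(qm$status[qm$queen_id == "e1_B"],
               "is_a_reconstructed_mother")
  # the gyne is a daughter of the breeder: a relative, not a mother
  expect_equal(qm$status[qm$queen_id == "e1_g"], "relative_of_mother")
  expect_gt(qm$max_r[qm$queen_id == "e1_g"], 0.25)

  # a queen typed at fewer than seven loci is unresolved
  ind <- e$table$individuals
  short <- ind$genotype[[which(ind$individual_id == "e1_B")]][1:5]
  ind2 <- ind
  ind2$genotype[[which(ind2$individual_id == "e1_B")]] <- short
  tab2 <- genotype_table(ind2[, c("individual_id", "colony_id",
                                  "caste", "ovary_status",
                                  "genotype")],
                         e$table$panel)
  recon2 <- reconstruct_colony(tab2, "e1", freqs = freqs)
  expect_equal(
    recon2$queen_match$status[recon2$queen_match$queen_id == "e1_B"],
    "unresolved")
})

test_that("unrelated queens fall below the relatedness threshold", {
  set.seed(99)
  cfg <- sim_config(n_colonies = 1, prob_queen_turnover = 0,
                    prob_multiple_breeders = 0,
                    prob_unrelated_adoptee = 1,
                    queen_min = 4L, seed = 55)
  ds <- generate_dataset(cfg)
  freqs <- estimate_allele_frequencies(ds$table)
  recon <- reconstruct_colony(ds$table, colony_ids(ds$table)[1],
                              freqs = freqs)
  tr <- ds$truth[[1]]
  adoptees <- tr$pedigree$individual_id[tr$pedigree$is_adoptee]
  qm <- recon$queen_match
  adopt_status <- qm$status[qm$queen_id %in% adoptees]
  expect_true(all(adopt_status %in% c("unrelated", "unresolved")))
  expect_true(any(adopt_status == "unrelated"))
})
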