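# Independent oracles and fixture builders. Everything here is written
# as plainly as possible and never calls the package internals it is
# used to check.

# --- brute-force per-locus parental solutions -------------------------
# All (father, mother pair) combinations over the observed alleles (NA
# as the second maternal slot = an allele no member demonstrates)
# consistent with every member pair. Returns the set of concrete
# mother pairs over observed alleles, as "m1/m2" strings.
brute_mother_pairs <- function(pairs) {
  obs <- sort(unique(unlist(pairs)))
  found <- character(0)
  for (f in obs) {
    for (m1 in obs) {
      for (m2 in c(obs[obs >= m1], NA)) {
        ok <- all(vapply(pairs, function(p) {
          a <- p[1]; b <- p[2]
          (a == f && (b %in% c(m1, m2[!is.na(m2)]))) ||
            (b == f && (a %in% c(m1, m2[!is.na(m2)])))
        }, logical(1)))
        if (!ok) next
        if (is.na(m2)) {
          found <- c(found, vapply(obs, function(y) {
            paste(sort(c(m1, y)), collapse = "/")
          }, character(1)))
        } else {
          found <- c(found, paste(sort(c(m1, m2)), collapse = "/"))
        }
      }
    }
  }
  sort(unique(found))
}

brute_locus_compatible <- function(pairs) {
  length(brute_mother_pairs(pairs)) > 0L
}

# --- completely unpruned set-partition enumeration --------------------
# Every restricted-growth string is generated and each complete
# partition is tested with verify_sibship(); nothing is pruned.
pure_min_partitions <- function(genotypes) {
  n <- length(genotypes)
  ids <- names(genotypes)
  results <- list()
  counts <- integer(0)
  assign <- integer(n)
  recurse <- function(i, nb) {
    if (i > n) {
      blocks <- lapply(seq_len(nb), function(b) which(assign == b))
      ok <- all(vapply(blocks, function(ix) {
        verify_sibship(genotypes[ix])
      }, logical(1)))
      if (ok) {
        results[[length(results) + 1L]] <<- assign[seq_len(n)]
        counts[length(counts) + 1L] <<- nb
      }
      return(invisible())
    }
    for (b in seq_len(nb + 1L)) {
      assign[i] <<- b
      recurse(i + 1L, max(nb, b))
    }
    invisible()
  }
  recurse(1L, 0L)
  mn <- min(counts)
  parts <- lapply(results[counts == mn], function(a) {
    lapply(seq_len(mn), function(b) ids[a == b])
  })
  list(min_count = mn, partitions = parts)
}

# canonical string form of a partition (list of id vectors), so
# partition *sets* can be compared across methods
partition_key <- function(p) {
  paste(sort(vapply(p, function(b) paste(sort(b), collapse = ","),
                    character(1))), collapse = "|")
}

partition_set_keys <- function(ps) sort(vapply(ps, partition_key,
                                               character(1)))

# --- direct Queller-Goodnight oracle ----------------------------------
# Transcribed term by term from the published estimator: for each focal
# individual x with alleles (a, b), numerator (Pxy - px_bar) and
# denominator (Pxx - px_bar) contributions, where Pxy is the average
# fraction of x's alleles matched in y. Structured around per-allele
# match fractions rather than indicator sums, then symmetrized as a
# ratio of sums over loci and both focal choices.
qg_oracle <- function(x, y, freqs) {
  dip <- function(a) if (length(a) == 1L) c(a, a) else a
  num <- 0; den <- 0
  for (l in intersect(names(x), names(y))) {
    if (!length(x[[l]]) || !length(y[[l]])) next
    gx <- dip(x[[l]]); gy <- dip(y[[l]])
    p <- freqs[[l]]
    for (focal in 1:2) {
      fa <- if (focal == 1) gx else gy
      ot <- if (focal == 1) gy else gx
      for (al in fa) {
        share <- mean(ot == al)          # fraction matched in partner
        self <- mean(fa == al)           # fraction matched in self
        num <- num + share - p[[as.character(al)]]
        den <- den + self - p[[as.character(al)]]
      }
    }
  }
  if (abs(den) < 1e-12) return(NA_real_)
  num / den
}

# --- fixture builders -------------------------------------------------
# genotype_table from a bare list of genotypes
toy_table <- function(genotypes, caste = "worker",
                      ovary = "unknown", colony = "c1",
                      ids = NULL, panel = NULL, min_loci = 7L) {
  n <- length(genotypes)
  if (is.null(ids)) ids <- paste0(colony, "_i", seq_len(n))
  loci <- unique(unlist(lapply(genotypes, names)))
  if (is.null(panel)) panel <- locus_panel(loci)
  ind <- data.frame(individual_id = ids,
                    colony_id = rep_len(colony, n),
                    caste = rep_len(caste, n),
                    ovary_status = rep_len(ovary, n),
                    stringsAsFactors = FALSE)
  ind$genotype <- genotypes
  genotype_table(ind, panel, min_loci = min_loci)
}

# equal frequencies over a named list of allele vectors
uniform_freqs <- function(alleles_by_locus) {
  lapply(alleles_by_locus, function(a) {
    stats::setNames(rep(1 / length(a), length(a)), as.character(a))
  })
}

# an engineered two-matriline colony where every inference step is
# identifiable: heterozygous mothers, distinct fathers, both maternal
# alleles segregating. Eight loci with allele ladder 10*i + (1..6).
# Founder F (absent) mothered workers w1..w4 and the current breeder
# B; B mothered workers w5..w8 and gyne g. Collected queens: B
# (developed) and g (undeveloped).
engineered_turnover_colony <- function(colony = "e1") {
  loci <- paste0("L", 1:8)
  al <- function(i, k) as.integer(10 * i + k)
  founder <- mateF <- breeder <- mateB <- list()
  for (i in 1:8) {
    l <- loci[i]
    founder[[l]] <- c(al(i, 1), al(i, 2))   # het mother
    mateF[[l]] <- al(i, 3)                  # distinct father
    mateB[[l]] <- al(i, 4)                  # distinct father
  }
  daughter <- function(mother, mate, pick) {
    g <- list()
    for (i in 1:8) {
      l <- loci[i]
      g[[l]] <- sort(c(mother[[l]][pick[i]], mate[[l]]))
    }
    g
  }
  # alternate maternal alleles so both always segregate
  picks <- list(rep(1L, 8), rep(2L, 8), rep(c(1L, 2L), 4),
                rep(c(2L, 1L), 4))
  breeder <- daughter(founder, mateF, rep(1L, 8))
  w14 <- lapply(picks, function(p) daughter(founder, mateF, p))
  w58 <- lapply(picks, function(p) daughter(breeder, mateB, p))
  gyne <- daughter(breeder, mateB, rep(2L, 8))
  genos <- c(w14, w58, list(breeder), list(gyne))
  ids <- c(paste0(colony, "_w", 1:8), paste0(colony, "_B"),
           paste0(colony, "_g"))
  ind <- data.frame(
    individual_id = ids, colony_id = colony,
    caste = c(rep("worker", 8), "queen", "queen"),
    ovary_status = c(rep("unknown", 8), "developed", "undeveloped"),
    stringsAsFactors = FALSE)
  ind$genotype <- genos
  list(table = genotype_table(ind, locus_panel(loci)),
       founder = founder, breeder = breeder,
       mateF = mateF, mateB = mateB,
       freqs = uniform_freqs(lapply(1:8, function(i) {
         stats::setNames(sapply(1:8, function(k) al(i, k)), NULL)
       }) |> stats::setNames(loci)))
}

# random unrelated diploid genotypes over a frequency list
rand_genos <- function(freqs, n) {
  lapply(seq_len(n), function(i) {
    lapply(freqs, function(p) {
      sort(as.integer(sample(names(p), 2, replace = TRUE, prob = p)))
    })
  })
}
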