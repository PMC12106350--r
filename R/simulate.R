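#' Simulation configuration for synthetic multi-queen colonies
#'
#' Defines the generative model used by [generate_dataset()]. The
#' defaults emulate the sampling design the package's analyses assume:
#' 33 colonies holding 2-15 collected queens (median 4), 8 genotyped
#' workers per colony, and an 8-locus microsatellite panel with allele
#' counts 5, 22, 12, 4, 23, 14, 8 and 5. Queens are singly mated
#' (monandry) and inheritance is haplodiploid: daughters receive one
#' uniformly chosen maternal allele plus the paternal allele at every
#' locus. Colonies may have undergone queen turnover (the founding
#' mother is absent at sampling, her daughters breed), may contain
#' unrelated adopted queens, and rarely carry triploid brood sired by a
#' diploid male.
#'
#' @param n_colonies Number of colonies (default 33).
#' @param workers_sampled Workers genotyped per colony (default 8).
#' @param queen_min,queen_max,queen_geom_p Collected queens per colony
#'   are drawn as `queen_min + min(rgeom(1, queen_geom_p), queen_max -
#'   queen_min)`; the defaults (2, 15, 0.25) give support 2-15 with
#'   median 4.
#' @param allele_counts Named integer vector of alleles per locus;
#'   default [default_allele_counts()].
#' @param freq_law `"dirichlet"` (flat Dirichlet over the simplex, the
#'   default) or `"equal"` allele frequencies.
#' @param prob_queen_turnover Probability the founding mother is absent
#'   at sampling, replaced by breeding daughter(s).
#' @param prob_multiple_breeders Probability that more than one queen
#'   contributes to the brood.
#' @param prob_unrelated_adoptee Probability that a non-breeding queen
#'   slot is filled by an unrelated adopted queen rather than a native
#'   daughter (gyne).
#' @param prob_adoptee_developed Probability an adopted queen has
#'   developed ovaries.
#' @param prob_triploid_brood Probability a colony's brood is sired by a
#'   diploid male, yielding triploid offspring.
#' @param contribution_alpha Symmetric Dirichlet concentration for
#'   breeder contribution weights (1 = flat; large = even shares).
#' @param contribution_weights Optional fixed contribution weight
#'   vector, recycled/truncated to the number of contributors; overrides
#'   `contribution_alpha`.
#' @param min_offspring_per_breeder,max_offspring_per_breeder Optional
#'   bounds on sampled offspring per contributor, enforced by rejection.
#' @param n_mito_haplotypes Size of the mitochondrial haplotype label
#'   pool; each matriline carries one label, adoptees draw their own.
#' @param seed Integer seed used by [generate_dataset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_colonies = 33L,
                       workers_sampled = 8L,
                       queen_min = 2L, queen_max = 15L,
                       queen_geom_p = 0.25,
                       allele_counts = default_allele_counts(),
                       freq_law = c("dirichlet", "equal"),
                       prob_queen_turnover = 0.6,
                       prob_multiple_breeders = 0.35,
                       prob_unrelated_adoptee = 0.15,
                       prob_adoptee_developed = 0.05,
                       prob_triploid_brood = 0.03,
                       contribution_alpha = 1,
                       contribution_weights = NULL,
                       min_offspring_per_breeder = 0L,
                       max_offspring_per_breeder = Inf,
                       n_mito_haplotypes = 4L,
                       seed = 1L) {
  freq_law <- match.arg(freq_law)
  probs <- c(prob_queen_turnover, prob_multiple_breeders,
             prob_unrelated_adoptee, prob_adoptee_developed,
             prob_triploid_brood)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(allele_counts < 2L)) stop("allele counts must be >= 2")
  if (workers_sampled < 1L) stop("workers_sampled must be >= 1")
  if (is.null(names(allele_counts))) {
    names(allele_counts) <- paste0("L", seq_along(allele_counts))
  }
  structure(list(
    n_colonies = as.integer(n_colonies),
    workers_sampled = as.integer(workers_sampled),
    queen_min = as.integer(queen_min), queen_max = as.integer(queen_max),
    queen_geom_p = queen_geom_p,
    allele_counts = allele_counts, freq_law = freq_law,
    prob_queen_turnover = prob_queen_turnover,
    prob_multiple_breeders = prob_multiple_breeders,
    prob_unrelated_adoptee = prob_unrelated_adoptee,
    prob_adoptee_developed = prob_adoptee_developed,
    prob_triploid_brood = prob_triploid_brood,
    contribution_alpha = contribution_alpha,
    contribution_weights = contribution_weights,
    min_offspring_per_breeder = min_offspring_per_breeder,
    max_offspring_per_breeder = max_offspring_per_breeder,
    n_mito_haplotypes = as.integer(n_mito_haplotypes),
    seed = as.integer(seed)), class = "sim_config")
}

#' Sample per-locus allele frequencies
#'
#' Draws one frequency vector per locus under the configured law. Allele
#' sizes are synthetic: locus `i` uses sizes `100 * i + 2 * (0:(K-1))`,
#' mimicking a dinucleotide repeat ladder.
#'
#' @param config A [sim_config()].
#' @return Named list (one element per locus) of named numeric vectors:
#'   names are allele sizes, values frequencies summing to 1.
#' @export
sample_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", length(config$allele_counts))
  names(out) <- names(config$allele_counts)
  for (i in seq_along(config$allele_counts)) {
    k <- config$allele_counts[[i]]
    p <- switch(config$freq_law,
                dirichlet = { g <- stats::rgamma(k, 1); g / sum(g) },
                equal = rep(1 / k, k))
    names(p) <- as.character(100L * i + 2L * (seq_len(k) - 1L))
    out[[i]] <- p
  }
  out
}

# one diploid genotype drawn i.i.d. from the frequency list
sample_diploid <- function(freqs) {
  lapply(freqs, function(p) {
    sort(as.integer(sample(names(p), 2L, replace = TRUE, prob = p)))
  })
}

# one haploid genome (a father), optionally diploid (a diploid male)
sample_haploid <- function(freqs, ploidy = 1L) {
  lapply(freqs, function(p) {
    sort(as.integer(sample(names(p), ploidy, replace = TRUE, prob = p)))
  })
}

# haplodiploid daughter: one uniform maternal allele + all paternal
# alleles (two for a diploid father, giving a triploid daughter)
make_daughter <- function(mother, father) {
  loci <- names(mother)
  g <- lapply(loci, function(l) {
    m <- mother[[l]][sample.int(2L, 1L)]
    sort(c(m, father[[l]]))
  })
  names(g) <- loci
  g
}

# contribution counts over k contributors, with optional per-breeder
# bounds enforced by rejection
draw_contributions <- function(config, k, n) {
  w <- if (!is.null(config$contribution_weights)) {
    w0 <- rep_len(config$contribution_weights, k)
    w0 / sum(w0)
  } else {
    g <- stats::rgamma(k, config$contribution_alpha)
    g / sum(g)
  }
  for (try in 1:1000) {
    cnt <- as.integer(stats::rmultinom(1, n, w))
    ok <- all(cnt >= config$min_offspring_per_breeder) &&
      all(cnt <= config$max_offspring_per_breeder)
    if (ok) return(list(weights = w, counts = cnt))
  }
  stop("could not satisfy per-breeder offspring bounds")
}

#' Simulate one colony
#'
#' Generates a founding queen and her haploid mate, applies queen
#' turnover, co-breeding, adoption and triploidy according to the
#' configuration, samples workers multinomially from the contributors'
#' weights, and returns both the observable records and the full
#' ground-truth pedigree. Consumes the current RNG stream; seed
#' upstream for reproducibility.
#'
#' @param config A [sim_config()].
#' @param freqs Allele frequencies from [sample_allele_frequencies()].
#' @param colony_id Colony identifier string.
#' @return A list with `individuals` (data.frame in
#'   [genotype_table()] row format) and `truth` (pedigree, contributor
#'   genotypes, true queen types, true nest type, flags).
#' @export
simulate_colony <- function(config, freqs, colony_id = "c1") {
  stopifnot(inherits(config, "sim_config"))
  mito_pool <- paste0("H", seq_len(config$n_mito_haplotypes))
  matriline_mito <- sample(mito_pool, 1L)

  founder <- sample_diploid(freqs)
  founder_id <- paste0(colony_id, "_F")
  turnover <- stats::runif(1) < config$prob_queen_turnover
  multiple <- stats::runif(1) < config$prob_multiple_breeders
  n_extra <- if (multiple) sample.int(2L, 1L) else 0L

  # contributors: mothers whose offspring can appear in the sample
  contrib <- list(list(id = founder_id, genotype = founder,
                       mate = sample_haploid(freqs),
                       present = !turnover, generation = 0L))
  n_new <- if (turnover) 1L + n_extra else n_extra
  if (n_new > 0L) {
    for (j in seq_len(n_new)) {
      dg <- make_daughter(founder, contrib[[1]]$mate)
      contrib[[length(contrib) + 1L]] <-
        list(id = paste0(colony_id, "_B", j), genotype = dg,
             mate = sample_haploid(freqs), present = TRUE,
             generation = 1L)
    }
  }
  k <- length(contrib)

  # rare diploid-male mating: one contributor's mate becomes diploid
  triploid_brood <- stats::runif(1) < config$prob_triploid_brood
  trip_idx <- 0L
  if (triploid_brood) {
    trip_idx <- sample.int(k, 1L)
    contrib[[trip_idx]]$mate <- sample_haploid(freqs, ploidy = 2L)
  }

  cc <- draw_contributions(config, k, config$workers_sampled)

  rows <- list()
  add_row <- function(id, caste, ovary, genotype, mito, mother, father,
                      adoptee = FALSE) {
    rows[[length(rows) + 1L]] <<- list(
      individual_id = id, colony_id = colony_id, caste = caste,
      ovary_status = ovary, mito_haplotype = mito, genotype = genotype,
      mother_id = mother, father_id = father, is_adoptee = adoptee)
  }

  # sampled workers
  wi <- 0L
  offspring_of <- stats::setNames(cc$counts,
                                  vapply(contrib, `[[`, "", "id"))
  for (i in seq_len(k)) {
    for (j in seq_len(cc$counts[i])) {
      wi <- wi + 1L
      add_row(paste0(colony_id, "_w", wi), "worker", "unknown",
              make_daughter(contrib[[i]]$genotype, contrib[[i]]$mate),
              matriline_mito, contrib[[i]]$id,
              paste0(contrib[[i]]$id, "_mate"))
    }
  }

  # collected queens: present breeders first, then gynes / adoptees
  present <- which(vapply(contrib, `[[`, logical(1), "present"))
  n_present_breeders <- length(present)
  n_queens <- config$queen_min +
    min(stats::rgeom(1, config$queen_geom_p),
        config$queen_max - config$queen_min)
  n_queens <- max(n_queens, n_present_breeders)
  for (i in present) {
    add_row(contrib[[i]]$id, "queen", "developed",
            contrib[[i]]$genotype,
            matriline_mito,
            if (contrib[[i]]$generation == 0L) NA_character_
            else founder_id,
            if (contrib[[i]]$generation == 0L) NA_character_
            else paste0(founder_id, "_mate"))
  }
  qi <- 0L
  for (s in seq_len(n_queens - n_present_breeders)) {
    qi <- qi + 1L
    qid <- paste0(colony_id, "_q", qi)
    if (stats::runif(1) < config$prob_unrelated_adoptee) {
      ov <- if (stats::runif(1) < config$prob_adoptee_developed)
        "developed" else "undeveloped"
      add_row(qid, "queen", ov, sample_diploid(freqs),
              sample(mito_pool, 1L), NA_character_, NA_character_,
              adoptee = TRUE)
    } else {
      i <- sample.int(k, 1L)
      add_row(qid, "queen", "undeveloped",
              make_daughter(contrib[[i]]$genotype, contrib[[i]]$mate),
              matriline_mito, contrib[[i]]$id,
              paste0(contrib[[i]]$id, "_mate"))
      offspring_of[contrib[[i]]$id] <-
        offspring_of[contrib[[i]]$id] + 1L
    }
  }

  ind <- data.frame(
    individual_id = vapply(rows, `[[`, "", "individual_id"),
    colony_id = vapply(rows, `[[`, "", "colony_id"),
    caste = vapply(rows, `[[`, "", "caste"),
    ovary_status = vapply(rows, `[[`, "", "ovary_status"),
    mito_haplotype = vapply(rows, `[[`, "", "mito_haplotype"),
    mother_id = vapply(rows, `[[`, "", "mother_id"),
    father_id = vapply(rows, `[[`, "", "father_id"),
    is_adoptee = vapply(rows, `[[`, logical(1), "is_adoptee"),
    stringsAsFactors = FALSE)
  ind$genotype <- lapply(rows, `[[`, "genotype")

  # truth-side queen types and nest type
  contributed <- offspring_of > 0L
  ids <- names(offspring_of)
  presence <- stats::setNames(
    vapply(contrib, `[[`, logical(1), "present"), ids)
  true_types <- character(0)
  for (id in ids[contributed]) {
    true_types[id] <- if (presence[id]) "2a" else "1"
  }
  for (i in present) {
    id <- contrib[[i]]$id
    if (!contributed[id]) true_types[id] <- "2b"
  }
  for (r in rows) {
    if (r$caste == "queen" && is.na(match(r$individual_id, ids))) {
      true_types[r$individual_id] <-
        if (r$ovary_status == "undeveloped") "3" else "2b"
    }
  }
  n_contrib <- sum(contributed)
  n_present_contrib <- sum(contributed & presence)
  true_nest <- if (n_contrib == 0L) "unclassified"
  else if (n_contrib == 1L) "A"
  else if (n_present_contrib >= 2L) "B"
  else "C"

  truth <- list(
    colony_id = colony_id,
    pedigree = ind[, c("individual_id", "mother_id", "father_id",
                       "is_adoptee")],
    contributors = stats::setNames(
      lapply(contrib, function(x)
        list(genotype = x$genotype, mate = x$mate,
             present = x$present)), ids),
    offspring_of = offspring_of,
    breeder_set = ids[contributed],
    true_queen_types = true_types,
    true_nest_type = true_nest,
    turnover = turnover,
    triploid_brood = triploid_brood,
    triploid_mother = if (trip_idx) ids[trip_idx] else NA_character_)

  ind$mother_id <- NULL; ind$father_id <- NULL; ind$is_adoptee <- NULL
  list(individuals = ind, truth = truth)
}

#' Generate a full synthetic dataset
#'
#' Draws allele frequencies, then simulates `n_colonies` colonies,
#' returning a validated [genotype_table()] alongside the ground-truth
#' records needed for parameter-recovery studies. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` (a [genotype_table()]), `truth`
#'   (list of per-colony truth records, see [simulate_colony()]) and
#'   `freqs` (the generating allele frequencies).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  freqs <- sample_allele_frequencies(config)
  panel <- locus_panel(names(freqs),
                       lapply(freqs, function(p) as.integer(names(p))))
  if (config$n_colonies == 0L) {
    empty <- data.frame(individual_id = character(0),
                        colony_id = character(0),
                        caste = character(0),
                        ovary_status = character(0),
                        stringsAsFactors = FALSE)
    empty$genotype <- list()
    return(list(table = genotype_table(empty, panel),
                truth = list(), freqs = freqs))
  }
  sims <- lapply(seq_len(config$n_colonies), function(i) {
    simulate_colony(config, freqs,
                    sprintf("c%02d", i))
  })
  ind <- do.call(rbind, lapply(sims, `[[`, "individuals"))
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- vapply(truth, `[[`, "", "colony_id")
  list(table = genotype_table(ind, panel), truth = truth,
       freqs = freqs)
}

#' Simulate genotype pairs of known relationship
#'
#' Draws independent pairs for calibrating the relatedness estimator:
#' haplodiploid full sisters (expected Queller-Goodnight relatedness
#' 0.75), mother-daughter pairs (0.5), or unrelated individuals (0).
#' Consumes the current RNG stream.
#'
#' @param freqs Allele frequencies, as from
#'   [sample_allele_frequencies()].
#' @param n Number of pairs.
#' @param relationship One of `"full_sisters"`, `"mother_daughter"`,
#'   `"unrelated"`.
#' @return A list of `n` elements, each a list of two genotypes.
#' @export
simulate_related_pairs <- function(freqs, n,
                                   relationship = c("full_sisters",
                                                    "mother_daughter",
                                                    "unrelated")) {
  relationship <- match.arg(relationship)
  replicate(n, {
    switch(relationship,
           full_sisters = {
             m <- sample_diploid(freqs); f <- sample_haploid(freqs)
             list(make_daughter(m, f), make_daughter(m, f))
           },
           mother_daughter = {
             m <- sample_diploid(freqs); f <- sample_haploid(freqs)
             list(m, make_daughter(m, f))
           },
           unrelated = list(sample_diploid(freqs),
                            sample_diploid(freqs)))
  }, simplify = FALSE)
}
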