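#' @title Sibship reconstruction under haplodiploid monandry
#' @description Internal machinery and user-facing operations for
#'   partitioning offspring into the minimal number of monandrous
#'   maternal sibships and inferring parental genotypes.
#' @name sibship
#' @keywords internal
NULL

# ---------------------------------------------------------------------
# Per-locus parental solution algebra.
#
# Under monandry every diploid offspring carries the father's single
# allele f plus one maternal allele. A compact exact representation of
# all parental solutions for a member set at one locus is the set of
# pairs (f, R) where R is the set of maternal alleles *required* by the
# members (|R| <= 2). The mother pair is R itself when |R| = 2; when
# |R| = 1 the second maternal allele is unconstrained. Adding a member
# can only filter rows or grow R, so the representation supports exact
# incremental updates during partition search.
#
# State encoding: each (f, R) row is packed into one double as
# f * 2^32 + r1 * 2^16 + r2, with r2 = 0 when only one maternal allele
# is required (allele sizes are validated to stay below 2^16). A state
# is a numeric vector of packed rows; length 0 = incompatible. The
# packing keeps filtering fully vectorized during partition search.
# ---------------------------------------------------------------------

.LS_F <- 2^32
.LS_R <- 2^16

.locus_state_init <- function(pair) {
  a <- pair[1]; b <- pair[2]
  if (a == b) {
    a * .LS_F + a * .LS_R
  } else {
    c(a * .LS_F + b * .LS_R, b * .LS_F + a * .LS_R)
  }
}

.locus_state_add <- function(state, pair) {
  a <- pair[1]; b <- pair[2]
  f <- state %/% .LS_F
  rest <- state %% .LS_F
  r1 <- rest %/% .LS_R
  r2 <- rest %% .LS_R
  out <- numeric(0)
  for (case in if (a == b) list(c(a, a)) else
       list(c(a, b), c(b, a))) {
    sel <- f == case[1]  # member carries the father allele
    if (!any(sel)) next
    o <- case[2]         # the member's maternal allele
    keep <- sel & (r1 == o | r2 == o)
    extend <- sel & r2 == 0 & r1 != o
    out <- c(out, state[keep],
             f[extend] * .LS_F + pmin(r1[extend], o) * .LS_R +
               pmax(r1[extend], o))
  }
  unique(out)
}

# unpack a state vector into an (f, r1, r2) matrix; r2 NA = any allele
.locus_state_decode <- function(state) {
  f <- state %/% .LS_F
  rest <- state %% .LS_F
  r2 <- rest %% .LS_R
  cbind(f = f, r1 = rest %/% .LS_R,
        r2 = ifelse(r2 == 0, NA_real_, r2))
}

# block state across loci: list(states = named list of per-locus
# matrices or NULL, members = integer indices)
.block_new <- function() list(states = list(), members = integer(0))

# geno: named list locus -> sorted pair (length-2 integer); NULL entries
# for untyped loci must be absent
.block_add <- function(block, idx, geno) {
  st <- block$states
  for (l in names(geno)) {
    pair <- geno[[l]]
    s <- st[[l]]
    s <- if (is.null(s)) .locus_state_init(pair)
    else .locus_state_add(s, pair)
    if (!length(s)) return(NULL)  # incompatible
    st[[l]] <- s
  }
  list(states = st, members = c(block$members, idx))
}

# brute-force compatibility oracle: enumerate father and mother-pair
# candidates over observed alleles (plus an unobserved-allele wildcard
# for the second maternal slot) and test every member directly.
# Independent of the incremental (f, R) machinery above.
.brute_locus_compatible <- function(pairs) {
  obs <- sort(unique(unlist(pairs)))
  for (f in obs) {
    for (m1 in obs) {
      for (m2 in c(obs[obs >= m1], NA_integer_)) {
        ok <- TRUE
        for (p in pairs) {
          a <- p[1]; b <- p[2]
          hit <- (a == f && (b == m1 || (!is.na(m2) && b == m2))) ||
            (b == f && (a == m1 || (!is.na(m2) && a == m2)))
          if (!hit) { ok <- FALSE; break }
        }
        if (ok) return(TRUE)
      }
    }
  }
  FALSE
}

#' Verify that a set of genotypes can form one monandrous sibship
#'
#' Brute-force check, by direct enumeration of candidate fathers and
#' mother pairs over the observed alleles at each locus, that all
#' members can be daughters of a single mother and a single haploid
#' father. Used as an independent verifier for the partition search.
#'
#' @param genotypes List of genotypes (named lists mapping locus to an
#'   allele vector of length 1 or 2; single calls are treated as
#'   homozygous). Missing loci impose no constraint.
#' @return `TRUE` if a compatible (mother, father) exists at every
#'   typed locus.
#' @export
verify_sibship <- function(genotypes) {
  pl <- lapply(genotypes, .pairs_view)
  loci <- unique(unlist(lapply(pl, names)))
  for (l in loci) {
    pairs <- lapply(pl, function(g) g[[l]])
    pairs <- pairs[!vapply(pairs, is.null, logical(1))]
    if (length(pairs) && !.brute_locus_compatible(pairs)) return(FALSE)
  }
  TRUE
}

# single calls doubled to homozygote pairs; triploid loci are an error
.pairs_view <- function(g) {
  out <- list()
  for (l in names(g)) {
    a <- g[[l]]
    if (!length(a)) next
    if (length(a) == 1L) out[[l]] <- c(a, a)
    else if (length(a) == 2L) out[[l]] <- a
    else stop("triploid locus present; run collapse_triploid() first")
  }
  out
}

#' Enumerate parental solutions for one candidate sibship
#'
#' Returns, per locus, every (mother pair, father allele) combination
#' consistent with all members being full sisters under haplodiploid
#' monandry. Mother-pair alternatives are reported over the observed
#' alleles at the locus; a second maternal allele that no member
#' demonstrates is reported as `NA` (any allele).
#'
#' @param genotypes List of member genotypes (named lists; length-1
#'   calls treated as homozygous, missing loci unconstrained).
#' @return Object of class `parentage`: a list with `compatible`
#'   (logical), and `loci`, a named list with per-locus elements
#'   `solutions` (data.frame `father`, `mother1`, `mother2`, `NA` =
#'   unconstrained slot), `mother_pairs` (matrix of distinct concrete
#'   mother pairs over observed alleles), and `unique_mother` (logical).
#'   Loci typed in no member are absent (unconstrained).
#' @examples
#' infer_parents(list(list(L1 = c(100L, 104L)),
#'                    list(L1 = c(100L, 106L))))
#' @export
infer_parents <- function(genotypes) {
  stopifnot(length(genotypes) >= 1L)
  pl <- lapply(genotypes, .pairs_view)
  loci <- unique(unlist(lapply(pl, names)))
  res <- list()
  compatible <- TRUE
  for (l in loci) {
    pairs <- lapply(pl, function(g) g[[l]])
    pairs <- pairs[!vapply(pairs, is.null, logical(1))]
    if (!length(pairs)) next
    st <- .locus_state_init(pairs[[1]])
    if (length(pairs) > 1L) {
      for (p in pairs[-1]) {
        st <- .locus_state_add(st, p)
        if (!length(st)) break
      }
    }
    obs <- sort(unique(unlist(pairs)))
    dec <- .locus_state_decode(st)
    sol <- data.frame(father = dec[, 1L], mother1 = dec[, 2L],
                      mother2 = dec[, 3L])
    mp <- .mother_pairs(dec, obs)
    res[[l]] <- list(solutions = sol, mother_pairs = mp,
                     unique_mother = nrow(mp) == 1L)
    if (!length(st)) compatible <- FALSE
  }
  structure(list(compatible = compatible, loci = res),
            class = "parentage")
}

# concrete mother pairs implied by an (f, R) state, restricted to
# observed alleles for the unconstrained slot
.mother_pairs <- function(state, observed) {
  if (!nrow(state)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("m1", "m2"))))
  }
  rows <- list()
  for (i in seq_len(nrow(state))) {
    r1 <- state[i, 2L]; r2 <- state[i, 3L]
    if (!is.na(r2)) {
      rows[[length(rows) + 1L]] <- c(r1, r2)
    } else {
      for (y in observed) {
        rows[[length(rows) + 1L]] <- sort(c(r1, y))
      }
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("m1", "m2")
  m[!duplicated(m), , drop = FALSE]
}

#' @export
print.parentage <- function(x, ...) {
  cat("<parentage> ", if (x$compatible) "compatible"
      else "incompatible", ", ", length(x$loci),
      " constrained loci\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------
# Minimal sibship partition search
# ---------------------------------------------------------------------

#' Partition offspring into the minimal number of monandrous sibships
#'
#' Finds every partition of the offspring into compatible full-sister
#' groups that achieves the minimal number of groups, i.e. the minimal
#' number of mother queens needed to explain the genotypes under
#' haplodiploid monandry. The default search is branch-and-bound over
#' set partitions with exact incremental compatibility filtering; an
#' exhaustive enumerator over all set partitions is available as an
#' oracle for small instances.
#'
#' @param genotypes Named list of offspring genotypes (names are
#'   individual ids; each genotype a named list locus -> allele vector
#'   of length 1-2; collapse triploids first).
#' @param method `"branch_bound"` (default) or `"exhaustive"`.
#' @param max_exhaustive Maximum offspring count accepted by the
#'   exhaustive method (default 10; Bell(10) = 115,975 partitions).
#' @return Object of class `sibship_partition`: list with `min_count`,
#'   `partitions` (list of minimal partitions, each a list of character
#'   vectors of member ids), `ambiguous` (more than one structurally
#'   distinct minimal partition) and `n_candidates_explored`.
#' @export
min_sibship_partition <- function(genotypes,
                                  method = c("branch_bound",
                                             "exhaustive"),
                                  max_exhaustive = 10L) {
  method <- match.arg(method)
  n <- length(genotypes)
  stopifnot(n >= 1L)
  ids <- names(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pl <- lapply(genotypes, .pairs_view)

  if (method == "exhaustive") {
    if (n > max_exhaustive) {
      stop("exhaustive enumeration limited to ", max_exhaustive,
           " offspring")
    }
    res <- .exhaustive_partitions(pl)
  } else {
    res <- .bb_partitions(pl)
  }
  partitions <- lapply(res$partitions, function(assign) {
    lapply(seq_len(max(assign)), function(b) ids[assign == b])
  })
  # canonical order: blocks by first member index; partitions sorted
  partitions <- lapply(partitions, function(p) {
    p[order(vapply(p, function(b) match(b[1], ids), integer(1)))]
  })
  key <- vapply(partitions, function(p) {
    paste(vapply(p, function(b) paste(sort(b), collapse = ","),
                 character(1)), collapse = "|")
  }, character(1))
  partitions <- partitions[order(key)]
  structure(list(min_count = res$min_count,
                 partitions = partitions,
                 ambiguous = length(partitions) > 1L,
                 n_candidates_explored = res$explored),
            class = "sibship_partition")
}

#' @export
print.sibship_partition <- function(x, ...) {
  cat("<sibship_partition> minimum ", x$min_count, " sibship(s), ",
      length(x$partitions), " minimal partition(s)",
      if (x$ambiguous) " [ambiguous]", "\n", sep = "")
  invisible(x)
}

# branch and bound over restricted-growth assignments: individual i may
# join any open block whose state stays compatible, or open block
# (#blocks + 1). Prune when #blocks would exceed the best known count.
# Individuals are visited most-constrained first (fewest pairwise
# compatibilities), and a pairwise-compatibility matrix prefilters
# block joins before the exact per-locus state update.
.bb_partitions <- function(pl) {
  n <- length(pl)
  if (n == 1L) {
    return(list(min_count = 1L, partitions = list(1L), explored = 1L))
  }
  compat <- matrix(TRUE, n, n)
  for (i in seq_len(n - 1L)) {
    bi <- .block_add(.block_new(), i, pl[[i]])
    for (j in (i + 1L):n) {
      ok <- !is.null(.block_add(bi, j, pl[[j]]))
      compat[i, j] <- ok
      compat[j, i] <- ok
    }
  }
  ord <- order(rowSums(compat))
  pl <- pl[ord]
  compat <- compat[ord, ord, drop = FALSE]

  best <- Inf
  results <- list()
  explored <- 0L
  assign <- integer(n)

  recurse <- function(i, blocks) {
    nb <- length(blocks)
    if (i > n) {
      explored <<- explored + 1L
      if (nb < best) {
        best <<- nb
        results <<- list(assign[seq_len(n)])
      } else if (nb == best) {
        results[[length(results) + 1L]] <<- assign[seq_len(n)]
      }
      return(invisible())
    }
    for (b in seq_len(nb)) {
      if (!all(compat[i, blocks[[b]]$members])) next
      nbk <- .block_add(blocks[[b]], i, pl[[i]])
      if (!is.null(nbk)) {
        old <- blocks[[b]]
        blocks[[b]] <- nbk
        assign[i] <<- b
        recurse(i + 1L, blocks)
        blocks[[b]] <- old
      }
    }
    if (nb + 1L <= best) {  # opening one more block can still tie
      nbk <- .block_add(.block_new(), i, pl[[i]])
      blocks[[nb + 1L]] <- nbk
      assign[i] <<- nb + 1L
      recurse(i + 1L, blocks)
    }
    invisible()
  }
  recurse(1L, list())
  # map assignments back to the caller's individual order
  results <- lapply(results, function(a) {
    out <- integer(n)
    out[ord] <- a
    # renumber blocks by first appearance so numbering is canonical
    match(out, unique(out))
  })
  list(min_count = as.integer(best), partitions = results,
       explored = explored)
}

# exhaustive oracle: enumerate every set partition (restricted growth
# strings); a block is tested with the brute-force verifier each time a
# member is added, pruning only provably infeasible blocks (adding
# members never restores compatibility). No minimality pruning.
.exhaustive_partitions <- function(pl) {
  n <- length(pl)
  results <- list()
  counts <- integer(0)
  explored <- 0L
  assign <- integer(n)
  loci_of <- lapply(pl, names)

  block_ok <- function(members) {
    loci <- unique(unlist(loci_of[members]))
    for (l in loci) {
      pairs <- lapply(members, function(j) pl[[j]][[l]])
      pairs <- pairs[!vapply(pairs, is.null, logical(1))]
      if (length(pairs) && !.brute_locus_compatible(pairs)) {
        return(FALSE)
      }
    }
    TRUE
  }
  recurse <- function(i, nb) {
    if (i > n) {
      explored <<- explored + 1L
      results[[length(results) + 1L]] <<- assign[seq_len(n)]
      counts[length(counts) + 1L] <<- nb
      return(invisible())
    }
    for (b in seq_len(nb + 1L)) {
      assign[i] <<- b
      if (block_ok(which(assign[seq_len(i)] == b))) {
        recurse(i + 1L, max(nb, b))
      }
    }
    invisible()
  }
  recurse(1L, 0L)
  mn <- min(counts)
  list(min_count = as.integer(mn),
       partitions = results[counts == mn], explored = explored)
}

# ---------------------------------------------------------------------
# Sibship objects, reliability rule, queen matching
# ---------------------------------------------------------------------

#' Build a sibship object from member genotypes
#'
#' @param ids Character vector of member ids.
#' @param genotypes List of member genotypes (parallel to `ids`).
#' @return Object of class `sibship`: members, per-locus `parentage`
#'   (see [infer_parents()]), the mother genotype (named list of
#'   allele pairs, `NULL` at loci that are unconstrained or ambiguous),
#'   father alleles (named integer vector, `NA` where ambiguous), and
#'   logical `unique_solution` (mother pair unique at every typed
#'   locus).
#' @export
build_sibship <- function(ids, genotypes) {
  par <- infer_parents(genotypes)
  if (!par$compatible) stop("members are not a compatible sibship")
  mother <- list()
  father <- integer(0)
  uniq <- TRUE
  for (l in names(par$loci)) {
    pl <- par$loci[[l]]
    if (pl$unique_mother) {
      mother[[l]] <- as.integer(pl$mother_pairs[1, ])
    } else {
      uniq <- FALSE
    }
    fs <- unique(pl$solutions$father)
    father[[l]] <- if (length(fs) == 1L) fs else NA_integer_
  }
  structure(list(members = ids, parentage = par, mother = mother,
                 father = father, size = length(ids),
                 unique_solution = uniq),
            class = "sibship")
}

#' @export
print.sibship <- function(x, ...) {
  cat("<sibship> ", x$size, " member(s), ",
      if (x$unique_solution) "unique" else "ambiguous",
      " parental solution\n", sep = "")
  invisible(x)
}

#' Apply the minimum-offspring reliability rule
#'
#' A reconstructed mother genotype is only emitted for sibships with at
#' least `min_offspring` members and (by default) a uniquely determined
#' mother pair at every typed locus. All other sibships contribute only
#' to the count of additional queens required to explain the genotypes.
#'
#' @param sibships List of [build_sibship()] objects (one minimal
#'   partition).
#' @param min_offspring Minimum members for reliable reconstruction
#'   (default 3).
#' @param require_unique If `TRUE` (default) a sibship whose mother
#'   pair is ambiguous at any typed locus is not emitted; if `FALSE`
#'   such loci are emitted as `NULL` (unknown) instead.
#' @return List with `mothers` (emitted sibships, with index into
#'   `sibships`), `extra_queen_count`, and logical vector `reliable`.
#' @export
apply_reliability_rule <- function(sibships, min_offspring = 3L,
                                   require_unique = TRUE) {
  reliable <- vapply(sibships, function(s) {
    s$size >= min_offspring && (!require_unique || s$unique_solution)
  }, logical(1))
  mothers <- lapply(which(reliable), function(i) {
    s <- sibships[[i]]
    list(sibship = i, genotype = s$mother, father = s$father,
         members = s$members)
  })
  list(mothers = mothers,
       extra_queen_count = sum(!reliable),
       reliable = reliable)
}

#' Match collected queens against reconstructed mothers
#'
#' A collected queen is `is_a_reconstructed_mother` of a sibship with
#' at least `min_offspring` members when her genotype is among the
#' sibship's reconstructed mother-pair alternatives at every locus
#' constrained by the offspring and typed in the queen; where the
#' offspring determine the mother uniquely this is plain genotype
#' identity, and where they leave alternatives the queen's own
#' genotype resolves them. A non-matching queen is
#' `relative_of_mother` when her maximal Queller-Goodnight relatedness
#' to a reconstructed mother genotype (its uniquely determined loci)
#' reaches `threshold`, else `unrelated`. Queens typed at fewer than
#' `min_loci` loci, or with no candidate sibship to compare against,
#' are `unresolved`.
#'
#' @param sibships List of [build_sibship()] objects (the reported
#'   minimal partition).
#' @param queens Data.frame of collected queens (rows of a
#'   [genotype_table()]'s `individuals`, diploid).
#' @param freqs Allele frequencies from
#'   [estimate_allele_frequencies()].
#' @param threshold Relatedness threshold separating relatives from
#'   unrelated queens (default 0.25).
#' @param min_loci Minimum typed loci for a queen to be matched
#'   (default 7).
#' @param min_offspring Minimum sibship size for a mother comparison
#'   (default 3, the reliability rule).
#' @return Data.frame: `queen_id`, `status`, `matched_sibship`
#'   (index into `sibships` or `NA`), `max_r`, and `multi_match`
#'   (queen consistent with two or more distinct sibships' mothers, an
#'   ambiguity signal).
#' @export
match_queens <- function(sibships, queens, freqs, threshold = 0.25,
                         min_loci = 7L, min_offspring = 3L) {
  out <- data.frame(queen_id = character(0), status = character(0),
                    matched_sibship = integer(0), max_r = numeric(0),
                    multi_match = logical(0),
                    stringsAsFactors = FALSE)
  cand <- which(vapply(sibships, function(s) {
    s$size >= min_offspring
  }, logical(1)))
  for (i in seq_len(nrow(queens))) {
    qid <- queens$individual_id[i]
    g <- .pairs_view(queens$genotype[[i]])
    if (length(g) < min_loci || !length(cand)) {
      out[nrow(out) + 1L, ] <- list(qid, "unresolved", NA_integer_,
                                    NA_real_, FALSE)
      next
    }
    hits <- integer(0)
    rs <- rep(NA_real_, length(cand))
    for (jj in seq_along(cand)) {
      s <- sibships[[cand[jj]]]
      # the queen cannot be her own sibship's mother, but she can be
      # (and usually is) a relative of it
      if (!qid %in% s$members) {
        loci <- intersect(names(g), names(s$parentage$loci))
        ok <- length(loci) > 0L && all(vapply(loci, function(l) {
          mp <- s$parentage$loci[[l]]$mother_pairs
          any(mp[, 1] == g[[l]][1] & mp[, 2] == g[[l]][2])
        }, logical(1)))
        if (ok) hits <- c(hits, cand[jj])
      }
      if (length(s$mother)) {
        rs[jj] <- qg_relatedness(queens$genotype[[i]], s$mother,
                                 freqs)
      }
    }
    max_r <- if (all(is.na(rs))) NA_real_ else max(rs, na.rm = TRUE)
    if (length(hits)) {
      out[nrow(out) + 1L, ] <- list(qid, "is_a_reconstructed_mother",
                                    hits[1], max_r, length(hits) > 1L)
    } else if (!is.na(max_r) && max_r >= threshold) {
      out[nrow(out) + 1L, ] <- list(qid, "relative_of_mother",
                                    NA_integer_, max_r, FALSE)
    } else if (is.na(max_r)) {
      out[nrow(out) + 1L, ] <- list(qid, "unresolved", NA_integer_,
                                    NA_real_, FALSE)
    } else {
      out[nrow(out) + 1L, ] <- list(qid, "unrelated", NA_integer_,
                                    max_r, FALSE)
    }
  }
  out
}

#' Reconstruct the genetic structure of one colony
#'
#' Runs the full per-colony procedure: triploids are collapsed, all
#' offspring (sampled workers and collected queens alike, the latter
#' treated as potential daughters) are partitioned into the minimal
#' number of monandrous sibships, the minimum-offspring reliability
#' rule is applied, and collected queens are matched against the
#' emitted mother genotypes. Blocks consisting solely of queens who
#' were matched as mothers are not counted as additional queens: their
#' genotypes are explained by their being mothers, not offspring.
#'
#' @param table A [genotype_table()].
#' @param colony One colony id present in `table`.
#' @param freqs Allele frequencies (default: estimated from the whole
#'   table, pool `"all"`).
#' @param min_offspring Reliability threshold (default 3).
#' @param threshold Queen-matching relatedness threshold (default
#'   0.25).
#' @param require_unique Passed to [apply_reliability_rule()].
#' @param method,max_exhaustive Passed to [min_sibship_partition()].
#' @param collapse_rule Triploid collapse rule used for matching and
#'   relatedness, see [collapse_triploid()]. For the partition search
#'   itself, loci with three allele calls are treated as uninformative
#'   (missing): the haploid-father decomposition does not apply to
#'   diploid-male brood, and collapsing there could discard the shared
#'   paternal allele and inflate the minimal queen count.
#' @return Object of class `colony_reconstruction`: colony id, minimal
#'   sibship count, all minimal partitions, ambiguity flag (multiple
#'   minimal partitions or a queen matching several mothers), the
#'   reported partition's sibships, emitted mothers, queen match table,
#'   extra queen count and the number of identified contributors
#'   (emitted mothers + extra queens).
#' @export
reconstruct_colony <- function(table, colony, freqs = NULL,
                               min_offspring = 3L, threshold = 0.25,
                               require_unique = TRUE,
                               method = "branch_bound",
                               max_exhaustive = 10L,
                               collapse_rule = "smallest_two") {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(table)
  sub_raw <- subset_colony(table, colony)
  sub <- collapse_triploid(sub_raw, rule = collapse_rule)
  ind <- sub$individuals
  if (!nrow(ind)) stop("no individuals in colony ", colony)
  # 3-call loci carry no parentage information under the monandrous
  # haploid-father model; drop them from the partition genotypes
  genos <- stats::setNames(
    lapply(sub_raw$individuals$genotype, function(g) {
      g[vapply(g, length, integer(1)) <= 2L]
    }), ind$individual_id)
  queens <- ind[ind$caste == "queen", , drop = FALSE]
  part <- min_sibship_partition(genos, method = method,
                                max_exhaustive = max_exhaustive)

  evals <- lapply(part$partitions, function(p) {
    .evaluate_partition(p, genos, queens, freqs, min_offspring,
                        threshold, require_unique)
  })
  # a collected mother queen is always pairwise compatible with any
  # single daughter, so block-minimal partitions that merely re-seat a
  # matched mother as a worker's "sister" tie on block count; the
  # operative objective is the net number of queens required, so the
  # partition minimizing identified contributors is reported and
  # ambiguity means disagreement among those optima
  nc <- vapply(evals, `[[`, integer(1), "n_contributors")
  considered <- which(nc == min(nc))
  ev <- evals[[considered[1]]]
  ambiguous <- length(considered) > 1L || any(ev$match$multi_match)
  structure(list(colony_id = colony,
                 min_sibships = part$min_count,
                 partitions = part$partitions,
                 considered = considered,
                 nest_by_partition =
                   vapply(evals, `[[`, character(1), "nest_type"),
                 ambiguous = ambiguous,
                 sibships = ev$sibs,
                 reliable = ev$reliable,
                 mothers = ev$mothers,
                 queen_match = ev$match,
                 extra_queen_count = ev$extra,
                 n_contributors = ev$n_contributors,
                 n_offspring = nrow(ind)),
            class = "colony_reconstruction")
}

# reliability, queen matching, extra-queen accounting and nest typing
# for one candidate partition
.evaluate_partition <- function(partition, genos, queens, freqs,
                                min_offspring, threshold,
                                require_unique) {
  sibs <- lapply(partition, function(ids) {
    build_sibship(ids, genos[ids])
  })
  rel <- apply_reliability_rule(sibs, min_offspring = min_offspring,
                                require_unique = require_unique)
  match <- match_queens(sibs, queens, freqs, threshold = threshold,
                        min_offspring = min_offspring)
  developed <- queens$individual_id[queens$ovary_status ==
                                      "developed"]
  is_claim <- match$status == "is_a_reconstructed_mother" &
    match$queen_id %in% developed
  claimed <- match$matched_sibship[is_claim]
  matched_ids <- match$queen_id[is_claim]
  # an unreliable sibship is not an anonymous extra queen when it is
  # claimed by a matched developed-ovary queen, when its members are
  # all queens already matched as mothers (their genotypes are
  # explained by motherhood, not by an additional queen), or when it
  # is a lone collected queen (nobody's sampled offspring: her mother
  # need not be a colony breeder -- adoptees and turnover survivors)
  queen_ids <- queens$individual_id
  extra <- 0L
  for (i in seq_along(sibs)) {
    if (rel$reliable[i] || i %in% claimed) next
    mem <- sibs[[i]]$members
    if (all(mem %in% matched_ids)) next
    if (length(mem) == 1L && mem %in% queen_ids) next
    extra <- extra + 1L
  }
  emitted <- vapply(rel$mothers, `[[`, integer(1), "sibship")
  n_contributors <- length(unique(c(emitted, claimed))) + extra
  n1 <- sum(!emitted %in% claimed)
  n2a <- length(unique(claimed))
  nest <- classify_nest(c(rep("1", n1), rep("2a", n2a)), extra)
  list(sibs = sibs, reliable = rel$reliable, mothers = rel$mothers,
       match = match, extra = extra,
       n_contributors = n_contributors, nest_type = nest)
}

#' @export
print.colony_reconstruction <- function(x, ...) {
  cat("<colony_reconstruction> ", x$colony_id, ": minimum ",
      x$min_sibships, " sibship(s), ", length(x$mothers),
      " reconstructed mother(s), ", x$extra_queen_count,
      " extra queen(s)", if (x$ambiguous) " [ambiguous]", "\n",
      sep = "")
  invisible(x)
}

#' Reconstruct every colony of a table
#'
#' @inheritParams reconstruct_colony
#' @param ... Passed to [reconstruct_colony()].
#' @return Named list of `colony_reconstruction` objects.
#' @export
reconstruct_colonies <- function(table, freqs = NULL, ...) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(table)
  ids <- colony_ids(table)
  out <- lapply(ids, function(cid) {
    reconstruct_colony(table, cid, freqs = freqs, ...)
  })
  names(out) <- ids
  out
}
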