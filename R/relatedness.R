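#' Collapse triploid genotypes to diploid
#'
#' Microsatellite loci showing three allele calls (triploid offspring
#' of a diploid-male mating) are reduced to diploid by keeping the two
#' smallest distinct alleles, so that all downstream relatedness and
#' reconstruction operates on diploid genotypes. The rule is
#' configurable because the choice between the two smallest and the
#' two largest alleles is a scoring convention, not biology; the number
#' of discarded allele calls is reported either way.
#'
#' @param table A [genotype_table()].
#' @param rule `"smallest_two"` (default) or `"largest_two"`.
#' @return The table with all loci diploid (or fewer calls). Attribute
#'   `n_discarded` gives the total number of discarded allele calls and
#'   attribute `discarded_by_individual` a named count per affected
#'   individual.
#' @export
collapse_triploid <- function(table, rule = c("smallest_two",
                                              "largest_two")) {
  stopifnot(inherits(table, "genotype_table"))
  rule <- match.arg(rule)
  ind <- table$individuals
  per_ind <- integer(0)
  total <- 0L
  for (i in seq_len(nrow(ind))) {
    g <- ind$genotype[[i]]
    nd <- 0L
    for (l in names(g)) {
      a <- g[[l]]
      if (length(a) == 3L) {
        d <- sort(unique(a))
        keep <- if (length(d) == 1L) c(d, d)
        else if (rule == "smallest_two") d[1:2]
        else d[(length(d) - 1L):length(d)]
        g[[l]] <- sort(keep)
        nd <- nd + 1L
      }
    }
    if (nd > 0L) {
      ind$genotype[[i]] <- g
      per_ind[ind$individual_id[i]] <- nd
      total <- total + nd
    }
  }
  ind$triploid <- vapply(ind$genotype, function(g) {
    any(vapply(g, length, integer(1)) == 3L)
  }, logical(1))
  out <- table
  out$individuals <- ind
  attr(out, "n_discarded") <- total
  attr(out, "discarded_by_individual") <- per_ind
  out
}

#' Estimate population allele frequencies
#'
#' Counts allele calls per locus over a chosen pool of individuals and
#' normalizes over non-missing calls. Triploid loci are collapsed (two
#' smallest distinct alleles) before counting; single calls count as
#' homozygous.
#'
#' @param table A [genotype_table()].
#' @param pool `"all"` (every genotyped individual, equally weighted;
#'   the default), `"one_worker_per_colony"` (the first worker by id
#'   order in each colony, the pool used for marker quality checks), or
#'   `"queens_only"`.
#' @param exclude Optional individual ids to drop from the pool (e.g.
#'   a focal pair).
#' @return Named list per locus of named numeric vectors (names =
#'   allele sizes, values = frequencies summing to 1). Attributes
#'   `pool`, `n_individuals` and `n_calls` (per locus) record the
#'   estimation metadata.
#' @export
estimate_allele_frequencies <- function(table,
                                        pool = c("all",
                                                 "one_worker_per_colony",
                                                 "queens_only"),
                                        exclude = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  pool <- match.arg(pool)
  tab <- collapse_triploid(table)
  ind <- tab$individuals
  if (!is.null(exclude)) {
    ind <- ind[!ind$individual_id %in% exclude, , drop = FALSE]
  }
  ind <- switch(pool,
    all = ind,
    queens_only = ind[ind$caste == "queen", , drop = FALSE],
    one_worker_per_colony = {
      w <- ind[ind$caste == "worker", , drop = FALSE]
      keep <- unlist(lapply(split(seq_len(nrow(w)), w$colony_id),
                            function(ix) {
                              ix[order(w$individual_id[ix])[1]]
                            }))
      w[sort(keep), , drop = FALSE]
    })
  if (!nrow(ind)) stop("empty frequency pool")
  loci <- tab$panel$loci
  counts <- stats::setNames(
    lapply(loci, function(l) numeric(0)), loci)
  for (i in seq_len(nrow(ind))) {
    g <- ind$genotype[[i]]
    for (l in names(g)) {
      a <- g[[l]]
      if (length(a) == 1L) a <- c(a, a)
      for (al in a) {
        key <- as.character(al)
        counts[[l]][key] <- (counts[[l]][key] %||% 0) + 1
      }
    }
  }
  n_calls <- vapply(counts, sum, numeric(1))
  freqs <- lapply(counts, function(ct) {
    if (!length(ct)) return(stats::setNames(numeric(0), character(0)))
    ct <- ct[order(as.integer(names(ct)))]
    ct / sum(ct)
  })
  attr(freqs, "pool") <- pool
  attr(freqs, "n_individuals") <- nrow(ind)
  attr(freqs, "n_calls") <- n_calls
  freqs
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Queller-Goodnight pairwise relatedness
#'
#' Moment-based pairwise relatedness for codominant markers, in the
#' symmetrized ratio-of-sums form: per-locus numerators and
#' denominators are computed in both directions (x as focal, y as
#' focal), summed over loci and directions, and divided once. For a
#' focal individual with alleles a, b and partner alleles c, d at one
#' locus, the directional terms are
#' numerator = (I(a=c) + I(a=d) + I(b=c) + I(b=d)) / 2 - p_a - p_b and
#' denominator = 1 + I(a=b) - p_a - p_b, with p the population allele
#' frequencies. The estimator has expectation 0 for unrelated pairs,
#' 0.5 for mother-daughter pairs and 0.75 for haplodiploid full
#' sisters.
#'
#' @param x,y Genotypes (named lists locus -> allele vector of length
#'   1-2; single calls treated as homozygous; triploids must be
#'   collapsed). Loci missing in either individual are excluded.
#' @param freqs Allele frequencies from
#'   [estimate_allele_frequencies()] (or any compatible named list).
#' @return The relatedness estimate; `NA` when no jointly typed locus
#'   exists or the summed denominator is zero (e.g. both individuals
#'   homozygous for the locally most common allele everywhere), which
#'   is reported as missing rather than coerced to 0.
#' @examples
#' f <- list(L1 = c(a = .25, b = .25, c = .25, d = .25))
#' names(f$L1) <- c("100", "102", "104", "106")
#' qg_relatedness(list(L1 = c(100L, 102L)),
#'                list(L1 = c(100L, 102L)), f)  # identical pair: 1
#' @export
qg_relatedness <- function(x, y, freqs) {
  nd <- .qg_parts(x, y, freqs)
  if (is.null(nd) || abs(nd[2]) < 1e-12) return(NA_real_)
  nd[1] / nd[2]
}

# summed numerator and denominator of the symmetrized
# Queller-Goodnight estimator over jointly typed loci; NULL when no
# locus is jointly typed
.qg_parts <- function(x, y, freqs) {
  gx <- .pairs_view(x)
  gy <- .pairs_view(y)
  shared <- intersect(names(gx), names(gy))
  shared <- sort(shared[shared %in% names(freqs)])
  if (!length(shared)) return(NULL)
  num <- 0
  den <- 0
  for (l in shared) {
    p <- freqs[[l]]
    a <- gx[[l]][1]; b <- gx[[l]][2]
    c_ <- gy[[l]][1]; d <- gy[[l]][2]
    pp <- unname(p[as.character(c(a, b, c_, d))])
    if (anyNA(pp)) {
      stop("allele at locus ", l, " absent from frequency table")
    }
    pa <- pp[1]; pb <- pp[2]; pc <- pp[3]; pd <- pp[4]
    s <- (a == c_) + (a == d) + (b == c_) + (b == d)
    # direction terms are grouped per locus so the estimate is
    # bit-identical under argument swap (IEEE addition commutes)
    num <- num + ((s / 2 - pa - pb) + (s / 2 - pc - pd))
    den <- den + ((1 + (a == b) - pa - pb) +
                    (1 + (c_ == d) - pc - pd))
  }
  c(num, den)
}

#' Group-level Queller-Goodnight relatedness over many pairs
#'
#' The estimator's own aggregate form: numerators and denominators are
#' summed over all pairs (and loci, and both directions) before the
#' single division. Unlike the average of per-pair ratios -- which for
#' a handful of loci carries a small ratio bias -- the pooled estimate
#' is unbiased for the category's expected relatedness, which is why
#' group means are reported this way. A delta-method standard error is
#' returned.
#'
#' @param pairs List of genotype pairs (each a list of two genotypes),
#'   e.g. from [simulate_related_pairs()].
#' @param freqs Allele frequencies.
#' @return List with `r` (pooled estimate), `se` (delta-method
#'   standard error over pairs) and `n` (pairs contributing).
#' @export
qg_mean_relatedness <- function(pairs, freqs) {
  parts <- lapply(pairs, function(p) {
    .qg_parts(p[[1]], p[[2]], freqs)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(list(r = NA_real_, se = NA_real_, n = 0L))
  m <- do.call(rbind, parts)
  r <- sum(m[, 1]) / sum(m[, 2])
  se <- sqrt(sum((m[, 1] - r * m[, 2])^2)) / sum(m[, 2])
  list(r = r, se = se, n = nrow(m))
}

#' Pairwise relatedness among queens, by queen-pair category
#'
#' Emits one row per within-colony queen pair over the classified
#' queens (including virtual former mothers, whose genotypes are the
#' reconstructed ones), labelled with the symmetric pair category
#' (1-1, 1-2, 1-3, 2-2, 2-3, 3-3, optionally splitting 2a/2b). The
#' table is the ready input for routine distribution comparisons.
#'
#' @param classes Queen classification from [classify_queens()] (the
#'   `queens` data.frame, or the object itself).
#' @param freqs Allele frequencies.
#' @param split_2a2b Keep the 2a/2b distinction in category labels.
#' @return Data.frame: `colony_id`, `id1`, `id2`, `type1`, `type2`,
#'   `category`, `r`, `virtual1`, `virtual2`.
#' @export
pairwise_queen_relatedness <- function(classes, freqs,
                                       split_2a2b = FALSE) {
  q <- if (is.data.frame(classes)) classes else classes$queens
  q <- q[!is.na(q$type), , drop = FALSE]
  base <- function(t) if (split_2a2b) t else substr(t, 1, 1)
  out <- list()
  for (cid in unique(q$colony_id)) {
    sub <- q[q$colony_id == cid, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        cat_ <- paste(sort(c(base(sub$type[i]), base(sub$type[j]))),
                      collapse = "-")
        out[[length(out) + 1L]] <- data.frame(
          colony_id = cid,
          id1 = sub$queen_id[i], id2 = sub$queen_id[j],
          type1 = sub$type[i], type2 = sub$type[j],
          category = cat_,
          r = qg_relatedness(sub$genotype[[i]], sub$genotype[[j]],
                             freqs),
          virtual1 = sub$virtual[i], virtual2 = sub$virtual[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(colony_id = character(0), id1 = character(0),
                      id2 = character(0), type1 = character(0),
                      type2 = character(0), category = character(0),
                      r = numeric(0), virtual1 = logical(0),
                      virtual2 = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
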