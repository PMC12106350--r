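#' Genotype tables
#'
#' A `genotype_table` holds all genotyped individuals of a study: queens
#' and workers, grouped by colony, each with a per-locus allele multiset.
#' Multiset sizes encode ploidy: 0 = missing, 1 = single call (treated as
#' homozygous in analysis), 2 = diploid, 3 = triploid. Individuals typed
#' at fewer than `min_loci` of the panel's loci are retained but flagged
#' `low_coverage`; downstream modules decide exclusion.
#'
#' @param individuals A data.frame with columns `individual_id`,
#'   `colony_id`, `caste` ("queen" or "worker"), `ovary_status`
#'   ("developed", "undeveloped" or "unknown"), optionally
#'   `mito_haplotype`, and a list column `genotype` (per individual, a
#'   named list mapping locus to a sorted integer vector of 0-3 allele
#'   sizes).
#' @param panel A [locus_panel()]. Alleles present in the data are added
#'   to the panel registry.
#' @param min_loci Minimum number of typed loci for full inclusion
#'   (default 7 of the 8-locus panel).
#'
#' @return An object of class `genotype_table` with elements `panel` and
#'   `individuals`; the latter gains logical columns `triploid` (any
#'   locus with three allele calls), `n_typed` and `low_coverage`.
#' @export
genotype_table <- function(individuals, panel = default_panel(),
                           min_loci = 7L) {
  req <- c("individual_id", "colony_id", "caste", "ovary_status",
           "genotype")
  miss <- setdiff(req, names(individuals))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (!nrow(individuals)) {
    individuals$mito_haplotype <- character(0)
    individuals$triploid <- logical(0)
    individuals$n_typed <- integer(0)
    individuals$low_coverage <- logical(0)
    return(structure(list(panel = panel, individuals = individuals,
                          min_loci = as.integer(min_loci)),
                     class = "genotype_table"))
  }
  if (anyDuplicated(individuals$individual_id)) {
    stop("duplicate individual ids")
  }
  if (any(!nzchar(as.character(individuals$colony_id)))) {
    stop("colony ids must be non-empty")
  }
  bad_caste <- setdiff(unique(individuals$caste), c("queen", "worker"))
  if (length(bad_caste)) {
    stop("unknown caste code(s): ", paste(bad_caste, collapse = ", "))
  }
  bad_ov <- setdiff(unique(individuals$ovary_status),
                    c("developed", "undeveloped", "unknown"))
  if (length(bad_ov)) {
    stop("unknown ovary_status code(s): ",
         paste(bad_ov, collapse = ", "))
  }
  if (is.null(individuals$mito_haplotype)) {
    individuals$mito_haplotype <- NA_character_
  }
  individuals$genotype <- lapply(individuals$genotype, function(g) {
    g <- g[vapply(g, length, integer(1)) > 0L]
    bad <- setdiff(names(g), panel$loci)
    if (length(bad)) {
      stop("genotype loci not in panel: ", paste(bad, collapse = ", "))
    }
    lapply(g, function(a) {
      a <- sort(as.integer(a))
      if (length(a) > 3L) stop("more than three alleles at one locus")
      if (any(is.na(a)) || any(a <= 0L) || any(a >= 65536L)) {
        stop("allele sizes must be positive integers below 65536")
      }
      a
    })
  })
  panel <- register_alleles(panel, individuals$genotype)
  individuals$triploid <- vapply(individuals$genotype, function(g) {
    any(vapply(g, length, integer(1)) == 3L)
  }, logical(1))
  individuals$n_typed <- vapply(individuals$genotype, function(g) {
    sum(vapply(g, length, integer(1)) > 0L)
  }, integer(1))
  individuals$low_coverage <- individuals$n_typed < as.integer(min_loci)
  rownames(individuals) <- NULL
  structure(list(panel = panel, individuals = individuals,
                 min_loci = as.integer(min_loci)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  ind <- x$individuals
  cat("<genotype_table> ", nrow(ind), " individuals, ",
      length(unique(ind$colony_id)), " colonies, ",
      length(x$panel$loci), " loci\n", sep = "")
  if (nrow(ind)) {
    cat("  queens: ", sum(ind$caste == "queen"),
        ", workers: ", sum(ind$caste == "worker"),
        ", triploid: ", sum(ind$triploid),
        ", low coverage (<", x$min_loci, " loci): ",
        sum(ind$low_coverage), "\n", sep = "")
  }
  invisible(x)
}

#' Subset a genotype table by colony
#'
#' @param table A [genotype_table()].
#' @param colony_id Colony identifier(s) to keep.
#' @return A `genotype_table` restricted to the given colonies.
#' @export
subset_colony <- function(table, colony_id) {
  stopifnot(inherits(table, "genotype_table"))
  keep <- table$individuals$colony_id %in% colony_id
  out <- table
  out$individuals <- table$individuals[keep, , drop = FALSE]
  rownames(out$individuals) <- NULL
  out
}

#' Colony identifiers of a table
#'
#' @param table A [genotype_table()].
#' @return Character vector of colony ids in order of first appearance.
#' @export
colony_ids <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  unique(as.character(table$individuals$colony_id))
}

# fetch one individual's genotype (named list) by id
get_genotype <- function(table, id) {
  i <- match(id, table$individuals$individual_id)
  if (is.na(i)) stop("unknown individual id: ", id)
  table$individuals$genotype[[i]]
}

# a diploid view of one genotype: single calls doubled, triploids must be
# collapsed beforehand
as_diploid_pairs <- function(g) {
  lapply(g, function(a) {
    if (length(a) == 1L) c(a, a)
    else if (length(a) == 2L) a
    else stop("triploid locus: collapse with collapse_triploid() first")
  })
}
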