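#' Microsatellite locus panel
#'
#' A `locus_panel` records the ordered set of locus names used in a study
#' together with the registry of allele sizes (integer sizes in base pairs)
#' observed at each locus. Allele identity is by integer size only; input
#' data are assumed pre-binned.
#'
#' @param loci Character vector of unique locus names.
#' @param alleles Optional named list mapping each locus to an integer
#'   vector of observed allele sizes. Loci without an entry start with an
#'   empty registry.
#'
#' @return An object of class `locus_panel` with elements `loci` and
#'   `alleles`.
#' @examples
#' locus_panel(c("L1", "L2"), list(L1 = c(100L, 104L)))
#' @export
locus_panel <- function(loci, alleles = NULL) {
  loci <- as.character(loci)
  if (anyDuplicated(loci)) {
    stop("locus names must be unique")
  }
  reg <- stats::setNames(vector("list", length(loci)), loci)
  for (l in loci) reg[[l]] <- integer(0)
  if (!is.null(alleles)) {
    if (is.null(names(alleles)) || !all(names(alleles) %in% loci)) {
      stop("'alleles' must be a named list over panel loci")
    }
    for (l in names(alleles)) {
      a <- as.integer(alleles[[l]])
      if (any(is.na(a)) || any(a <= 0)) {
        stop("allele sizes must be positive integers (locus ", l, ")")
      }
      reg[[l]] <- sort(unique(a))
    }
  }
  structure(list(loci = loci, alleles = reg), class = "locus_panel")
}

#' The default eight-locus panel
#'
#' The eight highly variable microsatellite loci used throughout the
#' package (LXAGa1, LXAGa2, L-18, LXGT218, LXGT223, 2MS34, 2MS46,
#' Ant10878), with the study-level allele counts 5, 22, 12, 4, 23, 14, 8
#' and 5. The allele registry is left empty; registries are filled from
#' data or by the simulator.
#'
#' @return A `locus_panel` of eight loci.
#' @export
default_panel <- function() {
  locus_panel(c("LXAGa1", "LXAGa2", "L-18", "LXGT218",
                "LXGT223", "2MS34", "2MS46", "Ant10878"))
}

#' Allele counts of the default panel
#'
#' @return Named integer vector: number of distinct alleles per locus of
#'   [default_panel()].
#' @export
default_allele_counts <- function() {
  stats::setNames(c(5L, 22L, 12L, 4L, 23L, 14L, 8L, 5L),
                  default_panel()$loci)
}

#' @export
print.locus_panel <- function(x, ...) {
  n <- vapply(x$alleles, length, integer(1))
  cat("<locus_panel> ", length(x$loci), " loci\n", sep = "")
  for (i in seq_along(x$loci)) {
    cat("  ", x$loci[i], ": ", n[i], " registered alleles\n", sep = "")
  }
  invisible(x)
}

# register alleles seen in a set of genotypes into the panel
register_alleles <- function(panel, genotypes) {
  for (g in genotypes) {
    for (l in names(g)) {
      a <- g[[l]]
      if (length(a)) {
        panel$alleles[[l]] <- sort(unique(c(panel$alleles[[l]],
                                            as.integer(a))))
      }
    }
  }
  panel
}
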