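#' Read a tidy genotype CSV
#'
#' The expected format is one row per individual x locus with header
#' columns `colony`, `individual`, `caste`, `ovary_status`, `locus`,
#' `allele1`, `allele2` and optionally `allele3` and `mito_haplotype`.
#' A missing allele call is encoded as 0 or an empty field. Individuals
#' typed at fewer than `min_loci` loci are retained but flagged, not
#' dropped.
#'
#' @param path Path to the CSV file.
#' @param panel Optional [locus_panel()]; by default the panel is built
#'   from the loci present in the file (in order of first appearance),
#'   or [default_panel()] for a header-only file.
#' @param min_loci Minimum typed loci for full inclusion (default 7).
#' @return A [genotype_table()].
#' @seealso [write_genotype_table()], [export_genepop()]
#' @export
read_genotype_table <- function(path, panel = NULL, min_loci = 7L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  req <- c("colony", "individual", "caste", "ovary_status", "locus",
           "allele1", "allele2")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("malformed genotype CSV, missing column(s): ",
         paste(miss, collapse = ", "))
  }
  has_a3 <- "allele3" %in% names(df)
  has_mito <- "mito_haplotype" %in% names(df)
  if (!nrow(df)) {
    if (is.null(panel)) panel <- default_panel()
    empty <- data.frame(individual_id = character(0),
                        colony_id = character(0),
                        caste = character(0),
                        ovary_status = character(0),
                        stringsAsFactors = FALSE)
    empty$genotype <- list()
    return(genotype_table(empty, panel, min_loci = min_loci))
  }

  parse_allele <- function(x, line) {
    x <- trimws(x)
    if (!length(x) || is.na(x) || x == "" || x == "0") return(NA_integer_)
    a <- suppressWarnings(as.integer(x))
    if (is.na(a) || a < 0) {
      stop("parse error at line ", line, ": bad allele value '", x, "'")
    }
    a
  }
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  if (any(!nzchar(trimws(df$individual)) | !nzchar(trimws(df$colony)) |
          !nzchar(trimws(df$locus)))) {
    bad <- lines[!nzchar(trimws(df$individual)) |
                   !nzchar(trimws(df$colony)) |
                   !nzchar(trimws(df$locus))][1]
    stop("parse error at line ", bad,
         ": empty colony, individual or locus field")
  }
  dup <- duplicated(df[, c("individual", "locus")])
  if (any(dup)) {
    stop("duplicate (individual, locus) row at line ", lines[dup][1],
         ": ", df$individual[dup][1], " / ", df$locus[dup][1])
  }

  loci_seen <- unique(df$locus)
  if (is.null(panel)) {
    panel <- locus_panel(loci_seen)
  } else {
    unknown <- setdiff(loci_seen, panel$loci)
    if (length(unknown)) {
      stop("loci not in supplied panel: ",
           paste(unknown, collapse = ", "))
    }
  }

  ids <- unique(df$individual)
  rows <- lapply(ids, function(id) {
    sub <- df[df$individual == id, , drop = FALSE]
    subl <- lines[df$individual == id]
    if (length(unique(sub$colony)) > 1L) {
      stop("individual ", id, " appears in more than one colony")
    }
    g <- list()
    for (j in seq_len(nrow(sub))) {
      a <- c(parse_allele(sub$allele1[j], subl[j]),
             parse_allele(sub$allele2[j], subl[j]),
             if (has_a3) parse_allele(sub$allele3[j], subl[j])
             else NA_integer_)
      a <- a[!is.na(a)]
      if (length(a)) g[[sub$locus[j]]] <- sort(a)
    }
    list(individual_id = id,
         colony_id = sub$colony[1],
         caste = sub$caste[1],
         ovary_status = sub$ovary_status[1],
         mito_haplotype = if (has_mito && nzchar(sub$mito_haplotype[1]))
           sub$mito_haplotype[1] else NA_character_,
         genotype = g)
  })
  ind <- data.frame(
    individual_id = vapply(rows, `[[`, character(1), "individual_id"),
    colony_id = vapply(rows, `[[`, character(1), "colony_id"),
    caste = vapply(rows, `[[`, character(1), "caste"),
    ovary_status = vapply(rows, `[[`, character(1), "ovary_status"),
    mito_haplotype = vapply(rows, `[[`, character(1), "mito_haplotype"),
    stringsAsFactors = FALSE)
  ind$genotype <- lapply(rows, `[[`, "genotype")
  genotype_table(ind, panel, min_loci = min_loci)
}

#' Write a genotype table as tidy CSV
#'
#' Inverse of [read_genotype_table()]: one row per individual x locus in
#' panel order, missing calls written as 0. Loci entirely missing for an
#' individual are written too, so missingness round-trips.
#'
#' @param table A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  ind <- table$individuals
  loci <- table$panel$loci
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(ind))) {
    g <- ind$genotype[[i]]
    for (l in loci) {
      a <- if (!is.null(g[[l]])) g[[l]] else integer(0)
      a <- c(a, rep(0L, 3L - length(a)))
      k <- k + 1L
      out[[k]] <- data.frame(
        colony = ind$colony_id[i], individual = ind$individual_id[i],
        caste = ind$caste[i], ovary_status = ind$ovary_status[i],
        mito_haplotype = ifelse(is.na(ind$mito_haplotype[i]), "",
                                ind$mito_haplotype[i]),
        locus = l, allele1 = a[1], allele2 = a[2], allele3 = a[3],
        stringsAsFactors = FALSE)
    }
  }
  df <- if (k) do.call(rbind, out) else
    data.frame(colony = character(0), individual = character(0),
               caste = character(0), ovary_status = character(0),
               mito_haplotype = character(0), locus = character(0),
               allele1 = integer(0), allele2 = integer(0),
               allele3 = integer(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a genotype table in GenePop format
#'
#' Writes the GenePop 4 dialect: a title line, one locus name per line,
#' then one `Pop` block per colony with comma-terminated individual ids
#' and space-separated 6-digit diploid genotypes (two 3-digit allele
#' codes; missing = 000). Allele sizes above 999 are re-coded through a
#' per-locus size-rank map so that codes stay within 3 digits.
#'
#' @param table A [genotype_table()]; must contain no triploid
#'   individuals (collapse them first, see [collapse_triploid()]).
#' @param path Output file path.
#' @param one_worker_per_colony If `TRUE`, emit only the first worker
#'   (by id order) of each colony, the usual input for
#'   Hardy-Weinberg / linkage checks on colonial data.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
export_genepop <- function(table, path, one_worker_per_colony = FALSE,
                           title = "queenline export") {
  stopifnot(inherits(table, "genotype_table"))
  ind <- table$individuals
  if (nrow(ind) && any(ind$triploid)) {
    stop("triploid individuals present; collapse them before GenePop ",
         "export")
  }
  loci <- table$panel$loci
  # 3-digit coding: allele size if < 1000, else rank within the locus
  code_map <- lapply(loci, function(l) {
    reg <- table$panel$alleles[[l]]
    if (!length(reg)) return(integer(0))
    if (max(reg) <= 999L) stats::setNames(reg, reg)
    else {
      if (length(reg) > 999L) stop("locus ", l,
                                   ": more than 999 alleles cannot be ",
                                   "3-digit coded")
      stats::setNames(seq_along(reg), reg)
    }
  })
  names(code_map) <- loci
  fmt <- function(g, l) {
    a <- g[[l]]
    if (is.null(a) || !length(a)) return("000000")
    if (length(a) == 1L) a <- c(a, a)
    codes <- code_map[[l]][as.character(a)]
    sprintf("%03d%03d", codes[1], codes[2])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (cid in unique(ind$colony_id)) {
    writeLines("Pop", con)
    sub <- ind[ind$colony_id == cid, , drop = FALSE]
    if (one_worker_per_colony) {
      w <- sub[sub$caste == "worker", , drop = FALSE]
      if (!nrow(w)) next
      sub <- w[order(w$individual_id)[1], , drop = FALSE]
    }
    for (i in seq_len(nrow(sub))) {
      gl <- vapply(loci, function(l) fmt(sub$genotype[[i]], l),
                   character(1))
      writeLines(paste0(sub$individual_id[i], " ,  ",
                        paste(gl, collapse = " ")), con)
    }
  }
  invisible(path)
}
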