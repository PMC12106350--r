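#' Classify queens of a reconstructed colony
#'
#' Assigns each identified queen one of the four types used to encode
#' colony genetic structure:
#' * type `1` — former mother: a reliably reconstructed mother genotype
#'   matching no collected queen (a virtual queen, detectable only
#'   through her offspring);
#' * type `2a` — collected queen with developed ovaries matched as a
#'   mother of sampled offspring;
#' * type `2b` — collected queen with developed ovaries but no sampled
#'   offspring;
#' * type `3` — collected queen with undeveloped ovaries, regardless of
#'   relatedness.
#' Collected queens with unknown ovary status are unclassifiable and
#' reported with type `NA`.
#'
#' @param recon A [reconstruct_colony()] result.
#' @param table The [genotype_table()] the reconstruction came from.
#' @return Object of class `queen_classification`: `queens`, a
#'   data.frame with `colony_id`, `queen_id`, `type`, `virtual`
#'   (type-1 mothers), `match_status` and a `genotype` list column
#'   (reconstructed genotype for virtual mothers, observed otherwise);
#'   plus `extra_queen_count` carried through from the reconstruction.
#' @export
classify_queens <- function(recon, table) {
  stopifnot(inherits(recon, "colony_reconstruction"),
            inherits(table, "genotype_table"))
  sub <- collapse_triploid(subset_colony(table, recon$colony_id))
  ind <- sub$individuals
  queens <- ind[ind$caste == "queen", , drop = FALSE]
  match <- recon$queen_match
  developed <- queens$individual_id[queens$ovary_status ==
                                      "developed"]
  matched_sibs <- match$matched_sibship[
    match$status == "is_a_reconstructed_mother" &
      match$queen_id %in% developed]

  rows <- list()
  # virtual type-1 former mothers: emitted mothers without a match
  vi <- 0L
  for (m in recon$mothers) {
    if (m$sibship %in% matched_sibs) next
    vi <- vi + 1L
    rows[[length(rows) + 1L]] <- list(
      colony_id = recon$colony_id,
      queen_id = paste0(recon$colony_id, "_M", m$sibship),
      type = "1", virtual = TRUE, match_status = NA_character_,
      genotype = m$genotype)
  }
  for (i in seq_len(nrow(queens))) {
    qid <- queens$individual_id[i]
    st <- match$status[match$queen_id == qid]
    st <- if (length(st)) st[1] else NA_character_
    ov <- queens$ovary_status[i]
    type <- if (ov == "unknown") NA_character_
    else if (ov == "undeveloped") "3"
    else if (identical(st, "is_a_reconstructed_mother")) "2a"
    else "2b"
    rows[[length(rows) + 1L]] <- list(
      colony_id = recon$colony_id, queen_id = qid, type = type,
      virtual = FALSE, match_status = st,
      genotype = queens$genotype[[i]])
  }
  df <- data.frame(
    colony_id = vapply(rows, `[[`, "", "colony_id"),
    queen_id = vapply(rows, `[[`, "", "queen_id"),
    type = vapply(rows, `[[`, "", "type"),
    virtual = vapply(rows, `[[`, logical(1), "virtual"),
    match_status = vapply(rows, `[[`, "", "match_status"),
    stringsAsFactors = FALSE)
  df$genotype <- lapply(rows, `[[`, "genotype")
  structure(list(queens = df,
                 extra_queen_count = recon$extra_queen_count,
                 ambiguous = recon$ambiguous),
            class = "queen_classification")
}

#' @export
print.queen_classification <- function(x, ...) {
  tt <- table(factor(x$queens$type, levels = c("1", "2a", "2b", "3")))
  cat("<queen_classification> ",
      paste(names(tt), tt, sep = ":", collapse = " "),
      " extra:", x$extra_queen_count, "\n", sep = " ")
  invisible(x)
}

#' Classify a nest from its queen types
#'
#' Nest types encode how offspring production is distributed:
#' * `A` — exactly one queen ever contributed to the sampled offspring
#'   (functional monogyny in the strict single-contributor sense);
#' * `B` — two or more contributors are still present in the nest
#'   (at least two type-2a queens);
#' * `C` — two or more queens contributed but at most one of them is
#'   present (turnover: contributors are mostly former mothers).
#' Contributors are the reliably reconstructed mothers (types 1 and
#' 2a) plus the additional queens required to explain genotypes of
#' small sibships; the latter can never count as "present".
#' A colony with zero identified contributors is `"unclassified"`.
#'
#' @param queen_types Character vector of queen types (`"1"`, `"2a"`,
#'   `"2b"`, `"3"`, `NA`), e.g. the `type` column of
#'   [classify_queens()].
#' @param extra_queen_count Additional queens required to explain
#'   genotypes (default 0).
#' @return `"A"`, `"B"`, `"C"` or `"unclassified"`.
#' @export
classify_nest <- function(queen_types, extra_queen_count = 0L) {
  n1 <- sum(queen_types == "1", na.rm = TRUE)
  n2a <- sum(queen_types == "2a", na.rm = TRUE)
  contributors <- n1 + n2a + extra_queen_count
  if (contributors == 0L) return("unclassified")
  if (contributors == 1L) return("A")
  if (n2a >= 2L) return("B")
  "C"
}

#' Classify every colony of a reconstructed table
#'
#' Applies [classify_queens()] and [classify_nest()] per colony. When
#' a colony admits several structurally distinct minimal partitions,
#' each partition is classified; if the resulting nest types disagree
#' the colony is reported as `"ambiguous"` (the analysis-exclusion
#' signal; queen types are reported from the first partition).
#'
#' @param recons Named list from [reconstruct_colonies()].
#' @param table The [genotype_table()].
#' @param freqs Unused; kept so pipeline calls can pass one set of
#'   frequencies throughout.
#' @return List with `summary` (data.frame: `colony_id`, `nest_type`,
#'   `n_type1`, `n_type2a`, `n_type2b`, `n_type3`, `n_unclassifiable`,
#'   `extra_queens`, `ambiguous`) and `queens` (row-bound
#'   [classify_queens()] tables).
#' @export
classify_colonies <- function(recons, table, freqs = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  qrows <- list()
  srows <- list()
  for (cid in names(recons)) {
    recon <- recons[[cid]]
    cls <- classify_queens(recon, table)
    nests <- unique(recon$nest_by_partition[recon$considered])
    nest <- if (length(nests) > 1L) "ambiguous" else nests[1]
    tt <- cls$queens$type
    srows[[length(srows) + 1L]] <- data.frame(
      colony_id = cid, nest_type = nest,
      n_type1 = sum(tt == "1", na.rm = TRUE),
      n_type2a = sum(tt == "2a", na.rm = TRUE),
      n_type2b = sum(tt == "2b", na.rm = TRUE),
      n_type3 = sum(tt == "3", na.rm = TRUE),
      n_unclassifiable = sum(is.na(tt)),
      extra_queens = recon$extra_queen_count,
      ambiguous = recon$ambiguous, stringsAsFactors = FALSE)
    qrows[[length(qrows) + 1L]] <- cls$queens
  }
  list(summary = if (length(srows)) do.call(rbind, srows)
       else data.frame(),
       queens = if (length(qrows)) do.call(rbind, qrows)
       else data.frame())
}
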