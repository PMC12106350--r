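#' Pipeline run configuration
#'
#' Bundles every stage parameter of the simulate/reconstruct/classify/
#' relatedness pipeline into one flat object, so a run is fully
#' described (and reproducible) from its configuration alone.
#'
#' @param input Optional path to a tidy genotype CSV; when `NULL` the
#'   dataset is simulated from `sim`.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param min_offspring,threshold,require_unique Reconstruction
#'   parameters, see [reconstruct_colony()].
#' @param pool Frequency pool, see [estimate_allele_frequencies()].
#' @param collapse_rule Triploid collapse rule, see
#'   [collapse_triploid()].
#' @param split_2a2b Split type-2 queens into 2a/2b in pair categories.
#' @param seed Seed recorded in every output; defaults to `sim$seed`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = sim_config(),
                       out_dir = tempfile("queenline_run_"),
                       min_offspring = 3L, threshold = 0.25,
                       require_unique = TRUE, pool = "all",
                       collapse_rule = "smallest_two",
                       split_2a2b = FALSE, seed = NULL) {
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  structure(list(input = input, sim = sim, out_dir = out_dir,
                 min_offspring = as.integer(min_offspring),
                 threshold = threshold,
                 require_unique = require_unique, pool = pool,
                 collapse_rule = collapse_rule,
                 split_2a2b = split_2a2b,
                 seed = as.integer(seed %||% sim$seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a genotype table, reconstructs every colony's
#' minimal sibship structure, classifies queens and nests, computes the
#' within-nest queen pair relatedness table, and writes all stage
#' outputs plus a machine-readable summary into the run directory.
#' Re-running with the same configuration and seed produces
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `table`, `truth` (when simulated),
#'   `freqs`, `recons`, `classes`, `pairs`, `report` and `out_dir`.
#'   Files written: `data.csv`, `truth.json` (simulated runs only),
#'   `recon.json`, `classes.csv`, `pairs.csv`, `report.json`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[queenline] ", ...)

  truth <- NULL
  if (is.null(config$input)) {
    say("simulating ", config$sim$n_colonies, " colonies (seed ",
        config$seed, ")")
    sim <- config$sim
    sim$seed <- config$seed
    ds <- generate_dataset(sim)
    table <- ds$table
    truth <- ds$truth
    write_genotype_table(table, file.path(config$out_dir, "data.csv"))
    .write_json(.truth_to_json(truth),
                file.path(config$out_dir, "truth.json"))
  } else {
    say("reading ", config$input)
    table <- read_genotype_table(config$input)
    write_genotype_table(table, file.path(config$out_dir, "data.csv"))
  }

  n_col <- length(colony_ids(table))
  if (n_col == 0L) {
    say("empty table; writing empty outputs")
    empty_classes <- data.frame(colony_id = character(0),
                                nest_type = character(0))
    utils::write.csv(empty_classes,
                     file.path(config$out_dir, "classes.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(),
                     file.path(config$out_dir, "pairs.csv"),
                     row.names = FALSE)
    report <- list(seed = config$seed, n_colonies = 0L,
                   nest_types = list(), queen_types = list(),
                   relatedness = list(),
                   ambiguous_colonies = character(0))
    .write_json(report, file.path(config$out_dir, "report.json"))
    .write_json(list(), file.path(config$out_dir, "recon.json"))
    return(invisible(list(table = table, truth = truth, freqs = NULL,
                          recons = list(),
                          classes = list(summary = empty_classes),
                          pairs = data.frame(), report = report,
                          out_dir = config$out_dir)))
  }

  freqs <- estimate_allele_frequencies(table, pool = config$pool)
  say("reconstructing ", n_col, " colonies")
  recons <- reconstruct_colonies(
    table, freqs = freqs, min_offspring = config$min_offspring,
    threshold = config$threshold,
    require_unique = config$require_unique,
    collapse_rule = config$collapse_rule)
  .write_json(.recons_to_json(recons),
              file.path(config$out_dir, "recon.json"))

  say("classifying queens and nests")
  classes <- classify_colonies(recons, table, freqs = freqs)
  cls_out <- classes$summary
  utils::write.csv(cls_out, file.path(config$out_dir, "classes.csv"),
                   row.names = FALSE)

  say("computing pairwise queen relatedness")
  pairs <- pairwise_queen_relatedness(classes$queens, freqs,
                                      split_2a2b = config$split_2a2b)
  utils::write.csv(pairs[, setdiff(names(pairs), "genotype")],
                   file.path(config$out_dir, "pairs.csv"),
                   row.names = FALSE)

  rel_summary <- lapply(split(pairs$r, pairs$category), function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(list(n = 0L))
    q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = length(r), q25 = q[1], median = q[2], q75 = q[3])
  })
  report <- list(
    seed = config$seed,
    n_colonies = n_col,
    nest_types = as.list(table(factor(
      cls_out$nest_type,
      levels = c("A", "B", "C", "unclassified", "ambiguous")))),
    queen_types = list(
      n_type1 = sum(cls_out$n_type1),
      n_type2a = sum(cls_out$n_type2a),
      n_type2b = sum(cls_out$n_type2b),
      n_type3 = sum(cls_out$n_type3),
      n_extra = sum(cls_out$extra_queens)),
    relatedness = rel_summary,
    n_pairs = nrow(pairs),
    ambiguous_colonies =
      cls_out$colony_id[cls_out$ambiguous |
                          cls_out$nest_type == "ambiguous"])
  .write_json(report, file.path(config$out_dir, "report.json"))
  say("done: ", config$out_dir)
  invisible(list(table = table, truth = truth, freqs = freqs,
                 recons = recons, classes = classes, pairs = pairs,
                 report = report, out_dir = config$out_dir))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
}

.truth_to_json <- function(truth) {
  lapply(truth, function(tr) {
    list(colony_id = tr$colony_id,
         breeder_set = as.list(tr$breeder_set),
         true_queen_types = as.list(tr$true_queen_types),
         true_nest_type = tr$true_nest_type,
         turnover = tr$turnover,
         triploid_brood = tr$triploid_brood,
         offspring_of = as.list(tr$offspring_of),
         pedigree = tr$pedigree)
  })
}

.recons_to_json <- function(recons) {
  lapply(recons, function(r) {
    list(colony_id = r$colony_id,
         min_sibships = r$min_sibships,
         n_minimal_partitions = length(r$partitions),
         ambiguous = r$ambiguous,
         partitions = lapply(r$partitions, function(p)
           lapply(p, as.list)),
         mothers = lapply(r$mothers, function(m) {
           list(sibship = m$sibship, members = as.list(m$members),
                genotype = lapply(m$genotype, as.list))
         }),
         extra_queen_count = r$extra_queen_count,
         queen_match = r$queen_match)
  })
}

#' Ground-truth sibship partition of a simulated colony
#'
#' Groups every sampled individual of a colony by its true mother;
#' individuals with no in-colony mother (adopted queens, the collected
#' founding queen herself) form singleton groups, matching how the
#' reconstruction must account for them.
#'
#' @param truth One colony's truth record from [simulate_colony()].
#' @return List of character vectors of individual ids.
#' @export
true_sibship_partition <- function(truth) {
  ped <- truth$pedigree
  key <- ifelse(is.na(ped$mother_id),
                paste0("self:", ped$individual_id), ped$mother_id)
  unname(split(ped$individual_id, key))
}

#' Simulation-based recovery study
#'
#' Measures how well the reconstruction recovers the simulated truth
#' across one or more scenario configurations: the fraction of colonies
#' whose true number of distinct parental groups is recovered exactly,
#' the fraction where the reconstructed minimum does not exceed the
#' truth (a logical guarantee of minimization), the ambiguity rate, and
#' queen-type and nest-type confusion matrices.
#'
#' @param configs A [sim_config()] or list of them (scenarios).
#' @param reps Dataset replicates per scenario.
#' @param seed Base seed; replicate `r` of scenario `s` uses
#'   `seed + 1000 * (s - 1) + r`.
#' @param ... Passed to [reconstruct_colonies()].
#' @return Data.frame (one row per scenario) with columns `scenario`,
#'   `n_colonies`, `frac_exact`, `frac_le_true`, `ambiguity_rate`,
#'   `frac_nest_correct`; attributes `queen_confusion` and
#'   `nest_confusion` hold per-scenario confusion matrices.
#' @export
recovery_study <- function(configs, reps = 1L, seed = 1L, ...) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  if (reps == 0L) {
    return(data.frame(scenario = integer(0), n_colonies = integer(0),
                      frac_exact = numeric(0),
                      frac_le_true = numeric(0),
                      ambiguity_rate = numeric(0),
                      frac_nest_correct = numeric(0)))
  }
  rows <- list()
  qconf <- list()
  nconf <- list()
  for (s in seq_along(configs)) {
    exact <- 0L; le <- 0L; amb <- 0L; total <- 0L
    nest_ok <- 0L; nest_n <- 0L
    qc <- table(factor(character(0),
                       levels = c("1", "2a", "2b", "3")),
                factor(character(0),
                       levels = c("1", "2a", "2b", "3", "missed")))
    nc <- table(factor(character(0),
                       levels = c("A", "B", "C", "unclassified")),
                factor(character(0),
                       levels = c("A", "B", "C", "unclassified",
                                  "ambiguous")))
    for (r in seq_len(reps)) {
      cfg <- configs[[s]]
      cfg$seed <- seed + 1000L * (s - 1L) + r
      ds <- generate_dataset(cfg)
      freqs <- estimate_allele_frequencies(ds$table)
      recons <- reconstruct_colonies(ds$table, freqs = freqs, ...)
      classes <- classify_colonies(recons, ds$table, freqs = freqs)
      for (cid in names(recons)) {
        tr <- ds$truth[[cid]]
        true_k <- length(true_sibship_partition(tr))
        got_k <- recons[[cid]]$min_sibships
        total <- total + 1L
        if (got_k == true_k) exact <- exact + 1L
        if (got_k <= true_k) le <- le + 1L
        if (recons[[cid]]$ambiguous) amb <- amb + 1L
        srow <- classes$summary[classes$summary$colony_id == cid, ]
        nest_n <- nest_n + 1L
        if (srow$nest_type[1] == tr$true_nest_type) {
          nest_ok <- nest_ok + 1L
        }
        nc_true <- factor(tr$true_nest_type,
                          levels = rownames(nc))
        nc_got <- factor(srow$nest_type[1], levels = colnames(nc))
        if (!is.na(nc_true) && !is.na(nc_got)) {
          nc[nc_true, nc_got] <- nc[nc_true, nc_got] + 1L
        }
        got_types <- classes$queens[
          classes$queens$colony_id == cid, ]
        for (qid in names(tr$true_queen_types)) {
          tt <- tr$true_queen_types[[qid]]
          gt <- got_types$type[got_types$queen_id == qid]
          gt <- if (length(gt)) gt[1] else "missed"
          ft <- factor(tt, levels = rownames(qc))
          fg <- factor(if (is.na(gt)) "missed" else gt,
                       levels = colnames(qc))
          if (!is.na(ft) && !is.na(fg)) {
            qc[ft, fg] <- qc[ft, fg] + 1L
          }
        }
      }
    }
    rows[[s]] <- data.frame(
      scenario = s, n_colonies = total,
      frac_exact = exact / total, frac_le_true = le / total,
      ambiguity_rate = amb / total,
      frac_nest_correct = nest_ok / max(nest_n, 1L))
    qconf[[s]] <- qc
    nconf[[s]] <- nc
  }
  out <- do.call(rbind, rows)
  attr(out, "queen_confusion") <- qconf
  attr(out, "nest_confusion") <- nconf
  out
}
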