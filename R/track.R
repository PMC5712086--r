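load_ontology_file <- function(path, ontology_id) {
  if (grepl("\\.obo$", path, ignore.case = TRUE))
    parse_obo(path, ontology_id = ontology_id)
  else parse_edgelist(path, ontology_id = ontology_id)
}

load_alignment_file <- function(path, system_name, family = system_name) {
  if (grepl("\\.(rdf|xml)$", path, ignore.case = TRUE))
    parse_rdf_alignment(path, system_name, family)
  else parse_tsv_alignment(path, system_name, family)
}

#' Read a track configuration file
#'
#' YAML with keys: \code{ontology1}, \code{ontology2} (OBO or edge-list
#' paths), \code{systems} (list of \code{name}/\code{family}/\code{path}),
#' optional \code{baseline} and \code{curated} alignment paths,
#' \code{vote_thresholds} (default 2 and 3), \code{assessment_cap}
#' (default 30), \code{seed} (default 1) and \code{output_dir}.
#'
#' @param path YAML file.
#' @return a validated config list.
#' @export
read_track_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
    else file.path(base, p)
  cfg$ontology1 <- resolve(cfg$ontology1)
  cfg$ontology2 <- resolve(cfg$ontology2)
  cfg$baseline <- resolve(cfg$baseline)
  cfg$curated <- resolve(cfg$curated)
  for (i in seq_along(cfg$systems))
    cfg$systems[[i]]$path <- resolve(cfg$systems[[i]]$path)
  validate_track_config(cfg)
}

validate_track_config <- function(cfg) {
  if (is.null(cfg$vote_thresholds)) cfg$vote_thresholds <- c(2, 3)
  if (is.null(cfg$assessment_cap)) cfg$assessment_cap <- 30
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$output_dir)) cfg$output_dir <- "track-results"
  if (length(cfg$systems) < 1) stop("config lists no systems", call. = FALSE)
  if (any(cfg$vote_thresholds < 1))
    stop("vote thresholds must be >= 1", call. = FALSE)
  for (p in c(cfg$ontology1, cfg$ontology2, cfg$baseline, cfg$curated,
              vapply(cfg$systems, `[[`, character(1), "path")))
    if (!is.null(p) && !file.exists(p))
      stop("configured file not found: ", p, call. = FALSE)
  for (i in seq_along(cfg$systems))
    if (is.null(cfg$systems[[i]]$family))
      cfg$systems[[i]]$family <- cfg$systems[[i]]$name
  cfg
}

fmt2 <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", round_half_up(x)))

write_fixed_table <- function(df, path) {
  cols <- vapply(seq_along(df), function(j) {
    v <- c(names(df)[j], as.character(df[[j]]))
    formatC(v, width = max(nchar(v)) + 2, flag = "-")
  }, character(nrow(df) + 1))
  writeLines(sub("\\s+$", "", apply(cols, 1, paste0, collapse = "")), path)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Run the full track evaluation
#'
#' Executes the whole evaluation procedure from a configuration: load the
#' ontology pair and the system alignments; build the family vote table
#' and the consensus alignments at each configured threshold; check the
#' coherence of every aligned ontology; score every system (and the
#' baseline, recall-only) against each consensus with semantic precision,
#' recall and F-measure; score systems against the curated alignment
#' (standard and semantic recall) when one is supplied; extract each
#' system's unique equivalence mappings relative to the vote-2 consensus
#' and write seeded review sheets capped at the assessment workload; and
#' emit CSV plus aligned-text report tables, the consensus alignments in
#' both mapping formats, a structured log, and a JSON manifest with input
#' hashes. Given one seed the whole bundle is byte-identical across runs.
#'
#' @param config a [read_track_config()] list or a path to the YAML file.
#' @return invisibly, a list with the in-memory results (consensus
#'   alignments, metric reports, unique sets, manifest).
#' @export
run_track <- function(config) {
  cfg <- if (is.character(config)) read_track_config(config)
    else validate_track_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  o1 <- load_ontology_file(cfg$ontology1, "O1")
  o2 <- load_ontology_file(cfg$ontology2, "O2")
  say("loaded ontology 1: %d classes, %d subsumptions",
      length(o1$classes), nrow(o1$subsumptions))
  say("loaded ontology 2: %d classes, %d subsumptions",
      length(o2$classes), nrow(o2$subsumptions))

  systems <- lapply(cfg$systems, function(s)
    load_alignment_file(s$path, s$name, s$family))
  for (s in systems)
    say("loaded system %s (family %s): %d mappings",
        s$system_name, s$family, nrow(s$mappings))
  baseline <- if (!is.null(cfg$baseline))
    load_alignment_file(cfg$baseline, "BioPortal-baseline", "baseline")
  curated <- if (!is.null(cfg$curated))
    load_alignment_file(cfg$curated, "curated", "curated")

  vt <- build_vote_table(systems)
  sweep <- threshold_sweep(vt)
  write_csv_plain(sweep, file.path(out, "consensus_sweep.csv"))
  write_fixed_table(sweep, file.path(out, "consensus_sweep.txt"))
  say("vote table: %d family votes over %d families", nrow(vt),
      length(attr(vt, "families")))

  cons <- lapply(cfg$vote_thresholds, function(v) consensus(vt, v))
  names(cons) <- sprintf("v%d", cfg$vote_thresholds)
  for (cv in cons) {
    write_rdf_alignment(cv, file.path(out, paste0(cv$system_name, ".rdf")))
    write_tsv_alignment(cv, file.path(out, paste0(cv$system_name, ".tsv")))
    say("consensus %s: %d mappings", cv$system_name, nrow(cv$mappings))
  }

  # per-system semantic P/R/F against each consensus
  rows <- lapply(systems, function(s) {
    row <- list(System = s$system_name, Mappings = nrow(s$mappings))
    for (v in cfg$vote_thresholds) {
      cv <- cons[[sprintf("v%d", v)]]
      rep <- if (nrow(cv$mappings) > 0)
        evaluate(s, cv, o1, o2, mode = "semantic")
      else report(s, cv, nrow(s$mappings), NA_real_, NA_real_, TRUE,
                  "empty consensus")
      if (nzchar(rep$notes)) say("%s vs %s: %s", s$system_name,
                                 cv$system_name, rep$notes)
      row[[sprintf("Precision.%d", v)]] <- fmt2(rep$precision)
      row[[sprintf("F.Measure.%d", v)]] <- fmt2(rep$f_measure)
      row[[sprintf("Recall.%d", v)]] <- fmt2(rep$recall)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(baseline) && nrow(baseline$mappings) > 0) {
    brow <- list(System = "BioPortal (baseline)",
                 Mappings = nrow(baseline$mappings))
    for (v in cfg$vote_thresholds) {
      cv <- cons[[sprintf("v%d", v)]]
      rep <- if (nrow(cv$mappings) > 0)
        evaluate(baseline, cv, o1, o2, mode = "semantic")
      else report(baseline, cv, nrow(baseline$mappings), NA_real_, NA_real_,
                  TRUE, "empty consensus")
      brow[[sprintf("Precision.%d", v)]] <- fmt2(rep$precision)
      brow[[sprintf("F.Measure.%d", v)]] <- fmt2(rep$f_measure)
      brow[[sprintf("Recall.%d", v)]] <- fmt2(rep$recall)
    }
    res <- rbind(res, as.data.frame(brow, stringsAsFactors = FALSE))
  }
  write_csv_plain(res, file.path(out, "consensus_results.csv"))
  write_fixed_table(res, file.path(out, "consensus_results.txt"))

  # baseline recall-only table (systems scored against the baseline)
  if (!is.null(baseline) && nrow(baseline$mappings) > 0) {
    brows <- lapply(systems, function(s) {
      rep <- evaluate(s, baseline, o1, o2, mode = "baseline")
      data.frame(System = s$system_name,
                 Semantic.Recall = fmt2(rep$recall),
                 stringsAsFactors = FALSE)
    })
    bres <- do.call(rbind, brows)
    write_csv_plain(bres, file.path(out, "baseline_recall.csv"))
    write_fixed_table(bres, file.path(out, "baseline_recall.txt"))
  }

  # curated alignment: standard + semantic recall
  if (!is.null(curated) && nrow(curated$mappings) > 0) {
    crows <- lapply(systems, function(s) {
      std <- standard_prf(s, curated)
      sem <- evaluate(s, curated, o1, o2, mode = "baseline")
      data.frame(System = s$system_name,
                 Standard.Recall = fmt2(std$recall),
                 Semantic.Recall = fmt2(sem$recall),
                 stringsAsFactors = FALSE)
    })
    cres <- do.call(rbind, crows)
    write_csv_plain(cres, file.path(out, "curated_recall.csv"))
    write_fixed_table(cres, file.path(out, "curated_recall.txt"))
  }

  # unique mappings vs the vote-2 consensus, with review sheets
  v2 <- if ("v2" %in% names(cons)) cons[["v2"]] else consensus(vt, 2)
  idx2 <- build_index(o1, o2, v2)
  uniq <- lapply(seq_along(systems), function(i) {
    u <- unique_mappings(systems[[i]], systems[-i], idx2)
    say("unique mappings of %s: %d", systems[[i]]$system_name,
        nrow(u$mappings))
    smp <- sample_for_assessment(u, cap = cfg$assessment_cap,
                                 seed = derive_seed(cfg$seed, 500 + i))
    write_review_sheet(smp, o1, o2, file.path(
      out, sprintf("review_%s.tsv", systems[[i]]$system_name)))
    u
  })
  usum <- data.frame(
    System = vapply(systems, `[[`, character(1), "system_name"),
    Unique.mappings = vapply(uniq, function(u) nrow(u$mappings),
                             integer(1)), stringsAsFactors = FALSE)
  write_csv_plain(usum, file.path(out, "unique_mappings.csv"))
  write_fixed_table(usum, file.path(out, "unique_mappings.txt"))

  inputs <- c(cfg$ontology1, cfg$ontology2, cfg$baseline, cfg$curated,
              vapply(cfg$systems, `[[`, character(1), "path"))
  manifest <- list(
    seed = cfg$seed,
    vote_thresholds = cfg$vote_thresholds,
    assessment_cap = cfg$assessment_cap,
    inputs = lapply(inputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    n_systems = length(systems),
    consensus_sizes = setNames(as.list(sweep$n_mappings),
                               sprintf("v%d", sweep$min_votes)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, file.path(out, "run.log"))
  invisible(list(consensus = cons, sweep = sweep, results = res,
                 unique = uniq, manifest = manifest, log = log))
}
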