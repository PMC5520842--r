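# Pipeline orchestration: a single structured config drives the staged
# analysis (identify -> tree / kaks / duplications -> dating ->
# expression), writing every intermediate artifact plus a machine-readable
# manifest, and report writers shaped like the family's summary tables.

pipeline_defaults <- function() {
  list(
    pattern = "SPYxEVRxxVxxxDDP",
    params_window = NULL,
    gap_policy = "complete",
    replicates = 1000L,
    lambda = RICE_LAMBDA,
    max_intervening = 20L,
    max_gap = 100000,
    min_anchors = 5L,
    fold_threshold = 2,
    pseudo = 1,
    min_tpm = 1,
    epsilon = 0
  )
}

known_config_keys <- c("inputs", "stages", "params", "outdir", "seed",
                       "verbosity")
known_input_keys <- c("proteins", "alignment", "cds", "pairs", "kaks_table",
                      "gene_map", "blocks", "anchors", "counts",
                      "contrasts", "overrides", "references", "outgroup")
known_stage_keys <- c("identify", "tree", "kaks", "dups", "date", "express")

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(config$inputs), known_input_keys)
  if (length(unknown))
    stop("unknown input keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(config$stages), known_stage_keys)
  if (length(unknown))
    stop("unknown stage toggles: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(config$params), names(pipeline_defaults()))
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config$params <- utils::modifyList(pipeline_defaults(),
                                     config$params %||% list())
  if (is.null(config$outdir)) stop("config needs an outdir", call. = FALSE)
  config$verbosity <- config$verbosity %||% 0L
  stages <- stats::setNames(as.list(rep(TRUE, length(known_stage_keys))),
                            known_stage_keys)
  config$stages <- utils::modifyList(stages, config$stages %||% list())
  # referenced input paths must exist before any stage runs
  for (key in names(config$inputs)) {
    p <- config$inputs[[key]]
    if (is.character(p) && length(p) == 1L && key != "outgroup" &&
        !file.exists(p))
      stop("input path for '", key, "' does not exist: ", p, call. = FALSE)
  }
  # cross-stage requirements checked up front, before execution
  if (isTRUE(config$stages$kaks) &&
      is.null(config$inputs$kaks_table) &&
      (is.null(config$inputs$cds) || is.null(config$inputs$pairs)))
    stop("kaks stage enabled but no cds+pairs (or kaks_table) input",
         call. = FALSE)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_pairs_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the staged gene-family expansion pipeline
#'
#' Executes the toggled stages — family identification, NJ tree with
#' bootstrap, Ka/Ks estimation, duplication classification, clock dating
#' with stage assignment, and expression diversification — from a single
#' structured config (a list, or the path of a YAML file). Every stage
#' writes its artifact into `outdir`; a manifest records package and R
#' versions, the seed, all parameter values and an md5 checksum per
#' artifact, so a rerun with an unchanged config is bit-identical.
#'
#' @param config Configuration list or YAML path. Recognised top-level
#'   keys: `inputs` (paths: `proteins`, `alignment`, `cds`, `pairs`,
#'   `kaks_table`, `gene_map`, `blocks`, `anchors`, `counts`, `contrasts`,
#'   `overrides`, `references`, `outgroup`), `stages` (logical toggles
#'   `identify`, `tree`, `kaks`, `dups`, `date`, `express`), `params`
#'   (see `optfam:::pipeline_defaults()`), `outdir`, `seed`, `verbosity`.
#'   Unknown keys are rejected.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  say <- function(...) if (config$verbosity > 0) message("[optfam] ", ...)
  artifacts <- character()
  emit <- function(x, name) {
    path <- file.path(config$outdir, name)
    if (inherits(x, "phylo")) write_newick(x, path) else write_tsv(x, path)
    artifacts <<- c(artifacts, path)
    path
  }
  outputs <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (isTRUE(config$stages$identify) && !is.null(config$inputs$proteins)) {
    say("identify: screening candidates")
    run_stage("identify", function() {
      cands <- read_protein_fasta(config$inputs$proteins)
      fam <- filter_family(cands, p$pattern, p$params_window %||% list())
      outputs$family <<- fam
      emit(fam, "family.tsv")
    })
  }

  if (isTRUE(config$stages$tree) && !is.null(config$inputs$alignment)) {
    say("tree: NJ with ", p$replicates, " bootstrap replicates")
    run_stage("tree", function() {
      aln <- read_protein_fasta(config$inputs$alignment)
      bs <- bootstrap_support(aln, replicates = p$replicates,
                              seed = config$seed,
                              gap_policy = p$gap_policy)
      outputs$tree <<- bs$tree
      emit(bs$tree, "tree.nwk")
      emit(bs$support, "tree_support.tsv")
      refs_path <- config$inputs$references
      if (!is.null(refs_path) && !is.null(config$inputs$outgroup)) {
        refs <- read_pairs_tsv(refs_path)   # columns taxon, group
        labels <- assign_clades(bs$tree,
                                stats::setNames(refs$group, refs$taxon),
                                config$inputs$outgroup)
        outputs$clades <<- labels
        emit(labels, "clades.tsv")
      }
    })
  }

  if (isTRUE(config$stages$kaks)) {
    say("kaks: Nei-Gojobori estimation")
    run_stage("kaks", function() {
      if (!is.null(config$inputs$kaks_table)) {
        kk <- read_pairs_tsv(config$inputs$kaks_table)
        kk$ratio <- ifelse(kk$Ks > 0, kk$Ka / kk$Ks, NA_real_)
        kk$selection <- vapply(kk$ratio, classify_selection, character(1),
                               epsilon = p$epsilon)
      } else {
        cds <- read_cds_fasta(config$inputs$cds)
        prs <- read_pairs_tsv(config$inputs$pairs)
        aln <- if (!is.null(config$inputs$alignment))
          read_protein_fasta(config$inputs$alignment) else NULL
        kk <- kaks_pairs(cds, prs, aln, epsilon = p$epsilon)
      }
      outputs$kaks <<- kk
      emit(kk, "kaks.tsv")
    })
  }

  if (isTRUE(config$stages$dups) && !is.null(config$inputs$gene_map)) {
    say("dups: tandem/segmental classification")
    run_stage("dups", function() {
      map <- read_gene_map(config$inputs$gene_map)
      blocks <- NULL
      if (!is.null(config$inputs$blocks)) {
        blocks <- read_pairs_tsv(config$inputs$blocks)
        if (!is.null(config$inputs$anchors))
          attr(blocks, "anchors") <- read_pairs_tsv(config$inputs$anchors)
      } else if (!is.null(config$inputs$anchors)) {
        blocks <- find_collinear_blocks(
          read_pairs_tsv(config$inputs$anchors),
          max_gap = p$max_gap, min_anchors = p$min_anchors)
      }
      prs <- if (!is.null(outputs$kaks)) outputs$kaks[, c("id_a", "id_b")]
             else read_pairs_tsv(config$inputs$pairs)
      ev <- classify_duplication(prs, map, blocks,
                                 max_intervening = p$max_intervening)
      outputs$events <<- ev
      emit(ev, "duplication_events.tsv")
    })
  }

  if (isTRUE(config$stages$date) && !is.null(outputs$kaks) &&
      !is.null(outputs$events)) {
    say("date: molecular-clock dating and staging")
    run_stage("date", function() {
      cfg <- stage_config()
      cfg$lambda <- p$lambda
      overrides <- if (!is.null(config$inputs$overrides))
        read_pairs_tsv(config$inputs$overrides) else NULL
      rep <- build_event_report(outputs$kaks, outputs$events, cfg,
                                overrides, epsilon = p$epsilon)
      outputs$report <<- rep
      emit(rep, "event_report.tsv")
    })
  }

  if (isTRUE(config$stages$express) && !is.null(config$inputs$counts)) {
    say("express: tpm normalization and diversification")
    run_stage("express", function() {
      counts <- read_counts_tsv(config$inputs$counts)
      tpm <- normalize_tpm(counts)
      contrasts <- read_pairs_tsv(config$inputs$contrasts)
      prof <- response_profiles(tpm, contrasts, p$fold_threshold,
                                p$pseudo, p$min_tpm)
      outputs$profiles <<- prof
      emit(as.data.frame(tpm), "tpm.tsv")
      emit(prof, "response_calls.tsv")
      if (!is.null(outputs$kaks)) {
        tissue_libs <- grep("^tissue", colnames(tpm), value = TRUE)
        if (length(tissue_libs)) {
          pres <- call_presence(tpm[, tissue_libs, drop = FALSE], p$min_tpm)
          div <- diversification_matrix(
            outputs$kaks[, c("id_a", "id_b")], pres, prof,
            classes = c("tissues", unique(contrasts$class)))
          outputs$diversification <<- div
          emit(div, "diversification.tsv")
        }
      }
    })
  }

  manifest <- list(
    package = "optfam",
    version = as.character(utils::packageVersion("optfam")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    params = p,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(outputs, list(manifest = manifest)))
}

#' Write summary reports shaped like the family's published tables
#'
#' Emits the family summary (basic protein information), the duplication
#' event table (Ka, Ks, Ka/Ks, date, duplicate type, purifying yes/no)
#' and the expression-diversification matrix (`+`/`-`) as TSVs, plus a
#' JSON summary carrying the full-precision values.
#'
#' @param outputs List with any of `family` (from [filter_family()]),
#'   `report` (from [build_event_report()]), `diversification` (from
#'   [diversification_matrix()]).
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(outputs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(outputs$family)) {
    t1 <- outputs$family
    names(t1) <- c("Locus ID", "Length(aa)", "MW (KDa)", "pI", "TM",
                   "Motif position(s)")[seq_along(t1)]
    paths <- c(paths, write_tsv(t1, file.path(outdir, "table1.tsv")))
  }
  if (!is.null(outputs$report)) {
    r <- outputs$report
    t2 <- data.frame(
      "Duplicated pair" = r$pair,
      "Ka" = sprintf("%.4f", r$Ka),
      "Ks" = sprintf("%.4f", r$Ks),
      "Ka/Ks" = sprintf("%.4f", r$ratio),
      "Date (million years)" = sprintf("%.2f", r$date_my),
      "Duplicate type" = paste0(toupper(substring(r$mechanism, 1, 1)),
                                substring(r$mechanism, 2)),
      "Purifying selection" = r$purifying,
      check.names = FALSE, stringsAsFactors = FALSE)
    paths <- c(paths, write_tsv(t2, file.path(outdir, "table2.tsv")))
  }
  if (!is.null(outputs$diversification)) {
    paths <- c(paths, write_tsv(outputs$diversification,
                                file.path(outdir, "table3.tsv")))
  }
  summary <- list(
    family = outputs$family,
    events = outputs$report,
    diversification = outputs$diversification)
  summary <- summary[!vapply(summary, is.null, logical(1))]
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(c(paths, file.path(outdir, "summary.json")))
}
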